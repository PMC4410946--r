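#' Canonical parameter names of the neural mass model
#'
#' The model has ten parameters, always kept in this order: four connection
#' strengths `g1..g4` (dimensionless), the intrinsic delay `delta` (ms), the
#' inhibitory membrane rate constant `tau_i` (ms) and maximum post-synaptic
#' amplitude `h_i` (mV), their excitatory counterparts `tau_e` and `h_e`, and
#' the input magnitude `u`.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' nmm_param_names()
nmm_param_names <- function() {
  c("g1", "g2", "g3", "g4", "delta", "tau_i", "h_i", "tau_e", "h_e", "u")
}

#' Construct a neural-mass-model parameter vector
#'
#' Builds a named numeric vector in the canonical parameter order. All
#' parameters must be strictly positive (they live on the support of the
#' Gamma priors).
#'
#' @param g1,g2,g3,g4 Connection strengths (dimensionless).
#' @param delta Intrinsic delay (ms).
#' @param tau_i,tau_e Membrane rate constants (ms).
#' @param h_i,h_e Maximum post-synaptic amplitudes (mV).
#' @param u Magnitude of the Heaviside input to the spiny-stellate cells.
#' @return Named numeric vector of length 10, class `nmm_params`.
#' @export
#' @examples
#' nmm_params(0.42, 0.76, 0.15, 0.16, 12.13, 7.77, 27.88, 5.77, 1.63, 3.94)
nmm_params <- function(g1, g2, g3, g4, delta, tau_i, h_i, tau_e, h_e, u) {
  theta <- c(g1 = g1, g2 = g2, g3 = g3, g4 = g4, delta = delta,
             tau_i = tau_i, h_i = h_i, tau_e = tau_e, h_e = h_e, u = u)
  as_nmm_params(theta)
}

#' Coerce to a canonical parameter vector
#'
#' Accepts a numeric vector of length 10 (named in any order using the
#' canonical names, or unnamed and taken to be in canonical order) and returns
#' it named and ordered.
#'
#' @param theta Numeric vector of length 10.
#' @param check_positive Require all entries strictly positive (default TRUE).
#' @return Named numeric vector of length 10.
#' @export
as_nmm_params <- function(theta, check_positive = TRUE) {
  theta <- unclass(theta)
  if (!is.numeric(theta) || length(theta) != 10L) {
    stop("a parameter vector must be numeric of length 10", call. = FALSE)
  }
  nms <- nmm_param_names()
  if (!is.null(names(theta)) && all(nzchar(names(theta)))) {
    if (!setequal(names(theta), nms)) {
      stop("parameter names must be exactly {", paste(nms, collapse = ", "),
           "}", call. = FALSE)
    }
    theta <- theta[nms]
  } else {
    names(theta) <- nms
  }
  if (check_positive && !all(is.finite(theta) & theta > 0)) {
    stop("all 10 parameters must be finite and strictly positive",
         call. = FALSE)
  }
  theta
}

#' Ground-truth parameters of the reference simulation
#'
#' The parameter values used throughout the package to generate the reference
#' synthetic dataset. The same values are the defaults of
#' [make_ground_truth()].
#'
#' @return Named numeric vector of length 10.
#' @export
#' @examples
#' nmm_true_params()
nmm_true_params <- function() {
  nmm_params(g1 = 0.42, g2 = 0.76, g3 = 0.15, g4 = 0.16, delta = 12.13,
             tau_i = 7.77, h_i = 27.88, tau_e = 5.77, h_e = 1.63, u = 3.94)
}
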