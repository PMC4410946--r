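#' Jacobian of the model right-hand side
#'
#' The 9x9 matrix of partial derivatives of [nmm_rhs()] with respect to the
#' states, at a given state, either in closed form (`"analytic"`, the
#' default) or by central finite differences with relative step 1e-6
#' (`"numeric"`, kept as a cross-check).
#'
#' @param params Parameter vector.
#' @param state State at which to linearise (length 9).
#' @param input_value Input value held constant during differentiation.
#' @param delay_mode See [sim_control()].
#' @param method `"analytic"` or `"numeric"`.
#' @return A 9x9 numeric matrix, rows ordered `x1..x9`.
#' @export
nmm_jacobian <- function(params, state, input_value = 0,
                         delay_mode = c("taylor1", "none"),
                         method = c("analytic", "numeric")) {
  delay_mode <- match.arg(delay_mode)
  method <- match.arg(method)
  p <- as_nmm_params(params)
  x <- as.numeric(state)
  stopifnot(length(x) == 9L)
  if (method == "numeric") {
    J <- matrix(0, 9, 9)
    for (j in 1:9) {
      h <- 1e-6 * max(1, abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      J[, j] <- (nmm_rhs(xp, p, input_value, delay_mode) -
                   nmm_rhs(xm, p, input_value, delay_mode)) / (2 * h)
    }
    return(J)
  }
  del <- if (delay_mode == "taylor1") p[["delta"]] else 0
  te <- p[["tau_e"]]; ti <- p[["tau_i"]]
  he <- p[["h_e"]]; hi <- p[["h_i"]]
  d9 <- x[9] - del * (x[5] - x[6])
  d1 <- x[1] - del * x[4]
  d7 <- x[7] - del * x[8]
  s9 <- nmm_sigmoid_deriv(d9)
  s1 <- nmm_sigmoid_deriv(d1)
  s7 <- nmm_sigmoid_deriv(d7)
  J <- matrix(0, 9, 9)
  J[1, 4] <- 1
  J[2, 5] <- 1
  J[3, 6] <- 1
  # xdot4 = he (g1 S(d9) + U)/te - x1/te^2 - 2 x4/te
  a4 <- he * p[["g1"]] * s9 / te
  J[4, 9] <- a4; J[4, 5] <- -del * a4; J[4, 6] <- del * a4
  J[4, 1] <- -1 / te^2; J[4, 4] <- J[4, 4] - 2 / te
  # xdot5 = g2 he S(d1)/te - x2/te^2 - 2 x5/te
  a5 <- p[["g2"]] * he * s1 / te
  J[5, 1] <- J[5, 1] + a5; J[5, 4] <- J[5, 4] - del * a5
  J[5, 2] <- -1 / te^2; J[5, 5] <- J[5, 5] - 2 / te
  # xdot6 = g4 hi S(d7)/ti - x3/ti^2 - 2 x6/ti
  a6 <- p[["g4"]] * hi * s7 / ti
  J[6, 7] <- a6; J[6, 8] <- -del * a6
  J[6, 3] <- -1 / ti^2; J[6, 6] <- J[6, 6] - 2 / ti
  J[7, 8] <- 1
  # xdot8 = g3 he S(d9)/te - x7/te^2 - 2 x8/te
  a8 <- p[["g3"]] * he * s9 / te
  J[8, 9] <- a8; J[8, 5] <- -del * a8; J[8, 6] <- del * a8
  J[8, 7] <- J[8, 7] - 1 / te^2; J[8, 8] <- J[8, 8] - 2 / te
  J[9, 5] <- 1; J[9, 6] <- -1
  J
}

#' Find a fixed point of the driven model
#'
#' Solves the steady-state equations under a constant input. Because the
#' pyramidal voltage `x9` integrates `x5 - x6`, the quantity `x9 - x2 + x3`
#' is conserved along every trajectory and fixed points form a
#' one-dimensional family; the solver therefore replaces the (identically
#' satisfied) ninth equation by the conservation constraint
#' `x9 - x2 + x3 = conserved`, which pins down the equilibrium reachable from
#' the zero initial state. The square system is solved by Levenberg-Marquardt
#' with the analytic Jacobian, starting from the origin and retrying from up
#' to `n_restarts` small seeded perturbations.
#'
#' @param params Parameter vector.
#' @param input_value Constant input (defaults to the parameter `u`: the
#'   steady state under the sustained Heaviside input).
#' @param delay_mode See [sim_control()].
#' @param tol Residual tolerance (infinity norm) for convergence.
#' @param n_restarts Number of perturbed restarts after the origin start.
#' @param conserved Value of `x9 - x2 + x3` (0 for the zero initial state).
#' @return A list with `state` (length-9 fixed point), `converged` (logical)
#'   and `residual` (infinity norm of the right-hand side at `state`).
#' @export
nmm_fixed_point <- function(params, input_value = NULL,
                            delay_mode = c("taylor1", "none"),
                            tol = 1e-8, n_restarts = 5, conserved = 0) {
  delay_mode <- match.arg(delay_mode)
  p <- as_nmm_params(params)
  if (is.null(input_value)) input_value <- p[["u"]]

  resid_fn <- function(x) {
    r <- nmm_rhs(x, p, input_value, delay_mode)
    r[9] <- x[9] - x[2] + x[3] - conserved
    r
  }
  jac_fn <- function(x) {
    J <- nmm_jacobian(p, x, input_value, delay_mode)
    J[9, ] <- 0
    J[9, 9] <- 1; J[9, 2] <- -1; J[9, 3] <- 1
    J
  }
  solve_from <- function(start) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-15, ptol = 1e-15))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    x <- unname(fit$par)
    res <- max(abs(resid_fn(x)))
    list(state = x, residual = res)
  }

  starts <- list(rep(0, 9))
  if (n_restarts > 0) {
    # deterministic perturbed starts (fixed internal seed, global RNG state
    # preserved) so repeated solves are identical
    scale <- max(1, abs(input_value))
    starts <- c(starts, local_rng(20240601L, {
      lapply(seq_len(n_restarts), function(k) rnorm(9, sd = scale * k))
    }))
  }
  best <- list(state = rep(0, 9), residual = Inf)
  for (start in starts) {
    sol <- solve_from(start)
    if (!is.null(sol) && sol$residual < best$residual) best <- sol
    if (best$residual < tol) break
  }
  rhs_res <- max(abs(nmm_rhs(best$state, p, input_value, delay_mode)))
  list(state = best$state,
       converged = best$residual < tol,
       residual = rhs_res)
}

# eigenvalues of the flow restricted to the invariant subspace
# x9 - x2 + x3 = const (removes the structural zero mode of the integrator
# state x9); returns the 8 eigenvalues
nmm_reduced_eigenvalues <- function(J) {
  A <- J[1:8, 1:8]
  A[, 2] <- A[, 2] + J[1:8, 9]
  A[, 3] <- A[, 3] - J[1:8, 9]
  eigen(A, only.values = TRUE)$values
}

#' Linear stability of the model at its fixed point
#'
#' Finds the fixed point under sustained input, linearises there, and
#' classifies the dynamics by the eigenvalues of the Jacobian. One eigenvalue
#' of the full 9x9 Jacobian is structurally zero (the conserved combination
#' `x9 - x2 + x3`); `max_real_eig` is therefore taken over the spectrum of
#' the flow restricted to the dynamically relevant 8-dimensional subspace,
#' and the model is stable exactly when that maximum real part is negative.
#' Non-converged fixed-point solves are classified unstable.
#'
#' @inheritParams nmm_fixed_point
#' @return A list of class `nmm_stability` with fields `fixed_point`,
#'   `jacobian` (full 9x9), `max_real_eig`, `stable`, `converged`.
#' @export
#' @examples
#' nmm_stability(nmm_true_params())$stable
nmm_stability <- function(params, input_value = NULL,
                          delay_mode = c("taylor1", "none"),
                          tol = 1e-8, n_restarts = 5) {
  delay_mode <- match.arg(delay_mode)
  p <- as_nmm_params(params)
  if (is.null(input_value)) input_value <- p[["u"]]
  fp <- nmm_fixed_point(p, input_value, delay_mode, tol = tol,
                        n_restarts = n_restarts)
  if (!fp$converged) {
    return(structure(list(fixed_point = fp$state, jacobian = NULL,
                          max_real_eig = NA_real_, stable = FALSE,
                          converged = FALSE),
                     class = "nmm_stability"))
  }
  J <- nmm_jacobian(p, fp$state, input_value, delay_mode)
  mre <- max(Re(nmm_reduced_eigenvalues(J)))
  structure(list(fixed_point = fp$state, jacobian = J, max_real_eig = mre,
                 stable = mre < 0, converged = TRUE),
            class = "nmm_stability")
}

#' Census of dynamical instability under the prior
#'
#' Draws `n` parameter vectors i.i.d. from the Gamma priors and reports the
#' fraction whose dynamics are classified unstable by [nmm_stability()]
#' (evaluated at the steady state under the drawn input `u`). The reference
#' prior is calibrated so that roughly half the draws are unstable.
#'
#' @param n Number of prior draws.
#' @param prior An [nmm_prior()] table.
#' @param seed Integer seed making the census reproducible.
#' @param delay_mode See [sim_control()].
#' @param input `"on"` evaluates stability under the sustained input `u`
#'   (the regime in which observations are made); `"off"` at zero input.
#' @return A list with `n`, `fraction_unstable`, `seed`, and the logical
#'   vector `unstable`.
#' @export
#' @examples
#' instability_census(50, seed = 1)$fraction_unstable
instability_census <- function(n, prior = nmm_prior(), seed = 1,
                               delay_mode = c("taylor1", "none"),
                               input = c("on", "off")) {
  stopifnot(n >= 1)
  delay_mode <- match.arg(delay_mode)
  input <- match.arg(input)
  prior <- as_nmm_prior(prior)
  set.seed(seed)
  draws <- as.matrix(draw_prior(n, prior))
  unstable <- vapply(seq_len(n), function(i) {
    theta <- draws[i, ]
    iv <- if (input == "on") theta[["u"]] else 0
    !nmm_stability(theta, input_value = iv, delay_mode = delay_mode)$stable
  }, logical(1))
  list(n = n, fraction_unstable = mean(unstable), seed = seed,
       unstable = unstable)
}
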