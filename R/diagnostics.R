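degenerate_series <- function() {
  structure(class = c("nmm_degenerate_series", "error", "condition"),
            list(message = "series is constant or non-finite; autocorrelation undefined",
                 call = NULL))
}

#' Normalized autocorrelation function of a series
#'
#' Autocorrelations `rho_q` for lags `0 .. lag_max` with the biased `1/R`
#' normalization (`rho_0 = 1`), computed via the FFT so that the full lag
#' range of a long chain is affordable.
#'
#' @param x Numeric series (length >= 2, non-constant).
#' @param lag_max Largest lag (default `length(x) - 1`).
#' @return Numeric vector of length `lag_max + 1`; element `q + 1` is the
#'   lag-`q` autocorrelation. Signals an error of class
#'   `nmm_degenerate_series` for constant or non-finite input.
#' @export
#' @examples
#' autocorrelation(rnorm(100), lag_max = 3)
autocorrelation <- function(x, lag_max = length(x) - 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 || any(!is.finite(x)) || var(x) == 0) stop(degenerate_series())
  lag_max <- min(lag_max, n - 1)
  xc <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- fft(c(xc, rep(0, m - n)))
  ac <- Re(fft(Mod(f)^2, inverse = TRUE))[1:(lag_max + 1)] / m
  ac / ac[1]
}

#' Effective sample size (initial monotone sequence estimator)
#'
#' Estimates `ESS = R / (1 + 2 * sum_q rho_q)` with the autocorrelation sum
#' truncated by Geyer's initial monotone sequence rule: adjacent-lag pair
#' sums `Gamma_m = rho_{2m} + rho_{2m+1}` are kept while positive, forced to
#' be non-increasing by taking running minima, and the sum stops at the
#' first non-positive pair. The estimate is clamped to `[1, R]`.
#'
#' @param x Numeric series (length >= 4, non-constant).
#' @return Scalar effective sample size.
#' @export
#' @examples
#' set.seed(1)
#' ess(rnorm(1000))
ess <- function(x) {
  n <- length(x)
  if (n < 4) stop("`x` must have at least 4 values", call. = FALSE)
  rho <- autocorrelation(x)
  n_pairs <- floor(n / 2)
  gsum <- 0
  running_min <- Inf
  for (m in seq_len(n_pairs) - 1L) {
    if (2 * m + 2 > n) break
    g <- rho[2 * m + 1] + rho[2 * m + 2]
    if (g <= 0) break
    running_min <- min(running_min, g)
    gsum <- gsum + running_min
  }
  tau <- 2 * gsum - 1
  if (tau <= 0) return(n)
  min(max(n / tau, 1), n)
}

#' Efficiency report for a chain
#'
#' Summarises a sampler run the way the samplers are compared throughout the
#' package: per-parameter effective sample sizes on the retained draws, their
#' mean and minimum, the wall time, the time needed per effectively
#' independent sample (`wall_time / min ESS` — the worst-case cost), and the
#' l2 error of the trajectory predicted at the posterior-mean parameters.
#'
#' @param chain An `nmm_chain` from [run_sampler()].
#' @param data The dataset the chain was run on (an `nmm_dataset` or
#'   [nmm_obs()]).
#' @param reference Residual reference for the l2 error: `"observed"`
#'   compares the posterior-mean prediction with the observed voltages (the
#'   default — all samplers are compared on the same fixed data);
#'   `"truth"` compares with the noiseless trajectory at the true
#'   parameters (requires an `nmm_dataset`).
#' @return One-row tibble of class `nmm_efficiency` with columns `sampler`,
#'   `time_min`, `mean_ess`, `min_ess`, `time_per_min_ess`, `l2_error` and a
#'   list column `ess` holding the ten per-parameter values. Parameters
#'   whose retained series is degenerate (a stuck chain) are reported with
#'   `ESS = 1`.
#' @export
efficiency_report <- function(chain, data,
                              reference = c("observed", "truth")) {
  reference <- match.arg(reference)
  obs <- nmm_obs(data)
  ret <- retained(chain)
  if (nrow(ret) < 4) stop("need at least 4 retained samples", call. = FALSE)
  pars <- nmm_param_names()
  ess_vec <- vapply(pars, function(p) {
    tryCatch(ess(ret[[p]]),
             nmm_degenerate_series = function(e) 1)
  }, numeric(1))
  post_mean <- vapply(pars, function(p) mean(ret[[p]]), numeric(1))
  pred <- nmm_predict(as_nmm_params(post_mean), obs$control, times = obs$time)
  ref <- if (reference == "observed") {
    obs$y
  } else {
    if (!inherits(data, "nmm_dataset")) {
      stop("`reference = \"truth\"` needs an nmm_dataset", call. = FALSE)
    }
    nmm_predict(as_nmm_params(data$true_params), obs$control,
                times = obs$time)
  }
  l2 <- if (is.null(pred) || is.null(ref)) NA_real_ else sqrt(sum((pred - ref)^2))
  time_min <- attr(chain, "wall_time") / 60
  out <- tibble::tibble(
    sampler = attr(chain, "sampler") %||% NA_character_,
    time_min = time_min,
    mean_ess = mean(ess_vec),
    min_ess = min(ess_vec),
    time_per_min_ess = time_min / min(ess_vec),
    l2_error = l2,
    ess = list(ess_vec))
  class(out) <- c("nmm_efficiency", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
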