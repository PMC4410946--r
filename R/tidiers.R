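#' Posterior summary of a chain
#'
#' One row per model parameter: posterior mean, standard deviation, median,
#' central 95% interval and effective sample size, all computed on the
#' retained (post-burn-in) draws.
#'
#' @param x An `nmm_chain` from [run_sampler()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `median`,
#'   `q2.5`, `q97.5`, `ess`.
#' @export
tidy.nmm_chain <- function(x, ...) {
  ret <- retained(x)
  purrr::map_dfr(nmm_param_names(), function(p) {
    v <- ret[[p]]
    tibble::tibble(
      parameter = p,
      mean = mean(v),
      sd = sd(v),
      median = stats::median(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)),
      ess = tryCatch(ess(v), nmm_degenerate_series = function(e) 1))
  })
}

#' One-row summary of a chain
#'
#' @param x An `nmm_chain`.
#' @param ... Unused.
#' @return A tibble with the sampler name, run sizes, acceptance rate over
#'   the retained draws, wall time and ESS summaries.
#' @export
glance.nmm_chain <- function(x, ...) {
  ret <- retained(x)
  td <- tidy(x)
  tibble::tibble(
    sampler = attr(x, "sampler"),
    n_total = nrow(x),
    n_burn = attr(x, "n_burn"),
    n_retained = nrow(ret),
    acceptance_rate = mean(ret$accepted),
    wall_time_min = attr(x, "wall_time") / 60,
    mean_ess = mean(td$ess),
    min_ess = min(td$ess))
}

#' Tidy a stability analysis
#'
#' @param x An `nmm_stability` from [nmm_stability()].
#' @param ... Unused.
#' @return One-row tibble with `stable`, `converged`, `max_real_eig` and the
#'   fixed-point pyramidal voltage.
#' @export
tidy.nmm_stability <- function(x, ...) {
  tibble::tibble(stable = x$stable, converged = x$converged,
                 max_real_eig = x$max_real_eig,
                 fixed_point_x9 = x$fixed_point[9])
}
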