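#' Benchmark the four samplers on one dataset
#'
#' Runs every requested sampler configuration on the same dataset under the
#' same run protocol and collects one [efficiency_report()] row per
#' configuration. Each configuration gets its own seed derived from the
#' master seed by stable hashing, so adding or removing a configuration
#' never changes the others' draws. A failing configuration is isolated: its
#' row is kept with `failed = TRUE` and the error message, and the remaining
#' rows are unaffected.
#'
#' @param data An `nmm_dataset` (or anything [nmm_obs()] accepts, with
#'   `sigma` supplied through `...`).
#' @param prior An [nmm_prior()] table.
#' @param samplers Character vector drawn from `"slice"`, `"rwm"`,
#'   `"adaptive"`, `"population_power"`, `"population_uniform"`.
#' @param n_total,n_burn,n_adapt Run protocol shared by all configurations.
#' @param seed Master seed.
#' @param ... Further arguments passed to [run_sampler()] (e.g.
#'   `proposal_scale`, `n_chains`).
#' @return A tibble of class `nmm_benchmark`: the efficiency-report columns
#'   plus `failed` and `error`; the fitted chains are attached as the
#'   `chains` attribute (named list).
#' @export
run_benchmark <- function(data, prior = nmm_prior(),
                          samplers = c("slice", "rwm", "adaptive",
                                       "population_power",
                                       "population_uniform"),
                          n_total = 2000, n_burn = 600, n_adapt = 300,
                          seed = 1, ...) {
  known <- c("slice", "rwm", "adaptive", "population_power",
             "population_uniform")
  stopifnot(all(samplers %in% known))
  chains <- list()
  rows <- lapply(samplers, function(name) {
    args <- list(data = data, prior = prior,
                 n_total = n_total, n_burn = n_burn, n_adapt = n_adapt,
                 seed = seed_from(seed, name), ...)
    if (name %in% c("population_power", "population_uniform")) {
      args$sampler <- "population"
      args$schedule <- sub("population_", "", name)
    } else {
      args$sampler <- name
    }
    res <- tryCatch({
      chain <- do.call(run_sampler, args)
      chains[[name]] <<- chain
      rep <- efficiency_report(chain, data)
      rep$sampler <- name
      rep$failed <- FALSE
      rep$error <- NA_character_
      rep
    }, error = function(e) {
      tibble::tibble(sampler = name, time_min = NA_real_,
                     mean_ess = NA_real_, min_ess = NA_real_,
                     time_per_min_ess = NA_real_, l2_error = NA_real_,
                     ess = list(NULL), failed = TRUE,
                     error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "chains") <- chains
  attr(out, "seed") <- seed
  class(out) <- c("nmm_benchmark", class(out))
  out
}

#' Render a benchmark as a text table
#'
#' @param x An `nmm_benchmark`.
#' @param ... Unused.
#' @export
print.nmm_benchmark <- function(x, ...) {
  tab <- data.frame(Sampler = x$sampler,
                    `Time (min)` = round(x$time_min, 3),
                    `Mean ESS` = round(x$mean_ess, 2),
                    `Min ESS` = round(x$min_ess, 2),
                    `Time/min ESS` = round(x$time_per_min_ess, 3),
                    `l2 error` = round(x$l2_error, 2),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}
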