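#' Plot a simulated trajectory
#'
#' Pyramidal voltage against time by default; `states = TRUE` facets all
#' nine states.
#'
#' @param object An `nmm_trajectory` from [nmm_simulate()].
#' @param states Plot all states rather than just the observable?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmm_trajectory <- function(object, states = FALSE, ...) {
  if (!states) {
    return(ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$x9)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "time (ms)", y = "pyramidal voltage (mV)"))
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "state", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL)
}

#' Trace plots of a chain
#'
#' Faceted parameter traces with the burn-in boundary marked.
#'
#' @param object An `nmm_chain`.
#' @param parameters Which parameters to show (default all ten).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmm_chain <- function(object, parameters = nmm_param_names(), ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("iter", parameters)],
    -"iter", names_to = "parameter", values_to = "value")
  long$parameter <- factor(long$parameter, levels = parameters)
  ggplot2::ggplot(long, ggplot2::aes(.data$iter, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = attr(object, "n_burn"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = paste0("sampler: ", attr(object, "sampler")))
}

#' Compare samplers in a benchmark
#'
#' Bar chart of mean ESS and of the time per effectively independent
#' sample.
#'
#' @param object An `nmm_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmm_benchmark <- function(object, ...) {
  keep <- !object$failed
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object[keep, c("sampler", "mean_ess",
                                     "time_per_min_ess")]),
    -"sampler", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$sampler, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
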