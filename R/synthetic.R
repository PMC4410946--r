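#' Generate the reference synthetic dataset
#'
#' Integrates the model at the ground-truth parameters and adds i.i.d.
#' Gaussian noise of standard deviation `sigma` to the pyramidal voltage
#' (only the observable is noised; hidden states are never observed).
#' When `sigma` is `NULL` it defaults to 10% of the standard deviation of
#' the noiseless voltage trace, keeping the signal-to-noise ratio fixed
#' regardless of the simulation window.
#'
#' @param sigma Noise standard deviation (>= 0), or `NULL` for the
#'   SNR-matched default.
#' @param seed Integer seed; regenerating with the same seed reproduces the
#'   observations bitwise.
#' @param control A [sim_control()].
#' @param params True parameters (defaults to [nmm_true_params()]).
#' @return A list of class `nmm_dataset` with fields `data` (tibble
#'   `time`, `voltage`), `true_params`, `sigma`, `seed`, `control`.
#' @export
#' @examples
#' ds <- make_ground_truth(seed = 1)
#' head(ds$data)
make_ground_truth <- function(sigma = NULL, seed = 1,
                              control = sim_control(),
                              params = nmm_true_params()) {
  params <- as_nmm_params(params)
  traj <- nmm_simulate(params, control) # fatal if the truth is unstable
  x9 <- traj$x9
  if (is.null(sigma)) sigma <- 0.1 * sd(x9)
  stopifnot(sigma >= 0)
  noise <- local_rng(seed, rnorm(length(x9), sd = sigma))
  structure(list(data = tibble::tibble(time = traj$time,
                                       voltage = x9 + noise),
                 true_params = params, sigma = sigma, seed = seed,
                 control = control),
            class = "nmm_dataset")
}

#' Generate a dataset from a random stable draw of the prior
#'
#' Rejection-samples the prior until a dynamically stable parameter vector
#' is found (by [nmm_stability()] under the drawn input), then proceeds as
#' [make_ground_truth()] with that truth. Used for parameter-recovery
#' studies beyond the single reference truth.
#'
#' @param prior An [nmm_prior()] table.
#' @param sigma,seed,control As in [make_ground_truth()].
#' @param max_draws Give up (with an error) after this many unstable draws.
#' @return An `nmm_dataset`; `true_params` is always classified stable.
#' @export
make_random_truth <- function(prior = nmm_prior(), sigma = NULL, seed = 1,
                              control = sim_control(), max_draws = 10000) {
  prior <- as_nmm_prior(prior)
  local_rng(seed, {
    truth <- NULL
    for (k in seq_len(max_draws)) {
      theta <- as.numeric(as.matrix(draw_prior(1, prior)))
      names(theta) <- nmm_param_names()
      st <- nmm_stability(theta, delay_mode = control$delay_mode)
      if (st$stable) {
        ok <- !is.null(nmm_predict(theta, control))
        if (ok) {
          truth <- theta
          break
        }
      }
    }
    if (is.null(truth)) {
      stop("no stable prior draw found in ", max_draws, " attempts",
           call. = FALSE)
    }
    traj <- nmm_simulate(truth, control)
    if (is.null(sigma)) sigma <- 0.1 * sd(traj$x9)
    noise <- rnorm(nrow(traj), sd = sigma)
    structure(list(data = tibble::tibble(time = traj$time,
                                         voltage = traj$x9 + noise),
                   true_params = truth, sigma = sigma, seed = seed,
                   control = control),
              class = "nmm_dataset")
  })
}

#' Write / read a synthetic dataset
#'
#' The observations go to a two-column CSV `time,voltage`; the metadata
#' (true parameters, noise standard deviation, seed, integrator settings)
#' goes to a JSON sidecar next to it. Reading the pair back reproduces the
#' dataset exactly.
#'
#' @param dataset An `nmm_dataset`.
#' @param path CSV file path.
#' @return The path invisibly; `read_dataset()` returns the `nmm_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "nmm_dataset"))
  write_csv_precise(dataset$data, path)
  meta <- list(true_params = as.list(dataset$true_params),
               sigma = dataset$sigma, seed = dataset$seed,
               control = unclass(dataset$control))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  data <- utils::read.csv(path, colClasses = "numeric")
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(list(data = tibble::as_tibble(data),
                 true_params = as_nmm_params(unlist(meta$true_params)),
                 sigma = meta$sigma, seed = meta$seed,
                 control = do.call(sim_control, meta$control)),
            class = "nmm_dataset")
}

#' @export
print.nmm_dataset <- function(x, ...) {
  cat("<nmm_dataset> ", nrow(x$data), " observations on [",
      min(x$data$time), ", ", max(x$data$time), "] ms, sigma = ",
      signif(x$sigma, 4), ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
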