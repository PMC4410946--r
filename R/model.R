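#' Heaviside step input
#'
#' The experimental input perturbing the spiny-stellate population: zero
#' before `onset`, `amplitude` from `onset` on (right-continuous, so the
#' boundary point receives the full amplitude).
#'
#' @param t Time (ms); may be a vector.
#' @param onset Onset time (ms).
#' @param amplitude Input magnitude.
#' @return Numeric vector the length of `t`.
#' @export
#' @examples
#' heaviside_input(c(-1, 0, 5), onset = 0, amplitude = 3.94)
heaviside_input <- function(t, onset = 0, amplitude = 1) {
  ifelse(t >= onset, amplitude, 0)
}

#' Centred firing-rate sigmoid
#'
#' The voltage-to-firing-rate transfer function of the model,
#' `1 / (1 + exp(-0.56 * v)) - 0.5`. It is odd, bounded in (-0.5, 0.5), and
#' zero at rest.
#'
#' @param v Membrane voltage (mV); may be a vector.
#' @return Numeric vector the length of `v`.
#' @export
#' @examples
#' nmm_sigmoid(0)
nmm_sigmoid <- function(v) {
  1 / (1 + exp(-0.56 * v)) - 0.5
}

#  derivative of nmm_sigmoid, used by the analytic Jacobian
nmm_sigmoid_deriv <- function(v) {
  s <- nmm_sigmoid(v)
  0.56 * (0.25 - s * s)
}

#' Integrator / simulation settings
#'
#' Collects every numerical choice of the forward model: solver tolerances
#' (both default to 1e-3), the stiff BDF method, the output grid, the
#' Heaviside input onset, and how delayed states are approximated.
#'
#' @param abs_tol,rel_tol Absolute / relative solver tolerances (> 0).
#' @param t_start,t_end Simulation window (ms).
#' @param n_points Number of equally spaced output points (>= 2).
#' @param method deSolve integration method; `"bdf"` (implicit
#'   backward-differentiation with dense Newton solves) is the default.
#' @param delay_mode `"taylor1"` replaces each delayed state `x(t - delta)`
#'   by the first-order expansion `x(t) - delta * xdot(t)` (using the exact
#'   position-state derivatives, so the right-hand side stays explicit);
#'   `"none"` ignores the delay.
#' @param input_onset Heaviside onset time (ms).
#' @param max_steps Maximum internal solver steps per output interval; hitting
#'   the limit is treated as an integration failure.
#' @param state_cap Any state exceeding this magnitude marks the trajectory
#'   divergent (integration failure).
#' @return A list with class `sim_control`.
#' @export
sim_control <- function(abs_tol = 1e-3, rel_tol = 1e-3, t_start = 0,
                        t_end = 100, n_points = 100, method = "bdf",
                        delay_mode = c("taylor1", "none"), input_onset = 0,
                        max_steps = 5000, state_cap = 1e6) {
  delay_mode <- match.arg(delay_mode)
  stopifnot(abs_tol > 0, rel_tol > 0, n_points >= 2, t_end > t_start,
            max_steps > 0, state_cap > 0)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol, t_start = t_start,
                 t_end = t_end, n_points = n_points, method = method,
                 delay_mode = delay_mode, input_onset = input_onset,
                 max_steps = max_steps, state_cap = state_cap),
            class = "sim_control")
}

sim_times <- function(control) {
  seq(control$t_start, control$t_end, length.out = control$n_points)
}

#' Time derivatives of the nine model states
#'
#' Evaluates the model right-hand side at one state. The three delayed terms
#' (`x1`, `x7`, `x9` at `t - delta`) can be supplied explicitly; when `NULL`
#' they are formed from `state` according to `delay_mode`.
#'
#' @param state Numeric vector of the 9 states `x1..x9`.
#' @param params Parameter vector (see [nmm_params()]).
#' @param input_value Current value of the input (already through the
#'   Heaviside gate).
#' @param delay_mode `"taylor1"` or `"none"`; see [sim_control()].
#' @param delayed_x1,delayed_x7,delayed_x9 Optional explicit delayed states.
#' @return Numeric vector of 9 derivatives.
#' @export
nmm_rhs <- function(state, params, input_value = 0,
                    delay_mode = c("taylor1", "none"),
                    delayed_x1 = NULL, delayed_x7 = NULL, delayed_x9 = NULL) {
  delay_mode <- match.arg(delay_mode)
  p <- as_nmm_params(params)
  x <- as.numeric(state)
  stopifnot(length(x) == 9L)
  del <- p[["delta"]]
  if (is.null(delayed_x9)) {
    delayed_x9 <- if (delay_mode == "taylor1") x[9] - del * (x[5] - x[6]) else x[9]
  }
  if (is.null(delayed_x1)) {
    delayed_x1 <- if (delay_mode == "taylor1") x[1] - del * x[4] else x[1]
  }
  if (is.null(delayed_x7)) {
    delayed_x7 <- if (delay_mode == "taylor1") x[7] - del * x[8] else x[7]
  }
  te <- p[["tau_e"]]; ti <- p[["tau_i"]]
  he <- p[["h_e"]]; hi <- p[["h_i"]]
  c(x[4],
    x[5],
    x[6],
    he * (p[["g1"]] * nmm_sigmoid(delayed_x9) + input_value) / te -
      x[1] / te^2 - 2 * x[4] / te,
    p[["g2"]] * he * nmm_sigmoid(delayed_x1) / te - x[2] / te^2 - 2 * x[5] / te,
    p[["g4"]] * hi * nmm_sigmoid(delayed_x7) / ti - x[3] / ti^2 - 2 * x[6] / ti,
    x[8],
    p[["g3"]] * he * nmm_sigmoid(delayed_x9) / te - x[7] / te^2 - 2 * x[8] / te,
    x[5] - x[6])
}

nmm_integration_failure <- function(message) {
  structure(class = c("nmm_integration_failure", "error", "condition"),
            list(message = message, call = NULL))
}

# core integration; returns the deSolve matrix or signals
# nmm_integration_failure
nmm_integrate <- function(params, control = sim_control(), times = NULL) {
  p <- as_nmm_params(params)
  if (is.null(times)) times <- sim_times(control)
  parms <- c(unname(p), control$input_onset,
             as.numeric(control$delay_mode == "taylor1"))
  out <- tryCatch(
    suppressWarnings(
      deSolve::ode(y = rep(0, 9), times = times, func = "nmm_derivs",
                   parms = parms, dllname = "nmminvert",
                   initfunc = "nmm_init", method = control$method,
                   atol = control$abs_tol, rtol = control$rel_tol,
                   maxsteps = control$max_steps)),
    error = function(e) NULL)
  bad <- is.null(out) || nrow(out) < length(times) ||
    anyNA(out) || any(!is.finite(out)) ||
    max(abs(out[, -1, drop = FALSE])) > control$state_cap
  if (!bad) {
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) bad <- TRUE
  }
  if (bad) stop(nmm_integration_failure("ODE integration diverged or failed"))
  out
}

#' Simulate the neural mass model
#'
#' Integrates the nine ODEs from the zero (resting) state with a Heaviside
#' input of magnitude `u` switched on at `control$input_onset`, on the output
#' grid defined by `control`. The pyramidal voltage `x9` is the model
#' observable.
#'
#' @param params Parameter vector (see [nmm_params()]).
#' @param control A [sim_control()] list.
#' @param times Optional explicit output time grid (overrides the grid in
#'   `control`).
#' @return A tibble with columns `time`, `x1`..`x9`, of class
#'   `nmm_trajectory`, carrying `params` and `control` as attributes.
#'   Signals an error of class `nmm_integration_failure` when the solver
#'   diverges (dynamically unstable parameters).
#' @export
#' @examples
#' traj <- nmm_simulate(nmm_true_params())
#' head(traj)
nmm_simulate <- function(params, control = sim_control(), times = NULL) {
  out <- nmm_integrate(params, control, times)
  traj <- tibble::as_tibble(as.data.frame(unclass(out)))
  names(traj) <- c("time", paste0("x", 1:9))
  attr(traj, "params") <- as_nmm_params(params)
  attr(traj, "control") <- control
  class(traj) <- c("nmm_trajectory", class(traj))
  traj
}

# observable (x9) on a grid, or NULL on integration failure
nmm_predict <- function(params, control, times = NULL) {
  out <- tryCatch(nmm_integrate(params, control, times),
                  nmm_integration_failure = function(e) NULL)
  if (is.null(out)) NULL else unname(out[, 10])
}

#' Write / read a trajectory
#'
#' `write_trajectory()` saves the full state time course as a CSV with header
#' `time,x1,...,x9` and a JSON sidecar (same path with extension `.json`)
#' holding the parameter vector and the integrator settings.
#' `write_observable()` exports the two-column `time,voltage` form.
#'
#' @param traj An `nmm_trajectory` tibble from [nmm_simulate()].
#' @param path CSV file path.
#' @return The path, invisibly (`read_trajectory()` returns the tibble).
#' @export
write_trajectory <- function(traj, path) {
  write_csv_precise(as.data.frame(traj)[, c("time", paste0("x", 1:9))], path)
  meta <- list(params = as.list(attr(traj, "params")),
               control = unclass(attr(traj, "control")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(traj, "params") <- as_nmm_params(unlist(meta$params))
    attr(traj, "control") <- do.call(sim_control, meta$control)
  }
  class(traj) <- c("nmm_trajectory", class(traj))
  traj
}

#' @rdname write_trajectory
#' @export
write_observable <- function(traj, path) {
  write_csv_precise(tibble::tibble(time = traj$time, voltage = traj$x9), path)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.[^./]*$", "", path) |> paste0(".json")
}

# write a data frame as CSV with doubles rendered round-trippably (17
# significant digits), so reading the file back reproduces them bitwise
write_csv_precise <- function(df, path) {
  df <- as.data.frame(df)
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  readr::write_csv(df, path)
  invisible(path)
}
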