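#' Metropolis-Hastings accept/reject decision
#'
#' For symmetric proposals the Hastings ratio reduces to the density ratio:
#' the move is accepted with probability `min(1, exp(log_new - log_old))`.
#' A uniform variate is always drawn, so callers consume the RNG stream
#' identically whether or not the ratio exceeds one.
#'
#' @param log_new,log_old Log target density at the proposed and current
#'   states (`log_old` must be finite; `log_new` may be `-Inf`).
#' @return Logical: accept the proposal?
#' @export
mh_accept <- function(log_new, log_old) {
  runif(1) <= mh_alpha(log_new, log_old)
}

# realized acceptance probability min(1, ratio); 0 for -Inf proposals
mh_alpha <- function(log_new, log_old) {
  if (!is.finite(log_new)) return(0)
  min(1, exp(log_new - log_old))
}

# theta + z L where L is the upper-triangular Cholesky factor of the
# proposal covariance (shared by the RWM and adaptive kernels so that the
# two consume the RNG identically)
propose_gaussian <- function(theta, chol_upper) {
  theta + drop(rnorm(length(theta)) %*% chol_upper)
}

chol_or_jitter <- function(Sigma, jitter = 1e-8) {
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) {
    L <- chol(Sigma + diag(jitter, nrow(Sigma)))
    attr(L, "jittered") <- TRUE
  }
  L
}

#' One random-walk Metropolis step
#'
#' Proposes from a multivariate Gaussian centred at the current state and
#' applies [mh_accept()]. Out-of-support proposals (log density `-Inf`) are
#' rejected.
#'
#' @param theta Current state (numeric vector).
#' @param target Log target: either a function returning a scalar log
#'   density, or a function returning a list with elements `lp` (log joint),
#'   `ll`, `prior`.
#' @param proposal_cov Proposal covariance matrix (or its pre-computed upper
#'   Cholesky factor via `proposal_chol`).
#' @param lp_current Optional cached value of the target at `theta`.
#' @param proposal_chol Optional upper Cholesky factor of `proposal_cov`.
#' @return List with `theta`, `lp` (log target there), `accepted`, and the
#'   full `value` list returned by the target.
#' @export
rwm_step <- function(theta, target, proposal_cov = NULL, lp_current = NULL,
                     proposal_chol = NULL) {
  target <- as_target(target)
  if (is.null(proposal_chol)) proposal_chol <- chol_or_jitter(proposal_cov)
  if (is.null(lp_current)) lp_current <- target(theta)$lp
  stopifnot(is.finite(lp_current))
  prop <- propose_gaussian(theta, proposal_chol)
  val <- target(prop)
  if (mh_accept(val$lp, lp_current)) {
    list(theta = prop, lp = val$lp, accepted = TRUE, value = val)
  } else {
    list(theta = theta, lp = lp_current, accepted = FALSE, value = NULL)
  }
}

#' One full sweep of univariate slice sampling
#'
#' Updates each coordinate in turn with Neal's stepping-out/shrinkage slice
#' sampler, working in log-density space: the slice level is
#' `log f(theta) + log U(0,1)`. The bracket of width `w` is expanded until
#' both ends fall outside the slice (the total number of expansions is
#' bounded by `max_stepouts`, split randomly between the two directions),
#' then candidate points are drawn uniformly in the bracket, shrinking it
#' toward the current point on each rejection. The update never stalls: in
#' the worst case the bracket collapses onto the current (in-slice) point.
#'
#' @inheritParams rwm_step
#' @param widths Per-coordinate bracket widths (recycled to the dimension).
#' @param max_stepouts Cap on bracket expansions per coordinate update.
#' @return List with `theta`, `lp`, `accepted` (always `TRUE`), `n_evals`.
#' @export
slice_step <- function(theta, target, widths, max_stepouts = 20,
                       lp_current = NULL) {
  target <- as_target(target)
  d <- length(theta)
  widths <- rep_len(widths, d)
  if (is.null(lp_current)) lp_current <- target(theta)$lp
  stopifnot(is.finite(lp_current))
  n_evals <- 0L
  eval_at <- function(j, xj) {
    th <- theta
    th[j] <- xj
    n_evals <<- n_evals + 1L
    target(th)$lp
  }
  for (j in seq_len(d)) {
    level <- lp_current + log(runif(1))
    w <- widths[j]
    lower <- theta[j] - w * runif(1)
    upper <- lower + w
    # stepping out, budget split at random between the two directions
    k_lower <- floor(max_stepouts * runif(1))
    k_upper <- max_stepouts - 1 - k_lower
    while (k_lower > 0 && eval_at(j, lower) > level) {
      lower <- lower - w
      k_lower <- k_lower - 1
    }
    while (k_upper > 0 && eval_at(j, upper) > level) {
      upper <- upper + w
      k_upper <- k_upper - 1
    }
    # shrinkage
    repeat {
      if (upper - lower < 1e-12 * max(1, abs(theta[j]))) break
      x_new <- runif(1, lower, upper)
      lp_new <- eval_at(j, x_new)
      if (lp_new >= level) {
        theta[j] <- x_new
        lp_current <- lp_new
        break
      }
      if (x_new < theta[j]) lower <- x_new else upper <- x_new
    }
  }
  list(theta = theta, lp = lp_current, accepted = TRUE, n_evals = n_evals)
}

#' State of the adaptive Metropolis sampler
#'
#' Holds the running proposal mean `mu`, covariance `Sigma`, global scale
#' `lambda`, the target acceptance rate, and the Robbins-Monro iteration
#' counter. `lambda` starts at 1 and `Sigma` at the identity.
#'
#' @param mu Initial mean (usually the chain's initial state).
#' @param lambda Initial global scale.
#' @param Sigma Initial covariance (identity by default).
#' @param alpha_target Desired acceptance rate (default 0.23, the classic
#'   optimum for random-walk proposals in moderate dimension).
#' @param sigma_delay Number of initial iterations during which `Sigma` is
#'   held fixed while `mu` and `lambda` adapt (default 100). Engaging the
#'   covariance update only after this settling window prevents the early
#'   chain — still stuck near its starting point — from collapsing `Sigma`
#'   toward a degenerate matrix.
#' @return A list of class `adaptive_state`.
#' @export
adaptive_state <- function(mu, lambda = 1, Sigma = diag(length(mu)),
                           alpha_target = 0.23, sigma_delay = 100) {
  stopifnot(lambda > 0, nrow(Sigma) == length(mu), ncol(Sigma) == length(mu))
  structure(list(mu = as.numeric(mu), lambda = lambda, Sigma = Sigma,
                 alpha_target = alpha_target, iteration = 0L,
                 sigma_delay = sigma_delay, chol = NULL, n_jitter = 0L),
            class = "adaptive_state")
}

#' One adaptive Metropolis step with Robbins-Monro updates
#'
#' Proposes from `N(theta, lambda * Sigma)` and applies [mh_accept()]. While
#' `adapting`, the mean and covariance are updated with the equal-weight
#' step size `gamma_i = 1/i` (i = 1, 2, ... — so they track the running
#' mean and covariance of the chain):
#' `mu <- mu + gamma * (theta_new - mu)` and
#' `Sigma <- Sigma + gamma * ((theta_new - mu)(theta_new - mu)' - Sigma)`
#' (pre-update mean; the covariance update engages after the
#' `sigma_delay` settling window). The global scale adapts on the faster
#' schedule `gamma_lambda = 1/sqrt(i)`,
#' `log lambda <- log lambda + gamma_lambda * (alpha - alpha_target)`,
#' using the realized acceptance probability `alpha = min(1, ratio)`; the
#' scalar feedback must equilibrate quickly against the slowly moving
#' covariance for the acceptance rate to settle at its target within a few
#' thousand iterations (two-timescale stochastic approximation). When
#' `adapting` is `FALSE` the state is frozen and the kernel is a plain
#' random-walk Metropolis with covariance `lambda * Sigma`.
#'
#' Proposals are centred at the current state (symmetric kernel); set
#' `center = "mean"` to centre them at the running mean instead (an
#' asymmetric variant retained for sensitivity analysis).
#'
#' A non-positive-definite `Sigma` (possible in the first iterations, when
#' the rank-one updates have not yet filled the space) is repaired by adding
#' `1e-8` to the diagonal; the repair count is kept in the state.
#'
#' @inheritParams rwm_step
#' @param state An [adaptive_state()].
#' @param adapting Update the state after the move?
#' @param center `"current"` or `"mean"`.
#' @return List with `theta`, `lp`, `accepted`, `alpha` (realized acceptance
#'   probability), `value`, and the updated `state`.
#' @export
adaptive_step <- function(theta, state, target, adapting = TRUE,
                          lp_current = NULL, center = c("current", "mean")) {
  center <- match.arg(center)
  target <- as_target(target)
  if (is.null(lp_current)) lp_current <- target(theta)$lp
  stopifnot(is.finite(lp_current))
  if (is.null(state$chol)) {
    L <- chol_or_jitter(state$lambda * state$Sigma)
    if (isTRUE(attr(L, "jittered"))) state$n_jitter <- state$n_jitter + 1L
    state$chol <- L
  }
  centre_vec <- if (center == "current") theta else state$mu
  prop <- propose_gaussian(centre_vec, state$chol)
  val <- target(prop)
  alpha <- mh_alpha(val$lp, lp_current)
  accepted <- runif(1) <= alpha
  if (accepted) {
    theta <- prop
    lp_current <- val$lp
  }
  if (adapting) {
    i <- state$iteration + 1L
    gamma <- 1 / i
    state$lambda <- exp(log(state$lambda) +
                          (alpha - state$alpha_target) / sqrt(i))
    dev <- theta - state$mu
    if (i > state$sigma_delay) {
      state$Sigma <- state$Sigma + gamma * (tcrossprod(dev) - state$Sigma)
    }
    state$mu <- state$mu + gamma * dev
    state$iteration <- i
    state$chol <- NULL # recompute next step
  }
  list(theta = theta, lp = lp_current, accepted = accepted, alpha = alpha,
       value = if (accepted) val else NULL, state = state)
}

#' Inverse-temperature ladder for population MCMC
#'
#' Chains are indexed `i = 0 .. N-1` so that the cold chain (`beta = 1`,
#' the posterior) always exists and supplies the retained samples. The power
#' schedule sets `beta_i = (1 - i/N)^p`; the uniform schedule sets
#' `beta_i = 1 - i/N`. With `p = 1` the two coincide.
#'
#' @param n_chains Number of chains `N` (>= 1).
#' @param p Exponent of the power schedule (default 5).
#' @param schedule `"power"` or `"uniform"`.
#' @param k_swap Exchange interval: a swap is attempted every `k_swap`
#'   iterations (default 10).
#' @return A list of class `nmm_ladder` with fields `betas`, `schedule`,
#'   `p`, `n_chains`, `k_swap`.
#' @export
#' @examples
#' build_ladder(4, p = 5)$betas
build_ladder <- function(n_chains = 4, p = 5,
                         schedule = c("power", "uniform"), k_swap = 10) {
  schedule <- match.arg(schedule)
  stopifnot(n_chains >= 1, p > 0, k_swap >= 1)
  i <- seq_len(n_chains) - 1
  betas <- if (schedule == "power") (1 - i / n_chains)^p else 1 - i / n_chains
  structure(list(betas = betas, schedule = schedule, p = p,
                 n_chains = n_chains, k_swap = k_swap),
            class = "nmm_ladder")
}

#' Replica-exchange swap decision
#'
#' Accepts a swap of the states of two tempered chains with probability
#' `min(1, exp((beta_i - beta_j) * (log_lik_j - log_lik_i)))` — the
#' Metropolis ratio of the product of tempered posteriors before and after
#' the exchange (the prior terms cancel).
#'
#' @param log_lik_i,log_lik_j Log likelihoods of the two chains' states.
#' @param beta_i,beta_j Their inverse temperatures.
#' @return Logical: perform the swap?
#' @export
swap_accept <- function(log_lik_i, log_lik_j, beta_i, beta_j) {
  stopifnot(is.finite(log_lik_i), is.finite(log_lik_j))
  runif(1) <= min(1, exp((beta_i - beta_j) * (log_lik_j - log_lik_i)))
}

#' Initialise a population of tempered chains
#'
#' @param thetas Matrix with one row per chain.
#' @param target Target function (list contract, see [rwm_step()]).
#' @param ladder An [build_ladder()] ladder.
#' @return A list of class `nmm_population` holding the states and cached
#'   log likelihood / log prior values.
#' @export
population_init <- function(thetas, target, ladder) {
  target <- as_target(target)
  thetas <- rbind(thetas)
  stopifnot(nrow(thetas) == ladder$n_chains)
  vals <- lapply(seq_len(nrow(thetas)), function(i) target(thetas[i, ]))
  structure(list(thetas = thetas,
                 ll = vapply(vals, `[[`, 0, "ll"),
                 prior = vapply(vals, `[[`, 0, "prior"),
                 accepted = rep(FALSE, nrow(thetas)),
                 last_swap = NULL),
            class = "nmm_population")
}

#' One iteration of the population MCMC sampler
#'
#' Advances every chain by one random-walk Metropolis step against its
#' tempered target `beta_i * log_lik + log_prior`; every `k_swap` iterations
#' one pair of chains is chosen uniformly at random and their states are
#' exchanged with the [swap_accept()] probability (cached log likelihoods
#' travel with the states).
#'
#' With a single chain (`n_chains = 1`) the update reduces exactly to
#' [rwm_step()] on the posterior.
#'
#' @param pop An `nmm_population` from [population_init()].
#' @param target Target function (list contract).
#' @param ladder An [build_ladder()] ladder.
#' @param iteration Current iteration number (drives the swap clock).
#' @param proposal_chol Upper Cholesky factor of the (shared) per-chain
#'   proposal covariance.
#' @param streams Optional list with elements `chains` (list of per-chain
#'   RNG streams) and `swap` (stream for exchange decisions); when `NULL`
#'   the ambient RNG is used for everything.
#' @return The updated population.
#' @export
population_step <- function(pop, target, ladder, iteration, proposal_chol,
                            streams = NULL) {
  target <- as_target(target)
  n <- ladder$n_chains
  pop$last_swap <- NULL
  step_chain <- function(i) {
    beta <- ladder$betas[i]
    lp_old <- beta * pop$ll[i] + pop$prior[i]
    prop <- propose_gaussian(pop$thetas[i, ], proposal_chol)
    val <- target(prop)
    lp_new <- if (is.finite(val$ll) && is.finite(val$prior)) {
      beta * val$ll + val$prior
    } else {
      -Inf
    }
    if (mh_accept(lp_new, lp_old)) {
      pop$thetas[i, ] <<- prop
      pop$ll[i] <<- val$ll
      pop$prior[i] <<- val$prior
      pop$accepted[i] <<- TRUE
    } else {
      pop$accepted[i] <<- FALSE
    }
  }
  for (i in seq_len(n)) {
    if (is.null(streams)) step_chain(i)
    else stream_eval(streams$chains[[i]], function() step_chain(i))
  }
  if (n >= 2 && iteration %% ladder$k_swap == 0) {
    do_swap <- function() {
      pair <- sort(sample.int(n, 2))
      i <- pair[1]; j <- pair[2]
      ok <- swap_accept(pop$ll[i], pop$ll[j],
                        ladder$betas[i], ladder$betas[j])
      if (ok) {
        tmp_th <- pop$thetas[i, ]
        pop$thetas[i, ] <<- pop$thetas[j, ]
        pop$thetas[j, ] <<- tmp_th
        tmp <- pop$ll[i]; pop$ll[i] <<- pop$ll[j]; pop$ll[j] <<- tmp
        tmp <- pop$prior[i]; pop$prior[i] <<- pop$prior[j]; pop$prior[j] <<- tmp
      }
      pop$last_swap <<- list(i = i, j = j, accepted = ok)
    }
    if (is.null(streams)) do_swap()
    else stream_eval(streams$swap, do_swap)
  }
  pop
}

#' Run an MCMC sampler on the neural-mass-model posterior
#'
#' The top-level inversion routine. Builds the log-joint target from the
#' observations and prior, initialises the chain from prior draws (redrawn
#' until the log joint is finite — roughly half of prior draws are
#' dynamically unstable by construction), runs the requested sampler for
#' `n_total` iterations, and returns the full trace. Samples after `n_burn`
#' are the retained posterior draws; the adaptive sampler adapts only during
#' the first `n_adapt` iterations (`n_adapt <= n_burn <= n_total`).
#'
#' Default proposal scales are tied to the prior: the random-walk and
#' population samplers use a diagonal proposal with standard deviation
#' `proposal_scale` times the prior standard deviation of each parameter,
#' and the slice sampler uses the prior standard deviation as its bracket
#' width.
#'
#' @param data An `nmm_dataset` (see [make_ground_truth()]), an [nmm_obs()],
#'   or a data frame with columns `time` and `voltage` (then `sigma` must be
#'   given).
#' @param prior An [nmm_prior()] table.
#' @param sampler One of `"adaptive"`, `"slice"`, `"rwm"`, `"population"`.
#' @param n_total,n_burn,n_adapt Run protocol: total samples, burn-in
#'   samples, adaptation window (adaptive sampler only).
#' @param seed Integer master seed; every random ingredient (initialisation,
#'   proposals, swaps) derives from it.
#' @param sigma,control Passed to [nmm_obs()] when `data` is a bare data
#'   frame.
#' @param proposal_scale Multiplier on the prior standard deviations for the
#'   diagonal random-walk proposal.
#' @param proposal_cov Full proposal covariance overriding the diagonal
#'   default (rwm / population).
#' @param slice_width_scale Multiplier on the prior standard deviations for
#'   the slice bracket widths.
#' @param max_stepouts Slice stepping-out budget per coordinate.
#' @param alpha_target Adaptive sampler's target acceptance rate.
#' @param adaptive_center Proposal centring of the adaptive sampler
#'   (`"current"`, symmetric, the default — or `"mean"`).
#' @param n_chains,p,schedule,k_swap Population sampler settings (see
#'   [build_ladder()]).
#' @param max_init_draws Initialisation gives up (with an error) after this
#'   many prior draws with non-finite log joint.
#' @return A tibble of class `nmm_chain` with one row per iteration and
#'   columns `iter`, the ten parameters, `log_joint`, `log_lik`, `accepted`;
#'   attributes hold the sampler name, seed, run protocol, and the wall time
#'   (seconds) spent in the sampling loop.
#' @export
run_sampler <- function(data, prior = nmm_prior(),
                        sampler = c("adaptive", "slice", "rwm", "population"),
                        n_total = 2000, n_burn = 600, n_adapt = 300,
                        seed = 1, sigma = NULL, control = NULL,
                        proposal_scale = 0.1, proposal_cov = NULL,
                        slice_width_scale = 1, max_stepouts = 20,
                        alpha_target = 0.23,
                        adaptive_center = c("current", "mean"),
                        n_chains = 4, p = 5,
                        schedule = c("power", "uniform"), k_swap = 10,
                        max_init_draws = 1000) {
  sampler <- match.arg(sampler)
  adaptive_center <- match.arg(adaptive_center)
  schedule <- match.arg(schedule)
  stopifnot(n_adapt <= n_burn, n_burn <= n_total, n_total >= 1)
  obs <- nmm_obs(data, sigma = sigma, control = control)
  prior <- as_nmm_prior(prior)
  target <- nmm_target(obs, prior)
  psd <- prior_sd(prior)

  draw_init <- function() {
    for (k in seq_len(max_init_draws)) {
      theta <- as.numeric(as.matrix(draw_prior(1, prior)))
      val <- target(theta)
      if (is.finite(val$lp)) return(list(theta = theta, value = val))
    }
    stop("initialisation failed: no prior draw with finite log joint after ",
         max_init_draws, " attempts", call. = FALSE)
  }

  d <- 10L
  samples <- matrix(NA_real_, n_total, d)
  log_joint <- numeric(n_total)
  log_lik <- numeric(n_total)
  accepted <- logical(n_total)
  swap_events <- list()

  t0 <- proc.time()[["elapsed"]]
  if (sampler == "population") {
    ladder <- build_ladder(n_chains, p = p, schedule = schedule,
                           k_swap = k_swap)
    streams <- list(
      chains = lapply(seq_len(n_chains), function(i)
        new_rng_stream(seed_from(seed, "chain", i))),
      swap = new_rng_stream(seed_from(seed, "swap")))
    inits <- lapply(seq_len(n_chains), function(i)
      stream_eval(streams$chains[[i]], draw_init))
    pop <- population_init(do.call(rbind, lapply(inits, `[[`, "theta")),
                           target, ladder)
    pcov <- if (is.null(proposal_cov)) diag((proposal_scale * psd)^2)
            else proposal_cov
    pchol <- chol_or_jitter(pcov)
    for (it in seq_len(n_total)) {
      pop <- population_step(pop, target, ladder, it, pchol, streams)
      samples[it, ] <- pop$thetas[1, ]
      log_lik[it] <- pop$ll[1]
      log_joint[it] <- pop$ll[1] + pop$prior[1]
      accepted[it] <- pop$accepted[1]
      if (!is.null(pop$last_swap)) {
        swap_events[[length(swap_events) + 1L]] <-
          c(iter = it, i = pop$last_swap$i, j = pop$last_swap$j,
            accepted = as.integer(pop$last_swap$accepted))
      }
    }
  } else {
    stream <- new_rng_stream(seed_from(seed, "chain", 1))
    init <- stream_eval(stream, draw_init)
    theta <- init$theta
    lp <- init$value$lp
    ll <- init$value$ll
    if (sampler == "rwm") {
      pcov <- if (is.null(proposal_cov)) diag((proposal_scale * psd)^2)
              else proposal_cov
      pchol <- chol_or_jitter(pcov)
      for (it in seq_len(n_total)) {
        st <- stream_eval(stream, function()
          rwm_step(theta, target, lp_current = lp, proposal_chol = pchol))
        theta <- st$theta; lp <- st$lp
        if (st$accepted) ll <- st$value$ll
        samples[it, ] <- theta
        log_joint[it] <- lp; log_lik[it] <- ll; accepted[it] <- st$accepted
      }
    } else if (sampler == "slice") {
      widths <- slice_width_scale * psd
      for (it in seq_len(n_total)) {
        st <- stream_eval(stream, function()
          slice_step(theta, target, widths, max_stepouts = max_stepouts,
                     lp_current = lp))
        theta <- st$theta; lp <- st$lp
        ll <- lp - nmm_log_prior(theta, prior)
        samples[it, ] <- theta
        log_joint[it] <- lp; log_lik[it] <- ll; accepted[it] <- TRUE
      }
    } else { # adaptive
      # identity proposal covariance in prior-standardised coordinates, so
      # the initial kernel is commensurate with every parameter's scale
      state <- adaptive_state(theta, Sigma = diag(psd^2),
                              alpha_target = alpha_target)
      for (it in seq_len(n_total)) {
        st <- stream_eval(stream, function()
          adaptive_step(theta, state, target, adapting = it <= n_adapt,
                        lp_current = lp, center = adaptive_center))
        theta <- st$theta; lp <- st$lp; state <- st$state
        if (st$accepted) ll <- st$value$ll
        samples[it, ] <- theta
        log_joint[it] <- lp; log_lik[it] <- ll; accepted[it] <- st$accepted
      }
    }
  }
  wall <- proc.time()[["elapsed"]] - t0

  colnames(samples) <- nmm_param_names()
  out <- tibble::as_tibble(as.data.frame(samples))
  out <- tibble::add_column(out, iter = seq_len(n_total), .before = 1)
  out$log_joint <- log_joint
  out$log_lik <- log_lik
  out$accepted <- accepted
  attr(out, "sampler") <- sampler
  attr(out, "seed") <- seed
  attr(out, "n_burn") <- n_burn
  attr(out, "n_adapt") <- if (sampler == "adaptive") n_adapt else 0L
  attr(out, "wall_time") <- wall
  attr(out, "schedule") <- if (sampler == "population") schedule else NULL
  attr(out, "swap_events") <- if (length(swap_events))
    tibble::as_tibble(do.call(rbind, swap_events)) else NULL
  class(out) <- c("nmm_chain", class(out))
  out
}

#' Retained (post-burn-in) draws of a chain
#'
#' @param chain An `nmm_chain` from [run_sampler()].
#' @return The tibble rows with `iter > n_burn`.
#' @export
retained <- function(chain) {
  stopifnot(inherits(chain, "nmm_chain"))
  chain[chain$iter > attr(chain, "n_burn"), , drop = FALSE]
}

#' Write / read a chain trace
#'
#' CSV with columns `iter,g1,...,u,log_joint,log_lik,accepted` plus a JSON
#' sidecar with the sampler name, seed, run protocol and wall time. The
#' schema is identical across samplers.
#'
#' @param chain An `nmm_chain`.
#' @param path CSV file path.
#' @return The path invisibly; `read_chain()` returns the `nmm_chain`.
#' @export
write_chain <- function(chain, path) {
  write_csv_precise(as.data.frame(chain), path)
  meta <- list(sampler = attr(chain, "sampler"), seed = attr(chain, "seed"),
               n_burn = attr(chain, "n_burn"), n_adapt = attr(chain, "n_adapt"),
               wall_time = attr(chain, "wall_time"),
               schedule = attr(chain, "schedule"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (f in names(meta)) attr(out, f) <- meta[[f]]
  }
  class(out) <- c("nmm_chain", class(out))
  out
}
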