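test_that("MH acceptance has the right probability", {
  set.seed(1)
  expect_true(all(vapply(1:50, function(i) mh_accept(0, -5), TRUE)))
  expect_false(any(vapply(1:50, function(i) mh_accept(-Inf, -1), TRUE)))
  set.seed(2)
  hits <- mean(vapply(1:100000, function(i) mh_accept(log(0.5), 0), TRUE))
  expect_equal(hits, 0.5, tolerance = 0.01)
})

test_that("random-walk Metropolis recovers the moments of a 2-D normal", {
  set.seed(3)
  tgt <- gaussian_target(d = 2, rho = 0)
  theta <- c(0, 0)
  lp <- tgt$logd(theta)
  n <- 100000
  draws <- matrix(0, n, 2)
  pchol <- chol(diag(2.4^2 / 2, 2))
  for (i in seq_len(n)) {
    st <- rwm_step(theta, tgt$logd, lp_current = lp, proposal_chol = pchol)
    theta <- st$theta
    lp <- st$lp
    draws[i, ] <- theta
  }
  draws <- draws[-(1:2000), ]
  expect_lt(max(abs(colMeans(draws))), 0.05)
  expect_lt(max(abs(cov(draws) - diag(2))), 0.05)
})

test_that("a vanishing proposal keeps the rwm chain in place, always accepting", {
  set.seed(4)
  tgt <- gaussian_target(d = 2)
  theta <- c(0.4, -0.2)
  st <- rwm_step(theta, tgt$logd, proposal_cov = diag(1e-30, 2))
  expect_true(st$accepted)
  expect_equal(st$theta, theta, tolerance = 1e-10)
})

test_that("out-of-support proposals are rejected", {
  set.seed(5)
  half_line <- function(x) if (any(x <= 0)) -Inf else -sum(x)
  theta <- c(0.05)
  rejections <- 0
  for (i in 1:200) {
    st <- rwm_step(theta, half_line, proposal_cov = diag(1, 1))
    if (!st$accepted) rejections <- rejections + 1
    expect_gt(st$theta, 0)
    theta <- st$theta
  }
  expect_gt(rejections, 0)
})

test_that("slice sampling reproduces analytic 1-D distributions", {
  set.seed(6)
  n <- 20000
  x <- 0.5
  lp <- dnorm(x, log = TRUE)
  draws <- numeric(n)
  for (i in seq_len(n)) {
    st <- slice_step(x, function(v) dnorm(v, log = TRUE), widths = 2,
                     lp_current = lp)
    x <- st$theta
    lp <- st$lp
    draws[i] <- x
  }
  ks <- suppressWarnings(stats::ks.test(draws, pnorm))
  expect_lt(unname(ks$statistic), 0.012)

  set.seed(7)
  x <- 1
  lp <- -1
  exp_draws <- numeric(n)
  exp_target <- function(v) if (v <= 0) -Inf else -v
  for (i in seq_len(n)) {
    st <- slice_step(x, exp_target, widths = 1, lp_current = lp)
    x <- st$theta
    lp <- st$lp
    exp_draws[i] <- x
  }
  expect_equal(mean(exp_draws), 1, tolerance = 0.03)
})

test_that("slice updates always land inside the slice", {
  set.seed(8)
  tgt <- gaussian_target(d = 3)
  theta <- rep(0.2, 3)
  for (i in 1:50) {
    lp_before <- tgt$logd(theta)
    st <- slice_step(theta, tgt$logd, widths = 1, lp_current = lp_before)
    # the defining property: the new point's density can drop below the old
    # one by at most the drawn slice level, which is itself <= the old density
    expect_true(is.finite(st$lp))
    expect_equal(st$lp, tgt$logd(st$theta), tolerance = 1e-12)
    theta <- st$theta
  }
})

test_that("Robbins-Monro step sizes follow the 1/i schedule", {
  set.seed(9)
  tgt <- gaussian_target(d = 2)
  st <- adaptive_state(c(0, 0))
  expect_equal(st$lambda, 1)
  expect_equal(st$Sigma, diag(2))
  expect_equal(st$iteration, 0L)
  theta <- c(0, 0)
  mus <- list()
  thetas <- list()
  for (i in 1:3) {
    out <- adaptive_step(theta, st, tgt$logd, adapting = TRUE)
    thetas[[i]] <- out$theta
    mus[[i]] <- out$state$mu
    theta <- out$theta
    st <- out$state
  }
  expect_equal(st$iteration, 3L)
  # gamma_1 = 1, gamma_2 = 1/2, gamma_3 = 1/3 for the mean update: mu is the
  # equal-weight running mean of the visited states
  expect_equal(mus[[1]], thetas[[1]])
  expect_equal(mus[[2]], (thetas[[1]] + thetas[[2]]) / 2)
  expect_equal(mus[[3]], Reduce(`+`, thetas) / 3)
})

test_that("frozen adaptive sampling is bitwise a random-walk Metropolis", {
  set.seed(10)
  tgt <- gaussian_target(d = 3)
  theta_a <- theta_r <- c(0.1, 0.2, -0.1)
  lp <- tgt$logd(theta_a)
  st <- adaptive_state(theta_a)
  set.seed(11)
  path_a <- lapply(1:40, function(i) {
    out <- adaptive_step(theta_a, st, tgt$logd, adapting = FALSE,
                         lp_current = lp)
    theta_a <<- out$theta
    lp <<- out$lp
    st <<- out$state
    theta_a
  })
  expect_equal(st$iteration, 0L) # adaptation never ran
  lp <- tgt$logd(theta_r)
  set.seed(11)
  pchol <- chol(diag(3))
  path_r <- lapply(1:40, function(i) {
    out <- rwm_step(theta_r, tgt$logd, lp_current = lp,
                    proposal_chol = pchol)
    theta_r <<- out$theta
    lp <<- out$lp
    theta_r
  })
  expect_identical(path_a, path_r)
})

test_that("temperature ladders match direct evaluation", {
  lad <- build_ladder(4, p = 5, schedule = "power")
  expect_equal(lad$betas, c(1, (3 / 4)^5, (1 / 2)^5, (1 / 4)^5))
  expect_equal(lad$betas[4], 0.0009765625)
  uni <- build_ladder(4, schedule = "uniform")
  expect_equal(uni$betas, c(1, 0.75, 0.5, 0.25))
  expect_equal(build_ladder(4, p = 1, schedule = "power")$betas, uni$betas)
  expect_equal(lad$betas[1], 1)
  expect_true(all(diff(lad$betas) < 0))
  expect_equal(lad$k_swap, 10)
})

test_that("swap acceptance matches the tempered Metropolis ratio", {
  set.seed(12)
  expect_true(all(vapply(1:50, function(i) swap_accept(-3, -3, 1, 0.5), TRUE)))
  expect_true(all(vapply(1:50, function(i) swap_accept(-7, -2, 0.4, 0.4), TRUE)))
  # beta_i = 1, beta_j = 0.5, ll_j - ll_i = log 4: alpha = 4^0.5 / ... = 2 > 1
  expect_true(all(vapply(1:50, function(i)
    swap_accept(-log(4), 0, 1, 0.5), TRUE)))
  # flipped sign: alpha = 4^{-0.5} = 0.5
  set.seed(13)
  hits <- mean(vapply(1:100000, function(i)
    swap_accept(0, -log(4), 1, 0.5), TRUE))
  expect_equal(hits, 0.5, tolerance = 0.01)
})

test_that("a single-chain population is bitwise a plain rwm run", {
  ds <- test_dataset(seed = 20)
  a <- run_sampler(ds, sampler = "population", n_chains = 1, n_total = 60,
                   n_burn = 10, n_adapt = 0, seed = 21)
  b <- run_sampler(ds, sampler = "rwm", n_total = 60, n_burn = 10,
                   n_adapt = 0, seed = 21)
  expect_equal(chain_df(a), chain_df(b))
})

test_that("population sampling hops between modes where plain rwm stays put", {
  bimodal <- function(x) {
    log(0.5 * dnorm(x, -3, 0.5) + 0.5 * dnorm(x, 3, 0.5))
  }
  tgt <- as_target_fn <- function(x) bimodal(x)
  n_iter <- 2000
  hop_pop <- 0
  hop_rwm <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    lad <- build_ladder(4, p = 2, schedule = "power", k_swap = 10)
    pop <- population_init(matrix(rep(-3, 4), 4, 1), tgt, lad)
    pchol <- chol(diag(0.5^2, 1))
    visited_pop <- c(FALSE, FALSE)
    theta <- -3
    lp <- bimodal(theta)
    visited_rwm <- c(TRUE, FALSE)
    for (i in seq_len(n_iter)) {
      pop <- population_step(pop, tgt, lad, i, pchol)
      if (pop$thetas[1, 1] < -1) visited_pop[1] <- TRUE
      if (pop$thetas[1, 1] > 1) visited_pop[2] <- TRUE
      st <- rwm_step(theta, tgt, lp_current = lp, proposal_chol = pchol)
      theta <- st$theta
      lp <- st$lp
      if (theta > 1) visited_rwm[2] <- TRUE
    }
    if (all(visited_pop)) hop_pop <- hop_pop + 1
    if (all(visited_rwm)) hop_rwm <- hop_rwm + 1
  }
  expect_gte(hop_pop, 0.75 * reps)
  expect_lte(hop_rwm, 0.1 * reps)
})

test_that("run_sampler honours the run protocol and is reproducible", {
  ds <- test_dataset(seed = 30)
  ch1 <- run_sampler(ds, sampler = "rwm", n_total = 50, n_burn = 15,
                     n_adapt = 0, seed = 31)
  ch2 <- run_sampler(ds, sampler = "rwm", n_total = 50, n_burn = 15,
                     n_adapt = 0, seed = 31)
  expect_equal(chain_df(ch1), chain_df(ch2))
  expect_equal(nrow(ch1), 50)
  expect_equal(nrow(retained(ch1)), 35)
  expect_true(all(is.finite(retained(ch1)$log_joint)))
  expect_error(run_sampler(ds, n_total = 10, n_burn = 20),
               "n_burn")
})

test_that("chain traces round-trip through CSV", {
  ds <- test_dataset(seed = 32)
  ch <- run_sampler(ds, sampler = "rwm", n_total = 20, n_burn = 5,
                    n_adapt = 0, seed = 33)
  path <- file.path(tempdir(), "chain.csv")
  write_chain(ch, path)
  back <- read_chain(path)
  expect_equal(as.data.frame(back)[, 1:13],
               as.data.frame(ch)[, 1:13])
  expect_equal(attr(back, "sampler"), "rwm")
  expect_equal(attr(back, "n_burn"), 5)
  unlink(c(path, sub("csv$", "json", path)))
})

test_that("tidy and glance summarise retained draws", {
  ds <- test_dataset(seed = 34)
  ch <- run_sampler(ds, sampler = "rwm", n_total = 60, n_burn = 20,
                    n_adapt = 0, seed = 35)
  td <- tidy(ch)
  expect_equal(td$parameter, nmm_param_names())
  expect_true(all(td$ess >= 1 & td$ess <= 40))
  gl <- glance(ch)
  expect_equal(gl$n_retained, 40)
  expect_equal(gl$sampler, "rwm")
})
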