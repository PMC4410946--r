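test_that("trivial Jacobian rows select the velocity states", {
  p <- nmm_true_params()
  x <- rep(0.3, 9)
  J <- nmm_jacobian(p, x, input_value = 2, delay_mode = "none")
  e <- function(j) replace(rep(0, 9), j, 1)
  expect_equal(J[1, ], e(4))
  expect_equal(J[2, ], e(5))
  expect_equal(J[3, ], e(6))
  expect_equal(J[7, ], e(8))
  expect_equal(J[9, ], e(5) - e(6))
})

test_that("analytic and finite-difference Jacobians agree", {
  set.seed(11)
  for (mode in c("taylor1", "none")) {
    for (k in 1:5) {
      p <- as_nmm_params(as.matrix(draw_prior(1))[1, ])
      x <- rnorm(9, sd = 3)
      Ja <- nmm_jacobian(p, x, input_value = p[["u"]], delay_mode = mode)
      Jn <- nmm_jacobian(p, x, input_value = p[["u"]], delay_mode = mode,
                         method = "numeric")
      expect_lt(max(abs(Ja - Jn)), 1e-4)
    }
  }
})

test_that("the input-free system has its fixed point at the origin", {
  fp <- nmm_fixed_point(nmm_true_params(), input_value = 0)
  expect_true(fp$converged)
  expect_equal(fp$state, rep(0, 9), tolerance = 1e-8)
})

test_that("velocity states vanish at the driven fixed point", {
  fp <- nmm_fixed_point(nmm_true_params(), input_value = 3.94)
  expect_true(fp$converged)
  expect_lt(fp$residual, 1e-8)
  expect_equal(fp$state[c(4, 5, 6, 8)], rep(0, 4), tolerance = 1e-8)
  # the reachable equilibrium keeps the conserved combination at zero
  expect_equal(fp$state[9] - fp$state[2] + fp$state[3], 0, tolerance = 1e-8)
})

test_that("fixed-point solves are deterministic", {
  a <- nmm_fixed_point(nmm_true_params())
  b <- nmm_fixed_point(nmm_true_params())
  expect_identical(a, b)
})

test_that("decoupled dynamics are stable with the closed-form rates", {
  # with all g -> 0 the blocks are damped second-order systems whose
  # eigenvalues are the double roots -1/tau
  p <- nmm_true_params()
  p[c("g1", "g2", "g3", "g4")] <- 1e-12
  st <- nmm_stability(p)
  expect_true(st$stable)
  eigs <- Re(eigen(st$jacobian, only.values = TRUE)$values)
  expect_equal(sort(unique(round(eigs, 6))),
               sort(unique(round(c(0, rep(-1 / p[["tau_e"]], 6),
                                   rep(-1 / p[["tau_i"]], 2)), 6))))
})

test_that("the ground-truth parameters are classified stable", {
  st <- nmm_stability(nmm_true_params())
  expect_true(st$converged)
  expect_true(st$stable)
  expect_lt(st$max_real_eig, 0)
})

test_that("the full Jacobian carries one structural zero eigenvalue", {
  st <- nmm_stability(nmm_true_params())
  eigs <- eigen(st$jacobian, only.values = TRUE)$values
  expect_lt(min(abs(eigs)), 1e-10)
})

test_that("classification agrees with a settle-vs-oscillate integration oracle", {
  set.seed(42)
  n <- 40
  draws <- as.matrix(draw_prior(n))
  ctrl <- sim_control(t_end = 2000, n_points = 400)
  agree <- 0
  checked <- 0
  for (i in seq_len(n)) {
    th <- as_nmm_params(draws[i, ])
    st <- nmm_stability(th)
    # the bounded sigmoid makes blow-up impossible: instability shows up as
    # a persistent oscillation about the fixed point
    tr <- tryCatch(nmm_simulate(th, ctrl), error = function(e) NULL)
    osc_unstable <- if (is.null(tr)) TRUE else {
      max(abs(tr$x9[tr$time > 1500] - st$fixed_point[9])) > 0.05
    }
    near_boundary <- is.na(st$max_real_eig) || abs(st$max_real_eig) < 1e-3
    if (!near_boundary) {
      checked <- checked + 1
      agree <- agree + ((!st$stable) == osc_unstable)
    }
  }
  expect_gt(checked, 20)
  expect_gte(agree / checked, 0.95)
})

test_that("the census is seeded, reproducible and sane", {
  c1 <- instability_census(120, seed = 7)
  c2 <- instability_census(120, seed = 7)
  expect_identical(c1$fraction_unstable, c2$fraction_unstable)
  expect_identical(c1$unstable, c2$unstable)
  expect_gte(c1$fraction_unstable, 0)
  expect_lte(c1$fraction_unstable, 1)
})

test_that("a prior concentrated on the stable truth yields a zero census", {
  truth <- nmm_true_params()
  tight <- nmm_prior(shape = rep(1e6, 10), scale = truth / 1e6)
  cs <- instability_census(60, prior = tight, seed = 3)
  expect_equal(cs$fraction_unstable, 0)
})

test_that("census standard error shrinks like n^(-1/2)", {
  # split one larger census into blocks: the block-to-block spread of the
  # fraction should scale with the inverse square root of the block size
  cs <- instability_census(800, seed = 5)
  f <- cs$unstable
  se_small <- sd(vapply(split(f, rep(1:20, each = 40)), mean, 0))
  se_large <- sd(vapply(split(f, rep(1:5, each = 160)), mean, 0))
  expect_gt(se_small / se_large, 1.2)
})
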