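test_that("heaviside input is right-continuous at the onset", {
  expect_equal(heaviside_input(-1, onset = 0, amplitude = 3.94), 0)
  expect_equal(heaviside_input(5, onset = 0, amplitude = 3.94), 3.94)
  expect_equal(heaviside_input(0, onset = 0, amplitude = 1), 1)
  expect_equal(heaviside_input(c(-2, 0, 2), onset = 0, amplitude = 2),
               c(0, 2, 2))
})

test_that("firing-rate sigmoid is centred, odd and bounded", {
  expect_equal(nmm_sigmoid(0), 0)
  # frozen from direct evaluation of 1/(1 + exp(-5.6)) - 0.5
  expect_equal(nmm_sigmoid(10), 0.49631576, tolerance = 1e-7)
  v <- seq(-30, 30, length.out = 41)
  expect_equal(nmm_sigmoid(v), -nmm_sigmoid(-v))
  expect_true(all(abs(nmm_sigmoid(c(-1e4, 1e4))) <= 0.5))
})

test_that("rhs position derivatives are the velocity states", {
  set.seed(4)
  p <- nmm_true_params()
  for (k in 1:10) {
    x <- rnorm(9, sd = 5)
    dx <- nmm_rhs(x, p, input_value = runif(1, 0, 5))
    expect_equal(dx[1], x[4])
    expect_equal(dx[2], x[5])
    expect_equal(dx[3], x[6])
    expect_equal(dx[7], x[8])
    expect_equal(dx[9], x[5] - x[6])
  }
})

test_that("origin is a fixed point of the input-free system", {
  dx <- nmm_rhs(rep(0, 9), nmm_true_params(), input_value = 0)
  expect_equal(dx, rep(0, 9))
})

test_that("rhs at zero state reproduces the hand-computed drive term", {
  p <- nmm_true_params()
  dx <- nmm_rhs(rep(0, 9), p, input_value = 3.94)
  # only the driven excitatory velocity is non-zero: h_e * u / tau_e
  expect_equal(dx[4], 1.63 * 3.94 / 5.77)
  expect_equal(dx[-4], rep(0, 8))
})

test_that("zero input from the zero state stays at rest", {
  ctrl <- test_control()
  p <- nmm_true_params()
  p["u"] <- 1e-12 # parameters must stay positive; onset beyond the window
  ctrl$input_onset <- 1e6
  traj <- nmm_simulate(p, ctrl)
  expect_lt(max(abs(as.matrix(traj[, -1]))), 10 * ctrl$abs_tol)
})

test_that("the step response at the true parameters moves the observable", {
  traj <- nmm_simulate(nmm_true_params(), test_control())
  expect_gt(diff(range(traj$x9)), 1)
  expect_equal(names(traj), c("time", paste0("x", 1:9)))
})

test_that("integration is deterministic", {
  t1 <- nmm_simulate(nmm_true_params(), test_control())
  t2 <- nmm_simulate(nmm_true_params(), test_control())
  expect_identical(t1, t2)
})

test_that("a vanishing delay matches the undelayed equations", {
  p <- nmm_true_params()
  p["delta"] <- 1e-6
  ctrl_t <- test_control(delay_mode = "taylor1")
  ctrl_n <- test_control(delay_mode = "none")
  a <- nmm_simulate(p, ctrl_t)
  b <- nmm_simulate(p, ctrl_n)
  expect_lt(max(abs(a$x9 - b$x9)), 10 * ctrl_t$rel_tol)
})

test_that("tightening the tolerances changes the endpoint less than the coarse tolerance", {
  p <- nmm_true_params()
  coarse <- nmm_simulate(p, test_control())
  fine <- nmm_simulate(p, test_control(abs_tol = 5e-4, rel_tol = 5e-4))
  expect_lt(abs(coarse$x9[60] - fine$x9[60]), 1e-3 * max(1, abs(fine$x9[60])))
})

test_that("second-order structure holds along integrated trajectories", {
  # positions integrate their velocity states: finite-difference check
  ctrl <- test_control(n_points = 400)
  tr <- nmm_simulate(nmm_true_params(), ctrl)
  dt <- diff(tr$time)[1]
  for (pair in list(c("x1", "x4"), c("x2", "x5"), c("x3", "x6"),
                    c("x7", "x8"))) {
    dpos <- diff(tr[[pair[1]]]) / dt
    vmid <- (head(tr[[pair[2]]], -1) + tail(tr[[pair[2]]], -1)) / 2
    expect_lt(max(abs(dpos - vmid)), 0.05 * max(1, max(abs(vmid))))
  }
})

test_that("trajectory round-trips through CSV with its metadata", {
  traj <- nmm_simulate(nmm_true_params(), test_control())
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj))
  expect_equal(attr(back, "params"), attr(traj, "params"))
  obs_path <- file.path(tempdir(), "obs.csv")
  write_observable(traj, obs_path)
  obs <- readr::read_csv(obs_path, show_col_types = FALSE)
  expect_equal(obs$voltage, traj$x9)
  unlink(c(path, sidecar_path <- sub("csv$", "json", path), obs_path))
})

test_that("parameter vectors are validated and canonically ordered", {
  p <- nmm_true_params()
  shuffled <- p[c(10, 1:9)]
  expect_equal(as_nmm_params(shuffled), p)
  expect_error(as_nmm_params(c(p[-1], g1 = -1)), "positive")
  expect_error(nmm_params(0.1, 0.2, 0.3, 0.4, 1, 1, 1, 1, 1, -2), "positive")
  expect_error(as_nmm_params(1:5), "length 10")
})
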