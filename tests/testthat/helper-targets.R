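# Analytic targets and small oracles shared across the test files.

# multivariate normal log density (up to a constant) with AR(1)-style
# correlation 0.5^|i-j|; returns a closure plus the true moments
gaussian_target <- function(d = 10, rho = 0.5) {
  V <- rho^abs(outer(seq_len(d), seq_len(d), "-"))
  Vi <- solve(V)
  list(logd = function(x) -0.5 * drop(x %*% Vi %*% x),
       mean = rep(0, d), cov = V)
}

# small control grid keeping model-based tests quick
test_control <- function(t_end = 100, n_points = 60, ...) {
  sim_control(t_end = t_end, n_points = n_points, ...)
}

# chain tibble stripped of run metadata (wall time etc.) for equality checks
chain_df <- function(chain) {
  x <- as.data.frame(chain)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}

test_dataset <- function(seed = 1, sigma = NULL) {
  make_ground_truth(sigma = sigma, seed = seed, control = test_control())
}

# direct enumeration of Geyer's initial monotone sequence rule, independent
# of the package's FFT/vectorised path (used for series of length <= 64)
ess_enumeration <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  gamma_hat <- vapply(0:(n - 1), function(lag) {
    sum(xc[1:(n - lag)] * xc[(1 + lag):n]) / n
  }, numeric(1))
  rho <- gamma_hat / gamma_hat[1]
  pair_sums <- c()
  m <- 0
  while (2 * m + 1 <= n - 1) {
    g <- rho[2 * m + 1] + rho[2 * m + 2]
    if (is.na(g) || g <= 0) break
    pair_sums <- c(pair_sums, g)
    m <- m + 1
  }
  if (length(pair_sums) > 1) {
    pair_sums <- cummin(pair_sums)
  }
  tau <- 2 * sum(pair_sums) - 1
  if (tau <= 0) return(n)
  min(max(n / tau, 1), n)
}

# AR(1) series with standard-normal innovations
ar1_series <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
  for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  x
}
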