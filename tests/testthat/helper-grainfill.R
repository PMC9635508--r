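# Shared fixtures and independent numeric oracles.

standard_days <- c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45)

# forward-simulate one observation series (multiplicative Gaussian noise)
make_series <- function(A, B, K, N, days = standard_days, sigma = 0,
                        seed = NULL) {
  w <- richards_weight(days, A, B, K, N)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    w <- w * (1 + rnorm(length(days), sd = sigma))
  }
  tibble::tibble(day = days, weight_mg = pmax(w, 0))
}

# random well-posed parameter sets with the rate peak inside (0, 60) days
random_params <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    A = runif(n, 10, 30),
    K = runif(n, 0.1, 1),
    N = exp(runif(n, log(0.05), log(5))),
    T_peak = runif(n, 2, 40),
    B = N * exp(K * T_peak)
  )
}

# oracle: maximise the rate curve on a fine grid + local refinement
numeric_rate_max <- function(A, B, K, N, interval = c(0, 60)) {
  grid <- seq(interval[1], interval[2], length.out = 2001)
  r <- filling_rate(grid, A, B, K, N)
  i <- which.max(r)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(t) filling_rate(t, A, B, K, N),
                         c(lo, hi), maximum = TRUE, tol = 1e-12)
  list(t_max = opt$maximum, rate_max = opt$objective,
       w_max = richards_weight(opt$maximum, A, B, K, N))
}

# oracle: invert the weight curve by bisection
bisect_time_to_fraction <- function(p, A, B, K, N) {
  stats::uniroot(function(t) richards_weight(t, A, B, K, N) - p * A,
                 c(-200, 400), tol = 1e-12)$root
}

# oracle: zeros of the second derivative of the rate curve by central
# differences + root bracketing, independent of the closed form
numeric_inflection_times <- function(A, B, K, N) {
  h <- 1e-4
  d2rate <- function(t) {
    (filling_rate(t + h, A, B, K, N) - 2 * filling_rate(t, A, B, K, N) +
       filling_rate(t - h, A, B, K, N)) / h^2
  }
  t_peak <- numeric_rate_max(A, B, K, N, c(-60, 120))$t_max
  t1 <- stats::uniroot(d2rate, c(t_peak - 80, t_peak - 1e-3),
                       tol = 1e-10)$root
  t2 <- stats::uniroot(d2rate, c(t_peak + 1e-3, t_peak + 80),
                       tol = 1e-10)$root
  c(t1 = t1, t2 = t2)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
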