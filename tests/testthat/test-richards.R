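test_that("the weight curve evaluates correctly at its anchor points", {
  A <- 22.91; B <- 13.79; K <- 0.24; N <- 0.55
  # direct evaluation A * (1 + B)^(-1/N) at t = 0, frozen from independent
  # arithmetic: 22.91 * 14.79^(-1/0.55)
  expect_equal(richards_weight(0, A, B, K, N), 0.170927, tolerance = 1e-4)
  # asymptote equals the final weight A
  expect_equal(richards_weight(1e6, A, B, K, N), A, tolerance = 1e-12)
  # degenerate position constant: B -> 0 flattens the curve at A
  expect_equal(richards_weight(c(-5, 0, 17), A, 1e-12, K, N),
               rep(A, 3), tolerance = 1e-9)
})

test_that("the weight curve is strictly increasing for random valid params", {
  params <- random_params(25, seed = 101)
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    # probe where the curve is numerically representable (0.1%-99.9% of A);
    # outside, double precision saturates at 0 or A
    grid <- seq(time_to_fraction(0.001, p$A, p$B, p$K, p$N),
                time_to_fraction(0.999, p$A, p$B, p$K, p$N),
                length.out = 200)
    w <- richards_weight(grid, p$A, p$B, p$K, p$N)
    expect_true(all(diff(w) > 0))
  }
})

test_that("the rate curve is the derivative of the weight curve", {
  params <- random_params(25, seed = 102)
  ts <- c(0.5, 3, 11, 27, 44)
  h <- 1e-5
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    fd <- (richards_weight(ts + h, p$A, p$B, p$K, p$N) -
             richards_weight(ts - h, p$A, p$B, p$K, p$N)) / (2 * h)
    an <- filling_rate(ts, p$A, p$B, p$K, p$N)
    expect_equal(an, fd, tolerance = 1e-6)
    expect_true(all(an > 0))
  }
})

test_that("the logistic special case has rate maximum A*K/4", {
  A <- 18; B <- 9; K <- 0.31
  t_peak <- log(B) / K  # T_max at N = 1
  expect_equal(filling_rate(t_peak, A, B, K, 1), A * K / 4,
               tolerance = 1e-12)
})

test_that("invalid parameters raise a parameter-domain error", {
  expect_error(richards_weight(1, -1, 2, 0.3, 1),
               class = "grainfill_error_params")
  expect_error(filling_rate(1, 20, 0, 0.3, 1),
               class = "grainfill_error_params")
  expect_error(time_to_fraction(0.5, 20, 2, -0.3, 1),
               class = "grainfill_error_params")
  expect_error(inflection_times(20, 2, 0.3, NA),
               class = "grainfill_error_params")
  expect_error(richards_weight(Inf, 20, 2, 0.3, 1),
               class = "grainfill_error_domain")
})

test_that("time_to_fraction inverts the weight curve", {
  # logistic half-weight time is ln(B)/K
  expect_equal(time_to_fraction(0.5, 20, 10, 0.3, 1), log(10) / 0.3,
               tolerance = 1e-12)
  # bisection oracle agreement and round-trip identity
  params <- random_params(20, seed = 103)
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    for (frac in c(0.1, 0.5, 0.9, 0.99)) {
      t_an <- time_to_fraction(frac, p$A, p$B, p$K, p$N)
      expect_equal(t_an, bisect_time_to_fraction(frac, p$A, p$B, p$K, p$N),
                   tolerance = 1e-7)
      expect_equal(richards_weight(t_an, p$A, p$B, p$K, p$N), frac * p$A,
                   tolerance = 1e-9)
    }
  }
  expect_error(time_to_fraction(0, 20, 10, 0.3, 1),
               class = "grainfill_error_domain")
  expect_error(time_to_fraction(1, 20, 10, 0.3, 1),
               class = "grainfill_error_domain")
})

test_that("inflection times match the numeric root-finding oracle", {
  # frozen oracle values for a representative superior-grain curve
  ti <- inflection_times(22.91, 13.79, 0.24, 0.55)
  num <- numeric_inflection_times(22.91, 13.79, 0.24, 0.55)
  expect_equal(ti$t1, unname(num["t1"]), tolerance = 1e-5)
  expect_equal(ti$t2, unname(num["t2"]), tolerance = 1e-5)
  expect_equal(ti$t1, 8.52, tolerance = 0.01)
  expect_equal(ti$t2, 18.32, tolerance = 0.01)

  # logistic closed form: u = 2 +/- sqrt(3)
  B <- 7; K <- 0.2
  ti1 <- inflection_times(20, B, K, 1)
  expect_equal(ti1$t1, (log(B) - log(2 + sqrt(3))) / K, tolerance = 1e-12)
  expect_equal(ti1$t2, (log(B) - log(2 - sqrt(3))) / K, tolerance = 1e-12)
})

test_that("inflection times are symmetric about the rate peak", {
  params <- random_params(50, seed = 104)
  ti <- inflection_times(params$A, params$B, params$K, params$N)
  t_max <- (log(params$B) - log(params$N)) / params$K
  expect_true(all(ti$t1 < t_max & t_max < ti$t2))
  expect_equal(ti$t1 + ti$t2, 2 * t_max, tolerance = 1e-9)
})

test_that("phase contributions conserve mass and match known values", {
  # logistic middle-phase share is 1/sqrt(3)
  ph1 <- phase_contributions(20, 10, 0.3, 1)
  expect_equal(ph1$frac_middle, 1 / sqrt(3), tolerance = 1e-12)

  # representative superior-grain curve: the middle sub-phase carries
  # just under 60% of final weight
  ph <- phase_contributions(22.91, 13.79, 0.24, 0.55)
  expect_equal(ph$frac_middle, 0.596, tolerance = 0.002)

  # conservation: fractions plus the weight present at t = 0 sum to 1
  params <- random_params(50, seed = 105)
  ph <- phase_contributions(params$A, params$B, params$K, params$N)
  w0 <- richards_weight(0, params$A, params$B, params$K, params$N)
  expect_equal(ph$frac_start + ph$frac_middle + ph$frac_late + w0 / params$A,
               rep(1, 50), tolerance = 1e-12)
  expect_true(all(ph$frac_middle > 0 & ph$frac_middle < 1))
  expect_true(all(ph$frac_late > 0))
  # the start fraction is positive whenever the first inflection follows
  # labeling; curves with t1 < 0 had part of their start phase pre-anthesis
  t1 <- inflection_times(params$A, params$B, params$K, params$N)$t1
  expect_true(all(ph$frac_start[t1 > 0] > 0))

  # frac_middle depends on the shape parameter only
  expect_equal(phase_contributions(5, 80, 0.7, 0.55)$frac_middle,
               phase_contributions(40, 2, 0.1, 0.55)$frac_middle,
               tolerance = 1e-12)
})

test_that("scaling A scales weights and rates but not times or fractions", {
  p <- list(A = 21, B = 12, K = 0.28, N = 0.7)
  scaled <- filling_characteristics(
    tibble::tibble(A = c(p$A, 3 * p$A), B = p$B, K = p$K, N = p$N)
  )
  expect_equal(scaled$GFR_max[2], 3 * scaled$GFR_max[1], tolerance = 1e-12)
  expect_equal(scaled$GFR_avg[2], 3 * scaled$GFR_avg[1], tolerance = 1e-12)
  expect_equal(scaled$W_max[2], 3 * scaled$W_max[1], tolerance = 1e-12)
  for (col in c("R0", "T_max", "GFD", "t1", "t2", "frac_start",
                "frac_middle", "frac_late")) {
    expect_equal(scaled[[col]][2], scaled[[col]][1], tolerance = 1e-12)
  }
  expect_equal(richards_weight(13, 3 * p$A, p$B, p$K, p$N),
               3 * richards_weight(13, p$A, p$B, p$K, p$N),
               tolerance = 1e-12)
})

test_that("replacing B by B*exp(K*s) shifts the curve in time by s", {
  p <- list(A = 21, B = 12, K = 0.28, N = 0.7)
  s <- 4.5
  shifted <- filling_characteristics(
    tibble::tibble(A = p$A, B = c(p$B, p$B * exp(p$K * s)),
                   K = p$K, N = p$N)
  )
  for (col in c("T_max", "t1", "t2", "GFD")) {
    expect_equal(shifted[[col]][2], shifted[[col]][1] + s, tolerance = 1e-9)
  }
  for (col in c("GFR_max", "W_max", "GFR_avg", "R0", "frac_middle")) {
    expect_equal(shifted[[col]][2], shifted[[col]][1], tolerance = 1e-12)
  }
  expect_equal(richards_weight(10 + s, p$A, p$B * exp(p$K * s), p$K, p$N),
               richards_weight(10, p$A, p$B, p$K, p$N), tolerance = 1e-12)
})
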