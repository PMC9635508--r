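test_that("the initial guess follows its construction and seeds recovery", {
  # noise-free logistic series
  obs <- make_series(20, 10, 0.3, 1)
  g <- init_guess(obs)
  expect_equal(g$A, 1.05 * max(obs$weight_mg), tolerance = 1e-12)
  expect_equal(g$N, 1)
  expect_true(g$K >= 0.01 && g$B >= 0.1)
  # the guess is a serviceable optimiser start: the fit launched from it
  # recovers the true parameters essentially exactly
  fit <- fit_richards(obs, multistart = 1, seed = 1)
  expect_equal(fit$fits$A, 20, tolerance = 1e-4)
  expect_equal(fit$fits$B, 10, tolerance = 1e-3)
  expect_equal(fit$fits$K, 0.3, tolerance = 1e-4)

  # definitional anchor: A0 is 5% above the observed maximum
  obs22 <- make_series(21, 8, 0.3, 0.8)
  obs22$weight_mg[which.max(obs22$weight_mg)] <- 22.0
  expect_equal(init_guess(obs22)$A, 23.1, tolerance = 1e-9)

  expect_error(init_guess(tibble::tibble(day = 1:6, weight_mg = rep(3, 6))),
               class = "grainfill_error_degenerate")
})

test_that("noise-free series are recovered to numerical precision", {
  truth <- c(A = 22.91, B = 13.79, K = 0.24, N = 0.55)
  obs <- make_series(truth["A"], truth["B"], truth["K"], truth["N"])
  fit <- fit_richards(obs, seed = 3)
  for (p in names(truth)) {
    expect_equal(fit$fits[[p]], unname(truth[p]), tolerance = 1e-4)
  }
  expect_gte(fit$fits$r_squared, 0.99999)
  expect_true(fit$fits$converged)
})

test_that("R^2 matches direct arithmetic and its boundary cases", {
  obs <- make_series(22.91, 13.79, 0.24, 0.55)
  expect_equal(r_squared(obs, 22.91, 13.79, 0.24, 0.55), 1, tolerance = 1e-12)

  # hand-computable 5-point oracle
  d5 <- tibble::tibble(day = c(2, 9, 16, 23, 37),
                       weight_mg = c(1.4, 6.2, 13.8, 18.9, 21.7))
  p <- c(A = 22, B = 10, K = 0.25, N = 0.8)
  pred <- richards_weight(d5$day, p["A"], p["B"], p["K"], p["N"])
  expected <- 1 - sum((d5$weight_mg - pred)^2) /
    sum((d5$weight_mg - mean(d5$weight_mg))^2)
  expect_equal(r_squared(d5, p["A"], p["B"], p["K"], p["N"]), expected,
               tolerance = 1e-12)

  expect_error(r_squared(tibble::tibble(day = 1:5, weight_mg = rep(2, 5)),
                         20, 10, 0.3, 1),
               class = "grainfill_error_degenerate")
})

test_that("the returned solution never loses to its own starting point", {
  for (seed in 1:5) {
    obs <- make_series(23, 12, 0.26, 0.7, sigma = 0.05, seed = 400 + seed)
    g <- init_guess(obs)
    sse_init <- sum((obs$weight_mg -
                       richards_weight(obs$day, g$A, g$B, g$K, g$N))^2)
    fit <- fit_richards(obs, seed = seed)
    expect_lte(fit$fits$sse, sse_init + 1e-12)
  }
})

test_that("fitting is deterministic and idempotent", {
  obs <- make_series(21, 9, 0.22, 0.6, sigma = 0.03, seed = 77)
  f1 <- fit_richards(obs, seed = 11)
  f2 <- fit_richards(obs, seed = 11)
  expect_identical(f1$fits, f2$fits)

  # refitting the fitted curve's own predictions returns the same curve
  pred <- tibble::tibble(
    day = obs$day,
    weight_mg = richards_weight(obs$day, f1$fits$A, f1$fits$B,
                                f1$fits$K, f1$fits$N)
  )
  f3 <- fit_richards(pred, seed = 11)
  expect_equal(f3$fits$A, f1$fits$A, tolerance = 1e-3)
  expect_equal(f3$fits$T_max, f1$fits$T_max, tolerance = 1e-3)
})

test_that("parameter recovery degrades gracefully with noise", {
  truth <- list(A = 22.91, B = 13.79, K = 0.24, N = 0.55)
  t_max_true <- (log(truth$B) - log(truth$N)) / truth$K
  for (cfg in list(list(sigma = 0.02, tol_A = 0.02, tol_T = 0.05))) {
    errs <- purrr::map_dfr(1:100, function(rep) {
      obs <- make_series(truth$A, truth$B, truth$K, truth$N,
                         sigma = cfg$sigma, seed = 1000 + rep)
      fit <- fit_richards(obs, seed = rep)
      tibble::tibble(eA = rel_err(fit$fits$A, truth$A),
                     eT = rel_err(fit$fits$T_max, t_max_true))
    })
    expect_lte(median(errs$eA), cfg$tol_A)
    expect_lte(median(errs$eT), cfg$tol_T)
  }
})

test_that("well-conditioned series at field-like noise fit with high R^2", {
  # 2% multiplicative noise, representative superior-grain dynamics
  r2 <- purrr::map_dbl(1:20, function(rep) {
    obs <- make_series(24.03, 20.24, 0.24, 0.66, sigma = 0.02,
                       seed = 2000 + rep)
    fit_richards(obs, seed = rep)$fits$r_squared
  })
  expect_true(all(r2 >= 0.98))
})

test_that("grouped data frames are fitted per unit with keys preserved", {
  units <- richards_reference_params()[c(1, 9), ]
  series <- purrr::pmap_dfr(
    units[c("cultivar", "site", "year", "grain_class", "A", "B", "K", "N")],
    function(cultivar, site, year, grain_class, A, B, K, N) {
      dplyr::mutate(make_series(A, B, K, N),
                    cultivar = cultivar, site = site, year = year,
                    grain_class = grain_class)
    }
  )
  fit <- fit_richards(series, seed = 5)
  expect_equal(nrow(fit$fits), 2)
  expect_setequal(fit$fits$cultivar, units$cultivar)
  expect_equal(sort(fit$fits$A), sort(units$A), tolerance = 1e-3)

  td <- tidy(fit)
  expect_equal(nrow(td), 8)  # 2 units x 4 parameters
  expect_setequal(unique(td$term), c("A", "B", "K", "N"))
  gl <- glance(fit)
  expect_true(all(c("r_squared", "sse", "converged", "n_obs") %in% names(gl)))
  au <- augment(fit)
  expect_equal(nrow(au), nrow(series))
  expect_lt(max(abs(au$.resid)), 1e-6)  # noise-free input
})

test_that("insufficient or malformed series are rejected", {
  expect_error(
    fit_richards(tibble::tibble(day = 1:4, weight_mg = c(1, 3, 7, 9))),
    class = "grainfill_error_insufficient"
  )
  expect_error(
    fit_richards(tibble::tibble(day = c(1, 1, 2, 3, 4, 5),
                                weight_mg = c(1, 1.2, 3, 7, 9, 10))),
    class = "grainfill_error_schema"
  )
  # the same duplicate days are accepted when averaging is requested
  fit <- fit_richards(
    tibble::tibble(day = c(1, 1, 5, 10, 15, 20, 25, 30, 35, 40, 45),
                   weight_mg = richards_weight(
                     c(1, 1, 5, 10, 15, 20, 25, 30, 35, 40, 45),
                     20, 10, 0.3, 1)),
    average_replicates = TRUE, seed = 2
  )
  expect_equal(fit$fits$n_obs, 10)
})
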