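#' Initial Richards parameter guess from a weight series
#'
#' Builds a deterministic starting point for the nonlinear fit:
#' `A0 = 1.05 * max(weight)`, `N0 = 1`, and `(B0, K0)` from the logistic
#' linearisation — an ordinary least-squares regression of
#' `log(A0 / W - 1)` on day over observations with `0 < W < A0`
#' (slope `-K0`, intercept `log(B0)`). `K0` is floored at 0.01 per day and
#' `B0` at 0.1 so the optimiser always starts inside its bounds.
#'
#' @param data A data frame with numeric columns `day` and `weight_mg` for a
#'   single series.
#' @return A one-row tibble with columns `A`, `B`, `K`, `N`.
#' @examples
#' days <- c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45)
#' obs <- data.frame(day = days,
#'                   weight_mg = richards_weight(days, 20, 10, 0.3, 1))
#' init_guess(obs)
#' @export
init_guess <- function(data) {
  obs <- check_series(data)
  w <- obs$weight_mg
  if (diff(range(w)) < .Machine$double.eps^0.5) {
    abort("All weights are equal; the series is degenerate.",
          class = "grainfill_error_degenerate")
  }
  A0 <- 1.05 * max(w)
  keep <- w > 0 & w < A0
  if (sum(keep) < 2) {
    abort("Too few informative observations for the linearised initialiser.",
          class = "grainfill_error_degenerate")
  }
  y <- log(A0 / w[keep] - 1)
  fit <- lm(y ~ obs$day[keep])
  K0 <- max(-unname(coef(fit)[2]), 0.01)
  B0 <- max(exp(unname(coef(fit)[1])), 0.1)
  tibble(A = A0, B = B0, K = K0, N = 1)
}

#' Coefficient of determination of a Richards fit
#'
#' `R^2 = 1 - SSE / SST` with `SST` the centred total sum of squares of the
#' observed weights. A value that is negative only within numerical
#' tolerance (> -1e-10) is clipped to 0.
#'
#' @inheritParams init_guess
#' @inheritParams richards_weight
#' @return A single number in \[0, 1\] (negative only for fits worse than
#'   the mean).
#' @export
r_squared <- function(data, A, B, K, N) {
  obs <- check_series(data)
  sst <- sum((obs$weight_mg - mean(obs$weight_mg))^2)
  if (sst < .Machine$double.eps) {
    abort("Zero total sum of squares; R^2 is undefined.",
          class = "grainfill_error_degenerate")
  }
  pred <- richards_weight(obs$day, A, B, K, N)
  r2 <- 1 - sum((obs$weight_mg - pred)^2) / sst
  if (r2 < 0 && r2 > -1e-10) r2 <- 0
  r2
}

#' Fit the Richards growth equation to grain-weight series
#'
#' Estimates the Richards parameters for every series in `data` by bounded
#' multi-start nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}), minimising the unweighted residual sum of squares of
#' weight. Series are defined by the key columns present among `cultivar`,
#' `site`, `year`, `grain_class`; a data frame without key columns is
#' treated as one series. Each series needs at least 5 observations (the
#' model has 4 free parameters).
#'
#' The first start is the deterministic [init_guess()]; the remaining
#' `multistart - 1` starts perturb it on the log scale using a seeded RNG
#' stream, guarding against the flat A-N ridge typical of Richards fits.
#' The lowest-SSE converged solution is returned; starts whose SSE ties
#' within 1e-10 relative are broken by smallest `N`, then smallest `B`.
#' Identical data, options and seed give identical results.
#'
#' Diagnostic flags accumulated per series in the `warnings` column:
#' `pre_anthesis_maximum` (fitted `B <= N`, rate peak at or before the time
#' origin), `boundary_hit` (a parameter within 1e-6 relative of its bound),
#' `multistart_disagreement` (converged starts differ by more than 1% in
#' SSE), `not_converged`.
#'
#' @param data A data frame with columns `day`, `weight_mg` and optionally
#'   the unit keys `cultivar`, `site`, `year`, `grain_class`.
#' @param multistart Number of optimisation starts per series (default 5).
#' @param seed Integer seed for the perturbed restarts.
#' @param lower,upper Named parameter bounds. Defaults:
#'   `A` in (0, 3 * max weight\], `B` in (0, 1e4\], `K` in (0, 5\],
#'   `N` in \[0.01, 10\]. `NA` entries keep the default.
#' @param gfd_fraction Passed to [filling_characteristics()].
#' @param average_replicates If `TRUE`, replicate weights sharing a
#'   (series, day) are averaged before fitting; otherwise duplicate days are
#'   an error.
#' @param control A [minpack.lm::nls.lm.control()] list; defaults use
#'   gradient/step tolerances of 1e-10 and at most 1e4 function evaluations.
#' @return An object of class `richards_fit`: a list with elements `fits`
#'   (a tibble, one row per series: keys, `A`, `B`, `K`, `N`, all derived
#'   characteristics, `sse`, `r_squared`, `converged`, `n_obs`, `warnings`),
#'   `data` (the observations used) and `options`. Supports [tidy()],
#'   [glance()], [augment()] and [autoplot()].
#' @examples
#' days <- c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45)
#' obs <- data.frame(day = days,
#'                   weight_mg = richards_weight(days, 22.91, 13.79, 0.24, 0.55))
#' fit <- fit_richards(obs, seed = 1)
#' glance(fit)
#' @export
fit_richards <- function(data, multistart = 5, seed = 1,
                         lower = NULL, upper = NULL,
                         gfd_fraction = 0.99,
                         average_replicates = FALSE,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, gtol = 1e-10,
                           maxfev = 10000, maxiter = 1000)) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "grainfill_error_schema")
  }
  keys <- intersect(c("cultivar", "site", "year", "grain_class"), names(data))
  data <- as_tibble(data)
  if (average_replicates) {
    data <- data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "day")))) |>
      dplyr::summarise(weight_mg = mean(.data$weight_mg), .groups = "drop")
  }
  grouped <- if (length(keys) > 0) {
    data |>
      dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "day")))) |>
      tidyr::nest(obs = !dplyr::all_of(keys))
  } else {
    tibble(obs = list(dplyr::arrange(data, .data$day)))
  }

  fits <- withr::with_seed(seed, {
    purrr::map(grouped$obs, function(obs) {
      fit_one_series(obs, multistart = multistart, lower = lower,
                     upper = upper, control = control)
    })
  })
  fits_tbl <- dplyr::bind_cols(
    dplyr::select(grouped, -"obs"),
    dplyr::bind_rows(fits)
  )
  ch <- filling_characteristics(
    dplyr::select(fits_tbl, dplyr::all_of(c(keys, "A", "B", "K", "N"))),
    gfd_fraction = gfd_fraction
  )
  fits_tbl <- ch |>
    dplyr::rename(flag_params = "warnings") |>
    dplyr::bind_cols(dplyr::select(fits_tbl, "sse", "r_squared",
                                   "converged", "n_obs",
                                   flag_fit = "warnings")) |>
    dplyr::mutate(
      warnings = trimws(paste(.data$flag_params, .data$flag_fit)),
      flag_params = NULL, flag_fit = NULL
    )

  structure(
    list(
      fits = fits_tbl,
      data = if (length(keys) > 0) {
        tidyr::unnest(grouped, "obs")
      } else {
        grouped$obs[[1]]
      },
      options = list(multistart = multistart, seed = seed,
                     gfd_fraction = gfd_fraction, keys = keys)
    ),
    class = "richards_fit"
  )
}

# single-series bounded multi-start Levenberg-Marquardt fit
fit_one_series <- function(obs, multistart, lower, upper, control) {
  obs <- check_series(obs, require_unique_days = TRUE)
  if (nrow(obs) < 5) {
    abort("At least 5 observations are required to fit 4 parameters.",
          class = "grainfill_error_insufficient")
  }
  lo <- c(A = 1e-8, B = 1e-8, K = 1e-8, N = 0.01)
  hi <- c(A = 3 * max(obs$weight_mg), B = 1e4, K = 5, N = 10)
  if (!is.null(lower)) lo[names(lower)[!is.na(lower)]] <- lower[!is.na(lower)]
  if (!is.null(upper)) hi[names(upper)[!is.na(upper)]] <- upper[!is.na(upper)]

  init <- init_guess(obs)
  p0 <- pmin(pmax(c(A = init$A, B = init$B, K = init$K, N = init$N), lo), hi)
  starts <- list(p0)
  if (multistart > 1) {
    for (i in seq_len(multistart - 1)) {
      pert <- p0 * exp(rnorm(4, sd = 0.3))
      starts[[i + 1]] <- pmin(pmax(pert, lo), hi)
    }
  }

  resid_fn <- function(par) {
    obs$weight_mg - par[["A"]] *
      (1 + par[["B"]] * exp(-par[["K"]] * obs$day))^(-1 / par[["N"]])
  }
  attempts <- purrr::map(starts, function(p) {
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p, lower = lo, upper = hi, fn = resid_fn,
                           control = control)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    list(par = res$par, sse = sum(res$fvec^2),
         converged = res$info %in% 1:4)
  })
  attempts <- purrr::compact(attempts)
  conv <- purrr::keep(attempts, ~ isTRUE(.x$converged))
  pool <- if (length(conv) > 0) conv else attempts
  if (length(pool) == 0) {
    abort("No optimisation start succeeded for this series.",
          class = "grainfill_error_nonconvergence")
  }
  sses <- purrr::map_dbl(pool, "sse")
  best_sse <- min(sses)
  tied <- which(sses <= best_sse * (1 + 1e-10) + 1e-300)
  if (length(tied) > 1) {
    ord <- order(purrr::map_dbl(pool[tied], ~ .x$par[["N"]]),
                 purrr::map_dbl(pool[tied], ~ .x$par[["B"]]))
    best <- pool[[tied[ord[1]]]]
  } else {
    best <- pool[[tied]]
  }

  flags <- character(0)
  rel <- function(x, y) abs(x - y) / pmax(abs(y), 1e-12)
  if (any(rel(best$par, lo) < 1e-6 | rel(best$par, hi) < 1e-6)) {
    flags <- c(flags, "boundary_hit")
  }
  if (length(conv) > 1) {
    spread <- (max(purrr::map_dbl(conv, "sse")) - best_sse) /
      max(best_sse, 1e-12)
    if (spread > 0.01 && best_sse > 1e-12) {
      flags <- c(flags, "multistart_disagreement")
    }
  }
  if (!best$converged) flags <- c(flags, "not_converged")

  sst <- sum((obs$weight_mg - mean(obs$weight_mg))^2)
  r2 <- 1 - best$sse / sst
  if (r2 < 0 && r2 > -1e-10) r2 <- 0
  tibble(
    A = best$par[["A"]], B = best$par[["B"]],
    K = best$par[["K"]], N = best$par[["N"]],
    sse = best$sse, r_squared = r2,
    converged = best$converged, n_obs = nrow(obs),
    warnings = paste(flags, collapse = " ")
  )
}

# validate a single-series observation table
check_series <- function(data, require_unique_days = FALSE,
                         call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("Series must be a data frame.", class = "grainfill_error_schema",
          call = call)
  }
  missing_cols <- setdiff(c("day", "weight_mg"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Series is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "grainfill_error_schema", call = call)
  }
  if (!is.numeric(data$day) || !is.numeric(data$weight_mg) ||
      any(!is.finite(data$day)) || any(!is.finite(data$weight_mg))) {
    abort("`day` and `weight_mg` must be finite numeric.",
          class = "grainfill_error_schema", call = call)
  }
  if (any(data$weight_mg < 0)) {
    abort("Weights must be non-negative.",
          class = "grainfill_error_schema", call = call)
  }
  data <- dplyr::arrange(as_tibble(data), .data$day)
  if (require_unique_days && anyDuplicated(data$day) > 0) {
    abort("Duplicate sampling days in one series; average replicates first.",
          class = "grainfill_error_schema", call = call)
  }
  data
}

#' @export
print.richards_fit <- function(x, ...) {
  n <- nrow(x$fits)
  cat("<richards_fit> ", n, " series, multistart = ",
      x$options$multistart, ", seed = ", x$options$seed, "\n", sep = "")
  print(glance(x), ...)
  invisible(x)
}

#' Tidy a Richards fit into one row per parameter
#'
#' @param x A `richards_fit` from [fit_richards()].
#' @param ... Unused.
#' @return A tibble with the series keys plus `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.richards_fit <- function(x, ...) {
  x$fits |>
    dplyr::select(dplyr::all_of(c(x$options$keys, "A", "B", "K", "N"))) |>
    tidyr::pivot_longer(dplyr::all_of(c("A", "B", "K", "N")),
                        names_to = "term", values_to = "estimate")
}

#' Per-series fit diagnostics
#'
#' @inheritParams tidy.richards_fit
#' @return A tibble with the series keys plus `r_squared`, `sse`,
#'   `converged`, `n_obs`, `warnings`.
#' @exportS3Method generics::glance
glance.richards_fit <- function(x, ...) {
  dplyr::select(x$fits, dplyr::all_of(c(
    x$options$keys, "r_squared", "sse", "converged", "n_obs", "warnings"
  )))
}

#' Observations augmented with fitted weights and residuals
#'
#' @inheritParams tidy.richards_fit
#' @return The observation tibble plus `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.richards_fit <- function(x, ...) {
  keys <- x$options$keys
  params <- dplyr::select(x$fits,
                          dplyr::all_of(c(keys, "A", "B", "K", "N")))
  obs <- if (length(keys) > 0) {
    dplyr::left_join(x$data, params, by = keys)
  } else {
    dplyr::bind_cols(x$data, params)
  }
  obs |>
    dplyr::mutate(
      .fitted = richards_weight(.data$day, .data$A, .data$B,
                                .data$K, .data$N),
      .resid = .data$weight_mg - .data$.fitted
    ) |>
    dplyr::select(-dplyr::all_of(c("A", "B", "K", "N")))
}
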