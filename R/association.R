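#' Pairwise Pearson correlations between filling characteristics and traits
#'
#' Computes the Pearson correlation for every pair of one `x_cols` and one
#' `y_cols` column over pairwise-complete rows, with the two-sided p-value
#' from the t statistic \eqn{r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of
#' freedom (`|r| = 1` gives `p = 0`). No multiple-testing adjustment is
#' applied by default; set `adjust = "BH"` for Benjamini-Hochberg across all
#' reported pairs.
#'
#' A pair with zero variance in either column is reported with `r = NA` and
#' no significance call rather than dropped, so the output shape is
#' predictable.
#'
#' @param data A data frame of per-unit trait and characteristic values.
#' @param x_cols,y_cols Character vectors of numeric column names to
#'   correlate (every x against every y).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param adjust P-value adjustment method, `"none"` (default) or any
#'   [stats::p.adjust()] method applied across all pairs.
#' @return A tibble with columns `x_name`, `y_name`, `r`, `p_value`, `n`,
#'   `significant`, `controls` (empty string: no controls).
#' @examples
#' traits <- data.frame(gfr = c(1.2, 1.5, 0.9, 1.8, 1.1),
#'                      yield = c(98, 110, 87, 121, 95))
#' trait_correlations(traits, "gfr", "yield")
#' @export
trait_correlations <- function(data, x_cols, y_cols, alpha = 0.05,
                               adjust = "none") {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "grainfill_error_schema")
  }
  missing_cols <- setdiff(c(x_cols, y_cols), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "grainfill_error_schema")
  }
  check_alpha(alpha)
  pairs <- tidyr::expand_grid(x_name = x_cols, y_name = y_cols)
  out <- purrr::pmap(pairs, function(x_name, y_name) {
    pearson_pair(data[[x_name]], data[[y_name]])
  })
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(out))
  if (!identical(adjust, "none")) {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  }
  out |>
    dplyr::mutate(
      significant = !is.na(.data$p_value) & .data$p_value < alpha,
      controls = ""
    )
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after ordinary
#' least-squares projection on the `controls` columns plus an intercept.
#' The p-value uses \eqn{n - 2 - k} degrees of freedom, where `k` is the
#' number of controls. With no controls this reduces exactly to the plain
#' correlation of [trait_correlations()].
#'
#' @inheritParams trait_correlations
#' @param x,y Names of the two columns to correlate.
#' @param controls Character vector of control column names (may be empty).
#' @return A one-row tibble with columns `x_name`, `y_name`, `r`, `p_value`,
#'   `n`, `significant`, `controls` (comma-separated).
#' @examples
#' d <- data.frame(z = 1:20)
#' d$x <- d$z + rnorm(20, sd = 0.5)
#' d$y <- d$z + rnorm(20, sd = 0.5)
#' partial_correlation(d, "x", "y", controls = "z")
#' @export
partial_correlation <- function(data, x, y, controls = character(),
                                alpha = 0.05) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "grainfill_error_schema")
  }
  cols <- c(x, y, controls)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "grainfill_error_schema")
  }
  check_alpha(alpha)
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  k <- length(controls)
  if (nrow(d) < k + 3) {
    abort("Need at least length(controls) + 3 complete rows.",
          class = "grainfill_error_insufficient")
  }
  if (k > 0) {
    X <- stats::model.matrix(
      ~ ., data = d[, controls, drop = FALSE]
    )
    if (qr(X)$rank < ncol(X)) {
      abort("Control columns are collinear (rank-deficient design).",
            class = "grainfill_error_rank")
    }
    rx <- stats::lm.fit(X, d[[x]])$residuals
    ry <- stats::lm.fit(X, d[[y]])$residuals
  } else {
    rx <- d[[x]]
    ry <- d[[y]]
  }
  res <- pearson_pair(rx, ry, df = nrow(d) - 2 - k)
  dplyr::mutate(
    dplyr::bind_cols(tibble(x_name = x, y_name = y), res),
    significant = !is.na(.data$p_value) & .data$p_value < alpha,
    controls = paste(controls, collapse = ",")
  )
}

#' Quadratic trend fit between two columns
#'
#' Convenience utility fitting the second-degree polynomial
#' `y ~ x + x^2` by ordinary least squares, for screening curvilinear
#' characteristic-trait relationships alongside the linear correlations.
#'
#' @inheritParams partial_correlation
#' @return A one-row tibble with the intercept, linear and quadratic
#'   coefficients and the regression `r_squared`.
#' @export
quadratic_trend <- function(data, x, y) {
  if (!is.data.frame(data) || !all(c(x, y) %in% names(data))) {
    abort("`data` must contain the named columns.",
          class = "grainfill_error_schema")
  }
  d <- data[complete.cases(data[c(x, y)]), c(x, y)]
  if (nrow(d) < 4) {
    abort("Need at least 4 complete rows for a quadratic fit.",
          class = "grainfill_error_insufficient")
  }
  fit <- lm(d[[y]] ~ poly(d[[x]], 2, raw = TRUE))
  cf <- unname(coef(fit))
  tibble(
    x_name = x, y_name = y,
    intercept = cf[1], linear = cf[2], quadratic = cf[3],
    r_squared = summary(fit)$r.squared,
    n = nrow(d)
  )
}

# Pearson r, p (two-sided t), n over complete pairs; df overrides n - 2
pearson_pair <- function(x, y, df = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("Fewer than 3 complete pairs.",
          class = "grainfill_error_insufficient")
  }
  if (sd(x) < .Machine$double.eps || sd(y) < .Machine$double.eps) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- cor(x, y)
  if (is.null(df)) df <- n - 2
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = df)
  }
  tibble(r = r, p_value = p, n = n)
}

check_alpha <- function(alpha, call = rlang::caller_env()) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single probability in (0, 1).",
          class = "grainfill_error_domain", call = call)
  }
  invisible(TRUE)
}
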