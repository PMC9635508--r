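#' Derived grain-filling characteristics of a Richards curve
#'
#' Takes a data frame with Richards parameter columns `A`, `B`, `K`, `N`
#' (one row per fitted grain-weight series) and appends the closed-form
#' kinetic characteristics of the filling process:
#'
#' * `R0` — initial relative growth rate, `K/N` (per day);
#' * `GFR_max` — maximum filling rate, \eqn{AK(1+N)^{-(N+1)/N}}
#'   (mg grain\eqn{^{-1}} day\eqn{^{-1}});
#' * `T_max` — time of maximum filling rate, \eqn{(\ln B - \ln N)/K} (days);
#' * `W_max` — grain weight at the rate peak, \eqn{A(N+1)^{-1/N}} (mg);
#' * `GFR_avg` — average filling rate, \eqn{AK/(2(N+2))};
#' * `GFD` — active grain-filling duration, the time to reach
#'   `gfd_fraction` of `A` (days, via [time_to_fraction()]);
#' * `t1`, `t2` — rate-curve inflection times bounding the middle sub-phase
#'   ([inflection_times()]);
#' * `frac_start`, `frac_middle`, `frac_late` — sub-phase contributions to
#'   final weight ([phase_contributions()]).
#'
#' When `B <= N` the rate peak falls at or before the time origin
#' (`T_max <= 0`); such near-degenerate fits do occur on slowly filling
#' inferior-grain series and are reported with the warning flag
#' `"pre_anthesis_maximum"` in the `warnings` column rather than rejected.
#'
#' @param data A data frame with numeric columns `A`, `B`, `K`, `N`; any
#'   other columns (cultivar, site, year, grain class, ...) are carried
#'   through unchanged.
#' @param gfd_fraction Fraction of final weight defining the end of active
#'   grain filling. Default 0.99.
#' @return A tibble: `data` plus the characteristic columns above and a
#'   `warnings` character column (`""` when clean).
#' @examples
#' library(tibble)
#' params <- tibble(A = 22.91, B = 13.79, K = 0.24, N = 0.55)
#' filling_characteristics(params)
#' @export
filling_characteristics <- function(data, gfd_fraction = 0.99) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "grainfill_error_schema")
  }
  missing_cols <- setdiff(c("A", "B", "K", "N"), names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("`data` is missing Richards parameter column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "grainfill_error_schema"
    )
  }
  if (!is.numeric(gfd_fraction) || length(gfd_fraction) != 1 ||
      gfd_fraction <= 0.9 || gfd_fraction >= 0.9999) {
    abort("`gfd_fraction` must be a single number in (0.9, 0.9999).",
          class = "grainfill_error_domain")
  }
  A <- data$A; B <- data$B; K <- data$K; N <- data$N
  check_params(A, B, K, N)

  ti <- inflection_times(A, B, K, N)
  ph <- phase_contributions(A, B, K, N)
  out <- dplyr::mutate(
    as_tibble(data),
    R0      = K / N,
    GFR_max = A * K * (1 + N)^(-(N + 1) / N),
    T_max   = (log(B) - log(N)) / K,
    W_max   = A * (N + 1)^(-1 / N),
    GFR_avg = A * K / (2 * (N + 2)),
    GFD     = time_to_fraction(gfd_fraction, A, B, K, N),
    t1      = ti$t1,
    t2      = ti$t2,
    frac_start  = ph$frac_start,
    frac_middle = ph$frac_middle,
    frac_late   = ph$frac_late,
    warnings = ifelse(B <= N, "pre_anthesis_maximum", "")
  )
  out
}
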