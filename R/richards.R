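#' The Richards growth equation
#'
#' `richards_weight()` evaluates the four-parameter Richards (generalised
#' logistic) growth law
#' \deqn{W(t) = A \, (1 + B e^{-Kt})^{-1/N},}
#' the standard model for grain dry-weight accumulation after anthesis.
#' `filling_rate()` evaluates its time derivative, the grain-filling rate
#' \deqn{\mathrm{GFR}(t) = \frac{dW}{dt}
#'   = \frac{AK}{N}\, u \,(1+u)^{-(N+1)/N}, \qquad u = B e^{-Kt}.}
#'
#' Time is measured in days after panicle labeling (approximately anthesis);
#' weight in mg per grain. The curve is strictly increasing, approaches the
#' final grain weight `A` as `t` grows, and reduces to the logistic law at
#' `N = 1`. All arguments are vectorised and recycled against each other.
#'
#' @param t Time in days after labeling. Negative values are permitted; the
#'   model is defined for all real `t`.
#' @param A Final grain weight, mg per grain. Must be positive.
#' @param B Position constant (dimensionless, positive); together with `K` it
#'   locates the curve on the time axis.
#' @param K Intrinsic rate constant, per day. Must be positive.
#' @param N Shape parameter (dimensionless, positive) controlling the
#'   asymmetry of the sigmoid; `N = 1` gives the symmetric logistic.
#'
#' @return A numeric vector: grain weight in mg (`richards_weight`) or
#'   filling rate in mg grain\eqn{^{-1}} day\eqn{^{-1}} (`filling_rate`).
#' @examples
#' richards_weight(c(0, 10, 20, 45), A = 22.91, B = 13.79, K = 0.24, N = 0.55)
#' filling_rate(13.4, A = 22.91, B = 13.79, K = 0.24, N = 0.55)
#' @seealso [filling_characteristics()] for the derived kinetic quantities.
#' @export
richards_weight <- function(t, A, B, K, N) {
  check_params(A, B, K, N)
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("`t` must be finite numeric.", class = "grainfill_error_domain")
  }
  u <- B * exp(-K * t)
  A * (1 + u)^(-1 / N)
}

#' @rdname richards_weight
#' @export
filling_rate <- function(t, A, B, K, N) {
  check_params(A, B, K, N)
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("`t` must be finite numeric.", class = "grainfill_error_domain")
  }
  u <- B * exp(-K * t)
  (A * K / N) * u * (1 + u)^(-(N + 1) / N)
}

#' Invert the Richards curve: time to reach a fraction of final weight
#'
#' Solves \eqn{W(t) = p A} in closed form,
#' \deqn{t_p = \frac{\ln B - \ln(p^{-N} - 1)}{K}.}
#' The solution is unique because the curve is strictly increasing; it may be
#' negative when the fraction is already reached before labeling. The active
#' grain-filling duration (GFD) reported by [filling_characteristics()] is
#' `time_to_fraction(0.99, ...)`, the time to reach 99% of `A`.
#'
#' @param p Fraction of the final weight `A`, strictly between 0 and 1.
#' @inheritParams richards_weight
#' @return Time in days, vectorised over the inputs.
#' @examples
#' # active filling duration of a representative superior-grain curve
#' time_to_fraction(0.99, A = 23.78, B = 9.01, K = 0.25, N = 0.60)
#' @export
time_to_fraction <- function(p, A, B, K, N) {
  check_params(A, B, K, N)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly between 0 and 1.",
          class = "grainfill_error_domain")
  }
  (log(B) - log(p^(-N) - 1)) / K
}

#' Inflection times of the filling-rate curve
#'
#' The rate curve GFR(t) is unimodal; its two inflection points (zeros of the
#' second derivative of the rate, i.e. of \eqn{d^3W/dt^3}) delimit the start,
#' middle and late sub-phases of grain filling. In terms of
#' \eqn{u = B e^{-Kt}} they are the roots of
#' \eqn{u^2 - N(N+3)u + N^2 = 0},
#' \deqn{u_\pm = \frac{N}{2}\left[(N+3) \pm \sqrt{(N+1)(N+5)}\right],}
#' giving \eqn{t_i = (\ln B - \ln u_i)/K}. Because \eqn{u_+ u_- = N^2} the
#' times are symmetric about the rate peak: \eqn{t_1 + t_2 = 2 T_{max}}.
#'
#' @inheritParams richards_weight
#' @return A tibble with columns `t1` and `t2` (days), `t1 < t2`.
#' @examples
#' inflection_times(A = 22.91, B = 13.79, K = 0.24, N = 0.55)
#' @export
inflection_times <- function(A, B, K, N) {
  check_params(A, B, K, N)
  disc <- sqrt((N + 1) * (N + 5))
  u_hi <- (N / 2) * ((N + 3) + disc)  # larger u <=> earlier time
  u_lo <- (N / 2) * ((N + 3) - disc)
  tibble(
    t1 = (log(B) - log(u_hi)) / K,
    t2 = (log(B) - log(u_lo)) / K
  )
}

#' Sub-phase contributions to final grain weight
#'
#' Splits the filling period at the rate-curve inflection times
#' ([inflection_times()]) into start (`t < t1`), middle (`t1..t2`) and late
#' (`t > t2`) sub-phases and reports the fraction of the final weight `A`
#' accumulated in each:
#' \deqn{f_{start} = \frac{W(t_1) - W(0)}{A},\quad
#'       f_{middle} = \frac{W(t_2) - W(t_1)}{A},\quad
#'       f_{late} = \frac{A - W(t_2)}{A}.}
#' The three fractions sum to \eqn{1 - W(0)/A} (the weight already present at
#' labeling is not attributed to any sub-phase). `frac_middle` depends on the
#' shape parameter `N` only; for typical grain-filling fits it is close to
#' 0.6, i.e. the middle sub-phase accounts for roughly 60% of grain weight.
#'
#' @inheritParams richards_weight
#' @return A tibble with columns `frac_start`, `frac_middle`, `frac_late`,
#'   each in (0, 1).
#' @examples
#' phase_contributions(A = 22.91, B = 13.79, K = 0.24, N = 0.55)
#' @export
phase_contributions <- function(A, B, K, N) {
  check_params(A, B, K, N)
  ti <- inflection_times(A, B, K, N)
  w0 <- richards_weight(0, A, B, K, N)
  w1 <- richards_weight(ti$t1, A, B, K, N)
  w2 <- richards_weight(ti$t2, A, B, K, N)
  tibble(
    frac_start  = (w1 - w0) / A,
    frac_middle = (w2 - w1) / A,
    frac_late   = (A - w2) / A
  )
}

# shared parameter-domain validation; vectorised
check_params <- function(A, B, K, N, call = rlang::caller_env()) {
  for (nm in c("A", "B", "K", "N")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) == 0 || any(!is.finite(v)) || any(v <= 0)) {
      abort(
        paste0("Richards parameter `", nm, "` must be finite and positive."),
        class = "grainfill_error_params", call = call
      )
    }
  }
  invisible(TRUE)
}
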