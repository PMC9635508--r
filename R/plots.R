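#' Plot fitted grain-filling curves over the observations
#'
#' Observed dry weights as points with the fitted Richards curve overlaid,
#' one facet per series.
#'
#' @param object A `richards_fit` from [fit_richards()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.richards_fit <- function(object, ...) {
  plot_filling_curves(object)
}

#' @rdname autoplot.richards_fit
#' @param fit A `richards_fit`.
#' @export
plot_filling_curves <- function(fit, ...) {
  stopifnot(inherits(fit, "richards_fit"))
  keys <- fit$options$keys
  obs <- unite_label(fit$data, keys)
  grid <- fit$fits |>
    dplyr::select(dplyr::all_of(c(keys, "A", "B", "K", "N"))) |>
    tidyr::expand_grid(day = seq(0, max(fit$data$day), length.out = 200)) |>
    dplyr::mutate(weight_mg = richards_weight(.data$day, .data$A, .data$B,
                                              .data$K, .data$N)) |>
    unite_label(keys)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$day,
                                         y = .data$weight_mg)) +
    ggplot2::geom_point(size = 1.4, alpha = 0.8) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(x = "Days after labeling", y = "Grain dry weight (mg)") +
    ggplot2::theme_minimal()
  if (".series" %in% names(obs)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$.series))
  }
  p
}

#' Plot fitted grain-filling rate curves
#'
#' The analytic filling-rate curve of every fitted series, with the rate
#' peak (`T_max`, `GFR_max`) and the sub-phase boundaries `t1`, `t2` marked.
#'
#' @inheritParams plot_filling_curves
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_filling_rates <- function(fit, ...) {
  stopifnot(inherits(fit, "richards_fit"))
  keys <- fit$options$keys
  grid <- fit$fits |>
    dplyr::select(dplyr::all_of(c(keys, "A", "B", "K", "N"))) |>
    tidyr::expand_grid(day = seq(0, max(fit$data$day), length.out = 200)) |>
    dplyr::mutate(rate = filling_rate(.data$day, .data$A, .data$B,
                                      .data$K, .data$N)) |>
    unite_label(keys)
  marks <- fit$fits |>
    dplyr::select(dplyr::all_of(c(keys, "t1", "T_max", "t2"))) |>
    tidyr::pivot_longer(dplyr::all_of(c("t1", "T_max", "t2")),
                        names_to = "boundary", values_to = "day") |>
    unite_label(keys)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$day, y = .data$rate)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$day,
                                     linetype = .data$boundary),
                        alpha = 0.6) +
    ggplot2::labs(x = "Days after labeling",
                  y = "Filling rate (mg/grain/day)", linetype = NULL) +
    ggplot2::theme_minimal()
  if (".series" %in% names(grid)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$.series))
  }
  p
}

unite_label <- function(data, keys) {
  if (length(keys) == 0) return(data)
  tidyr::unite(data, ".series", dplyr::all_of(keys), sep = " / ",
               remove = FALSE)
}
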