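#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cost breakdown
#'
#' Stacked single-bar view of the per-case cost categories.
#'
#' @param object A `cost_breakdown`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cost_breakdown <- function(object, ...) {
  df <- tibble::as_tibble(object)
  sc <- attr(object, "scenario")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(sc$cases_per_year),
                                   y = .data$eur_per_case,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cases per year", y = "EUR per case",
                  title = sprintf("Per-case cost, %s scenario", sc$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a sweep result
#'
#' Per-case total (solid) against the sweep axis; category curves can be
#' added by plotting `tidy(sweep)` directly.
#'
#' @param object A `cost_sweep` from [volume_sweep()] or [coverage_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cost_sweep <- function(object, ...) {
  axis <- attr(object, "axis_var")
  totals <- sweep_totals(object)
  ggplot2::ggplot(totals, ggplot2::aes(x = .data[[axis]],
                                       y = .data$total_eur_per_case)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = gsub("_", " ", axis), y = "EUR per case") +
    ggplot2::theme_minimal()
}
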