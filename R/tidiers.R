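#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost breakdown
#'
#' @param x A `cost_breakdown`.
#' @param ... Unused.
#' @return Tibble with one row per cost category: `category`, `eur_per_case`
#'   and the category's `share` of the pre-overhead total.
#' @export
tidy.cost_breakdown <- function(x, ...) {
  category_shares(x)[c("category", "eur_per_case", "share")]
}

#' One-row summary of a cost breakdown
#'
#' @param x A `cost_breakdown`.
#' @param ... Unused.
#' @return One-row tibble: scenario settings, pre-overhead total, overhead
#'   and total with overhead (full precision).
#' @export
glance.cost_breakdown <- function(x, ...) {
  sc <- attr(x, "scenario")
  tibble::tibble(
    cases_per_year = sc$cases_per_year,
    mode = sc$mode,
    error_rate = sc$error_rate,
    overhead_rate = sc$overhead_rate,
    total_eur_per_case = attr(x, "total_eur_per_case"),
    overhead_eur_per_case = attr(x, "overhead_eur_per_case"),
    total_with_overhead_eur_per_case = attr(x, "total_with_overhead_eur_per_case")
  )
}

#' Tidy a sweep result
#'
#' @param x A `cost_sweep`.
#' @param ... Unused.
#' @return The sweep as a plain long tibble (axis, category, EUR per case,
#'   per-axis total).
#' @export
tidy.cost_sweep <- function(x, ...) tibble::as_tibble(x)
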