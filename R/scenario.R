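#' Economic (inflation/deflation) scenario
#'
#' Deterministic annual compounding applied per cost category over a horizon.
#' Under inflation the equipment categories are excluded (equipment is bought
#' once, before the horizon, and its replacement is deliberately not
#' modelled). Under deflation personnel is additionally shielded, since
#' tariff wages do not usually fall during deflation.
#'
#' @param annual_rate Annual rate as a fraction (e.g. 0.02).
#' @param direction `"inflation"` or `"deflation"`.
#' @param horizon_years Number of years modelled (>= 0).
#' @param excluded_categories Categories the rate is not applied to. Defaults
#'   by direction: equipment capital + maintenance for inflation, those plus
#'   personnel for deflation. Equipment capital is always excluded.
#' @return A list of class `economic_scenario`.
#' @examples
#' economic_scenario(0.02, "inflation", 10)
#' @export
economic_scenario <- function(annual_rate,
                              direction = c("inflation", "deflation"),
                              horizon_years,
                              excluded_categories = NULL) {
  direction <- match.arg(direction)
  stopifnot(annual_rate >= 0, horizon_years >= 0)
  if (is.null(excluded_categories)) {
    excluded_categories <- c("equipment_capital", "equipment_maintenance")
    if (direction == "deflation") {
      excluded_categories <- c(excluded_categories, "personnel")
    }
  }
  must <- if (direction == "deflation") c("equipment_capital", "personnel")
          else "equipment_capital"
  if (!all(must %in% excluded_categories)) {
    stop(sprintf("%s must exclude at least: %s", direction,
                 paste(must, collapse = ", ")), call. = FALSE)
  }
  structure(list(annual_rate = annual_rate, direction = direction,
                 horizon_years = horizon_years,
                 excluded_categories = excluded_categories),
            class = "economic_scenario")
}

#' Project a cost breakdown under inflation or deflation
#'
#' Each non-excluded category is multiplied by `(1 + rate)^year` (inflation)
#' or `(1 - rate)^year` (deflation); excluded categories are unchanged.
#' Year 0 is the identity. Because the exclusion sets are asymmetric,
#' projecting inflation and then the matching deflation does not return the
#' original breakdown.
#'
#' @param breakdown A `cost_breakdown` from [total_cost_per_case()].
#' @param econ An [economic_scenario()].
#' @param year Year within the horizon (`0 <= year <= horizon_years`).
#' @return A `cost_breakdown` with projected categories and totals.
#' @export
project_economics <- function(breakdown, econ, year) {
  stopifnot(inherits(breakdown, "cost_breakdown"),
            inherits(econ, "economic_scenario"),
            year >= 0, year <= econ$horizon_years)
  rate <- if (econ$direction == "inflation") econ$annual_rate else -econ$annual_rate
  factor <- (1 + rate)^year
  out <- breakdown
  apply_to <- !(out$category %in% econ$excluded_categories)
  out$eur_per_case[apply_to] <- out$eur_per_case[apply_to] * factor
  total <- sum(out$eur_per_case)
  overhead_rate <- attr(breakdown, "scenario")$overhead_rate
  attr(out, "total_eur_per_case") <- total
  attr(out, "overhead_eur_per_case") <- total * overhead_rate
  attr(out, "total_with_overhead_eur_per_case") <- total * (1 + overhead_rate)
  out
}

new_cost_sweep <- function(rows, axis_var) {
  structure(rows, class = c("cost_sweep", class(rows)), axis_var = axis_var)
}

sweep_row <- function(breakdown, axis_var, axis_value) {
  df <- tibble::as_tibble(breakdown)
  df[[axis_var]] <- axis_value
  df$total_eur_per_case <- attr(breakdown, "total_with_overhead_eur_per_case")
  df[c(axis_var, "category", "eur_per_case", "total_eur_per_case")]
}

#' Case-volume sweep
#'
#' Recomputes the per-case breakdown over a grid of annual case volumes.
#' Between platform-capacity boundaries per-case totals are non-increasing
#' (equipment, R&D and annual-FTE personnel scale with 1/volume); crossing a
#' capacity boundary adds a platform and produces an upward equipment jump.
#'
#' @param ledger A [cost_ledger()].
#' @param volumes Ascending vector of cases/year (default the standard grid
#'   100 to 4000 in steps of 100).
#' @param mode,error_rate,overhead_rate Scenario settings applied at every
#'   volume (see [caseload_scenario()]).
#' @param cfg A [sequencing_config()].
#' @param cap A [platform_capacity_spec()].
#' @param flowcell Optional [flowcell_spec()] (or catalogue name) used to
#'   re-price the flow-cell consumable from coverage.
#' @return A `cost_sweep`: long tibble with `cases_per_year`, `category`,
#'   `eur_per_case` and the per-volume `total_eur_per_case`.
#' @examples
#' volume_sweep(calibrated_ledger("twist"), volumes = c(300, 2000))
#' @export
volume_sweep <- function(ledger, volumes = seq(100, 4000, by = 100),
                         mode = "idealised", error_rate = NULL,
                         overhead_rate = 0,
                         cfg = sequencing_config(),
                         cap = platform_capacity_spec(),
                         flowcell = NULL) {
  stopifnot(!is.unsorted(volumes, strictly = TRUE))
  rows <- purrr::map(volumes, function(v) {
    sc <- caseload_scenario(v, mode = mode, error_rate = error_rate,
                            overhead_rate = overhead_rate)
    sweep_row(total_cost_per_case(ledger, sc, cfg, cap, flowcell),
              "cases_per_year", v)
  })
  new_cost_sweep(dplyr::bind_rows(rows), "cases_per_year")
}

#' Tumour-coverage sweep
#'
#' Recomputes the breakdown over a grid of tumour mean coverages. The
#' flow-cell consumable, the per-gigabase data cost and the platform count
#' are re-derived at each coverage; totals are non-decreasing in coverage.
#' Coverages unreachable on the flow cell (zero patients per flow cell) are
#' marked rather than raising an error.
#'
#' @inheritParams volume_sweep
#' @param coverages Ascending vector of tumour mean coverages (default the
#'   standard grid 100, 250, 500, 1000).
#' @param cases_per_year Case volume held fixed across the sweep.
#' @param flowcell A [flowcell_spec()] or catalogue name (default the 25B
#'   flow cell); required to re-price sequencing from coverage.
#' @return A `cost_sweep` over `coverage_tumor` with an `unreachable` flag.
#' @examples
#' coverage_sweep(calibrated_ledger("twist"), cases_per_year = 300,
#'                coverages = c(100, 500))
#' @export
coverage_sweep <- function(ledger, coverages = c(100, 250, 500, 1000),
                           cases_per_year = 300,
                           mode = "idealised", error_rate = NULL,
                           overhead_rate = 0,
                           cfg = sequencing_config(),
                           cap = platform_capacity_spec(),
                           flowcell = "NovaSeq X 25B",
                           catalogue = flowcell_catalogue()) {
  stopifnot(!is.unsorted(coverages, strictly = TRUE))
  if (is.character(flowcell)) flowcell <- catalogue_flowcell(flowcell, catalogue)
  sc <- caseload_scenario(cases_per_year, mode = mode, error_rate = error_rate,
                          overhead_rate = overhead_rate)
  rows <- purrr::map(coverages, function(d_t) {
    cfg_c <- sequencing_config(coverage_tumor = d_t,
                               coverage_normal = cfg$coverage_normal,
                               efficiency = cfg$efficiency,
                               genome_size = cfg$genome_size)
    if (patients_per_flowcell(flowcell, cfg_c) < 1) {
      out <- sweep_row(total_cost_per_case(ledger, sc, cfg_c, cap, NULL),
                       "coverage_tumor", d_t)
      out$eur_per_case <- NA_real_
      out$total_eur_per_case <- NA_real_
      out$unreachable <- TRUE
      return(out)
    }
    out <- sweep_row(total_cost_per_case(ledger, sc, cfg_c, cap, flowcell),
                     "coverage_tumor", d_t)
    out$unreachable <- FALSE
    out
  })
  new_cost_sweep(dplyr::bind_rows(rows), "coverage_tumor")
}

#' Per-axis totals of a sweep
#'
#' @param sweep A `cost_sweep`.
#' @return Tibble with one row per axis value and its per-case total.
#' @export
sweep_totals <- function(sweep) {
  axis <- attr(sweep, "axis_var")
  dplyr::distinct(tibble::as_tibble(sweep)[c(axis, "total_eur_per_case")])
}

#' Compare two library-preparation protocols
#'
#' Runs the same scenario on two ledgers (e.g. mechanical-shearing vs
#' tagmentation library preparation) and reports per-category deltas.
#'
#' @param ledger_a,ledger_b Two [cost_ledger()]s.
#' @param scenario A [caseload_scenario()].
#' @inheritParams total_cost_per_case
#' @param labels Length-2 character vector naming the protocols.
#' @return Tibble with per-category costs for both ledgers, the delta
#'   (A - B), and a `total` row.
#' @examples
#' compare_protocols(calibrated_ledger("twist"),
#'                   calibrated_ledger("tagmentation"),
#'                   caseload_scenario(300))
#' @export
compare_protocols <- function(ledger_a, ledger_b, scenario,
                              cfg = sequencing_config(),
                              cap = platform_capacity_spec(),
                              flowcell = NULL,
                              labels = c("A", "B")) {
  ba <- total_cost_per_case(ledger_a, scenario, cfg, cap, flowcell)
  bb <- total_cost_per_case(ledger_b, scenario, cfg, cap, flowcell)
  out <- tibble::tibble(
    category = c(ba$category, "total"),
    a = c(ba$eur_per_case, breakdown_total(ba)),
    b = c(bb$eur_per_case, breakdown_total(bb))
  )
  names(out)[2:3] <- labels
  out$delta <- out[[2]] - out[[3]]
  out
}
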