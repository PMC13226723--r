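#' Caseload scenario
#'
#' Annual case volume plus the allocation mode and surcharges of a costing
#' scenario. In the idealised mode personnel are costed by hands-on minutes
#' where these were determined; in the realistic mode every role is staffed in
#' whole or half positions with vacation/sick-leave redundancy, backup
#' equipment units are counted, and a re-sequencing error surcharge applies.
#'
#' @param cases_per_year Diagnosed cases per year (>= 1).
#' @param mode `"idealised"` or `"realistic"`.
#' @param error_rate Fraction of cases requiring re-sequencing, in `[0, 1)`.
#'   Defaults to 0.01 in realistic mode (1 in 100 cases) and 0 in idealised
#'   mode; 0.05 and 0.15 are common sensitivity settings.
#' @param overhead_rate Flat overhead multiplier applied last (default 0;
#'   0.20 in overhead analyses).
#' @param redundancy_threshold_cases Case volume above which roles use their
#'   `redundancy_fte_high` cover instead of `redundancy_fte_low` (default
#'   1000; staffing cover grows from half to full positions with volume).
#' @return A list of class `caseload_scenario`.
#' @examples
#' caseload_scenario(300)
#' caseload_scenario(2000, mode = "realistic")
#' @export
caseload_scenario <- function(cases_per_year,
                              mode = c("idealised", "realistic"),
                              error_rate = NULL,
                              overhead_rate = 0,
                              redundancy_threshold_cases = 1000) {
  mode <- match.arg(mode)
  if (is.null(error_rate)) error_rate <- if (mode == "realistic") 0.01 else 0
  stopifnot(cases_per_year >= 1, error_rate >= 0, error_rate < 1,
            overhead_rate >= 0, is.finite(overhead_rate))
  structure(list(cases_per_year = cases_per_year, mode = mode,
                 error_rate = error_rate, overhead_rate = overhead_rate,
                 redundancy_threshold_cases = redundancy_threshold_cases),
            class = "caseload_scenario")
}

# staffing cover in force at this scenario's volume
role_redundancy <- function(personnel, scenario) {
  if (scenario$cases_per_year <= scenario$redundancy_threshold_cases) {
    personnel$redundancy_fte_low
  } else {
    personnel$redundancy_fte_high
  }
}

ceil_to_increment <- function(x, increment) ceiling(x / increment) * increment

#' Per-case equipment cost
#'
#' Capital is amortised linearly over each item's operating life
#' (`purchase_price / operating_years`); capital and maintenance are divided
#' by the annual case volume. In realistic mode each item's `backup_units`
#' are added. Sequencing-platform items are multiplied by the number of
#' platforms the volume requires at the configured coverage, which produces
#' the capacity step in volume sweeps.
#'
#' @param ledger A [cost_ledger()].
#' @param scenario A [caseload_scenario()].
#' @param cfg A [sequencing_config()] (sets the tumour coverage used for the
#'   platform count).
#' @param cap A [platform_capacity_spec()].
#' @return Tibble with one row per equipment item: unit count, per-case
#'   capital and maintenance.
#' @export
equipment_per_case <- function(ledger, scenario, cfg = sequencing_config(),
                               cap = platform_capacity_spec()) {
  stopifnot(inherits(ledger, "cost_ledger"), inherits(scenario, "caseload_scenario"))
  eq <- ledger$equipment
  v <- scenario$cases_per_year
  n_platforms <- platforms_required(v, cap, cfg$coverage_tumor)
  base_units <- ifelse(eq$is_sequencing_platform, n_platforms, 1)
  units <- base_units + if (scenario$mode == "realistic") eq$backup_units else 0
  tibble::tibble(
    name = eq$name,
    units = units,
    capital_eur_per_case = eq$purchase_price_eur / eq$operating_years * units / v,
    maintenance_eur_per_case = eq$annual_maintenance_eur * units / v
  )
}

#' Per-role personnel cost per case
#'
#' Idealised mode: hands-on roles cost `minutes * annual_cost /
#' annual_working_minutes` per case; annual-FTE roles cost `base_fte *
#' annual_cost / cases_per_year`.
#'
#' Realistic mode: hands-on roles are staffed in positions,
#' `positions = ceil(workload / fte_increment) * fte_increment + redundancy`,
#' where `workload = cases * minutes / annual_working_minutes` and the
#' redundancy cover depends on the volume band; annual-FTE roles keep their
#' base FTE unless a `cases_per_fte` capacity is set, in which case staffing
#' steps up as `max(base_fte, ceil_to_half(cases / cases_per_fte))`, plus the
#' role's redundancy cover.
#'
#' @inheritParams equipment_per_case
#' @return Tibble with one row per role: positions (realistic) and per-case
#'   cost.
#' @export
personnel_per_case <- function(ledger, scenario) {
  stopifnot(inherits(ledger, "cost_ledger"), inherits(scenario, "caseload_scenario"))
  pe <- ledger$personnel
  if (!nrow(pe)) {
    return(tibble::tibble(name = character(), positions = numeric(),
                          eur_per_case = numeric()))
  }
  v <- scenario$cases_per_year
  red <- role_redundancy(pe, scenario)
  hands_on <- pe$allocation == "hands_on"
  minutes <- ifelse(hands_on, pe$hands_on_minutes_per_case, 0)
  workload_fte <- v * minutes / pe$annual_working_minutes

  if (scenario$mode == "idealised") {
    positions <- ifelse(hands_on, workload_fte, pe$base_fte)
    cost <- ifelse(hands_on,
                   minutes * pe$annual_cost_eur / pe$annual_working_minutes,
                   pe$base_fte * pe$annual_cost_eur / v)
  } else {
    step_fte <- ifelse(is.finite(pe$cases_per_fte),
                       pmax(pe$base_fte, ceil_to_increment(v / pe$cases_per_fte, 0.5)),
                       pe$base_fte)
    positions <- ifelse(hands_on,
                        ceil_to_increment(workload_fte, pe$fte_increment) + red,
                        step_fte + red)
    cost <- positions * pe$annual_cost_eur / v
  }
  tibble::tibble(name = pe$name, allocation = pe$allocation,
                 positions = positions, eur_per_case = cost)
}

#' Idealised per-case personnel cost
#'
#' @inheritParams equipment_per_case
#' @return Total per-case personnel cost in EUR under hands-on allocation.
#' @export
personnel_idealised <- function(ledger, scenario) {
  scenario$mode <- "idealised"
  sum(personnel_per_case(ledger, scenario)$eur_per_case)
}

#' Realistic (whole-position) per-case personnel cost
#'
#' Always at least [personnel_idealised()] for the same ledger: position
#' ceilings and redundancy only add cost.
#'
#' @inheritParams equipment_per_case
#' @return Total per-case personnel cost in EUR under position staffing.
#' @export
personnel_realistic <- function(ledger, scenario) {
  scenario$mode <- "realistic"
  sum(personnel_per_case(ledger, scenario)$eur_per_case)
}

#' Per-case computational data-processing and storage cost
#'
#' `per_gigabase_eur * gigabases_per_case(cfg) + per_case_licence_eur +
#' per_case_storage_eur`; strictly increasing in coverage whenever the
#' per-gigabase price is positive.
#'
#' @inheritParams equipment_per_case
#' @return Per-case data cost in EUR.
#' @export
data_costs_per_case <- function(ledger, cfg = sequencing_config()) {
  stopifnot(inherits(ledger, "cost_ledger"))
  dc <- ledger$data_costs
  dc$per_gigabase_eur * gigabases_per_case(cfg) +
    dc$per_case_licence_eur + dc$per_case_storage_eur
}

#' Assemble the per-case cost breakdown
#'
#' Combines all cost categories for one scenario into a `cost_breakdown`:
#' consumables (WGS and WTS; shared items are folded into the WGS column),
#' personnel, equipment capital and maintenance, research & development
#' (annual flat fee / volume), and computational data analysis/storage.
#'
#' The re-sequencing error surcharge multiplies consumables and the compute
#' components of data costs (base-calling and interpretation licences) by
#' `1 + error_rate`; long-term storage is exempt because failed runs are not
#' archived. Overhead is applied last to the post-surcharge total and
#' reported as a separate additive line.
#'
#' When `flowcell` is supplied, the ledger's flow-cell item is re-priced from
#' the throughput equation at the configured coverage
#' ([flowcell_cost_per_case()]); otherwise the item's static ledger price is
#' used (the calibrated ledger stores the base-case value, so both routes
#' agree at default coverage).
#'
#' @inheritParams equipment_per_case
#' @param flowcell Optional [flowcell_spec()] used to re-price the flow-cell
#'   consumable from coverage, or a flow-cell name resolved in `catalogue`.
#' @param catalogue Flow-cell catalogue used when `flowcell` is a name.
#' @return A `cost_breakdown`: tibble of the seven cost categories with
#'   per-case EUR, carrying the scenario, totals and overhead as attributes.
#'   The category sum equals the pre-overhead total exactly.
#' @examples
#' ledger <- calibrated_ledger("twist")
#' total_cost_per_case(ledger, caseload_scenario(300))
#' @export
total_cost_per_case <- function(ledger, scenario,
                                cfg = sequencing_config(),
                                cap = platform_capacity_spec(),
                                flowcell = NULL,
                                catalogue = flowcell_catalogue()) {
  stopifnot(inherits(ledger, "cost_ledger"), inherits(scenario, "caseload_scenario"))
  v <- scenario$cases_per_year
  r <- scenario$error_rate

  if (is.character(flowcell)) flowcell <- catalogue_flowcell(flowcell, catalogue)

  items <- consumable_items(ledger)
  fc_cost <- NA_real_
  if (!is.null(flowcell)) {
    idx <- which(items$is_flowcell)
    if (length(idx)) {
      fc_cost <- flowcell_cost_per_case(flowcell, cfg)
      items$eur_per_case[idx] <- fc_cost
    }
  } else if (any(items$is_flowcell)) {
    fc_cost <- sum(items$eur_per_case[items$is_flowcell])
  }
  cons_wgs <- sum(items$eur_per_case[items$assay %in% c("WGS", "SHARED")])
  cons_wts <- sum(items$eur_per_case[items$assay == "WTS"])

  pers <- sum(personnel_per_case(ledger, scenario)$eur_per_case)
  eq <- equipment_per_case(ledger, scenario, cfg, cap)
  dc <- ledger$data_costs
  data_compute <- dc$per_gigabase_eur * gigabases_per_case(cfg) +
    dc$per_case_licence_eur
  data_storage <- dc$per_case_storage_eur
  rd <- ledger$rd_annual_eur / v

  categories <- tibble::tibble(
    category = c("consumables_wgs", "consumables_wts", "personnel",
                 "equipment_capital", "equipment_maintenance",
                 "research_development", "data_analysis_storage"),
    eur_per_case = c(cons_wgs * (1 + r),
                     cons_wts * (1 + r),
                     pers,
                     sum(eq$capital_eur_per_case),
                     sum(eq$maintenance_eur_per_case),
                     rd,
                     data_compute * (1 + r) + data_storage)
  )
  total <- sum(categories$eur_per_case)
  overhead <- total * scenario$overhead_rate
  structure(categories,
            class = c("cost_breakdown", class(categories)),
            scenario = scenario,
            config = cfg,
            flowcell_eur_per_case = fc_cost,
            surcharge_base_eur = cons_wgs + cons_wts + data_compute,
            total_eur_per_case = total,
            overhead_eur_per_case = overhead,
            total_with_overhead_eur_per_case = total + overhead)
}

#' Total per-case cost of a breakdown
#'
#' @param breakdown A `cost_breakdown`.
#' @param with_overhead Include the overhead line (default TRUE; the overhead
#'   line is 0 unless the scenario sets an overhead rate).
#' @return Per-case total in EUR (full precision; round with [round_cents()]).
#' @export
breakdown_total <- function(breakdown, with_overhead = TRUE) {
  if (with_overhead) attr(breakdown, "total_with_overhead_eur_per_case")
  else attr(breakdown, "total_eur_per_case")
}

#' Category shares of the total cost
#'
#' @param breakdown A `cost_breakdown`.
#' @return Tibble of categories with `share` fractions (summing to 1) and the
#'   0.1-percent rendering used in reports.
#' @examples
#' category_shares(total_cost_per_case(calibrated_ledger("twist"),
#'                                     caseload_scenario(300)))
#' @export
category_shares <- function(breakdown) {
  total <- attr(breakdown, "total_eur_per_case")
  if (!isTRUE(total > 0)) stop("shares undefined: breakdown total is zero", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(breakdown),
                share = .data$eur_per_case / total,
                share_pct = round(100 * .data$share, 1))
}

#' @export
print.cost_breakdown <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<cost_breakdown> %s, %d cases/year, error %.0f%%, overhead %.0f%%\n",
              sc$mode, sc$cases_per_year, 100 * sc$error_rate,
              100 * sc$overhead_rate))
  df <- tibble::as_tibble(x)
  cat(paste(sprintf("  %-22s %10s", df$category, format_eur(df$eur_per_case)),
            collapse = "\n"), "\n")
  if (sc$overhead_rate > 0) {
    cat(sprintf("  %-22s %10s\n", "overhead",
                format_eur(attr(x, "overhead_eur_per_case"))))
  }
  cat(sprintf("  %-22s %10s\n", "total per case",
              format_eur(attr(x, "total_with_overhead_eur_per_case"))))
  invisible(x)
}
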