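#' Flow-cell comparison table
#'
#' One row per catalogue flow cell at a given sequencing configuration:
#' patients per flow cell, flow cells consumed per case and the per-case
#' flow-cell cost, sorted by cost. Where not even one patient fits on a flow
#' cell at the requested coverage, the row is flagged `unreachable` and the
#' per-case cost is the price of the (whole) flow cells needed for a single
#' case — this is how benchtop flow cells reach five-digit per-case costs.
#'
#' @param catalogue Tibble from [flowcell_catalogue()] (or a path to one).
#' @param cfg A [sequencing_config()].
#' @return Tibble: `name`, `platform`, `patients_per_flowcell`,
#'   `flowcells_per_case`, `eur_per_case`, `unreachable`, sorted by
#'   `eur_per_case`.
#' @examples
#' flowcell_table(flowcell_catalogue(), sequencing_config())
#' @export
flowcell_table <- function(catalogue = flowcell_catalogue(),
                           cfg = sequencing_config()) {
  if (is.character(catalogue)) catalogue <- flowcell_catalogue(catalogue)
  if (!nrow(catalogue)) {
    warning("empty flow-cell catalogue", call. = FALSE)
    return(tibble::tibble(name = character(), platform = character(),
                          patients_per_flowcell = numeric(),
                          flowcells_per_case = numeric(),
                          eur_per_case = numeric(), unreachable = logical()))
  }
  rows <- purrr::pmap(catalogue, function(name, platform, n_reads, n_cycles,
                                          list_price_eur) {
    fc <- flowcell_spec(name, platform, n_reads, n_cycles, list_price_eur)
    cont <- patients_per_flowcell_continuous(fc, cfg)
    n <- floor(cont)
    if (n >= 1) {
      tibble::tibble(name = name, platform = platform,
                     patients_per_flowcell = n,
                     flowcells_per_case = 1 / n,
                     eur_per_case = round_cents(list_price_eur / n),
                     unreachable = FALSE)
    } else {
      cells <- ceiling(1 / cont)
      tibble::tibble(name = name, platform = platform,
                     patients_per_flowcell = 0,
                     flowcells_per_case = cells,
                     eur_per_case = round_cents(list_price_eur * cells),
                     unreachable = TRUE)
    }
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$eur_per_case)
}

#' Export a cost breakdown to CSV and JSON
#'
#' Machine-readable exports carry cent-rounded money, one row/object per
#' category plus the overhead line (when non-zero) and the total. Repeated
#' runs on the same inputs produce byte-identical files.
#'
#' @param breakdown A `cost_breakdown`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The exported table, invisibly.
#' @export
export_breakdown <- function(breakdown, csv_path = NULL, json_path = NULL) {
  sc <- attr(breakdown, "scenario")
  rows <- tibble::tibble(category = breakdown$category,
                         eur_per_case = round_cents(breakdown$eur_per_case))
  if (sc$overhead_rate > 0) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      category = "overhead",
      eur_per_case = round_cents(attr(breakdown, "overhead_eur_per_case"))))
  }
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    category = "total",
    eur_per_case = round_cents(attr(breakdown, "total_with_overhead_eur_per_case"))))
  if (!is.null(csv_path)) readr::write_csv(rows, csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(rows, json_path, dataframe = "rows", digits = NA)
  }
  invisible(rows)
}

#' Run a full costing report from a configuration
#'
#' Thin orchestration layer over the engine, used by the command-line script:
#' reads a ledger and a key-value (YAML) scenario configuration, computes the
#' breakdown and category shares, and writes `breakdown.csv`,
#' `breakdown.json`, `shares.csv` and a human-readable `summary.txt` into the
#' output directory. Every number in the summary is recomputable from the
#' machine-readable files.
#'
#' @param config Path to a YAML configuration or an equivalent named list.
#'   Recognised keys: `ledger` (path), `cases_per_year`, `mode`,
#'   `error_rate`, `overhead_rate`, `coverage_tumor`, `coverage_normal`,
#'   `efficiency`, `flowcell` (catalogue name), `capacity_base`,
#'   `capacity_base_coverage`, `out_dir`.
#' @param out_dir Output directory (overrides the config key; default `"."`).
#' @return The `cost_breakdown`, invisibly.
#' @export
run_report <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  pick <- function(key, default) config[[key]] %||% default
  ledger <- if (is.character(config$ledger)) read_cost_ledger(config$ledger)
            else config$ledger %||% stop("config needs a `ledger`", call. = FALSE)
  scenario <- caseload_scenario(
    cases_per_year = pick("cases_per_year", 300),
    mode = pick("mode", "idealised"),
    error_rate = config$error_rate,
    overhead_rate = pick("overhead_rate", 0))
  cfg <- sequencing_config(
    coverage_tumor = pick("coverage_tumor", 100),
    coverage_normal = pick("coverage_normal", 30),
    efficiency = pick("efficiency", 0.44))
  cap <- platform_capacity_spec(
    base_capacity = pick("capacity_base", 2500),
    base_coverage = pick("capacity_base_coverage", 100))
  breakdown <- total_cost_per_case(ledger, scenario, cfg, cap,
                                   flowcell = config$flowcell)

  out_dir <- out_dir %||% pick("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  export_breakdown(breakdown,
                   csv_path = file.path(out_dir, "breakdown.csv"),
                   json_path = file.path(out_dir, "breakdown.json"))
  shares <- category_shares(breakdown)
  readr::write_csv(shares[c("category", "share_pct")],
                   file.path(out_dir, "shares.csv"), progress = FALSE)

  lines <- c(
    sprintf("WGS/WTS per-case costing — %s scenario, %d cases/year",
            scenario$mode, scenario$cases_per_year),
    sprintf("coverage %gx tumour / %gx normal, efficiency %g",
            cfg$coverage_tumor, cfg$coverage_normal, cfg$efficiency),
    "",
    sprintf("  %-22s %10s  %6s", "category", "EUR/case", "share"),
    sprintf("  %-22s %10s  %5.1f%%", shares$category,
            format_eur(shares$eur_per_case), shares$share_pct))
  if (scenario$overhead_rate > 0) {
    lines <- c(lines, sprintf("  %-22s %10s", "overhead increment",
                              format_eur(attr(breakdown, "overhead_eur_per_case"))))
  }
  lines <- c(lines, sprintf("  %-22s %10s", "total per case",
                            format_eur(breakdown_total(breakdown))))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(breakdown)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
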