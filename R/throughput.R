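#' Flow-cell specification
#'
#' Describes a sequencing flow cell by its total single reads passing filter,
#' total paired-end cycles and list price. Read length is `n_cycles / 2`.
#'
#' @param name Flow-cell name, e.g. `"NovaSeq X 25B"`.
#' @param platform Instrument the flow cell runs on.
#' @param n_reads Total reads passing filter per flow cell.
#' @param n_cycles Total sequencing cycles (paired-end).
#' @param list_price_eur List price in EUR (ex VAT).
#' @return One-row tibble of class `flowcell_spec`.
#' @examples
#' flowcell_spec("NovaSeq X 25B", "NovaSeq X Plus", 52e9, 300, 16480)
#' @export
flowcell_spec <- function(name, platform, n_reads, n_cycles, list_price_eur) {
  stopifnot(n_reads > 0, n_cycles > 0)
  check_money(list_price_eur, "list_price_eur")
  out <- tibble::tibble(name = name, platform = platform,
                        n_reads = as.numeric(n_reads),
                        n_cycles = as.numeric(n_cycles),
                        list_price_eur = as.numeric(list_price_eur))
  class(out) <- c("flowcell_spec", class(out))
  out
}

#' Sequencing configuration
#'
#' Coverage targets and laboratory efficiency that link flow-cell output to
#' realised mean coverage. The efficiency factor accounts for duplicate,
#' non-human and short-fragment reads; 0.44 is the observed value for an FFPE
#' tumour workflow and is the model default.
#'
#' @param coverage_tumor Mean coverage of the tumour sample (default 100).
#' @param coverage_normal Mean coverage of the germline sample (default 30).
#' @param efficiency Sequencing efficiency in (0, 1] (default 0.44).
#' @param genome_size Human genome size in bases (default 3.3e9).
#' @return A list of class `sequencing_config`.
#' @export
sequencing_config <- function(coverage_tumor = 100, coverage_normal = 30,
                              efficiency = 0.44, genome_size = 3.3e9) {
  stopifnot(coverage_tumor >= 0, coverage_normal >= 0,
            coverage_tumor + coverage_normal > 0,
            efficiency > 0, efficiency <= 1, genome_size > 0)
  structure(list(coverage_tumor = coverage_tumor,
                 coverage_normal = coverage_normal,
                 efficiency = efficiency,
                 genome_size = genome_size),
            class = "sequencing_config")
}

#' Sequencing platform capacity specification
#'
#' One platform's annual case throughput at a reference tumour coverage.
#' Capacity scales inverse-proportionally with tumour coverage (the germline
#' sample is held at its configured coverage throughout).
#'
#' @param base_capacity Cases per year at the base coverage (default 2500).
#' @param base_coverage Tumour mean coverage defining the base capacity
#'   (default 100).
#' @return A list of class `platform_capacity_spec`.
#' @export
platform_capacity_spec <- function(base_capacity = 2500, base_coverage = 100) {
  stopifnot(base_capacity > 0, base_coverage > 0)
  structure(list(base_capacity = base_capacity, base_coverage = base_coverage),
            class = "platform_capacity_spec")
}

#' Patients per flow cell
#'
#' Inverts the coverage equation
#' \deqn{d_T + d_N = \tfrac{1}{2} e \, n_{reads} \, n_{cycles} / (n_{patients} \, n_{genome})}
#' for the number of patients, where the factor 1/2 accounts for paired-end
#' sequencing. Partial patients cannot be sequenced, so the continuous value
#' is floored. A result of 0 means the requested coverage is unreachable on
#' this flow cell (flagged, not an error).
#'
#' @param fc A [flowcell_spec()] (or one-row tibble with its columns).
#' @param cfg A [sequencing_config()].
#' @return Integer number of patients per flow cell (>= 0).
#' @examples
#' fc <- flowcell_spec("25B", "NovaSeq X Plus", 52e9, 300, 16480)
#' patients_per_flowcell(fc, sequencing_config())  # 8
#' @export
patients_per_flowcell <- function(fc, cfg = sequencing_config()) {
  floor(patients_per_flowcell_continuous(fc, cfg))
}

# continuous (un-floored) patients per flow cell
patients_per_flowcell_continuous <- function(fc, cfg) {
  d <- cfg$coverage_tumor + cfg$coverage_normal
  0.5 * cfg$efficiency * fc$n_reads * fc$n_cycles / (d * cfg$genome_size)
}

#' Flow-cell cost per case
#'
#' The flow-cell list price divided by the (floored) number of patients per
#' flow cell, cent-rounded. Piecewise-constant and non-decreasing in tumour
#' coverage, with jumps exactly where [patients_per_flowcell()] decrements.
#'
#' @inheritParams patients_per_flowcell
#' @return Flow-cell cost per case in EUR.
#' @examples
#' fc <- flowcell_spec("25B", "NovaSeq X Plus", 52e9, 300, 16480)
#' flowcell_cost_per_case(fc, sequencing_config())  # 2060
#' @export
flowcell_cost_per_case <- function(fc, cfg = sequencing_config()) {
  n <- patients_per_flowcell(fc, cfg)
  if (n < 1) {
    stop(sprintf("coverage unreachable on flow cell '%s' (%.0fx tumour coverage)",
                 fc$name, cfg$coverage_tumor), call. = FALSE)
  }
  round_cents(fc$list_price_eur / n)
}

#' Gigabases sequenced per case
#'
#' Bases that must be sequenced per patient to realise the target coverage:
#' `(d_T + d_N) * genome_size / efficiency`, in gigabases. Scales the
#' per-gigabase component of data-processing costs.
#'
#' @param cfg A [sequencing_config()].
#' @return Gigabases per case.
#' @examples
#' gigabases_per_case(sequencing_config())  # 975
#' @export
gigabases_per_case <- function(cfg = sequencing_config()) {
  (cfg$coverage_tumor + cfg$coverage_normal) * cfg$genome_size /
    cfg$efficiency / 1e9
}

#' Annual platform capacity at a given tumour coverage
#'
#' `floor(base_capacity * base_coverage / coverage_tumor)`: doubling tumour
#' coverage halves the number of cases one platform can sequence per year.
#'
#' @param cap A [platform_capacity_spec()].
#' @param coverage_tumor Tumour mean coverage (> 0).
#' @return Cases per year one platform can process.
#' @examples
#' platform_capacity(platform_capacity_spec(), 500)  # 500
#' @export
platform_capacity <- function(cap = platform_capacity_spec(), coverage_tumor = 100) {
  stopifnot(coverage_tumor > 0)
  floor(cap$base_capacity * cap$base_coverage / coverage_tumor)
}

#' Number of sequencing platforms required
#'
#' `ceiling(volume / platform_capacity)`; 0 when the volume is 0. The per-case
#' capital cost of the fleet exhibits a sawtooth jump at every capacity
#' boundary.
#'
#' @param volume Cases per year (>= 0).
#' @inheritParams platform_capacity
#' @return Integer number of platforms.
#' @examples
#' platforms_required(4000, platform_capacity_spec(), 500)  # 8
#' @export
platforms_required <- function(volume, cap = platform_capacity_spec(),
                               coverage_tumor = 100) {
  stopifnot(volume >= 0)
  ceiling(volume / platform_capacity(cap, coverage_tumor))
}

#' Flow-cell catalogue
#'
#' Reads a flow-cell catalogue CSV (`name,platform,n_reads,n_cycles,
#' list_price_eur`). The catalogue shipped with the package covers the
#' flow cells of the instrument comparison; the 25B and S4 prices are
#' back-solved from their published per-case costs, the remaining rows are
#' synthetic but consistent entries users are expected to edit.
#'
#' @param path Catalogue CSV; default is the packaged catalogue.
#' @return Tibble with one row per flow cell.
#' @export
flowcell_catalogue <- function(path = system.file("extdata",
                                                  "flowcell_catalogue.csv",
                                                  package = "wgscost")) {
  readr::read_csv(path, col_types = "ccddd", progress = FALSE)
}

# fetch one catalogue row as a flowcell_spec
catalogue_flowcell <- function(name, catalogue = flowcell_catalogue()) {
  row <- catalogue[catalogue$name == name, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(sprintf("flow cell '%s' not found in catalogue", name), call. = FALSE)
  }
  flowcell_spec(row$name, row$platform, row$n_reads, row$n_cycles,
                row$list_price_eur)
}
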