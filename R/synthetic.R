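#' Calibrated synthetic cost ledger
#'
#' Builds the synthetic ledger that stands in for the itemised supplementary
#' cost inventory of the published workflow. Its aggregates reproduce, to the
#' cent, the published figures for both library-preparation protocols:
#' per-case totals of 5273.11 / 3455.00 EUR (mechanical shearing, "twist") and
#' 5195.24 / 3431.56 EUR (tagmentation) at 300 / 2000 cases per year in the
#' idealised scenario, 7611.35 / 3860.22 EUR in the realistic scenario, the
#' consumable blocks (WTS 278.86, WGS sequencing 2068.48 including the
#' 2060.00 flow cell, library preparation 122.44 / 112.19) and the personnel
#' components (technical assistant 159.11 -> 403.79 / 211.99, biologist
#' 61.15 -> 276.22 / 103.58, totals 747.59 / 309.61 and 1571.47 / 464.43).
#'
#' Only those aggregates are published; the per-item splits below them are
#' back-solved, deterministic choices (marked `derived` in the source) and
#' are one consistent solution, not actual list prices. The joint DNA/RNA
#' extraction consumables are folded into the WTS bundle so that the
#' published assay-level blocks are reproduced exactly.
#'
#' @param protocol `"twist"` (mechanical shearing; includes the shearing
#'   device and its consumables) or `"tagmentation"`.
#' @return A validated [cost_ledger()].
#' @examples
#' ledger <- calibrated_ledger("twist")
#' round_cents(consumables_per_case(ledger, assay = "WGS"))
#' @export
calibrated_ledger <- function(protocol = c("twist", "tagmentation")) {
  protocol <- match.arg(protocol)
  twist <- protocol == "twist"

  # Wet-lab library prep blocks: published per-case totals 122.44 (shearing
  # protocol) / 112.19 (tagmentation); item splits derived.
  lib_prep <- if (twist) {
    tibble::tibble(
      name = c("WGS library prep kit (mechanical shearing)",
               "Shearing consumables (AFA vessels)",
               "WGS library QC (fluorometry, capillary electrophoresis)"),
      assay = "WGS", stage = "library_prep",
      unit_price_eur = c(94.50, 10.50, 17.44),  # derived split of 122.44
      units_per_case = 1, is_flowcell = FALSE)
  } else {
    tibble::tibble(
      name = c("WGS library prep kit (tagmentation)",
               "WGS library QC (fluorometry, capillary electrophoresis)"),
      assay = "WGS", stage = "library_prep",
      unit_price_eur = c(98.75, 13.44),         # derived split of 112.19
      units_per_case = 1, is_flowcell = FALSE)
  }

  consumables <- dplyr::bind_rows(
    tibble::tibble(
      # flow cell: 16480 list price back-solved from 2060.00 x 8 patients;
      # 1/8 flow cell per case at base coverage (100x/30x, e = 0.44)
      name = "NovaSeq X 25B flow cell (300 cycles)",
      assay = "WGS", stage = "sequencing",
      unit_price_eur = 16480.00, units_per_case = 1 / 8, is_flowcell = TRUE),
    tibble::tibble(
      name = "WGS sequencing run consumables & QC",
      assay = "WGS", stage = "sequencing",
      unit_price_eur = 8.48, units_per_case = 1,  # derived: 2068.48 - 2060.00
      is_flowcell = FALSE),
    lib_prep,
    # WTS bundle, published total 278.86/case; carries the joint DNA/RNA
    # extraction consumables (derived split)
    tibble::tibble(
      name = c("DNA/RNA extraction (FFPE + blood reference)",
               "WTS library prep kit",
               "WTS sequencing reagent share"),
      assay = "WTS",
      stage = c("extraction", "library_prep", "sequencing"),
      unit_price_eur = c(48.90, 162.71, 67.25),
      units_per_case = 1, is_flowcell = FALSE)
  )

  # Personnel: wages incl. social contributions; per-minute rates use a
  # 1790 h/year = 107,400 min working-time constant for all roles. Hands-on
  # minutes and annual costs are back-solved from the published per-case
  # role costs and position counts (derived).
  minutes_year <- 107400
  ta_minutes <- if (twist) 282.14 else 275.78  # derived; shearing adds TA time
  personnel <- tibble::tibble(
    name = c("Technical assistant (wet lab)",
             "Biologist (variant interpretation)",
             "Trainee doctor (tumour annotation)",
             "Medical specialist (report sign-out)",
             "Bioinformatician (pipeline development)",
             "Bioinformatician (database maintenance)",
             "Quality management",
             "Case management"),
    tariff_label = c("TV-L E8/3", "TV-L E13/3", "TV-Ä Ä1/3",
                     "TV-Ä Ä2/3", "TV-L E13/3", "TV-L E13/3",
                     "TV-L E13/3", "TV-L E8/3"),
    annual_cost_eur = c(60568.50, 82866.00, 95709.50, 130000.00,
                        82866.00, 82866.00, 82866.00, 60568.50),
    annual_working_minutes = minutes_year,
    hands_on_minutes_per_case = c(ta_minutes, 79.26, 7.50, 4.432,
                                  NA, NA, NA, NA),
    allocation = c(rep("hands_on", 4), rep("annual_fte", 4)),
    base_fte = c(0, 0, 0, 0, 0.5, 0.5, 0.5, 0.5),
    # technical assistants are staffed in whole positions, everyone else in
    # halves; cover is half a position at low volume, a full one above the
    # volume threshold (biologists), constant for technical assistants
    fte_increment = c(1.0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    redundancy_fte_low = c(1.0, 0.5, 0, 0, 0, 0, 0, 0),
    redundancy_fte_high = c(1.0, 1.0, 0, 0, 0, 0, 0, 0),
    # one case-management FTE per 2000 cases/year in the realistic scenario
    cases_per_fte = c(NA, NA, NA, NA, NA, NA, NA, 2000)
  )

  equipment <- dplyr::bind_rows(
    tibble::tibble(name = "NovaSeq X Plus sequencing platform",
                   purchase_price_eur = 1100000, operating_years = 5,
                   annual_maintenance_eur = 90000, backup_units = 1,
                   is_sequencing_platform = TRUE),
    tibble::tibble(name = "DRAGEN compute server",
                   purchase_price_eur = 250000, operating_years = 5,
                   annual_maintenance_eur = 25000, backup_units = 1,
                   is_sequencing_platform = FALSE),
    tibble::tibble(name = "Storage servers (raw + processed data)",
                   purchase_price_eur = 140000, operating_years = 7,
                   annual_maintenance_eur = 6000, backup_units = 1,
                   is_sequencing_platform = FALSE),
    tibble::tibble(name = "Extraction & library-prep instruments",
                   purchase_price_eur = 94500, operating_years = 7,
                   annual_maintenance_eur = 1523.00,  # derived balancing value
                   backup_units = 1, is_sequencing_platform = FALSE),
    tibble::tibble(name = "Loaner instrument service retainer",
                   purchase_price_eur = 0, operating_years = 7,
                   annual_maintenance_eur = 437.00,   # derived balancing value
                   backup_units = 2, is_sequencing_platform = FALSE),
    if (twist) {
      tibble::tibble(name = "Focused-ultrasound shearing device",
                     purchase_price_eur = 94500, operating_years = 7,
                     annual_maintenance_eur = 5710, backup_units = 1,
                     is_sequencing_platform = FALSE)
    }
  )

  cost_ledger(
    consumables = consumables,
    personnel = personnel,
    equipment = equipment,
    data_costs = list(per_gigabase_eur = 0.20,      # base calling, per base
                      per_case_licence_eur = 69.22, # interpretation databases
                      per_case_storage_eur = 167.84),
    # R&D flat fee: half a scientific staff position (E13/3) per year
    rd_annual_eur = 0.5 * 82866.00
  )
}

#' Specification for seeded random ledgers
#'
#' Parameter ranges for [random_ledger()]; used by the property-test suite.
#' Prices are drawn log-uniformly, counts uniformly.
#'
#' @param seed Integer seed; the same seed always yields the same ledger.
#' @param n_consumables,n_personnel,n_equipment Length-2 integer ranges for
#'   the number of items per section.
#' @param price_range Length-2 range for unit/purchase prices (log-uniform).
#' @param minutes_range Length-2 range for hands-on minutes per case.
#' @return A list of class `random_ledger_spec`.
#' @export
random_ledger_spec <- function(seed,
                               n_consumables = c(1L, 8L),
                               n_personnel = c(1L, 6L),
                               n_equipment = c(0L, 5L),
                               price_range = c(1, 20000),
                               minutes_range = c(1, 400)) {
  for (rg in list(n_consumables, n_personnel, n_equipment, price_range,
                  minutes_range)) {
    if (length(rg) != 2 || rg[1] > rg[2]) {
      stop("each range must be length 2 with min <= max", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_consumables = n_consumables,
                 n_personnel = n_personnel, n_equipment = n_equipment,
                 price_range = price_range, minutes_range = minutes_range),
            class = "random_ledger_spec")
}

#' Draw a random cost ledger
#'
#' Generates a valid ledger from the distributions of a
#' [random_ledger_spec()]. Deterministic under the spec's seed (the global
#' RNG state is restored afterwards). Intended for property tests: round-trip
#' identity, oracle-sum equality, scaling laws and mode dominance.
#'
#' @param spec A [random_ledger_spec()].
#' @return A validated [cost_ledger()].
#' @examples
#' random_ledger(random_ledger_spec(seed = 1))
#' @export
random_ledger <- function(spec) {
  stopifnot(inherits(spec, "random_ledger_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n_in <- function(rg) if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1)
  rprice <- function(n) {
    exp(stats::runif(n, log(spec$price_range[1]), log(spec$price_range[2])))
  }
  nc <- n_in(spec$n_consumables)
  np <- n_in(spec$n_personnel)
  ne <- n_in(spec$n_equipment)

  consumables <- if (nc > 0) {
    assay <- sample(c("WGS", "WTS", "SHARED"), nc, replace = TRUE)
    is_fc <- rep(FALSE, nc)
    # at most one flow-cell item, always on a WGS row
    if (any(assay == "WGS") && stats::runif(1) < 0.5) {
      is_fc[which(assay == "WGS")[1]] <- TRUE
    }
    tibble::tibble(
      name = sprintf("consumable_%02d", seq_len(nc)),
      assay = assay,
      stage = sample(c("extraction", "library_prep", "sequencing", "other"),
                     nc, replace = TRUE),
      unit_price_eur = round(rprice(nc), 2),
      units_per_case = round(stats::runif(nc, 0.05, 4), 3),
      is_flowcell = is_fc)
  } else empty_consumables()

  personnel <- if (np > 0) {
    alloc <- sample(c("hands_on", "annual_fte"), np, replace = TRUE)
    tibble::tibble(
      name = sprintf("role_%02d", seq_len(np)),
      tariff_label = "synthetic",
      annual_cost_eur = round(stats::runif(np, 30000, 140000), 2),
      annual_working_minutes = 107400,
      hands_on_minutes_per_case = ifelse(
        alloc == "hands_on",
        round(stats::runif(np, spec$minutes_range[1], spec$minutes_range[2]), 1),
        NA_real_),
      allocation = alloc,
      base_fte = ifelse(alloc == "annual_fte",
                        sample(c(0.5, 1), np, replace = TRUE), 0),
      fte_increment = sample(c(0.5, 1), np, replace = TRUE),
      redundancy_fte_low = sample(c(0, 0.5), np, replace = TRUE),
      redundancy_fte_high = sample(c(0.5, 1), np, replace = TRUE),
      cases_per_fte = NA_real_)
  } else empty_personnel()

  equipment <- if (ne > 0) {
    tibble::tibble(
      name = sprintf("equipment_%02d", seq_len(ne)),
      purchase_price_eur = round(rprice(ne) * 20, 2),
      operating_years = sample(c(5, 7), ne, replace = TRUE),
      annual_maintenance_eur = round(rprice(ne), 2),
      backup_units = sample(0:2, ne, replace = TRUE),
      is_sequencing_platform = c(TRUE, rep(FALSE, ne - 1)))
  } else empty_equipment()

  cost_ledger(
    consumables = consumables,
    personnel = personnel,
    equipment = equipment,
    data_costs = list(per_gigabase_eur = round(stats::runif(1, 0, 0.5), 3),
                      per_case_licence_eur = round(stats::runif(1, 0, 300), 2),
                      per_case_storage_eur = round(stats::runif(1, 0, 300), 2)),
    rd_annual_eur = round(stats::runif(1, 0, 60000), 2)
  )
}
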