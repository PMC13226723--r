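#' Construct an itemised cost ledger
#'
#' A cost ledger is the full itemised input of the costing model: consumable
#' items, personnel roles, equipment items, per-case data-processing costs and
#' an annual research-and-development flat fee. It mirrors the structure of a
#' laboratory's line-item cost inventory.
#'
#' @param consumables Tibble with columns `name`, `assay` (`"WGS"`, `"WTS"`,
#'   `"SHARED"`), `stage` (`"extraction"`, `"library_prep"`, `"sequencing"`,
#'   `"other"`), `unit_price_eur`, `units_per_case`, `is_flowcell`.
#' @param personnel Tibble with columns `name`, `tariff_label`,
#'   `annual_cost_eur` (wage incl. social contributions), `annual_working_minutes`,
#'   `hands_on_minutes_per_case` (`NA` for annual-FTE roles), `allocation`
#'   (`"hands_on"` or `"annual_fte"`), `base_fte`, `fte_increment` (staffing
#'   granularity in FTE, e.g. 0.5 or 1), `redundancy_fte_low`,
#'   `redundancy_fte_high` (vacation/sick-leave cover added in realistic mode,
#'   below/above the scenario's volume threshold), `cases_per_fte` (optional
#'   case-capacity of one FTE for annual-FTE roles whose staffing steps up
#'   with volume; `NA` otherwise).
#' @param equipment Tibble with columns `name`, `purchase_price_eur`,
#'   `operating_years`, `annual_maintenance_eur`, `backup_units`,
#'   `is_sequencing_platform`.
#' @param data_costs Named list or one-row tibble with `per_gigabase_eur`
#'   (base-calling licence priced per base), `per_case_licence_eur`
#'   (interpretation databases) and `per_case_storage_eur` (long-term storage;
#'   exempt from the re-sequencing surcharge since failed runs are not
#'   archived).
#' @param rd_annual_eur Annual research-and-development flat fee in EUR.
#'
#' @return A validated object of class `cost_ledger`.
#' @seealso [read_cost_ledger()], [write_cost_ledger()], [consumables_per_case()]
#' @examples
#' ledger <- calibrated_ledger("twist")
#' consumables_per_case(ledger)
#' @export
cost_ledger <- function(consumables = empty_consumables(),
                        personnel = empty_personnel(),
                        equipment = empty_equipment(),
                        data_costs = list(per_gigabase_eur = 0,
                                          per_case_licence_eur = 0,
                                          per_case_storage_eur = 0),
                        rd_annual_eur = 0) {
  ledger <- structure(
    list(
      consumables = as_section(consumables, consumable_cols()),
      personnel = as_section(personnel, personnel_cols()),
      equipment = as_section(equipment, equipment_cols()),
      data_costs = tibble::as_tibble(data_costs[c("per_gigabase_eur",
                                                  "per_case_licence_eur",
                                                  "per_case_storage_eur")]),
      rd_annual_eur = as.numeric(rd_annual_eur)
    ),
    class = "cost_ledger"
  )
  validate_cost_ledger(ledger)
}

consumable_cols <- function() {
  c(name = "character", assay = "character", stage = "character",
    unit_price_eur = "numeric", units_per_case = "numeric",
    is_flowcell = "logical")
}

personnel_cols <- function() {
  c(name = "character", tariff_label = "character",
    annual_cost_eur = "numeric", annual_working_minutes = "numeric",
    hands_on_minutes_per_case = "numeric", allocation = "character",
    base_fte = "numeric", fte_increment = "numeric",
    redundancy_fte_low = "numeric", redundancy_fte_high = "numeric",
    cases_per_fte = "numeric")
}

equipment_cols <- function() {
  c(name = "character", purchase_price_eur = "numeric",
    operating_years = "numeric", annual_maintenance_eur = "numeric",
    backup_units = "numeric", is_sequencing_platform = "logical")
}

#' @export
empty_consumables <- function() empty_section(consumable_cols())

#' @export
empty_personnel <- function() empty_section(personnel_cols())

#' @export
empty_equipment <- function() empty_section(equipment_cols())

empty_section <- function(cols) {
  out <- lapply(cols, function(ty) vector(ty, 0L))
  tibble::as_tibble(out)
}

as_section <- function(x, cols) {
  x <- tibble::as_tibble(x)
  missing <- setdiff(names(cols), names(x))
  if (length(missing)) {
    stop(sprintf("ledger section is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- x[names(cols)]
  for (nm in names(cols)) {
    x[[nm]] <- switch(cols[[nm]],
                      character = as.character(x[[nm]]),
                      numeric = as.numeric(x[[nm]]),
                      logical = as.logical(x[[nm]]))
  }
  x
}

#' Validate a cost ledger
#'
#' Checks all structural invariants: unique names per section, non-negative
#' prices and units, positive working minutes, the hands-on/annual-FTE field
#' correspondence, and at most one flow-cell item per assay.
#'
#' @param ledger A `cost_ledger`.
#' @return The ledger, invisibly unchanged, or an error naming the offending
#'   item and field.
#' @export
validate_cost_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  co <- ledger$consumables
  pe <- ledger$personnel
  eq <- ledger$equipment

  for (sec in list(co = co, pe = pe, eq = eq)) {
    if (anyDuplicated(sec$name)) {
      stop(sprintf("duplicate item name in ledger: %s",
                   sec$name[duplicated(sec$name)][1]), call. = FALSE)
    }
  }
  bad_num <- function(v) !is.finite(v) | v < 0
  if (nrow(co)) {
    co$assay <- toupper(co$assay)
    co$stage <- tolower(co$stage)
    if (!all(co$assay %in% c("WGS", "WTS", "SHARED"))) {
      stop("consumable `assay` must be WGS, WTS or SHARED", call. = FALSE)
    }
    if (!all(co$stage %in% c("extraction", "library_prep", "sequencing", "other"))) {
      stop("consumable `stage` must be extraction, library_prep, sequencing or other",
           call. = FALSE)
    }
    for (fld in c("unit_price_eur", "units_per_case")) {
      if (any(bad <- bad_num(co[[fld]]))) {
        stop(sprintf("consumable '%s': `%s` must be finite and >= 0",
                     co$name[bad][1], fld), call. = FALSE)
      }
    }
    fc <- co[co$is_flowcell %in% TRUE, ]
    if (any(tab <- table(fc$assay) > 1)) {
      stop(sprintf("more than one flow-cell item for assay %s",
                   names(tab)[tab][1]), call. = FALSE)
    }
  }
  if (nrow(pe)) {
    pe$allocation <- tolower(pe$allocation)
    if (!all(pe$allocation %in% c("hands_on", "annual_fte"))) {
      stop("personnel `allocation` must be hands_on or annual_fte", call. = FALSE)
    }
    if (any(bad <- !is.finite(pe$annual_cost_eur) | pe$annual_cost_eur < 0)) {
      stop(sprintf("personnel '%s': `annual_cost_eur` must be finite and >= 0",
                   pe$name[bad][1]), call. = FALSE)
    }
    if (any(bad <- !is.finite(pe$annual_working_minutes) | pe$annual_working_minutes <= 0)) {
      stop(sprintf("personnel '%s': `annual_working_minutes` must be > 0",
                   pe$name[bad][1]), call. = FALSE)
    }
    ho <- pe$allocation == "hands_on"
    if (any(bad <- ho & !is.finite(pe$hands_on_minutes_per_case))) {
      stop(sprintf("personnel '%s': hands_on role needs `hands_on_minutes_per_case`",
                   pe$name[bad][1]), call. = FALSE)
    }
    if (any(bad <- !ho & is.finite(pe$hands_on_minutes_per_case))) {
      stop(sprintf("personnel '%s': annual_fte role must not carry hands-on minutes",
                   pe$name[bad][1]), call. = FALSE)
    }
    for (fld in c("base_fte", "redundancy_fte_low", "redundancy_fte_high")) {
      v <- pe[[fld]]
      if (any(bad <- !is.finite(v) | v < 0)) {
        stop(sprintf("personnel '%s': `%s` must be finite and >= 0",
                     pe$name[bad][1], fld), call. = FALSE)
      }
    }
    if (any(bad <- !is.finite(pe$fte_increment) | pe$fte_increment <= 0)) {
      stop(sprintf("personnel '%s': `fte_increment` must be > 0",
                   pe$name[bad][1]), call. = FALSE)
    }
  }
  if (nrow(eq)) {
    for (fld in c("purchase_price_eur", "annual_maintenance_eur", "backup_units")) {
      if (any(bad <- bad_num(eq[[fld]]))) {
        stop(sprintf("equipment '%s': `%s` must be finite and >= 0",
                     eq$name[bad][1], fld), call. = FALSE)
      }
    }
    if (any(bad <- !is.finite(eq$operating_years) | eq$operating_years <= 0)) {
      stop(sprintf("equipment '%s': `operating_years` must be > 0",
                   eq$name[bad][1]), call. = FALSE)
    }
  }
  dc <- ledger$data_costs
  for (fld in names(dc)) check_money(dc[[fld]], fld)
  check_money(ledger$rd_annual_eur, "rd_annual_eur")

  ledger$consumables <- co
  ledger$personnel <- pe
  ledger$equipment <- eq
  ledger
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat("<cost_ledger>\n")
  cat(sprintf("  consumables: %d items (%.2f EUR/case)\n",
              nrow(x$consumables), consumables_per_case(x)))
  cat(sprintf("  personnel:   %d roles\n", nrow(x$personnel)))
  cat(sprintf("  equipment:   %d items\n", nrow(x$equipment)))
  cat(sprintf("  data costs:  %.2f EUR/Gb + %.2f licence + %.2f storage per case\n",
              x$data_costs$per_gigabase_eur, x$data_costs$per_case_licence_eur,
              x$data_costs$per_case_storage_eur))
  cat(sprintf("  R&D flat fee: %.2f EUR/year\n", x$rd_annual_eur))
  invisible(x)
}

# ---- file io --------------------------------------------------------------

ledger_file_cols <- function() {
  unique(c("section", names(consumable_cols()), names(personnel_cols()),
           names(equipment_cols()), "key", "value"))
}

#' Read a cost ledger from a sectioned CSV file
#'
#' The file holds all ledger sections in one UTF-8, dot-decimal CSV with a
#' mandatory header and a `section` column taking values `consumables`,
#' `personnel`, `equipment`, `data_costs` and `rd`. Item sections use their
#' own columns; `data_costs` and `rd` rows are `key`,`value` pairs. Columns
#' irrelevant to a section are left blank.
#'
#' @param path Path to the ledger CSV.
#' @return A validated [cost_ledger()].
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cost_ledger(calibrated_ledger("twist"), path)
#' read_cost_ledger(path)
#' @export
read_cost_ledger <- function(path) {
  if (!file.exists(path)) stop(sprintf("ledger file not found: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"section" %in% names(raw)) {
    stop("ledger file is missing required column: section", call. = FALSE)
  }
  pick <- function(section, cols) {
    rows <- raw[raw$section == section, , drop = FALSE]
    missing <- setdiff(names(cols), names(raw))
    if (nrow(rows) && length(missing)) {
      stop(sprintf("ledger file is missing column(s) for section '%s': %s",
                   section, paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (!nrow(rows)) return(empty_section(cols))
    out <- rows[intersect(names(cols), names(rows))]
    for (nm in names(cols)) {
      out[[nm]] <- switch(cols[[nm]],
                          character = as.character(out[[nm]]),
                          numeric = parse_num(out[[nm]], nm),
                          logical = parse_bool(out[[nm]], nm))
    }
    out
  }
  kv <- function(section) {
    rows <- raw[raw$section == section, , drop = FALSE]
    if (!nrow(rows)) return(numeric())
    stats::setNames(parse_num(rows$value, "value"), rows$key)
  }
  dc <- kv("data_costs")
  dc_full <- list(per_gigabase_eur = unname(dc["per_gigabase_eur"] %|na|% 0),
                  per_case_licence_eur = unname(dc["per_case_licence_eur"] %|na|% 0),
                  per_case_storage_eur = unname(dc["per_case_storage_eur"] %|na|% 0))
  rd <- kv("rd")
  cost_ledger(
    consumables = pick("consumables", consumable_cols()),
    personnel = pick("personnel", personnel_cols()),
    equipment = pick("equipment", equipment_cols()),
    data_costs = dc_full,
    rd_annual_eur = unname(rd["rd_annual_eur"] %|na|% 0)
  )
}

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  out[is.na(x) | x == ""] <- NA_real_
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop(sprintf("non-numeric value '%s' in column `%s`", x[bad][1], what),
         call. = FALSE)
  }
  out
}

parse_bool <- function(x, what) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "", NA)] <- FALSE
  out[is.na(lx)] <- FALSE
  as.logical(out)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Write a cost ledger to a sectioned CSV file
#'
#' Inverse of [read_cost_ledger()]: a ledger round-trips through
#' `write_cost_ledger()` / `read_cost_ledger()` without loss (money compared
#' at cent precision; stored at full precision).
#'
#' @param ledger A [cost_ledger()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cost_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "cost_ledger"))
  cols <- ledger_file_cols()
  blank_frame <- function(n) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(rep(NA_character_, n)), length(cols)), cols))
    out
  }
  fmt <- function(v) {
    out <- character(length(v))
    ok <- !is.na(v)
    if (is.logical(v)) {
      out[ok] <- c("FALSE", "TRUE")[v[ok] + 1L]
    } else if (is.numeric(v)) {
      out[ok] <- sprintf("%.15g", v[ok])
    } else {
      out[ok] <- as.character(v[ok])
    }
    out
  }
  section_rows <- function(df, section) {
    out <- blank_frame(nrow(df))
    out$section <- rep(section, nrow(df))
    for (nm in names(df)) out[[nm]] <- fmt(df[[nm]])
    out
  }
  kv_rows <- function(keys, values, section) {
    out <- blank_frame(length(keys))
    out$section <- rep(section, length(keys))
    out$key <- keys
    out$value <- fmt(as.numeric(values))
    out
  }
  dc <- ledger$data_costs
  all_rows <- dplyr::bind_rows(
    section_rows(ledger$consumables, "consumables"),
    section_rows(ledger$personnel, "personnel"),
    section_rows(ledger$equipment, "equipment"),
    kv_rows(names(dc), unlist(dc), "data_costs"),
    kv_rows("rd_annual_eur", ledger$rd_annual_eur, "rd")
  )
  readr::write_csv(all_rows, path, na = "", progress = FALSE)
  invisible(path)
}

# ---- aggregation ----------------------------------------------------------

#' Per-case consumable cost
#'
#' Sums `unit_price_eur * units_per_case` over consumable items, optionally
#' filtered by assay and/or workflow stage. The result is volume-independent
#' and additive over ledger concatenation.
#'
#' @param ledger A [cost_ledger()].
#' @param assay Optional filter: `"WGS"`, `"WTS"` or `"SHARED"`.
#' @param stage Optional filter: `"extraction"`, `"library_prep"`,
#'   `"sequencing"` or `"other"`.
#' @return Per-case consumable cost in EUR (full precision).
#' @examples
#' consumables_per_case(calibrated_ledger("twist"), assay = "WTS")
#' @export
consumables_per_case <- function(ledger, assay = NULL, stage = NULL) {
  stopifnot(inherits(ledger, "cost_ledger"))
  co <- ledger$consumables
  if (!is.null(assay)) co <- co[co$assay %in% toupper(assay), , drop = FALSE]
  if (!is.null(stage)) co <- co[co$stage %in% tolower(stage), , drop = FALSE]
  if (!nrow(co)) return(0)
  sum(co$unit_price_eur * co$units_per_case)
}

#' Itemised per-case consumable costs
#'
#' @param ledger A [cost_ledger()].
#' @return Tibble of consumable items with their per-case cost.
#' @export
consumable_items <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  dplyr::mutate(ledger$consumables,
                eur_per_case = .data$unit_price_eur * .data$units_per_case)
}
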