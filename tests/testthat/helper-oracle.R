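# Independent "naive spreadsheet" oracles used by the property tests.
# Deliberately written with plain loops over the raw ledger tables, without
# calling any engine aggregation code, so they constitute a second route to
# the same quantities.

oracle_consumables <- function(ledger, assay = NULL, stage = NULL) {
  co <- ledger$consumables
  total <- 0
  for (i in seq_len(nrow(co))) {
    if (!is.null(assay) && !(co$assay[i] %in% assay)) next
    if (!is.null(stage) && !(co$stage[i] %in% stage)) next
    total <- total + co$unit_price_eur[i] * co$units_per_case[i]
  }
  total
}

# brute-force patients per flow cell: reads needed per sample from coverage,
# then how many samples' reads fit on the cell
oracle_patients <- function(n_reads, n_cycles, d_total, efficiency,
                            genome_size = 3.3e9) {
  read_length <- n_cycles / 2
  bases_needed <- d_total * genome_size / efficiency
  reads_needed <- bases_needed / read_length
  floor(n_reads / reads_needed)
}

# full per-case total, recomputed step by step the way a spreadsheet would
oracle_total <- function(ledger, cases_per_year, mode = "idealised",
                         error_rate = 0, overhead_rate = 0,
                         coverage_tumor = 100, coverage_normal = 30,
                         efficiency = 0.44, base_capacity = 2500,
                         base_coverage = 100, threshold = 1000) {
  v <- cases_per_year
  cons <- oracle_consumables(ledger)

  pe <- ledger$personnel
  pers <- 0
  for (i in seq_len(nrow(pe))) {
    red <- if (v <= threshold) pe$redundancy_fte_low[i] else pe$redundancy_fte_high[i]
    if (pe$allocation[i] == "hands_on") {
      if (mode == "idealised") {
        pers <- pers + pe$hands_on_minutes_per_case[i] *
          pe$annual_cost_eur[i] / pe$annual_working_minutes[i]
      } else {
        w <- v * pe$hands_on_minutes_per_case[i] / pe$annual_working_minutes[i]
        pos <- ceiling(w / pe$fte_increment[i]) * pe$fte_increment[i] + red
        pers <- pers + pos * pe$annual_cost_eur[i] / v
      }
    } else {
      fte <- pe$base_fte[i]
      if (mode == "realistic") {
        if (is.finite(pe$cases_per_fte[i])) {
          fte <- max(fte, ceiling(v / pe$cases_per_fte[i] / 0.5) * 0.5)
        }
        fte <- fte + red
      }
      pers <- pers + fte * pe$annual_cost_eur[i] / v
    }
  }

  eq <- ledger$equipment
  cap_eur <- 0; maint_eur <- 0
  n_platforms <- ceiling(v / floor(base_capacity * base_coverage / coverage_tumor))
  for (i in seq_len(nrow(eq))) {
    units <- if (eq$is_sequencing_platform[i]) n_platforms else 1
    if (mode == "realistic") units <- units + eq$backup_units[i]
    cap_eur <- cap_eur + eq$purchase_price_eur[i] / eq$operating_years[i] * units / v
    maint_eur <- maint_eur + eq$annual_maintenance_eur[i] * units / v
  }

  gb <- (coverage_tumor + coverage_normal) * 3.3e9 / efficiency / 1e9
  dc <- ledger$data_costs
  data_compute <- dc$per_gigabase_eur * gb + dc$per_case_licence_eur
  data_storage <- dc$per_case_storage_eur
  rd <- ledger$rd_annual_eur / v

  total <- cons * (1 + error_rate) + pers + cap_eur + maint_eur + rd +
    data_compute * (1 + error_rate) + data_storage
  total * (1 + overhead_rate)
}
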