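twist <- calibrated_ledger("twist")

test_that("equipment amortisation and volume scaling are exact", {
  one <- cost_ledger(equipment = tibble::tibble(
    name = "device", purchase_price_eur = 70000, operating_years = 7,
    annual_maintenance_eur = 0, backup_units = 1,
    is_sequencing_platform = FALSE))
  id <- equipment_per_case(one, caseload_scenario(1000))
  expect_equal(id$capital_eur_per_case, 10)
  re <- equipment_per_case(one, caseload_scenario(1000, mode = "realistic"))
  expect_equal(re$capital_eur_per_case, 20)  # backup unit doubles it

  eq300 <- equipment_per_case(twist, caseload_scenario(300))
  eq2000 <- equipment_per_case(twist, caseload_scenario(2000))
  expect_equal(eq2000$capital_eur_per_case * 2000 / 300,
               eq300$capital_eur_per_case)
  expect_equal(eq2000$maintenance_eur_per_case * 2000 / 300,
               eq300$maintenance_eur_per_case)
})

test_that("idealised personnel costs follow hands-on minutes and FTE wages", {
  p300 <- personnel_per_case(twist, caseload_scenario(300))
  ta <- p300$eur_per_case[p300$name == "Technical assistant (wet lab)"]
  bio <- p300$eur_per_case[p300$name == "Biologist (variant interpretation)"]
  expect_identical(round_cents(ta), 159.11)
  expect_identical(round_cents(bio), 61.15)
  expect_identical(round_cents(personnel_idealised(twist, caseload_scenario(300))),
                   747.59)
  expect_identical(round_cents(personnel_idealised(twist, caseload_scenario(2000))),
                   309.61)

  zero <- cost_ledger(personnel = tibble::tibble(
    name = "idle", tariff_label = "x", annual_cost_eur = 50000,
    annual_working_minutes = 107400, hands_on_minutes_per_case = 0,
    allocation = "hands_on", base_fte = 0, fte_increment = 0.5,
    redundancy_fte_low = 0, redundancy_fte_high = 0, cases_per_fte = NA))
  expect_identical(personnel_idealised(zero, caseload_scenario(500)), 0)
})

test_that("realistic staffing rounds workload up to positions plus cover", {
  p300 <- personnel_per_case(twist, caseload_scenario(300, mode = "realistic"))
  p2000 <- personnel_per_case(twist, caseload_scenario(2000, mode = "realistic"))
  get <- function(df, nm, col) df[[col]][df$name == nm]
  expect_identical(get(p300, "Technical assistant (wet lab)", "positions"), 2)
  expect_identical(get(p2000, "Technical assistant (wet lab)", "positions"), 7)
  expect_identical(get(p300, "Biologist (variant interpretation)", "positions"), 1)
  expect_identical(get(p2000, "Biologist (variant interpretation)", "positions"), 2.5)
  expect_identical(round_cents(get(p300, "Technical assistant (wet lab)",
                                   "eur_per_case")), 403.79)
  expect_identical(round_cents(get(p2000, "Technical assistant (wet lab)",
                                   "eur_per_case")), 211.99)
  expect_identical(round_cents(get(p300, "Biologist (variant interpretation)",
                                   "eur_per_case")), 276.22)
  expect_identical(round_cents(get(p2000, "Biologist (variant interpretation)",
                                   "eur_per_case")), 103.58)
  # case management steps from half to a full position with volume
  expect_identical(get(p300, "Case management", "positions"), 0.5)
  expect_identical(get(p2000, "Case management", "positions"), 1)

  # a role whose workload is exactly a whole position and has no cover costs
  # its wage divided by the volume
  exact <- cost_ledger(personnel = tibble::tibble(
    name = "fully loaded", tariff_label = "x", annual_cost_eur = 60000,
    annual_working_minutes = 107400, hands_on_minutes_per_case = 107.4,
    allocation = "hands_on", base_fte = 0, fte_increment = 1,
    redundancy_fte_low = 0, redundancy_fte_high = 0, cases_per_fte = NA))
  expect_equal(personnel_realistic(exact, caseload_scenario(1000)), 60000 / 1000)
})

test_that("realistic personnel dominates idealised on random ledgers", {
  for (seed in 1:50) {
    ledger <- random_ledger(random_ledger_spec(seed = seed))
    for (v in c(150, 1000, 3000)) {
      sc <- caseload_scenario(v)
      expect_gte(personnel_realistic(ledger, sc) + 1e-9,
                 personnel_idealised(ledger, sc))
    }
  }
})

test_that("data costs scale with sequenced gigabases", {
  dc_only <- cost_ledger(data_costs = list(per_gigabase_eur = 0,
                                           per_case_licence_eur = 50,
                                           per_case_storage_eur = 25))
  expect_equal(data_costs_per_case(dc_only), 75)
  base <- data_costs_per_case(twist, sequencing_config(100, 30))
  doubled <- data_costs_per_case(twist, sequencing_config(200, 60))
  gb_part <- twist$data_costs$per_gigabase_eur * 975
  expect_equal(doubled - base, gb_part)
  expect_identical(round_cents(base), 432.06)
})

test_that("the error surcharge adds exactly rate times the surcharge base", {
  for (seed in c(1, 7, 23)) {
    ledger <- random_ledger(random_ledger_spec(seed = seed))
    for (r in c(0.01, 0.05, 0.15)) {
      b0 <- total_cost_per_case(ledger, caseload_scenario(400, "realistic",
                                                          error_rate = 0))
      br <- total_cost_per_case(ledger, caseload_scenario(400, "realistic",
                                                          error_rate = r))
      base <- attr(b0, "surcharge_base_eur")
      expect_equal(breakdown_total(br) - breakdown_total(b0), r * base)
    }
  }
})

test_that("overhead multiplies the post-surcharge total and is reported separately", {
  b <- total_cost_per_case(twist, caseload_scenario(300, overhead_rate = 0.2))
  b0 <- total_cost_per_case(twist, caseload_scenario(300))
  expect_equal(breakdown_total(b), 1.2 * breakdown_total(b0))
  expect_equal(attr(b, "overhead_eur_per_case"), 0.2 * breakdown_total(b0))
  expect_equal(breakdown_total(b, with_overhead = FALSE), breakdown_total(b0))
})

test_that("volume-independent and 1/volume categories scale as stated", {
  vols <- c(250, 500, 1500, 2000)
  rows <- lapply(vols, function(v)
    total_cost_per_case(twist, caseload_scenario(v)))
  pick <- function(b, cat) b$eur_per_case[b$category == cat]
  for (cat in c("consumables_wgs", "consumables_wts", "data_analysis_storage")) {
    vals <- sapply(rows, pick, cat = cat)
    expect_equal(max(vals) - min(vals), 0)
  }
  for (cat in c("equipment_capital", "equipment_maintenance",
                "research_development")) {
    vals <- sapply(rows, pick, cat = cat) * vols
    expect_equal(diff(range(vals)), 0, tolerance = 1e-9)
  }
})

test_that("the engine total equals the naive spreadsheet oracle on 100 random ledgers", {
  set.seed(99)
  for (seed in 1:100) {
    ledger <- random_ledger(random_ledger_spec(seed = seed))
    v <- sample(c(200, 800, 2600), 1)
    mode <- sample(c("idealised", "realistic"), 1)
    r <- sample(c(0, 0.01, 0.15), 1)
    b <- total_cost_per_case(ledger, caseload_scenario(v, mode, error_rate = r,
                                                       overhead_rate = 0.2))
    expect_equal(round_cents(breakdown_total(b)),
                 round_cents(oracle_total(ledger, v, mode, error_rate = r,
                                          overhead_rate = 0.2)))
  }
})

test_that("breakdown categories sum exactly to the pre-overhead total", {
  for (seed in 1:20) {
    ledger <- random_ledger(random_ledger_spec(seed = seed))
    b <- total_cost_per_case(ledger, caseload_scenario(300, "realistic"))
    expect_equal(sum(b$eur_per_case), breakdown_total(b, with_overhead = FALSE))
    expect_true(all(b$eur_per_case >= 0))
  }
})

test_that("category shares sum to one and degenerate cases error", {
  b <- total_cost_per_case(twist, caseload_scenario(300))
  sh <- category_shares(b)
  expect_equal(sum(sh$share), 1)
  single <- cost_ledger(consumables = tibble::tibble(
    name = "only", assay = "WGS", stage = "other", unit_price_eur = 10,
    units_per_case = 1, is_flowcell = FALSE))
  sh1 <- category_shares(total_cost_per_case(single, caseload_scenario(100)))
  expect_equal(sh1$share[sh1$category == "consumables_wgs"], 1)
  expect_error(category_shares(total_cost_per_case(cost_ledger(),
                                                   caseload_scenario(100))),
               "zero")
})
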