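twist <- calibrated_ledger("twist")
base300 <- total_cost_per_case(twist, caseload_scenario(300))

test_that("economic projection at year zero or rate zero is the identity", {
  econ <- economic_scenario(0.02, "inflation", 10)
  expect_equal(project_economics(base300, econ, 0)$eur_per_case,
               base300$eur_per_case)
  flat <- economic_scenario(0, "inflation", 10)
  expect_equal(breakdown_total(project_economics(base300, flat, 10)),
               breakdown_total(base300))
})

test_that("an equipment-free breakdown compounds by the closed form", {
  no_equip <- cost_ledger(consumables = twist$consumables,
                          personnel = twist$personnel,
                          data_costs = as.list(twist$data_costs),
                          rd_annual_eur = twist$rd_annual_eur)
  b <- total_cost_per_case(no_equip, caseload_scenario(300))
  proj <- project_economics(b, economic_scenario(0.02, "inflation", 5), 5)
  expect_equal(breakdown_total(proj), breakdown_total(b) * 1.02^5)
})

test_that("equipment is shielded from inflation, and deflation also shields wages", {
  econ_i <- economic_scenario(0.05, "inflation", 5)
  proj_i <- project_economics(base300, econ_i, 5)
  pick <- function(b, cat) b$eur_per_case[b$category == cat]
  for (cat in c("equipment_capital", "equipment_maintenance")) {
    expect_equal(pick(proj_i, cat), pick(base300, cat))
  }
  expect_equal(pick(proj_i, "personnel"), pick(base300, "personnel") * 1.05^5)

  econ_d <- economic_scenario(0.05, "deflation", 5)
  proj_d <- project_economics(base300, econ_d, 5)
  expect_equal(pick(proj_d, "personnel"), pick(base300, "personnel"))
  expect_equal(pick(proj_d, "consumables_wgs"),
               pick(base300, "consumables_wgs") * 0.95^5)

  # asymmetric exclusions: inflation then matching deflation is not identity
  back <- project_economics(proj_i, econ_d, 5)
  expect_gt(abs(breakdown_total(back) - breakdown_total(base300)), 1)

  expect_error(economic_scenario(0.02, "deflation", 5,
                                 excluded_categories = "equipment_capital"),
               "personnel")
})

test_that("ten-year 2% inflation stays below the unshielded compound bound", {
  proj <- project_economics(base300, economic_scenario(0.02, "inflation", 10), 10)
  rel <- breakdown_total(proj) / breakdown_total(base300) - 1
  expect_lt(rel, 1.02^10 - 1)
  expect_gt(rel, 0)
})

test_that("volume sweeps fall between capacity steps and jump at the boundary", {
  sw <- volume_sweep(twist, volumes = c(300, 2000))
  tot <- sweep_totals(sw)
  expect_identical(round_cents(tot$total_eur_per_case), c(5273.11, 3455.00))

  sw2 <- volume_sweep(twist, volumes = c(2400, 2600))
  cap_rows <- tidy(sw2)[tidy(sw2)$category == "equipment_capital", ]
  expect_gt(cap_rows$eur_per_case[2], cap_rows$eur_per_case[1])

  # within one platform's range totals never increase; annual programme cost
  # (total x volume) is non-decreasing throughout
  sw3 <- volume_sweep(twist, volumes = seq(100, 4000, by = 100))
  tot3 <- sweep_totals(sw3)
  inside <- tot3$cases_per_year <= 2500
  expect_true(all(diff(tot3$total_eur_per_case[inside]) <= 1e-9))
  annual <- tot3$total_eur_per_case * tot3$cases_per_year
  expect_true(all(diff(annual) >= -1e-6))
  jumps <- which(diff(tot3$total_eur_per_case) > 1e-9)
  expect_identical(tot3$cases_per_year[jumps + 1], 2600)
})

test_that("a single-volume sweep equals the direct breakdown", {
  sw <- volume_sweep(twist, volumes = 700)
  expect_equal(sweep_totals(sw)$total_eur_per_case,
               breakdown_total(total_cost_per_case(twist, caseload_scenario(700))))
})

test_that("coverage sweeps recompute flow cell, data and platform components", {
  sw <- coverage_sweep(twist, coverages = c(100, 250, 500, 1000),
                       cases_per_year = 300)
  tot <- sweep_totals(sw)
  expect_true(all(diff(tot$total_eur_per_case) >= 0))
  # base coverage reproduces the base breakdown
  expect_equal(tot$total_eur_per_case[1], breakdown_total(base300))

  # cross-module consistency: the flow-cell consumable at each coverage
  # equals the throughput module's independent price-per-case
  fc <- flowcell_spec("NovaSeq X 25B", "NovaSeq X Plus", 52e9, 300, 16480)
  for (d in c(250, 500, 1000)) {
    cfg_d <- sequencing_config(coverage_tumor = d)
    b <- total_cost_per_case(twist, caseload_scenario(300),
                             cfg = cfg_d, flowcell = fc)
    expect_equal(attr(b, "flowcell_eur_per_case"),
                 flowcell_cost_per_case(fc, cfg_d))
  }

  # a coverage no patient fits at is flagged, not an error
  small <- flowcell_spec("benchtop", "x", 130e6, 300, 1310)
  sw_un <- coverage_sweep(twist, coverages = c(100, 200), cases_per_year = 300,
                          flowcell = small)
  expect_true(all(tidy(sw_un)$unreachable))
})

test_that("protocol comparison reports the published paired totals and zero self-deltas", {
  tag <- calibrated_ledger("tagmentation")
  cmp300 <- compare_protocols(twist, tag, caseload_scenario(300),
                              labels = c("twist", "tagmentation"))
  expect_identical(round_cents(cmp300$twist[cmp300$category == "total"]), 5273.11)
  expect_identical(round_cents(cmp300$tagmentation[cmp300$category == "total"]),
                   5195.24)
  cmp2000 <- compare_protocols(twist, tag, caseload_scenario(2000),
                               labels = c("twist", "tagmentation"))
  expect_identical(round_cents(cmp2000$twist[cmp2000$category == "total"]), 3455.00)
  expect_identical(round_cents(cmp2000$tagmentation[cmp2000$category == "total"]),
                   3431.56)
  self <- compare_protocols(twist, twist, caseload_scenario(300))
  expect_true(all(self$delta == 0))
})
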