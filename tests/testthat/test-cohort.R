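fx <- celestial_fixture()
cabo_de <- strategy_from_fixture(fx, "Germany", "cabozantinib")
bsc_de <- strategy_from_fixture(fx, "Germany", "BSC")

test_that("state occupancy partitions the cohort", {
  pfs <- fx$survival$cabozantinib$pfs
  os <- fx$survival$cabozantinib$os
  expect_equal(state_occupancy(pfs, os, 0),
               c(stable = 1, progressive = 0, dead = 0))
  # partition identity at an intermediate time: S_PFS=0.4ish, S_OS=0.7ish
  occ <- state_occupancy(pfs, os, 6)
  expect_equal(unname(occ["stable"]), survival_at(pfs, 6))
  expect_equal(unname(occ["dead"]), 1 - survival_at(os, 6))
  expect_equal(sum(occ), 1, tolerance = 1e-12)

  # crossing curves: progressive clamped to 0, excess assigned to dead
  pfs_hi <- surv_dist("exponential", rate = 0.05)
  os_lo <- surv_dist("exponential", rate = 0.10)
  expect_warning(occ2 <- state_occupancy(pfs_hi, os_lo, 12), "clamped")
  expect_equal(unname(occ2["progressive"]), 0)
  expect_equal(unname(occ2["stable"]) + unname(occ2["dead"]), 1,
               tolerance = 1e-12)
})

test_that("undiscounted life years match the closed-form geometric sum", {
  lam <- 0.08
  d <- surv_dist("exponential", rate = lam)
  strat <- strategy_inputs("x", pfs_dist = d, os_dist = d,
                           u_stable = 1, u_progressive = 1)
  tr <- run_cohort(strat, model_settings(horizon_cycles = 84,
                                         annual_discount_rate = 0))
  expected <- sum(exp(-lam * 0:83)) / 12   # geometric sum of S(k)/12
  expect_equal(tr$totals$ly, expected, tolerance = 1e-9)
  expect_equal(tr$totals$qaly, expected, tolerance = 1e-9)  # utility 1
})

test_that("trace invariants hold: conservation, monotone states", {
  for (arm in c("cabozantinib", "BSC")) {
    tr <- run_cohort(strategy_from_fixture(fx, "Germany", arm))$trace
    expect_true(all(abs(tr$stable + tr$progressive + tr$dead - 1) < 1e-12))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$stable) <= 1e-12))
  }
})

test_that("per-category costs decompose the grand total", {
  tot <- run_cohort(cabo_de)$totals
  expect_equal(sum(tot$cost_by_category), tot$cost, tolerance = 1e-9)
  expect_equal(tot$ly_stable + tot$ly_progressive, tot$ly, tolerance = 1e-12)
})

test_that("discounted life years strictly decrease with the discount rate", {
  ly <- vapply(c(0, 0.03, 0.05), function(r) {
    run_cohort(cabo_de, model_settings(annual_discount_rate = r))$totals$ly
  }, numeric(1))
  expect_true(all(diff(ly) < 0))
})

test_that("identical survival and zero drug/AE costs give zero increments", {
  base <- strategy_inputs("a", pfs_dist = fx$survival$BSC$pfs,
                          os_dist = fx$survival$BSC$os,
                          consultation_first = 37,
                          consultation_subsequent = 37,
                          imaging_first = 93, imaging_subsequent = 93)
  other <- base; other$arm <- "b"
  ta <- run_cohort(base)$totals
  tb <- run_cohort(other)$totals
  ce <- compute_icer(ta, tb)
  expect_equal(ce$d_cost, 0)
  expect_equal(ce$d_qaly, 0)
})

test_that("drug-cost identity: total = monthly price x discounted stable months", {
  tr <- run_cohort(cabo_de)
  stable_months <- with(tr$trace, sum(stable * discount))
  expect_equal(unname(tr$totals$cost_by_category["drug"]),
               6841 * stable_months, tolerance = 1e-9)
})

test_that("a 4-cycle therapy cap restricts drug cost and nothing else", {
  base <- run_cohort(cabo_de)
  capped <- run_cohort(cabo_de, scenario = scenario_spec(therapy_cap_cycles = 4))
  expect_equal(unname(capped$totals$cost_by_category["drug"]),
               sum(base$trace$cost_drug[1:4]), tolerance = 1e-9)
  for (cat in c("ae", "consultation", "laboratory", "imaging")) {
    expect_equal(capped$totals$cost_by_category[[cat]],
                 base$totals$cost_by_category[[cat]], tolerance = 1e-12)
  }
  expect_equal(capped$totals$qaly, base$totals$qaly)
  expect_error(run_cohort(cabo_de,
                          scenario = scenario_spec(therapy_cap_cycles = 99)),
               "horizon")
})

test_that("the progression rebate credits exactly the expected drug mass", {
  base <- run_cohort(cabo_de)
  reb <- run_cohort(cabo_de, scenario = scenario_spec(progression_rebate = TRUE))
  tr <- base$trace
  entrants <- c(0, pmax(0, -diff(tr$stable)))
  expected_credit <- 6841 * sum(entrants * tr$discount)
  expect_equal(unname(base$totals$cost_by_category["drug"] -
                        reb$totals$cost_by_category["drug"]),
               expected_credit, tolerance = 1e-9)
})

test_that("quality adjustment reproduces the published products", {
  expect_equal(round(qaly_from_ly(0.646, 0.76), 3), 0.491)
  expect_equal(round(qaly_from_ly(0.341, 0.76), 3), 0.259)
  expect_equal(qaly_from_ly(1.23, 1.0), 1.23)
  expect_error(qaly_from_ly(0.5, 1.2), "\\[0, 1\\]")
})

test_that("scenario utility variants map to the published sets", {
  expect_identical(apply_scenario(cabo_de, scenario_spec()), cabo_de)

  rcc <- scenario_spec(utility_variant = "rcc_first_line")
  expect_equal(apply_scenario(cabo_de, rcc)$u_stable, 0.817)
  expect_equal(apply_scenario(cabo_de, rcc)$u_progressive, 0.777)
  expect_equal(apply_scenario(bsc_de, rcc)$u_stable, 0.817)

  aed <- scenario_spec(utility_variant = "ae_disutility")
  expect_equal(apply_scenario(cabo_de, aed)$u_stable, 0.728)
  expect_equal(apply_scenario(bsc_de, aed)$u_stable, 0.751)
  expect_equal(apply_scenario(bsc_de, aed)$u_progressive, 0.680)

  aa <- scenario_spec(utility_variant = "abou_alfa")
  expect_equal(apply_scenario(cabo_de, aa)$u_stable, 0.852)
  expect_equal(apply_scenario(bsc_de, aa)$u_stable, 0.760)
})

test_that("the progressive-utility decrement lowers QALYs but not LYs", {
  base <- run_cohort(bsc_de)
  dec <- run_cohort(bsc_de,
                    scenario = scenario_spec(
                      progressive_utility_decrement_per_cycle = 0.005))
  expect_lt(dec$totals$qaly, base$totals$qaly)
  expect_equal(dec$totals$ly, base$totals$ly)
  expect_equal(dec$totals$qaly_stable, base$totals$qaly_stable)
})

test_that("half-cycle correction shifts accruals by less than one cycle", {
  plain <- run_cohort(cabo_de)$totals$ly
  hcc <- run_cohort(cabo_de,
                    model_settings(half_cycle_correction = TRUE))$totals$ly
  expect_lt(hcc, plain)              # occupancy falls within each cycle
  expect_lt(plain - hcc, 1 / 12)     # by less than one undiscounted month
})
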