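test_that("threshold arithmetic is exact", {
  expect_identical(threshold_value(54457, 3), 163371)
  expect_identical(threshold_value(62853, 3), 188559)
  expect_identical(threshold_value(1e6, 0), 0)
  tab <- thresholds_table(c(Germany = 54457, `United States` = 62853))
  expect_setequal(tab$threshold,
                  c(163371, 326742, 490113, 188559, 377118, 565677))
  expect_error(threshold_value(-1, 3))
})

test_that("PPP conversion divides by the foreign-per-dollar rate", {
  expect_equal(round(convert_currency(30000, 0.689)), 43541)
  expect_equal(round(convert_currency(138000, 0.689)), 200290)
  expect_identical(convert_currency(0, 0.741), 0)
  expect_error(convert_currency(100, 0))
})

test_that("ICER quadrants and dominance labels", {
  mk <- function(cost, ly, qaly) list(cost = cost, ly = ly, qaly = qaly)
  ce <- compute_icer(mk(56621, 1.151, 0.834), mk(2064, 0.973, 0.688))
  expect_equal(ce$d_cost, 54557)
  expect_equal(ce$icer_per_ly, 54557 / 0.178, tolerance = 1e-10)
  expect_identical(ce$dominance_ly, "")

  # equal cost, more effective: dominant with ICER 0
  dom <- compute_icer(mk(1000, 1.2, 1.0), mk(1000, 1.0, 0.8))
  expect_identical(dom$dominance_qaly, "dominant")
  expect_equal(dom$icer_per_qaly, 0)

  # costlier and not more effective: dominated, no ICER
  bad <- compute_icer(mk(2000, 1.0, 0.8), mk(1000, 1.2, 1.0))
  expect_identical(bad$dominance_qaly, "dominated")
  expect_true(is.na(bad$icer_per_qaly))

  # cheaper and less effective: southwest quadrant
  sw <- compute_icer(mk(500, 1.0, 0.8), mk(1000, 1.2, 1.0))
  expect_identical(sw$dominance_ly, "southwest")
})

test_that("ICER increments are invariant to a common cost shift", {
  mk <- function(cost) list(cost = cost, ly = 1.2, qaly = 1.0)
  mk2 <- function(cost) list(cost = cost, ly = 1.0, qaly = 0.8)
  a <- compute_icer(mk(5000), mk2(1000))
  b <- compute_icer(mk(5000 + 777), mk2(1000 + 777))
  expect_equal(a$d_cost, b$d_cost)
  expect_equal(a$icer_per_qaly, b$icer_per_qaly)
})

test_that("threshold verdicts honour dominance and the ICER comparison", {
  thr <- thresholds_table(c(Germany = 54457))
  mk <- function(cost, ly, qaly) list(cost = cost, ly = ly, qaly = qaly)
  ce <- compute_icer(mk(56621, 1.151, 0.834), mk(2064, 0.973, 0.688),
                     country = "Germany")
  v <- threshold_verdicts(ce, thr)
  expect_identical(v$ce_per_ly, c(FALSE, TRUE, TRUE))  # ICER ~306k $/LY
})

test_that("the chi-squared screen matches the textbook Pearson statistic", {
  # equal proportions: statistic 0, p = 1, excluded
  eq <- ae_screen(50, 100, 50, 100)
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
  expect_false(eq$include)

  # hand Pearson oracle (no continuity correction)
  pearson <- function(a, na, b, nb) {
    tab <- rbind(c(a, na - a), c(b, nb - b))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  sc <- ae_screen(80, 470, 10, 237)
  expect_equal(sc$statistic, pearson(80, 470, 10, 237), tolerance = 1e-10)
  expect_equal(sc$p, pchisq(pearson(80, 470, 10, 237), 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(sc$include)
  expect_lt(sc$p, 0.05)

  # alpha = 1 includes anything with valid margins
  expect_true(ae_screen(50, 100, 50, 100, alpha = 1)$include)

  expect_warning(zm <- ae_screen(0, 100, 0, 100), "zero margin")
  expect_false(zm$include)
})

test_that("incidence-weighted AE costs follow the accrual split", {
  # zero incidence contributes nothing
  none <- data.frame(incidence = 0, item_cost = 500, recurring = TRUE)
  expect_equal(unname(weighted_ae_cost(none)), c(0, 0))

  # one recurring item: incidence x cost in both cycles
  rec <- data.frame(incidence = 0.5, item_cost = 24, recurring = TRUE)
  expect_equal(weighted_ae_cost(rec), c(first = 12, subsequent = 12))

  # mixed: one-time component only hits the first cycle
  mix <- data.frame(incidence = c(0.5, 0.5), item_cost = c(24, 100),
                    recurring = c(TRUE, FALSE))
  expect_equal(weighted_ae_cost(mix), c(first = 62, subsequent = 12))
})

test_that("the synthetic AE fixture reproduces the published totals", {
  path <- system.file("extdata", "ae_items_synthetic.csv",
                      package = "cabohce")
  items <- read.csv(path)
  cabo <- weighted_ae_cost(items, arm = "cabozantinib")
  expect_lt(abs(cabo[["first"]] - 682) / 682, 0.05)
  expect_lt(abs(cabo[["subsequent"]] - 139) / 139, 0.05)
  bsc <- weighted_ae_cost(items, arm = "BSC")
  expect_lt(abs(bsc[["first"]] - 213) / 213, 0.05)
})

test_that("break-even price finds the threshold fixed point", {
  fx <- celestial_fixture()
  closure <- build_ce_closure(fx, "Germany")
  model_fn <- function(price) {
    closure(overrides = list(drug_cost_monthly = price))
  }
  base_icer <- closure()$icer_per_qaly

  # threshold at the current ICER: searching from the (higher) list price
  # recovers the current reimbursement amount as the break-even price
  be <- breakeven_drug_price(model_fn, base_icer, 8461)
  expect_identical(be$status, "break_even")
  expect_lt(abs(be$price - 6841), 2)

  # break-even price is monotone in the threshold
  lo <- breakeven_drug_price(model_fn, 163371, 6841)$price
  hi <- breakeven_drug_price(model_fn, 250000, 6841)$price
  expect_lt(lo, hi)

  # a huge threshold is already met at list price
  big <- breakeven_drug_price(model_fn, 1e9, 6841)
  expect_identical(big$status, "cost_effective_at_list_price")

  # halving the price halves the incremental drug cost exactly
  full <- closure(full = TRUE)
  half <- closure(overrides = list(drug_cost_monthly = 6841 / 2), full = TRUE)
  expect_equal(unname(half$cabozantinib$totals$cost_by_category["drug"]),
               unname(full$cabozantinib$totals$cost_by_category["drug"]) / 2,
               tolerance = 1e-9)
})
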