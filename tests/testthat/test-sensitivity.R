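fx <- celestial_fixture()
closure_de <- build_ce_closure(fx, "Germany")

test_that("parameter draws match their specified moments", {
  # degenerate gamma: point mass at the mean
  d0 <- sample_params(list(param_spec("x", 100, dist = "gamma", se = 0)),
                      n = 50, seed = 1)
  expect_true(all(d0$x == 100))

  # gamma: sample mean within 2% of the target mean at n = 10,000
  g <- sample_params(list(param_spec("c", 6841, dist = "gamma", se = 1368)),
                     n = 10000, seed = 2)
  expect_lt(abs(mean(g$c) - 6841) / 6841, 0.02)
  expect_true(all(g$c > 0))
  expect_gt(mean((g$c - mean(g$c))^3), 0)  # positive skew

  # scaled beta on [0, 0.05] with mean 0.03 (alpha=6, beta=4)
  b <- sample_params(list(param_spec("r", 0.03, low = 0, high = 0.05,
                                     dist = "beta_scaled", lo = 0, hi = 0.05)),
                     n = 10000, seed = 3)
  expect_true(all(b$r >= 0 & b$r <= 0.05))
  expect_equal(mean(b$r), 0.03, tolerance = 0.01 / 0.03)

  # truncated normal utilities stay in [0, 1]
  u <- sample_params(list(param_spec("u", 0.76, dist = "normal_trunc",
                                     se = 0.2)),
                     n = 5000, seed = 4)
  expect_true(all(u$u >= 0 & u$u <= 1))

  expect_error(param_spec("x", 5, low = 6), "low <= base")
  expect_error(param_spec("x", 5, dist = "gamma"), "requires se")
})

test_that("tornado bars behave and rank the known cost drivers first", {
  specs <- list(
    param_spec("drug_cost_monthly", 6841),
    param_spec("u_stable", 0.76, low = 0.68, high = 0.84),
    param_spec("cost_consultation", 37),
    param_spec("cost_imaging", 93),
    param_spec("annual_discount_rate", 0.03, low = 0, high = 0.05)
  )
  tor <- one_way(specs, closure_de, effect = "qaly")
  expect_equal(nrow(tor), 5)
  expect_true(all(diff(tor$width) <= 0))  # sorted descending
  # drug price and utility dominate monitoring/discounting
  expect_setequal(tor$param[1:2], c("drug_cost_monthly", "u_stable"))
  expect_true(is.finite(attr(tor, "base_icer")))

  # zero-width bar when low = high = base
  z <- one_way(list(param_spec("cost_imaging", 93, low = 93, high = 93)),
               closure_de)
  expect_equal(z$width, 0)

  # bar set invariant to listing order
  tor_rev <- one_way(rev(specs), closure_de, effect = "qaly")
  expect_equal(tor$param, tor_rev$param)
  expect_equal(tor$width, tor_rev$width)
})

test_that("cost overrides scale their category linearly", {
  base <- closure_de(full = TRUE)
  dbl <- closure_de(overrides = list(cost_imaging = 186), full = TRUE)
  inc <- function(x, cat) {
    unname(x$cabozantinib$totals$cost_by_category[cat] -
             x$BSC$totals$cost_by_category[cat])
  }
  expect_equal(inc(dbl, "imaging"), 2 * inc(base, "imaging"),
               tolerance = 1e-9)
  expect_equal(inc(dbl, "drug"), inc(base, "drug"), tolerance = 1e-12)
})

test_that("scenario runner: identity, cap and decreasing utility", {
  scen <- run_scenarios(list(
    base = scenario_spec(),
    cap4 = scenario_spec(therapy_cap_cycles = 4),
    rebate = scenario_spec(progression_rebate = TRUE),
    decreasing_utility = scenario_spec(
      progressive_utility_decrement_per_cycle = 0.005)
  ), closure_de)

  base_ce <- closure_de()
  expect_identical(scen$icer_per_qaly[scen$scenario == "base"],
                   base_ce$icer_per_qaly)
  # capping therapy slashes drug cost, hence the ICER
  expect_lt(scen$icer_per_ly[scen$scenario == "cap4"],
            0.6 * base_ce$icer_per_ly)
  # the rebate lowers cost without touching effects
  expect_lt(scen$d_cost[scen$scenario == "rebate"], base_ce$d_cost)
  expect_equal(scen$d_qaly[scen$scenario == "rebate"], base_ce$d_qaly)
  # decreasing utility after progression lowers the incremental QALY
  expect_lt(abs(scen$d_qaly[scen$scenario == "decreasing_utility"]),
            abs(base_ce$d_qaly) + 1e-12)
  expect_equal(scen$d_ly[scen$scenario == "decreasing_utility"],
               base_ce$d_ly)
})

test_that("the PSA is seed-reproducible and unbiased around base case", {
  specs <- psa_default_specs(fx, "Germany")
  a <- psa(specs, closure_de, n_iter = 300, seed = 99)
  b <- psa(specs, closure_de, n_iter = 300, seed = 99)
  expect_identical(a$iterations, b$iterations)

  base_ce <- closure_de()
  expect_lt(abs(mean(a$iterations$d_cost) - base_ce$d_cost) /
              base_ce$d_cost, 0.05)
  # every sampled scenario keeps the survival benefit
  expect_true(all(a$iterations$d_qaly > 0))

  expect_warning(psa(specs, closure_de, n_iter = 50, seed = 1), "fewer than")
})

test_that("degenerate distributions collapse the PSA to the base case", {
  pts <- list(
    param_spec("drug_cost_monthly", 6841, dist = "point"),
    param_spec("u_stable", 0.76, dist = "point")
  )
  r <- psa(pts, closure_de, n_iter = 120, seed = 5)
  base_ce <- closure_de()
  expect_true(all(r$iterations$d_cost == base_ce$d_cost))
  expect_true(all(r$iterations$d_qaly == base_ce$d_qaly))
})

test_that("acceptability is a monotone curve with the right limits", {
  specs <- psa_default_specs(fx, "Germany")
  r <- psa(specs, closure_de, n_iter = 400, seed = 17)
  lambdas <- c(0, 163371, 326742, 490113, 1e8)
  acc <- acceptability(r, lambdas, effect = "qaly")
  expect_true(all(diff(acc$probability) >= 0))
  # lambda = 0: NMB > 0 iff the iteration saves money
  expect_equal(acc$probability[1], mean(r$iterations$d_cost < 0))
  # lambda -> infinity: probability of any positive effect
  expect_equal(acc$probability[5], mean(r$iterations$d_qaly > 0))
})
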