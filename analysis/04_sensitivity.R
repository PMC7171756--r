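#!/usr/bin/env Rscript
# Stage 4: one-way (tornado) and scenario sensitivity analyses for both
# countries.
library(cabohce)

fx <- celestial_fixture()
dir.create("results", showWarnings = FALSE)

tornado_all <- list()
scenario_all <- list()
for (country in c("Germany", "United States")) {
  closure <- build_ce_closure(fx, country)
  drug <- fx$costs$cost_first[fx$costs$country == country &
                                fx$costs$arm == "cabozantinib" &
                                fx$costs$category == "drug"]
  ae <- fx$costs$cost_first[fx$costs$country == country &
                              fx$costs$arm == "cabozantinib" &
                              fx$costs$category == "ae"]
  specs <- list(
    param_spec("drug_cost_monthly", drug),
    param_spec("u_stable", 0.76, low = 0.68, high = 0.84),
    param_spec("u_progressive", 0.68, low = 0.60, high = 0.76),
    param_spec("cost_ae", ae),
    param_spec("cost_consultation",
               fx$costs$cost_first[fx$costs$country == country &
                                     fx$costs$arm == "cabozantinib" &
                                     fx$costs$category == "consultation"]),
    param_spec("cost_imaging",
               fx$costs$cost_first[fx$costs$country == country &
                                     fx$costs$arm == "cabozantinib" &
                                     fx$costs$category == "imaging"]),
    param_spec("annual_discount_rate", 0.03, low = 0, high = 0.05)
  )
  tor <- one_way(specs, closure, effect = "qaly")
  tor$country <- country
  tornado_all[[country]] <- tor
  cat(sprintf("\n== %s tornado (base ICER $%.0f/QALY) ==\n", country,
              attr(tor, "base_icer")))
  print(tor[, c("param", "icer_low", "icer_high", "width")], digits = 6)

  scen <- run_scenarios(list(
    base = scenario_spec(),
    therapy_cap_4_cycles = scenario_spec(therapy_cap_cycles = 4),
    progression_rebate = scenario_spec(progression_rebate = TRUE),
    utilities_abou_alfa = scenario_spec(utility_variant = "abou_alfa"),
    utilities_rcc_first_line = scenario_spec(utility_variant = "rcc_first_line"),
    utilities_ae_disutility = scenario_spec(utility_variant = "ae_disutility"),
    decreasing_prog_utility = scenario_spec(
      progressive_utility_decrement_per_cycle = 0.005)
  ), closure)
  scenario_all[[country]] <- scen
  cat(sprintf("\n== %s scenarios ==\n", country))
  print(scen[, c("scenario", "d_qaly", "icer_per_ly", "icer_per_qaly")],
        digits = 6)
}
write.csv(do.call(rbind, tornado_all), "results/tornado.csv",
          row.names = FALSE)
write.csv(do.call(rbind, scenario_all), "results/scenarios.csv",
          row.names = FALSE)
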