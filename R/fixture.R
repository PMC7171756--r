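## CELESTIAL-like input bundle: median-matched Weibull survival curves plus
## the published monthly cost tables, utilities, GDP values and PPP rates.

.cost_table <- function() {
  ## Monthly costs in $ per category; `first` applies to the first model
  ## cycle, `subsequent` to all later cycles (the published tables give
  ## deviating second-and-following-month values in brackets).
  rows <- rbind(
    data.frame(country = "Germany", arm = "cabozantinib",
               category = c("drug", "consultation", "laboratory", "imaging", "ae"),
               cost_first = c(6841, 37, 27, 93, 682),
               cost_subsequent = c(6841, 37, 14, 93, 139)),
    data.frame(country = "Germany", arm = "BSC",
               category = c("drug", "consultation", "laboratory", "imaging", "ae"),
               cost_first = c(0, 37, 27, 93, 213),
               cost_subsequent = c(0, 37, 14, 93, 52)),
    data.frame(country = "United States", arm = "cabozantinib",
               category = c("drug", "consultation", "laboratory", "imaging", "ae"),
               cost_first = c(21581, 110, 110, 162, 1673),
               cost_subsequent = c(21581, 75, 55, 162, 645)),
    data.frame(country = "United States", arm = "BSC",
               category = c("drug", "consultation", "laboratory", "imaging", "ae"),
               cost_first = c(0, 110, 110, 162, 557),
               cost_subsequent = c(0, 75, 55, 162, 166))
  )
  rownames(rows) <- NULL
  rows
}

#' CELESTIAL-like model input bundle
#'
#' Builds the complete input set the analysis consumes without any download:
#' four Weibull survival distributions whose medians match the published
#' trial medians (OS 10.2 vs 8.0 months; PFS 5.2 vs 1.9 months) at a common
#' shape, the published per-country monthly cost tables, base-case utilities
#' (0.76 stable / 0.68 progressive), 2018 GDP per capita values and 2019
#' purchasing-power-parity rates.
#'
#' @param shape Weibull shape shared by the four curves (default 1.3, a
#'   monotonically increasing hazard).
#' @return A list with elements `survival` (nested by arm then endpoint),
#'   `costs` (data.frame `country, arm, category, cost_first,
#'   cost_subsequent`), `utilities`, `gdp`, `ppp`, `drug_list_price`.
#' @export
celestial_fixture <- function(shape = 1.3) {
  list(
    survival = list(
      cabozantinib = list(pfs = weibull_from_median(5.2, shape),
                          os  = weibull_from_median(10.2, shape)),
      BSC          = list(pfs = weibull_from_median(1.9, shape),
                          os  = weibull_from_median(8.0, shape))
    ),
    costs = .cost_table(),
    utilities = c(stable = 0.76, progressive = 0.68),
    gdp = c(Germany = 54457, `United States` = 62853),
    ppp = c(EUR_per_USD = 0.741, GBP_per_USD = 0.689),
    drug_list_price = c(Germany = 8461, `United States` = 21581)
  )
}

#' Build per-arm strategy inputs from a fixture bundle
#'
#' @param fixture Output of [celestial_fixture()] (or a like-shaped list).
#' @param country `"Germany"` or `"United States"`.
#' @param arm `"cabozantinib"` or `"BSC"`.
#' @return A [strategy_inputs()] object.
#' @export
strategy_from_fixture <- function(fixture, country, arm) {
  country <- match.arg(country, unique(fixture$costs$country))
  arm <- match.arg(arm, names(fixture$survival))
  ct <- fixture$costs[fixture$costs$country == country &
                        fixture$costs$arm == arm, ]
  get <- function(cat, col) ct[ct$category == cat, col]
  strategy_inputs(
    arm = arm,
    pfs_dist = fixture$survival[[arm]]$pfs,
    os_dist = fixture$survival[[arm]]$os,
    u_stable = fixture$utilities[["stable"]],
    u_progressive = fixture$utilities[["progressive"]],
    drug_cost_monthly = get("drug", "cost_first"),
    ae_cost_first = get("ae", "cost_first"),
    ae_cost_subsequent = get("ae", "cost_subsequent"),
    consultation_first = get("consultation", "cost_first"),
    consultation_subsequent = get("consultation", "cost_subsequent"),
    laboratory_first = get("laboratory", "cost_first"),
    laboratory_subsequent = get("laboratory", "cost_subsequent"),
    imaging_first = get("imaging", "cost_first"),
    imaging_subsequent = get("imaging", "cost_subsequent")
  )
}
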