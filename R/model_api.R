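## High-level driver: compare cabozantinib against best supportive care for
## one country, and build parameter-override closures for the sensitivity
## module.

#' Run the full comparison for one country
#'
#' Builds both strategies from a fixture bundle, runs the cohort trace for
#' each (the scenario applies to both arms; drug-specific switches only
#' affect the arm with a non-zero drug cost), and computes increments.
#'
#' @param fixture A [celestial_fixture()]-shaped input bundle.
#' @param country `"Germany"` or `"United States"`.
#' @param settings A [model_settings()].
#' @param scenario A [scenario_spec()].
#' @param overrides Named list of input overrides, see
#'   [build_ce_closure()].
#' @return A list with `ce` (a `ce_result`), and the two `cohort_trace`s
#'   (`cabozantinib`, `BSC`).
#' @export
ce_compare <- function(fixture, country, settings = model_settings(),
                       scenario = scenario_spec(), overrides = list()) {
  closure <- build_ce_closure(fixture, country, settings)
  closure(overrides = overrides, scenario = scenario, full = TRUE)
}

.apply_overrides <- function(strategy, overrides, base_costs) {
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    switch(nm,
      drug_cost_monthly = {
        if (strategy$drug_cost_monthly > 0) strategy$drug_cost_monthly <- val
      },
      u_stable = { strategy$u_stable <- val },
      u_progressive = { strategy$u_progressive <- val },
      cost_ae = ,
      cost_consultation = ,
      cost_laboratory = ,
      cost_imaging = {
        ## absolute first-month value for the intervention arm; both arms
        ## and the subsequent-month value scale by the same ratio
        cat0 <- sub("^cost_", "", nm)
        base <- base_costs[[cat0]]
        mult <- val / base
        f <- paste0(switch(cat0, ae = "ae_cost", cat0), "_first")
        s <- paste0(switch(cat0, ae = "ae_cost", cat0), "_subsequent")
        strategy[[f]] <- strategy[[f]] * mult
        strategy[[s]] <- strategy[[s]] * mult
      },
      annual_discount_rate = NULL,
      stop(sprintf("unknown override '%s'", nm), call. = FALSE)
    )
  }
  strategy
}

#' Build a parameter-override closure for sensitivity analyses
#'
#' The returned function maps a named list of overrides (and optionally a
#' scenario) to a `ce_result`, re-running the cohort model for both arms.
#' Supported override names: `drug_cost_monthly` (intervention arm, $/month),
#' `u_stable`, `u_progressive` (both arms), `annual_discount_rate`, and
#' `cost_ae`, `cost_consultation`, `cost_laboratory`, `cost_imaging`
#' (absolute first-month $ value for the intervention arm; both arms and the
#' subsequent-month values scale proportionally).
#'
#' @param fixture A [celestial_fixture()]-shaped bundle.
#' @param country Country label present in `fixture$costs`.
#' @param settings A [model_settings()].
#' @return `function(overrides = list(), scenario = scenario_spec(),
#'   full = FALSE)`; with `full = TRUE` the traces are returned alongside.
#' @export
build_ce_closure <- function(fixture, country,
                             settings = model_settings()) {
  cabo0 <- strategy_from_fixture(fixture, country, "cabozantinib")
  bsc0 <- strategy_from_fixture(fixture, country, "BSC")
  base_costs <- list(
    ae = cabo0$ae_cost_first,
    consultation = cabo0$consultation_first,
    laboratory = cabo0$laboratory_first,
    imaging = cabo0$imaging_first
  )
  force(country)
  function(overrides = list(), scenario = scenario_spec(), full = FALSE) {
    set <- settings
    if (!is.null(overrides$annual_discount_rate)) {
      set$annual_discount_rate <- overrides$annual_discount_rate
    }
    cabo <- .apply_overrides(cabo0, overrides, base_costs)
    bsc <- .apply_overrides(bsc0, overrides, base_costs)
    tr_cabo <- run_cohort(cabo, set, scenario)
    tr_bsc <- run_cohort(bsc, set, scenario)
    ce <- compute_icer(tr_cabo$totals, tr_bsc$totals, country = country)
    if (full) list(ce = ce, cabozantinib = tr_cabo, BSC = tr_bsc) else ce
  }
}

#' Table-4-style cost and utility breakdown
#'
#' @param comparison Output of [ce_compare()] (with traces).
#' @return data.frame: per-arm and incremental discounted LY/QALY by state
#'   and per-category costs with percent-of-total columns (computed from
#'   unrounded values).
#' @export
ce_breakdown <- function(comparison) {
  tc <- comparison$cabozantinib$totals
  tb <- comparison$BSC$totals
  cats <- names(tc$cost_by_category)
  rows <- data.frame(
    item = c("ly_stable", "ly_progressive", "ly_total",
             "qaly_stable", "qaly_progressive", "qaly_total",
             paste0("cost_", cats), "cost_total"),
    cabozantinib = c(tc$ly_stable, tc$ly_progressive, tc$ly,
                     tc$qaly_stable, tc$qaly_progressive, tc$qaly,
                     unname(tc$cost_by_category), tc$cost),
    bsc = c(tb$ly_stable, tb$ly_progressive, tb$ly,
            tb$qaly_stable, tb$qaly_progressive, tb$qaly,
            unname(tb$cost_by_category), tb$cost)
  )
  rows$incremental <- rows$cabozantinib - rows$bsc
  is_cost <- grepl("^cost_", rows$item)
  pct <- function(col) {
    ifelse(is_cost, 100 * col / col[rows$item == "cost_total"], NA_real_)
  }
  rows$cabozantinib_pct <- pct(rows$cabozantinib)
  rows$bsc_pct <- pct(rows$bsc)
  rows$incremental_pct <- pct(rows$incremental)
  rows
}
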