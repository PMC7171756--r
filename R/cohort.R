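## Three-state (stable -> progressive -> dead) cohort model. State occupancy
## comes from the partitioned-survival identity on the fitted PFS and OS
## curves; costs and (quality-adjusted) life years accrue per cycle with
## annual discounting.

#' Model settings
#'
#' @param horizon_cycles Number of cycles (default 84, a lifetime horizon at
#'   monthly cycles for this palliative population).
#' @param cycle_length Cycle length in months (default 1, representing a
#'   30-day cycle).
#' @param annual_discount_rate Annual discount rate for costs and effects,
#'   in `[0, 0.10]` (default 0.03).
#' @param half_cycle_correction Average state occupancy over each cycle
#'   (trapezoid) instead of using cycle-start occupancy. Default `FALSE`.
#' @return A `model_settings` list.
#' @export
model_settings <- function(horizon_cycles = 84, cycle_length = 1,
                           annual_discount_rate = 0.03,
                           half_cycle_correction = FALSE) {
  stopifnot(horizon_cycles >= 1, cycle_length > 0,
            annual_discount_rate >= 0, annual_discount_rate <= 0.10)
  structure(list(horizon_cycles = as.integer(horizon_cycles),
                 cycle_length = cycle_length,
                 annual_discount_rate = annual_discount_rate,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_settings")
}

#' Per-arm strategy inputs
#'
#' Monthly costs in $ per category, with the first-cycle value and the
#' deviating second-and-following-month value given separately. Accrual
#' rules: drug and adverse-event costs accrue in stable cycles only;
#' consultation, laboratory and imaging accrue in all alive cycles;
#' `one_time_costs` accrue in cycle 1 of stable.
#'
#' @param arm Arm label.
#' @param pfs_dist,os_dist [surv_dist()] objects for progression-free and
#'   overall survival.
#' @param u_stable,u_progressive Health-state utilities in `[0, 1]`.
#' @param drug_cost_monthly Drug cost per month in $ (stable cycles only).
#' @param ae_cost_first,ae_cost_subsequent Adverse-event treatment cost per
#'   month (stable cycles only).
#' @param consultation_first,consultation_subsequent,laboratory_first,laboratory_subsequent,imaging_first,imaging_subsequent
#'   Monitoring costs per month (all alive cycles).
#' @param one_time_costs One-off cost charged in the first cycle.
#' @return A `strategy_inputs` list.
#' @export
strategy_inputs <- function(arm, pfs_dist, os_dist,
                            u_stable = 0.76, u_progressive = 0.68,
                            drug_cost_monthly = 0,
                            ae_cost_first = 0, ae_cost_subsequent = 0,
                            consultation_first = 0, consultation_subsequent = 0,
                            laboratory_first = 0, laboratory_subsequent = 0,
                            imaging_first = 0, imaging_subsequent = 0,
                            one_time_costs = 0) {
  stopifnot_surv_dist(pfs_dist)
  stopifnot_surv_dist(os_dist)
  costs <- c(drug_cost_monthly, ae_cost_first, ae_cost_subsequent,
             consultation_first, consultation_subsequent,
             laboratory_first, laboratory_subsequent,
             imaging_first, imaging_subsequent, one_time_costs)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  for (u in c(u_stable, u_progressive)) {
    if (is.na(u) || u < 0 || u > 1) {
      stop("utilities must be in [0, 1]", call. = FALSE)
    }
  }
  structure(list(
    arm = arm, pfs_dist = pfs_dist, os_dist = os_dist,
    u_stable = u_stable, u_progressive = u_progressive,
    drug_cost_monthly = drug_cost_monthly,
    ae_cost_first = ae_cost_first, ae_cost_subsequent = ae_cost_subsequent,
    consultation_first = consultation_first,
    consultation_subsequent = consultation_subsequent,
    laboratory_first = laboratory_first,
    laboratory_subsequent = laboratory_subsequent,
    imaging_first = imaging_first, imaging_subsequent = imaging_subsequent,
    one_time_costs = one_time_costs
  ), class = "strategy_inputs")
}

#' Scenario switches
#'
#' @param therapy_cap_cycles Optional integer: drug cost accrues only in the
#'   first N stable cycles (the published sensitivity analysis caps therapy
#'   at 4 months).
#' @param progression_rebate If `TRUE`, one monthly drug price is credited
#'   for the probability mass newly entering the progressive state each
#'   cycle, discounted at the entry cycle.
#' @param utility_variant Optional named utility set: one of
#'   `"base"`, `"abou_alfa"`, `"rcc_first_line"`, `"ae_disutility"`.
#' @param progressive_utility_decrement_per_cycle Utility decrement applied
#'   to the progressive state per model month (0.005 in the
#'   decreasing-utility scenario; default 0).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(therapy_cap_cycles = NULL,
                          progression_rebate = FALSE,
                          utility_variant = NULL,
                          progressive_utility_decrement_per_cycle = 0) {
  if (!is.null(therapy_cap_cycles)) {
    stopifnot(therapy_cap_cycles >= 1)
    therapy_cap_cycles <- as.integer(therapy_cap_cycles)
  }
  if (!is.null(utility_variant)) {
    utility_variant <- match.arg(utility_variant, names(.utility_variants))
  }
  stopifnot(progressive_utility_decrement_per_cycle >= 0)
  structure(list(
    therapy_cap_cycles = therapy_cap_cycles,
    progression_rebate = isTRUE(progression_rebate),
    utility_variant = utility_variant,
    progressive_utility_decrement_per_cycle =
      progressive_utility_decrement_per_cycle
  ), class = "scenario_spec")
}

## Utility sensitivity sets: (stable, progressive) per arm.
.utility_variants <- list(
  base          = list(cabozantinib = c(0.760, 0.680), BSC = c(0.760, 0.680)),
  abou_alfa     = list(cabozantinib = c(0.852, 0.680), BSC = c(0.760, 0.680)),
  rcc_first_line = list(cabozantinib = c(0.817, 0.777), BSC = c(0.817, 0.777)),
  ae_disutility = list(cabozantinib = c(0.728, 0.680), BSC = c(0.751, 0.680))
)

#' Apply a scenario's strategy-level modifications
#'
#' Utility variants replace the per-arm utilities (matched on the strategy's
#' arm label; arms not named in a variant keep their inputs). Runtime rules
#' (therapy cap, progression rebate, progressive-utility decrement) are
#' handled by [run_cohort()] and leave the strategy unchanged here.
#'
#' @param base A [strategy_inputs()] object.
#' @param scenario A [scenario_spec()].
#' @return A modified `strategy_inputs`.
#' @export
apply_scenario <- function(base, scenario = scenario_spec()) {
  stopifnot(inherits(base, "strategy_inputs"),
            inherits(scenario, "scenario_spec"))
  out <- base
  if (!is.null(scenario$utility_variant)) {
    set <- .utility_variants[[scenario$utility_variant]]
    if (base$arm %in% names(set)) {
      out$u_stable <- set[[base$arm]][1]
      out$u_progressive <- set[[base$arm]][2]
    }
  }
  out
}

#' State occupancy at one cycle via the partitioned-survival identity
#'
#' `stable = S_PFS(t)`, `dead = 1 - S_OS(t)`,
#' `progressive = max(0, S_OS(t) - S_PFS(t))` with `t = cycle * delta`.
#' When the extrapolated curves cross (`S_PFS > S_OS`) the progressive share
#' is clamped to 0 and the excess assigned to dead, with a warning.
#'
#' @param pfs,os [surv_dist()] objects.
#' @param cycle Non-negative cycle index.
#' @param delta Cycle length in months.
#' @return Named numeric vector `(stable, progressive, dead)` summing to 1.
#' @export
state_occupancy <- function(pfs, os, cycle, delta = 1) {
  stopifnot(cycle >= 0, delta > 0)
  t <- cycle * delta
  sp <- survival_at(pfs, t)
  so <- survival_at(os, t)
  if (sp > so + 1e-12) {
    warning("S_PFS exceeds S_OS; progressive share clamped to 0")
  }
  stable <- sp
  progressive <- max(0, so - sp)
  dead <- 1 - stable - progressive
  c(stable = stable, progressive = progressive, dead = max(0, dead))
}

#' Run the discounted cohort trace
#'
#' Evaluates state occupancy at each cycle start `t_k = k * delta`
#' (k = 0, ..., horizon-1), applies the discount factor
#' `d(t) = (1 + r)^(-t/12)`, and accrues life years, QALYs and per-category
#' costs under the accrual rules in [strategy_inputs()]. With
#' `half_cycle_correction = TRUE` occupancy is averaged between cycle start
#' and end for all accruals.
#'
#' @param strategy A [strategy_inputs()].
#' @param settings A [model_settings()].
#' @param scenario A [scenario_spec()]; utility variants are applied via
#'   [apply_scenario()], and therapy cap / rebate / utility decrement are
#'   enforced during the trace.
#' @return A `cohort_trace`: list with `trace` (per-cycle data.frame) and
#'   `totals` (discounted LY/QALY by state and per-category costs).
#' @export
run_cohort <- function(strategy, settings = model_settings(),
                       scenario = scenario_spec()) {
  stopifnot(inherits(strategy, "strategy_inputs"),
            inherits(settings, "model_settings"))
  strategy <- apply_scenario(strategy, scenario)
  H <- settings$horizon_cycles
  if (!is.null(scenario$therapy_cap_cycles) &&
      scenario$therapy_cap_cycles > H) {
    stop("therapy_cap_cycles exceeds the model horizon", call. = FALSE)
  }
  delta <- settings$cycle_length
  r <- settings$annual_discount_rate

  k <- 0:(H - 1)
  t <- k * delta
  disc <- (1 + r)^(-t / 12)

  sp <- survival_at(strategy$pfs_dist, t)
  so <- survival_at(strategy$os_dist, t)
  if (any(sp > so + 1e-12)) {
    warning("S_PFS exceeds S_OS in the extrapolated tail; progressive share clamped to 0")
  }
  stable <- sp
  progressive <- pmax(0, so - sp)
  dead <- pmax(0, 1 - stable - progressive)

  if (settings$half_cycle_correction) {
    t_end <- t + delta
    sp1 <- survival_at(strategy$pfs_dist, t_end)
    so1 <- survival_at(strategy$os_dist, t_end)
    stable_eff <- (stable + sp1) / 2
    progressive_eff <- (progressive + pmax(0, so1 - sp1)) / 2
  } else {
    stable_eff <- stable
    progressive_eff <- progressive
  }
  alive_eff <- stable_eff + progressive_eff

  first <- as.numeric(k == 0)
  later <- 1 - first

  drug_mask <- if (is.null(scenario$therapy_cap_cycles)) {
    rep(1, H)
  } else {
    as.numeric(k < scenario$therapy_cap_cycles)
  }
  cost_drug <- strategy$drug_cost_monthly * delta * stable_eff * disc * drug_mask
  if (scenario$progression_rebate) {
    ## mass leaving stable each cycle, credited one monthly drug price at
    ## the entry cycle (cohort translation of the individual-level rule)
    entrants <- c(0, pmax(0, -diff(stable)))
    cost_drug <- cost_drug - strategy$drug_cost_monthly * entrants * disc
  }
  per_month <- function(f, s) f * first + s * later
  cost_ae <- per_month(strategy$ae_cost_first, strategy$ae_cost_subsequent) *
    delta * stable_eff * disc
  cost_consultation <- per_month(strategy$consultation_first,
                                 strategy$consultation_subsequent) *
    delta * alive_eff * disc
  cost_laboratory <- per_month(strategy$laboratory_first,
                               strategy$laboratory_subsequent) *
    delta * alive_eff * disc
  cost_imaging <- per_month(strategy$imaging_first,
                            strategy$imaging_subsequent) *
    delta * alive_eff * disc
  cost_drug[1] <- cost_drug[1] + strategy$one_time_costs * stable_eff[1] * disc[1]

  ly_stable <- stable_eff * delta / 12 * disc
  ly_progressive <- progressive_eff * delta / 12 * disc
  u_prog_k <- pmax(0, strategy$u_progressive -
                     scenario$progressive_utility_decrement_per_cycle * k)
  qaly_stable <- ly_stable * strategy$u_stable
  qaly_progressive <- progressive_eff * delta / 12 * disc * u_prog_k

  trace <- data.frame(
    cycle = k, time = t,
    stable = stable, progressive = progressive, dead = dead,
    discount = disc,
    cost_drug = cost_drug, cost_ae = cost_ae,
    cost_consultation = cost_consultation,
    cost_laboratory = cost_laboratory, cost_imaging = cost_imaging,
    ly = ly_stable + ly_progressive,
    qaly = qaly_stable + qaly_progressive
  )
  cost_by_category <- c(
    drug = sum(cost_drug), ae = sum(cost_ae),
    consultation = sum(cost_consultation),
    laboratory = sum(cost_laboratory), imaging = sum(cost_imaging)
  )
  totals <- list(
    ly_stable = sum(ly_stable), ly_progressive = sum(ly_progressive),
    ly = sum(ly_stable + ly_progressive),
    qaly_stable = sum(qaly_stable), qaly_progressive = sum(qaly_progressive),
    qaly = sum(qaly_stable + qaly_progressive),
    cost_by_category = cost_by_category,
    cost = sum(cost_by_category)
  )
  structure(list(arm = strategy$arm, trace = trace, totals = totals,
                 settings = settings, scenario = scenario),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace %s: %d cycles, cost=%.0f, LY=%.3f, QALY=%.3f>\n",
              x$arm, nrow(x$trace), x$totals$cost, x$totals$ly,
              x$totals$qaly))
  invisible(x)
}

#' Quality-adjust discounted life years
#'
#' @param ly_state Discounted life years accrued in one state (>= 0).
#' @param utility Health-state utility in `[0, 1]`.
#' @return Discounted QALYs (unrounded).
#' @export
qaly_from_ly <- function(ly_state, utility) {
  stopifnot(all(ly_state >= 0))
  if (any(utility < 0 | utility > 1)) {
    stop("utility must be in [0, 1]", call. = FALSE)
  }
  ly_state * utility
}
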