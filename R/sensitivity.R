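## One-way (tornado), scenario and probabilistic sensitivity analyses with
## cost-effectiveness acceptability output.

#' Parameter specification for sensitivity analyses
#'
#' For one-way analysis `low`/`high` bound the deterministic sweep (default
#' +/- 25% of base when omitted). For the PSA, `dist` names the sampling
#' distribution: `"gamma"` for costs (mean = base, `se` given; positive
#' skew, no upper limit), `"beta_scaled"` on `[lo, hi]` with mean = base
#' (used for the discount rate on [0, 0.05]), `"normal_trunc"` for utilities
#' (truncated to [0, 1] by resampling), or `"point"` (degenerate).
#'
#' @param name Override name understood by the model closure, see
#'   [build_ce_closure()].
#' @param base Base-case value; equals the sampling distribution's mean.
#' @param low,high One-way bounds (`low <= base <= high`).
#' @param dist Sampling distribution for the PSA.
#' @param se Standard error (gamma, normal_trunc).
#' @param lo,hi Support bounds (beta_scaled).
#' @return A `param_spec` list.
#' @export
param_spec <- function(name, base, low = NULL, high = NULL,
                       dist = c("point", "gamma", "beta_scaled",
                                "normal_trunc"),
                       se = NULL, lo = NULL, hi = NULL) {
  dist <- match.arg(dist)
  if (is.null(low)) low <- 0.75 * base
  if (is.null(high)) high <- 1.25 * base
  stopifnot(low <= base, base <= high)
  if (dist == "beta_scaled") {
    stopifnot(!is.null(lo), !is.null(hi), lo < hi, base > lo, base < hi)
  }
  if (dist %in% c("gamma", "normal_trunc") && is.null(se)) {
    stop("dist '", dist, "' requires se", call. = FALSE)
  }
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, se = se, lo = lo, hi = hi),
            class = "param_spec")
}

.sample_one <- function(spec, n) {
  with(spec, switch(dist,
    point = rep(base, n),
    gamma = {
      if (is.null(se) || se <= 0) rep(base, n)
      else stats::rgamma(n, shape = (base / se)^2, scale = se^2 / base)
    },
    beta_scaled = {
      m <- (base - lo) / (hi - lo)
      conc <- 10  # alpha + beta; gives alpha=6, beta=4 at mean 3% on [0,5%]
      lo + (hi - lo) * stats::rbeta(n, conc * m, conc * (1 - m))
    },
    normal_trunc = {
      if (is.null(se) || se <= 0) return(rep(base, n))
      x <- stats::rnorm(n, base, se)
      bad <- x < 0 | x > 1
      while (any(bad)) {
        x[bad] <- stats::rnorm(sum(bad), base, se)
        bad <- x < 0 | x > 1
      }
      x
    }
  ))
}

#' Draw parameter sets for the PSA
#'
#' @param specs List of [param_spec()]s.
#' @param n Number of draws.
#' @param seed Optional seed (deterministic draws under a fixed seed).
#' @return data.frame with one column per parameter, `n` rows.
#' @export
sample_params <- function(specs, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(specs, .sample_one, n = n)
  names(out) <- vapply(specs, `[[`, character(1), "name")
  as.data.frame(out, check.names = FALSE)
}

#' One-way (tornado) sensitivity analysis
#'
#' Runs the model at each parameter's low and high value, holding the rest
#' at base, and reports the ICER swing sorted by bar width.
#'
#' @param specs List of [param_spec()]s.
#' @param closure Model closure from [build_ce_closure()].
#' @param effect `"qaly"` or `"ly"`.
#' @return data.frame `param, low, high, icer_low, icer_high, width` sorted
#'   by descending width, with the base-case ICER as attribute
#'   `"base_icer"`.
#' @export
one_way <- function(specs, closure, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  field <- paste0("icer_per_", effect)
  base_icer <- closure()[[field]]
  rows <- lapply(specs, function(sp) {
    icer_lo <- closure(overrides = stats::setNames(list(sp$low), sp$name))[[field]]
    icer_hi <- closure(overrides = stats::setNames(list(sp$high), sp$name))[[field]]
    data.frame(param = sp$name, low = sp$low, high = sp$high,
               icer_low = icer_lo, icer_high = icer_hi,
               width = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

#' Run a set of named scenarios
#'
#' @param scenarios Named list of [scenario_spec()]s.
#' @param closure Model closure from [build_ce_closure()].
#' @return data.frame with one row per scenario: increments and ICERs.
#' @export
run_scenarios <- function(scenarios, closure) {
  rows <- lapply(names(scenarios), function(nm) {
    ce <- closure(scenario = scenarios[[nm]])
    data.frame(scenario = nm, country = ce$country,
               d_cost = ce$d_cost, d_ly = ce$d_ly, d_qaly = ce$d_qaly,
               icer_per_ly = ce$icer_per_ly,
               icer_per_qaly = ce$icer_per_qaly)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` parameter sets and runs the full cohort comparison for
#' each, collecting incremental cost and effects (the cost-effectiveness
#' plane scatter).
#'
#' @param specs List of [param_spec()]s with PSA distributions.
#' @param closure Model closure from [build_ce_closure()].
#' @param n_iter Number of iterations (default 10000; a warning is issued
#'   under 100).
#' @param seed Optional seed; identical seeds give identical results.
#' @return A `psa_result`: list with `iterations` (data.frame `iteration,
#'   d_cost, d_ly, d_qaly`), `n_iter`, `seed`, `country`.
#' @export
psa <- function(specs, closure, n_iter = 10000, seed = NULL) {
  if (n_iter < 100) warning("fewer than 100 PSA iterations")
  draws <- sample_params(specs, n = n_iter, seed = seed)
  nms <- names(draws)
  d_cost <- d_ly <- d_qaly <- numeric(n_iter)
  country <- NA_character_
  for (i in seq_len(n_iter)) {
    ov <- stats::setNames(as.list(unlist(draws[i, , drop = FALSE],
                                         use.names = FALSE)), nms)
    ce <- closure(overrides = ov)
    d_cost[i] <- ce$d_cost
    d_ly[i] <- ce$d_ly
    d_qaly[i] <- ce$d_qaly
    if (i == 1) country <- ce$country
  }
  structure(list(
    iterations = data.frame(iteration = seq_len(n_iter), d_cost = d_cost,
                            d_ly = d_ly, d_qaly = d_qaly),
    n_iter = n_iter, seed = seed, country = country
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result%s: %d iterations, mean d_cost=%.0f, mean d_qaly=%.3f>\n",
    if (is.na(x$country)) "" else paste0(" ", x$country),
    x$n_iter, mean(x$iterations$d_cost), mean(x$iterations$d_qaly)))
  invisible(x)
}

#' Cost-effectiveness acceptability
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations
#' with positive net monetary benefit `lambda * d_effect - d_cost > 0`.
#' NMB is sign-safe when an iteration's incremental effect is negative,
#' unlike an ICER comparison.
#'
#' @param result A `psa_result`.
#' @param thresholds Numeric vector of thresholds, or a data.frame from
#'   [thresholds_table()] (its `threshold` column is used and carried along).
#' @param effect `"qaly"` or `"ly"`.
#' @return data.frame `threshold, probability` (plus any threshold-table
#'   columns).
#' @export
acceptability <- function(result, thresholds, effect = c("qaly", "ly")) {
  stopifnot(inherits(result, "psa_result"),
            nrow(result$iterations) > 0)
  effect <- match.arg(effect)
  d_eff <- result$iterations[[paste0("d_", effect)]]
  d_cost <- result$iterations$d_cost
  tab <- if (is.data.frame(thresholds)) thresholds
         else data.frame(threshold = as.numeric(thresholds))
  tab$effect <- effect
  tab$probability <- vapply(tab$threshold, function(l) {
    mean(l * d_eff - d_cost > 0)
  }, numeric(1))
  tab
}

#' Default PSA parameter specifications
#'
#' Gamma distributions for every cost input with se = 20% of the mean,
#' truncated normals for the two utilities (se 0.05), and a scaled beta on
#' [0, 0.05] with mean 0.03 for the annual discount rate.
#'
#' @param fixture A [celestial_fixture()]-shaped bundle.
#' @param country Country label.
#' @param cost_se_frac Cost standard error as a fraction of the mean.
#' @param utility_se Utility standard error (absolute).
#' @return List of [param_spec()]s.
#' @export
psa_default_specs <- function(fixture, country, cost_se_frac = 0.20,
                              utility_se = 0.05) {
  ct <- fixture$costs[fixture$costs$country == country &
                        fixture$costs$arm == "cabozantinib", ]
  cost <- function(cat) ct$cost_first[ct$category == cat]
  gamma_spec <- function(name, base) {
    param_spec(name, base, dist = "gamma", se = cost_se_frac * base)
  }
  list(
    gamma_spec("drug_cost_monthly", cost("drug")),
    gamma_spec("cost_ae", cost("ae")),
    gamma_spec("cost_consultation", cost("consultation")),
    gamma_spec("cost_laboratory", cost("laboratory")),
    gamma_spec("cost_imaging", cost("imaging")),
    param_spec("u_stable", fixture$utilities[["stable"]],
               dist = "normal_trunc", se = utility_se),
    param_spec("u_progressive", fixture$utilities[["progressive"]],
               dist = "normal_trunc", se = utility_se),
    param_spec("annual_discount_rate", 0.03, low = 0, high = 0.05,
               dist = "beta_scaled", lo = 0, hi = 0.05)
  )
}
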