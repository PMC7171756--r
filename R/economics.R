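## Thresholds, currency conversion, ICER/NMB arithmetic, adverse-event
## screening and the break-even drug price analysis.

#' Willingness-to-pay threshold from GDP per capita
#'
#' Thresholds are multiples (conventionally 3, 6, 9) of GDP per capita per
#' gained LY or QALY, following the WHO 3x-GDP rule.
#'
#' @param gdp GDP per capita in $ (> 0).
#' @param factor Non-negative multiple.
#' @return Threshold in $ per LY (QALY); the exact product.
#' @export
threshold_value <- function(gdp, factor) {
  stopifnot(gdp > 0, factor >= 0)
  gdp * factor
}

#' Threshold table for several countries and factors
#'
#' @param gdp Named numeric vector of GDP per capita values.
#' @param factors Integer multiples (default `c(3, 6, 9)`).
#' @return data.frame `country, factor, threshold`.
#' @export
thresholds_table <- function(gdp, factors = c(3, 6, 9)) {
  out <- expand.grid(country = names(gdp), factor = factors,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$threshold <- threshold_value(gdp[out$country], out$factor)
  rownames(out) <- NULL
  out
}

#' Convert a foreign-currency amount to $ by a PPP rate
#'
#' @param amount Amount in the foreign currency.
#' @param ppp_rate Purchasing-power-parity rate in foreign units per $
#'   (e.g. 0.741 EUR/$, 0.689 GBP/$).
#' @return Amount in $.
#' @export
convert_currency <- function(amount, ppp_rate) {
  stopifnot(ppp_rate > 0)
  amount / ppp_rate
}

#' Incremental cost-effectiveness result
#'
#' Increments are intervention minus comparator. ICERs are defined only for
#' a positive incremental effect; a costlier, not-more-effective intervention
#' is `"dominated"`, a cheaper-or-equal, more effective one is `"dominant"`
#' (ICER reported as the ratio, <= 0). Cost-saving and less effective
#' combinations fall in the southwest quadrant and carry no ICER.
#'
#' @param intervention,comparator Lists (or `cohort_trace$totals`) with
#'   numeric elements `cost`, `ly`, `qaly`.
#' @param country Optional label.
#' @return A `ce_result` list: per-arm totals, increments `d_cost`, `d_ly`,
#'   `d_qaly`, `icer_per_ly`, `icer_per_qaly` and dominance labels.
#' @export
compute_icer <- function(intervention, comparator, country = NA_character_) {
  need <- c("cost", "ly", "qaly")
  stopifnot(all(need %in% names(intervention)),
            all(need %in% names(comparator)))
  d_cost <- intervention$cost - comparator$cost
  d_ly <- intervention$ly - comparator$ly
  d_qaly <- intervention$qaly - comparator$qaly
  one <- function(d_eff) {
    if (d_eff > 0) {
      list(icer = d_cost / d_eff,
           dominance = if (d_cost <= 0) "dominant" else "")
    } else if (d_cost > 0) {
      list(icer = NA_real_, dominance = "dominated")
    } else {
      list(icer = NA_real_, dominance = "southwest")
    }
  }
  ly <- one(d_ly)
  qaly <- one(d_qaly)
  structure(list(
    country = country,
    intervention = intervention[need], comparator = comparator[need],
    d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
    icer_per_ly = ly$icer, icer_per_qaly = qaly$icer,
    dominance_ly = ly$dominance, dominance_qaly = qaly$dominance
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf(
    "<ce_result%s: d_cost=%.0f d_ly=%.3f d_qaly=%.3f ICER=%.0f $/LY, %.0f $/QALY>\n",
    if (is.na(x$country)) "" else paste0(" ", x$country),
    x$d_cost, x$d_ly, x$d_qaly, x$icer_per_ly, x$icer_per_qaly))
  invisible(x)
}

#' Threshold verdicts for a cost-effectiveness result
#'
#' @param ce A `ce_result`.
#' @param thresholds data.frame from [thresholds_table()] (optionally
#'   pre-filtered to the result's country).
#' @return The thresholds table with logical columns `ce_per_ly`,
#'   `ce_per_qaly` (ICER at or under the threshold; dominance counts as
#'   cost-effective, dominated as not).
#' @export
threshold_verdicts <- function(ce, thresholds) {
  stopifnot(inherits(ce, "ce_result"))
  verdict <- function(icer, dominance, lambda) {
    if (dominance == "dominant") TRUE
    else if (is.na(icer)) FALSE
    else icer <= lambda
  }
  thresholds$ce_per_ly <- vapply(thresholds$threshold, function(l) {
    verdict(ce$icer_per_ly, ce$dominance_ly, l)
  }, logical(1))
  thresholds$ce_per_qaly <- vapply(thresholds$threshold, function(l) {
    verdict(ce$icer_per_qaly, ce$dominance_qaly, l)
  }, logical(1))
  thresholds
}

#' Chi-squared screen for an adverse event
#'
#' Pearson chi-squared test without continuity correction on the 2x2
#' affected/unaffected table; the event is retained only when the arms
#' differ significantly (one-sided inclusion rule `p < alpha`).
#'
#' @param affected_a,total_a Affected count and arm size, intervention arm.
#' @param affected_b,total_b Affected count and arm size, comparator arm.
#' @param alpha Significance level (default 0.05).
#' @return List `include` (logical), `p`, `statistic`.
#' @export
ae_screen <- function(affected_a, total_a, affected_b, total_b,
                      alpha = 0.05) {
  counts <- c(affected_a, total_a, affected_b, total_b)
  stopifnot(all(counts >= 0), all(counts == round(counts)),
            affected_a <= total_a, affected_b <= total_b)
  tab <- rbind(c(affected_a, total_a - affected_a),
               c(affected_b, total_b - affected_b))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in the 2x2 table; adverse event excluded")
    return(list(include = FALSE, p = NA_real_, statistic = NA_real_))
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  p <- unname(ht$p.value)
  ## alpha = 1 is the everything-with-valid-margins boundary (p is never < 1
  ## by a strict comparison when the arms agree exactly)
  list(include = p < alpha || alpha >= 1, p = p,
       statistic = unname(ht$statistic))
}

#' Incidence-weighted adverse-event cost per cycle
#'
#' Each screened item contributes `incidence x item_cost`. Recurring items
#' (permanent therapy, e.g. antihypertensives) contribute to every stable
#' cycle; one-time items (defined-duration treatments, hospitalizations)
#' contribute to the first cycle only.
#'
#' @param items data.frame with columns `affected`, `total` (or a
#'   pre-computed `incidence`), `item_cost`, `recurring` (logical), and
#'   optionally `arm`.
#' @param arm Optional arm filter.
#' @return Named numeric `c(first, subsequent)` in $ per month.
#' @export
weighted_ae_cost <- function(items, arm = NULL) {
  if (!is.null(arm)) items <- items[items$arm == arm, , drop = FALSE]
  if (!"incidence" %in% names(items)) {
    items$incidence <- items$affected / items$total
  }
  stopifnot(all(items$incidence >= 0 & items$incidence <= 1),
            all(items$item_cost >= 0))
  w <- items$incidence * items$item_cost
  rec <- as.logical(items$recurring)
  c(first = sum(w), subsequent = sum(w[rec]))
}

#' Break-even monthly drug price for a willingness-to-pay threshold
#'
#' Finds, by bisection to +/- $1, the monthly drug price at which the ICER
#' equals the threshold. The ICER is monotone increasing in the price, so
#' prices above the break-even are not cost-effective.
#'
#' @param model_fn Function mapping a monthly drug price ($) to a
#'   `ce_result`.
#' @param threshold Willingness-to-pay in $ per effect unit (> 0).
#' @param list_price Upper bound for the search ($).
#' @param effect `"ly"` or `"qaly"`.
#' @param tol Price tolerance in $ (default 1).
#' @return List `price` ($/month) and `status`: `"break_even"`,
#'   `"cost_effective_at_list_price"`, or `"never"`.
#' @export
breakeven_drug_price <- function(model_fn, threshold, list_price,
                                 effect = c("qaly", "ly"), tol = 1) {
  effect <- match.arg(effect)
  stopifnot(threshold > 0, list_price > 0)
  field <- paste0("icer_per_", effect)
  g <- function(price) {
    ce <- model_fn(price)
    icer <- ce[[field]]
    if (is.na(icer)) icer <- if (ce$d_cost > 0) Inf else -Inf
    icer - threshold
  }
  if (g(list_price) <= 0) {
    return(list(price = list_price, status = "cost_effective_at_list_price"))
  }
  if (g(0) > 0) {
    return(list(price = NA_real_, status = "never"))
  }
  lo <- 0; hi <- list_price
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  list(price = (lo + hi) / 2, status = "break_even")
}
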