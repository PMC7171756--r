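## Least-squares fitting of parametric survival curves to digitized KM points,
## SSR-based information criteria, and model selection.

#' Information criteria for a least-squares survival fit
#'
#' Gaussian least-squares forms: `aic = n*log(ssr/n) + 2k` and
#' `bic = n*log(ssr/n) + k*log(n)`. A perfect fit (`ssr = 0`) returns `-Inf`
#' for both with a warning.
#'
#' @param ssr Sum of squared residuals, `>= 0`.
#' @param n Number of fitted points, `> k`.
#' @param k Number of free parameters.
#' @return Named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(ssr, n, k) {
  stopifnot(ssr >= 0, n > k, k >= 1)
  if (ssr == 0) {
    warning("ssr is exactly 0; information criteria degenerate to -Inf")
    return(c(aic = -Inf, bic = -Inf))
  }
  base <- n * log(ssr / n)
  c(aic = base + 2 * k, bic = base + k * log(n))
}

.fit_starts <- function(family, med) {
  ## Deterministic multi-start grid anchored at a median estimate.
  switch(family,
    exponential = lapply(c(0.25, 0.5, 1, 2, 4), function(f) {
      c(rate = f * log(2) / med)
    }),
    weibull = lapply(c(0.6, 1, 1.3, 2, 3), function(g) {
      c(scale = med / log(2)^(1 / g), shape = g)
    }),
    gompertz = lapply(c(0.01, 0.05, 0.1, 0.2, 0.5), function(a) {
      c(shape = a, rate = a * log(2) / (exp(a * med) - 1))
    }),
    loglogistic = lapply(c(0.8, 1.3, 2, 3, 5), function(b) {
      c(scale = med, shape = b)
    }),
    lognormal = lapply(c(0.25, 0.5, 0.75, 1, 1.5), function(s) {
      c(meanlog = log(med), sdlog = s)
    })
  )
}

.km_median_guess <- function(curve) {
  s <- curve$survival
  t <- curve$time
  if (min(s) <= 0.5) {
    i <- which(s <= 0.5)[1]
    if (i == 1) return(max(t[1], 1e-6))
    ## linear interpolation across the 0.5 crossing
    t[i - 1] + (t[i] - t[i - 1]) * (s[i - 1] - 0.5) /
      max(s[i - 1] - s[i], 1e-12)
  } else {
    ## curve never reaches 0.5 within follow-up: extrapolate beyond last point
    2 * max(t)
  }
}

## positive parameters are optimized on the log scale; lognormal meanlog free
.transform <- function(family, p) {
  if (family == "lognormal") c(p[["meanlog"]], log(p[["sdlog"]])) else log(p)
}

.untransform <- function(family, theta) {
  nm <- .family_params[[family]]
  p <- if (family == "lognormal") c(theta[1], exp(theta[2])) else exp(theta)
  stats::setNames(as.list(p), nm)
}

#' Fit a parametric survival distribution to KM points by least squares
#'
#' Minimizes the sum of squared residuals between the digitized survival
#' points and the parametric survival function, using Nelder-Mead from five
#' deterministic median-anchored starts with positive parameters
#' log-transformed. This mirrors how published curves are extrapolated when
#' only plot coordinates (not patient-level data) are available.
#'
#' @param curve A [km_curve()].
#' @param family One of `surv_families()`.
#' @return A `parametric_fit`: list with `distribution`, `ssr`, `aic`, `bic`,
#'   `n_points`, `k_params`, `family`, `degenerate`.
#' @export
fit_parametric <- function(curve, family) {
  stopifnot(inherits(curve, "km_curve"))
  family <- match.arg(family, surv_families())
  k <- length(.family_params[[family]])
  n <- nrow(curve)
  if (n < k + 1) {
    stop(sprintf("need at least %d points to fit family '%s'", k + 1, family),
         call. = FALSE)
  }
  degenerate <- diff(range(curve$survival)) < 1e-12
  if (degenerate) {
    warning(sprintf(
      "degenerate curve (all survival values equal); family '%s' fit pushed to the rate->0 boundary",
      family))
  }
  obj <- function(theta) {
    p <- .untransform(family, theta)
    d <- try(do.call(surv_dist, c(list(family), p)), silent = TRUE)
    if (inherits(d, "try-error")) return(1e10)
    r <- curve$survival - survival_at(d, curve$time)
    v <- sum(r * r)
    if (!is.finite(v)) 1e10 else v
  }
  med <- .km_median_guess(curve)
  best <- NULL
  for (start in .fit_starts(family, med)) {
    theta0 <- .transform(family, start)
    opt <- try(
      if (length(theta0) == 1) {
        stats::optim(theta0, obj, method = "Brent",
                     lower = theta0 - 15, upper = theta0 + 15,
                     control = list(maxit = 2000))
      } else {
        stats::optim(theta0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
      },
      silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10) {
    stop(sprintf("fitting family '%s' failed to converge from all starts",
                 family), call. = FALSE)
  }
  params <- .untransform(family, best$par)
  dist <- do.call(surv_dist, c(list(family), params))
  ssr <- best$value
  ic <- suppressWarnings(information_criteria(max(ssr, .Machine$double.xmin),
                                              n, k))
  structure(
    list(distribution = dist, family = family, params = params,
         ssr = ssr, aic = ic[["aic"]], bic = ic[["bic"]],
         n_points = n, k_params = k, degenerate = degenerate),
    class = "parametric_fit"
  )
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("<parametric_fit %s: ssr=%.4g aic=%.4g bic=%.4g (n=%d)>\n",
              x$family, x$ssr, x$aic, x$bic, x$n_points))
  invisible(x)
}

#' Fit all five families to one curve
#'
#' @param curve A [km_curve()].
#' @param families Families to fit (default all).
#' @return Named list of `parametric_fit` objects.
#' @export
fit_all_families <- function(curve, families = surv_families()) {
  stats::setNames(lapply(families, function(f) fit_parametric(curve, f)),
                  families)
}

.fits_to_table <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("family", "ssr", "aic", "bic") %in% names(fits)))
    return(fits)
  }
  do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$family, ssr = f$ssr, aic = f$aic, bic = f$bic)
  }))
}

#' Select the best-fitting family
#'
#' Ranks candidate fits by SSR, with AIC then BIC as tie-breakers and the
#' fixed family order of `surv_families()` as the final deterministic
#' tie-break. If the winner's long-run hazard vanishes (log-logistic,
#' lognormal) and the curve is an overall-survival endpoint, a plausibility
#' warning is raised: a hazard that decays to zero is inconsistent with a
#' palliative setting.
#'
#' @param fits A list of `parametric_fit`s or a data.frame with columns
#'   `family`, `ssr`, `aic`, `bic`.
#' @param endpoint Optional endpoint context, `"OS"` or `"PFS"`.
#' @return List with `family` (the winner), `ranking` (full ordered table
#'   with rank column), and `hazard_flag` (logical).
#' @export
select_best <- function(fits, endpoint = NA_character_) {
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  tab <- .fits_to_table(fits)
  if (is.null(tab) || nrow(tab) == 0) stop("no fits supplied", call. = FALSE)
  tab$family_order <- match(tab$family, surv_families())
  ord <- order(tab$ssr, tab$aic, tab$bic, tab$family_order)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  winner <- tab$family[1]
  flag <- hazard_vanishes(winner)
  if (flag && identical(toupper(endpoint), "OS")) {
    warning(sprintf(
      "selected family '%s' has a hazard that decreases towards 0 at long times; implausible for an overall-survival endpoint in a palliative setting",
      winner))
  }
  list(family = winner, ranking = tab[, c("rank", "family", "ssr", "aic", "bic")],
       hazard_flag = flag)
}

#' Per-cycle transition probability from a survival distribution
#'
#' Conditional-survival conversion: the probability of leaving the state
#' during cycle `i` (spanning `[i*delta, (i+1)*delta)`) given survival to its
#' start, `p = 1 - S(t + delta) / S(t)`.
#'
#' @param dist A [surv_dist()].
#' @param cycle_index Non-negative integer cycle index, vectorized.
#' @param cycle_length Cycle length in months (> 0).
#' @return Probabilities in `[0, 1]`. When `S(t)` underflows to 0 the
#'   probability is 1 (with a message).
#' @export
cycle_transition_prob <- function(dist, cycle_index, cycle_length = 1) {
  stopifnot(cycle_length > 0, all(cycle_index >= 0))
  t0 <- cycle_index * cycle_length
  s0 <- survival_at(dist, t0)
  s1 <- survival_at(dist, t0 + cycle_length)
  p <- ifelse(s0 <= 0, 1, 1 - s1 / s0)
  if (any(s0 <= 0)) {
    message("survival underflow at cycle start; transition probability set to 1")
  }
  pmin(pmax(p, 0), 1)
}
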