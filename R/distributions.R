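#' @keywords internal
"_PACKAGE"

## Parameterizations (conventional survival-analysis forms):
##   exponential  S(t) = exp(-rate * t)
##   weibull      S(t) = exp(-(t/scale)^shape)
##   gompertz     S(t) = exp((rate/shape) * (1 - exp(shape * t)))
##   loglogistic  S(t) = 1 / (1 + (t/scale)^shape)
##   lognormal    S(t) = 1 - pnorm((log t - meanlog)/sdlog)

#' Supported parametric survival families
#'
#' Family names in the fixed reporting/tie-break order.
#'
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal")
}

.family_params <- list(
  exponential = "rate",
  weibull     = c("scale", "shape"),
  gompertz    = c("shape", "rate"),
  loglogistic = c("scale", "shape"),
  lognormal   = c("meanlog", "sdlog")
)

#' Construct a parametric survival distribution
#'
#' Time is measured in months throughout. All scale/rate/shape parameters must
#' be strictly positive; a Gompertz shape `a <= 0` is rejected because the
#' resulting survival function does not vanish as t grows, which is
#' incompatible with a palliative lifetime-horizon model. The lognormal
#' `meanlog` may be any real number.
#'
#' @param family One of `surv_families()`.
#' @param ... Named parameters for the family: `rate` (exponential);
#'   `scale`, `shape` (weibull, loglogistic); `shape`, `rate` (gompertz);
#'   `meanlog`, `sdlog` (lognormal).
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("weibull", scale = 13.52, shape = 1.3)
#' survival_at(d, 10.2)
#' @export
surv_dist <- function(family, ...) {
  family <- match.arg(family, surv_families())
  params <- list(...)
  wanted <- .family_params[[family]]
  if (!setequal(names(params), wanted)) {
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(wanted, collapse = ", ")), call. = FALSE)
  }
  params <- lapply(params[wanted], as.numeric)
  if (any(!vapply(params, is.finite, logical(1)))) {
    stop("distribution parameters must be finite", call. = FALSE)
  }
  positive <- setdiff(wanted, "meanlog")
  for (p in positive) {
    if (params[[p]] <= 0) {
      stop(sprintf("parameter '%s' of family '%s' must be > 0", p, family),
           call. = FALSE)
    }
  }
  structure(list(family = family, params = params), class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat(sprintf("<surv_dist %s: %s>\n", x$family,
              paste(sprintf("%s=%.6g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

stopifnot_surv_dist <- function(dist) {
  if (!inherits(dist, "surv_dist")) {
    stop("expected a 'surv_dist' object", call. = FALSE)
  }
}

#' Survival function S(t)
#'
#' @param dist A [surv_dist()] object.
#' @param t Time in months, vectorized, all `>= 0`.
#' @return Survival probabilities in `[0, 1]`; `S(0) = 1` for every family.
#' @export
survival_at <- function(dist, t) {
  stopifnot_surv_dist(dist)
  t <- as.numeric(t)
  if (any(is.na(t)) || any(t < 0)) {
    stop("t must be non-negative", call. = FALSE)
  }
  p <- dist$params
  s <- switch(dist$family,
    exponential = exp(-p$rate * t),
    weibull     = exp(-(t / p$scale)^p$shape),
    gompertz    = exp((p$rate / p$shape) * (1 - exp(p$shape * t))),
    loglogistic = 1 / (1 + (t / p$scale)^p$shape),
    lognormal   = stats::pnorm((log(t) - p$meanlog) / p$sdlog,
                               lower.tail = FALSE)
  )
  ## t = 0 with a fractional power can produce NaN only through 0^0; guard.
  s[t == 0] <- 1
  pmin(pmax(s, 0), 1)
}

#' Inverse survival function
#'
#' Returns the time `t` at which `S(t) = s`. Used for inverse-CDF sampling
#' (with `s` uniform on (0,1)) and for medians.
#'
#' @param dist A [surv_dist()] object.
#' @param s Survival probabilities in (0, 1], vectorized.
#' @return Times in months.
#' @export
surv_inverse <- function(dist, s) {
  stopifnot_surv_dist(dist)
  s <- as.numeric(s)
  if (any(is.na(s)) || any(s <= 0) || any(s > 1)) {
    stop("s must be in (0, 1]", call. = FALSE)
  }
  p <- dist$params
  switch(dist$family,
    exponential = -log(s) / p$rate,
    weibull     = p$scale * (-log(s))^(1 / p$shape),
    gompertz    = log(1 - (p$shape / p$rate) * log(s)) / p$shape,
    loglogistic = p$scale * ((1 - s) / s)^(1 / p$shape),
    lognormal   = exp(p$meanlog + p$sdlog * stats::qnorm(1 - s))
  )
}

#' Median survival time
#'
#' @param dist A [surv_dist()] object.
#' @return Median time in months (`S(median) = 0.5`).
#' @export
median_surv <- function(dist) {
  surv_inverse(dist, 0.5)
}

#' Weibull distribution matched to a printed median
#'
#' Solves `S(median) = 0.5` for the scale at a given shape:
#' `scale = median / log(2)^(1/shape)`.
#'
#' @param median Median survival in months.
#' @param shape Weibull shape parameter (> 0).
#' @return A Weibull [surv_dist()].
#' @export
weibull_from_median <- function(median, shape = 1.3) {
  stopifnot(median > 0, shape > 0)
  surv_dist("weibull", scale = median / log(2)^(1 / shape), shape = shape)
}

#' Does the family's hazard vanish at long times?
#'
#' Log-logistic and lognormal hazards tend to zero as t grows; for an overall
#' survival endpoint in a palliative setting this implies an implausible
#' near-immortal extrapolated tail, so model selection flags these families.
#'
#' @param family A family name.
#' @return Logical.
#' @export
hazard_vanishes <- function(family) {
  family <- match.arg(family, surv_families())
  family %in% c("loglogistic", "lognormal")
}
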