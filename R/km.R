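#' Kaplan-Meier curve container
#'
#' An ordered set of (time, survival) points for one endpoint/arm, as obtained
#' by digitizing a published Kaplan-Meier plot or from [kaplan_meier()].
#'
#' @param time Times in months, strictly increasing, all `>= 0`.
#' @param survival Survival probabilities in `[0, 1]`, non-increasing.
#' @param endpoint `"PFS"` or `"OS"` (optional context, used by
#'   [select_best()]'s hazard-plausibility flag).
#' @param arm Arm label, e.g. `"cabozantinib"` or `"BSC"`.
#' @return An object of class `km_curve` (a data.frame with attributes).
#' @export
km_curve <- function(time, survival, endpoint = NA_character_,
                     arm = NA_character_) {
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  if (length(time) != length(survival) || length(time) == 0) {
    stop("time and survival must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(is.na(time)) || any(is.na(survival))) {
    stop("km_curve points must be non-missing", call. = FALSE)
  }
  if (any(time < 0) || any(diff(time) <= 0)) {
    stop("time must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(survival < 0) || any(survival > 1)) {
    stop("survival must be in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    stop("survival must be non-increasing", call. = FALSE)
  }
  structure(
    data.frame(time = time, survival = survival),
    endpoint = endpoint, arm = arm,
    class = c("km_curve", "data.frame")
  )
}

#' Evaluate a KM step function
#'
#' The product-limit estimate is a right-continuous step function equal to 1
#' before the first tabulated time.
#'
#' @param curve A [km_curve()].
#' @param time Times at which to evaluate, vectorized.
#' @return Survival probabilities.
#' @export
km_at <- function(curve, time) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(as.numeric(time), function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Resample a KM curve on a regular grid
#'
#' Digitization emulation: reads the step function at the given times
#' (default: monthly points to month 24, the approximate published follow-up
#' span). Duplicate leading 1s are kept; strictly-increasing time is enforced
#' by the grid itself.
#'
#' @param curve A [km_curve()].
#' @param times Grid times in months.
#' @return A [km_curve()] on the grid, inheriting endpoint/arm.
#' @export
km_on_grid <- function(curve, times = 1:24) {
  km_curve(times, km_at(curve, times),
           endpoint = attr(curve, "endpoint"), arm = attr(curve, "arm"))
}
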