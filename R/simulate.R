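## Synthetic survival data: simulated censored cohorts and their Kaplan-Meier
## estimates, standing in for the published trial curves so every downstream
## stage is testable offline.

#' Simulate a censored survival cohort
#'
#' Event times are drawn by inverse-CDF sampling from the given parametric
#' distribution. Censoring combines administrative censoring at
#' `max_followup` with independent Uniform(0, C) random censoring, where C is
#' calibrated by bisection on the drawn sample so that the realized censoring
#' fraction matches `censor_rate`.
#'
#' @param dist A [surv_dist()] generating event times (months).
#' @param n Number of subjects (>= 10).
#' @param censor_rate Target fraction censored, in `[0, 1)`.
#' @param max_followup Administrative censoring time in months (may be `Inf`).
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#' @return A `simulated_cohort`: data.frame with columns `time`, `event`
#'   (logical) and attributes `dist`, `censor_rate`, `seed`.
#' @export
simulate_survival <- function(dist, n, censor_rate = 0, max_followup = Inf,
                              seed = NULL) {
  stopifnot_surv_dist(dist)
  stopifnot(n >= 10, censor_rate >= 0, censor_rate < 1, max_followup > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  event_time <- surv_inverse(dist, u)
  v <- stats::runif(n)  # drawn unconditionally to keep the stream stable

  if (censor_rate == 0) {
    time <- pmin(event_time, max_followup)
    event <- event_time <= max_followup
  } else {
    frac_cens <- function(C) mean(pmin(v * C, max_followup) < event_time)
    ## administrative censoring alone may already exceed the target
    if (frac_cens(Inf) >= censor_rate) {
      warning("administrative censoring alone meets or exceeds the target censor rate")
      C <- Inf
    } else {
      lo <- 1e-6
      hi <- max(event_time) * 2 + 1
      while (frac_cens(hi) > censor_rate) hi <- hi * 2
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (frac_cens(mid) > censor_rate) lo <- mid else hi <- mid
      }
      C <- hi
    }
    cens_time <- pmin(v * C, max_followup)
    time <- pmin(event_time, cens_time)
    event <- event_time <= cens_time
  }
  structure(
    data.frame(time = time, event = event),
    dist = dist, censor_rate = censor_rate, seed = seed,
    class = c("simulated_cohort", "data.frame")
  )
}

#' Kaplan-Meier estimate of a simulated cohort
#'
#' Product-limit estimate via [survival::survfit()], reduced to the event
#' times (the points where the step function drops).
#'
#' @param cohort A `simulated_cohort` (or any data.frame with `time`, `event`).
#' @param endpoint,arm Optional labels carried onto the returned curve.
#' @return A [km_curve()].
#' @export
kaplan_meier <- function(cohort, endpoint = NA_character_,
                         arm = NA_character_) {
  stopifnot(all(c("time", "event") %in% names(cohort)))
  if (!any(cohort$event)) stop("cohort has no events", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(cohort))
  keep <- fit$n.event > 0
  km_curve(fit$time[keep], fit$surv[keep], endpoint = endpoint, arm = arm)
}
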