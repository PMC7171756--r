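## Tabular IO: digitized KM points, cost tables, fit reports, trace exports
## and the structured run configuration. All CSV is headered with dot
## decimals.

#' Read digitized Kaplan-Meier points
#'
#' Expects columns `endpoint, arm, time_months, survival`.
#'
#' @param path CSV path.
#' @return Named list of [km_curve()]s, one per `endpoint.arm` combination.
#' @export
read_km_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("endpoint", "arm", "time_months", "survival")
  if (!all(need %in% names(df))) {
    stop(sprintf("KM CSV '%s' must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop("KM CSV is empty: ", path, call. = FALSE)
  parts <- split(df, interaction(df$endpoint, df$arm, drop = TRUE))
  lapply(parts, function(p) {
    p <- p[order(p$time_months), ]
    km_curve(p$time_months, p$survival,
             endpoint = p$endpoint[1], arm = p$arm[1])
  })
}

#' Write KM curves to CSV
#'
#' @param curves List of [km_curve()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(endpoint = attr(cv, "endpoint"), arm = attr(cv, "arm"),
               time_months = cv$time, survival = cv$survival)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-item cost table
#'
#' Expects columns `country, arm, category, item, cost_first,
#' cost_subsequent`; items are summed within category.
#'
#' @param path CSV path.
#' @return data.frame `country, arm, category, cost_first, cost_subsequent`.
#' @export
read_cost_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "arm", "category", "item", "cost_first",
            "cost_subsequent")
  if (!all(need %in% names(df))) {
    stop(sprintf("cost CSV '%s' must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(df$cost_first < 0) || any(df$cost_subsequent < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  agg <- stats::aggregate(cbind(cost_first, cost_subsequent) ~
                            country + arm + category, data = df, FUN = sum)
  agg[order(agg$country, agg$arm, agg$category), ]
}

#' Write a fit report
#'
#' One row per (curve, family) with SSR, AIC, BIC and the parameters
#' serialized as `name=value;...`.
#'
#' @param fits Named list (per curve) of lists of `parametric_fit`s.
#' @param path Output CSV path.
#' @return The report data.frame, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  rows <- do.call(rbind, lapply(names(fits), function(curve_id) {
    do.call(rbind, lapply(fits[[curve_id]], function(f) {
      data.frame(
        curve = curve_id, family = f$family,
        ssr = f$ssr, aic = f$aic, bic = f$bic, n_points = f$n_points,
        params = paste(sprintf("%s=%.10g", names(f$params),
                               unlist(f$params)), collapse = ";")
      )
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Export a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(trace$trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a structured run configuration
#'
#' YAML with optional blocks `model` (horizon_cycles, cycle_length,
#' annual_discount_rate, half_cycle_correction), `utilities` (stable,
#' progressive) and `fixture` (weibull shape). Missing entries fall back to
#' package defaults.
#'
#' @param path YAML path.
#' @return List with `settings` (a [model_settings()]), `utilities`,
#'   and the raw parsed config under `raw`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- cfg$model %||% list()
  settings <- model_settings(
    horizon_cycles = m$horizon_cycles %||% 84,
    cycle_length = m$cycle_length %||% 1,
    annual_discount_rate = m$annual_discount_rate %||% 0.03,
    half_cycle_correction = m$half_cycle_correction %||% FALSE
  )
  u <- cfg$utilities %||% list()
  utilities <- c(stable = u$stable %||% 0.76,
                 progressive = u$progressive %||% 0.68)
  list(settings = settings, utilities = utilities, raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
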