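# Independent oracles used across the suite.

# Hand product-limit estimator: survival at each distinct event time.
pl_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# Brute-force SSR minimum over a 50x50 parameter grid (Weibull).
grid_ssr_weibull <- function(curve, n_grid = 50) {
  med <- max(curve$time[which(curve$survival <= 0.5)[1]], 1, na.rm = TRUE)
  scales <- exp(seq(log(med * 0.2), log(med * 5), length.out = n_grid))
  shapes <- exp(seq(log(0.4), log(4), length.out = n_grid))
  best <- Inf
  for (sc in scales) {
    for (sh in shapes) {
      s_hat <- exp(-(curve$time / sc)^sh)
      ssr <- sum((curve$survival - s_hat)^2)
      if (ssr < best) best <- ssr
    }
  }
  best
}

# Random noisy survival curve (Weibull truth + noise, projected onto the
# KM-curve invariants).
random_curve <- function(seed) {
  set.seed(seed)
  sh <- runif(1, 0.7, 2.5)
  sc <- runif(1, 4, 15)
  t <- 1:24
  s <- exp(-(t / sc)^sh) + rnorm(24, 0, 0.015)
  s <- pmin(pmax(s, 0), 1)
  s <- rev(cummax(rev(s)))  # enforce non-increasing
  km_curve(t, s)
}

fixture_totals <- function(country, arm) {
  fx <- celestial_fixture()
  run_cohort(strategy_from_fixture(fx, country, arm))$totals
}
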