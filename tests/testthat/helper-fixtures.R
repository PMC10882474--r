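# Shared fixtures: tiny cohorts and a minimal signal bundle, built in code.

tiny_cohort_config <- function(...) {
  defaults <- list(n_participants = 1L, n_days = 1L, prompts_per_day = 6L,
                   eda_hz = 4, accel_hz = 16, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# A deterministic signal bundle spanning `minutes` minutes.
toy_bundle <- function(minutes = 10, eda_hz = 4, temp_hz = 1, accel_hz = 16,
                       rr_ms = 800) {
  beat_t <- seq(0, minutes * 60, by = rr_ms / 1000)
  rr <- tibble::tibble(time_s = beat_t, rr_ms = rr_ms)
  mk <- function(hz, value) tibble::tibble(
    time_s = (seq_len(minutes * 60 * hz + 1) - 1) / hz, value = value)
  structure(list(
    participant_id = 1L,
    rr = rr,
    eda = mk(eda_hz, 2),
    temperature = mk(temp_hz, 33),
    accel = mk(accel_hz, 1),
    rates = list(eda_hz = eda_hz, temp_hz = temp_hz, accel_hz = accel_hz)
  ), class = "signal_bundle")
}

# Independent brute-force evaluators used as oracles against the package
# implementations (kept deliberately naive).
oracle_rmssd <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  sqrt(sum(d^2) / length(d))
}

oracle_kappa <- function(a, b) {
  lev <- union(unique(a), unique(b))
  po <- mean(a == b)
  pe <- 0
  for (l in lev) pe <- pe + mean(a == l) * mean(b == l)
  (po - pe) / (1 - pe)
}

oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

oracle_oneway_f <- function(y, g) {
  g <- factor(g)
  n <- length(y); k <- nlevels(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}
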