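# RR-interval validation and heart-rate-variability features.

#' Validate an RR-interval series
#'
#' Two-stage artifact rejection: (1) beats outside the physiologic band are
#' dropped; (2) a beat is dropped when its absolute difference from the
#' running median of the last 5 accepted beats exceeds the criterion beat
#' difference `max(expected_frac * running_median, min_artifact_ms)`.
#' Ordering is preserved; the rule is idempotent on its own output.
#'
#' @param rr_ms Numeric vector of RR intervals, ms.
#' @param band Physiologic band, ms (default 300-2000).
#' @param expected_frac Maximum expected beat-to-beat change as a fraction
#'   of the running median (default 0.2).
#' @param min_artifact_ms Minimal artifact difference, ms (default 50).
#' @return Logical vector marking accepted beats (same length as `rr_ms`).
#' @export
validate_rr <- function(rr_ms, band = c(300, 2000), expected_frac = 0.2,
                        min_artifact_ms = 50) {
  if (length(rr_ms) == 0) abort("Empty RR series.")
  .validate_rr_cpp(as.numeric(rr_ms), band[1], band[2], expected_frac,
                   min_artifact_ms)
}

hrv_time_names <- c("mean", "median", "mode", "min", "range", "rms",
                    "zero_cross", "kurtosis", "skew", "q25", "q75",
                    "rmssd", "sdnn", "cvsd", "cvnni",
                    "nni50", "nni20", "pnni50", "pnni20")

#' Time-domain heart-rate-variability features
#'
#' Statistical block (mean, median, mode, minimum, range, RMS, zero-cross
#' about the window mean, kurtosis, skew, 25th/75th percentiles) plus RMSSD
#' (root mean square of successive differences), SDNN (SD of intervals),
#' their coefficients of variation CVSD = RMSSD/mean and CVNNI = SDNN/mean,
#' and the NNI50/NNI20 counts and PNNI50/PNNI20 percentages of successive
#' differences exceeding 50/20 ms.
#'
#' @param rr_ms Validated RR intervals, ms.
#' @param min_beats Minimum beats required (default 3); fewer yields
#'   missing markers.
#' @return Named numeric vector of the 19 features.
#' @export
hrv_time_features <- function(rr_ms, min_beats = 3L) {
  rr_ms <- rr_ms[!is.na(rr_ms)]
  if (length(rr_ms) < min_beats) return(na_features(hrv_time_names))
  d <- diff(rr_ms)
  rmssd <- sqrt(mean(d^2))
  sdnn <- sd(rr_ms)
  c(stat_block(rr_ms),
    rmssd = rmssd,
    sdnn = sdnn,
    cvsd = rmssd / mean(rr_ms),
    cvnni = sdnn / mean(rr_ms),
    nni50 = sum(abs(d) > 50),
    nni20 = sum(abs(d) > 20),
    pnni50 = 100 * sum(abs(d) > 50) / length(d),
    pnni20 = 100 * sum(abs(d) > 20) / length(d))
}

# Classic Lomb-Scargle periodogram of an unevenly sampled series.
# Returns power at each frequency (Hz); unnormalised (variance units).
lomb_power <- function(t, x, freqs) {
  x <- x - mean(x)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
}

hrv_freq_names <- c("vlf", "lf", "hf", "hf_lf_ratio")

#' Frequency-domain heart-rate-variability features
#'
#' Band powers of the RR tachogram in the very-low (0.003-0.04 Hz), low
#' (0.04-0.15 Hz) and high (0.15-0.40 Hz) frequency bands, plus the HF/LF
#' ratio. Computed with a Lomb-Scargle periodogram on the unevenly sampled
#' beat times, avoiding resampling artifacts on short windows. A band whose
#' lowest frequency has period longer than the window is reported missing.
#'
#' @param beat_time_s Beat times, seconds.
#' @param rr_ms RR intervals at those beats, ms.
#' @param bands Named list of band edges, Hz.
#' @param oversample Frequency-grid oversampling factor.
#' @return Named numeric vector `vlf`, `lf`, `hf`, `hf_lf_ratio` (ms^2).
#' @export
hrv_freq_features <- function(beat_time_s, rr_ms,
                              bands = list(vlf = c(0.003, 0.04),
                                           lf = c(0.04, 0.15),
                                           hf = c(0.15, 0.40)),
                              oversample = 2) {
  ok <- !is.na(rr_ms)
  beat_time_s <- beat_time_s[ok]; rr_ms <- rr_ms[ok]
  out <- na_features(hrv_freq_names)
  if (length(rr_ms) < 4) return(out)
  T_span <- diff(range(beat_time_s))
  if (T_span <= 0 || sd(rr_ms) == 0) {
    out[c("vlf", "lf", "hf")] <- 0; out["hf_lf_ratio"] <- NA_real_
    return(out)
  }
  df <- 1 / (oversample * T_span)
  fmax <- max(vapply(bands, max, numeric(1)))
  freqs <- seq(df, fmax, by = df)
  p <- lomb_power(beat_time_s, rr_ms, freqs)
  for (b in names(bands)) {
    if (1 / bands[[b]][1] > T_span) next  # band unresolvable in this window
    sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
    out[b] <- sum(p[sel]) * df
  }
  out["hf_lf_ratio"] <- if (!is.na(out["lf"]) && out["lf"] > 0)
    out["hf"] / out["lf"] else NA_real_
  out
}
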