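# Windowed feature extraction over a signal bundle: evaluates the battery
# on arbitrary (lookback) windows ending at given times, with stable
# column names `<signal>_<feature>_<lookback>`.

lookback_label <- function(minutes) {
  ifelse(minutes <= 1, "momentary", paste0(minutes, "min"))
}

#' Names of the feature battery
#'
#' @param battery Subset of `c("hrv_time", "hrv_freq", "temp", "eda",
#'   "accel")`.
#' @param lookback_minutes Lookbacks used, minutes (1 = momentary).
#' @return Character vector of column names, stable across calls.
#' @export
feature_battery_names <- function(battery = c("hrv_time", "temp", "eda", "accel"),
                                  lookback_minutes = c(1, 5, 30, 60)) {
  base <- c(
    if ("hrv_time" %in% battery) paste0("ecg_", hrv_time_names),
    if ("hrv_freq" %in% battery) paste0("ecg_", hrv_freq_names),
    if ("temp" %in% battery) paste0("temp_", temp_names),
    if ("eda" %in% battery) paste0("eda_", eda_names),
    if ("accel" %in% battery) paste0("acc_", accel_names)
  )
  as.vector(t(outer(lookback_label(lookback_minutes), base,
                    function(l, b) paste(b, l, sep = "_"))))
}

#' Extract the feature battery on windows of a signal bundle
#'
#' For every window end time and every lookback, evaluates the configured
#' battery on the window `[end - lookback, end]`. Windows that start before
#' the stream begins yield missing markers for that lookback. The
#' accelerometer stream is low-pass filtered once over its whole span
#' (filtering is linear, so this equals per-window filtering away from the
#' window edges) and the RR stream is artifact-validated once.
#'
#' @param bundle A `signal_bundle`.
#' @param end_s Vector of window end times, seconds.
#' @param lookback_minutes Lookbacks, minutes; 1 is the momentary window.
#' @param battery Feature families to compute.
#' @param accel_cutoff_hz,accel_threshold,eda_lowpass_hz,rr_band Tuning of
#'   the underlying extractors.
#' @return Tibble: `end_s` plus one column per battery feature per lookback.
#' @export
extract_features <- function(bundle, end_s,
                             lookback_minutes = c(1, 5, 30, 60),
                             battery = c("hrv_time", "temp", "eda", "accel"),
                             accel_cutoff_hz = 10, accel_threshold = 0.1,
                             eda_lowpass_hz = 1, rr_band = c(300, 2000)) {
  cols <- feature_battery_names(battery, lookback_minutes)
  out <- matrix(NA_real_, length(end_s), length(cols),
                dimnames = list(NULL, cols))

  use_rr <- any(c("hrv_time", "hrv_freq") %in% battery)
  if (use_rr) {
    keep <- validate_rr(bundle$rr$rr_ms, band = rr_band)
    rr_t <- bundle$rr$time_s[keep]; rr_v <- bundle$rr$rr_ms[keep]
  }
  if ("eda" %in% battery) {
    eda_t <- bundle$eda$time_s; eda_v <- bundle$eda$value
    eda_hz <- bundle$rates$eda_hz
    eda_f <- if (eda_hz > 2 * eda_lowpass_hz) {
      bf <- signal::butter(4, eda_lowpass_hz / (eda_hz / 2), type = "low")
      filtfilt_padded(bf, eda_v)
    } else eda_v
  }
  if ("temp" %in% battery) {
    tm_t <- bundle$temperature$time_s; tm_v <- bundle$temperature$value
  }
  if ("accel" %in% battery) {
    ac_t <- bundle$accel$time_s
    ac_hz <- bundle$rates$accel_hz
    ac_f <- accel_filter(bundle$accel$value, ac_hz, accel_cutoff_hz)
  }
  t0 <- min(c(if (use_rr) rr_t[1], if ("eda" %in% battery) eda_t[1],
              if ("temp" %in% battery) tm_t[1],
              if ("accel" %in% battery) ac_t[1]), na.rm = TRUE)

  for (li in seq_along(lookback_minutes)) {
    lab <- lookback_label(lookback_minutes[li])
    span <- lookback_minutes[li] * 60
    # integer column indices for this lookback (string lookups are too
    # slow inside the window loop)
    ci_hrv <- match(paste0("ecg_", hrv_time_names, "_", lab), cols)
    ci_frq <- match(paste0("ecg_", hrv_freq_names, "_", lab), cols)
    ci_tmp <- match(paste0("temp_", temp_names, "_", lab), cols)
    ci_eda <- match(paste0("eda_", eda_names, "_", lab), cols)
    ci_acc <- match(paste0("acc_", accel_names, "_", lab), cols)
    los <- end_s - span
    if (use_rr) {
      r1 <- findInterval(los, rr_t, left.open = TRUE) + 1L
      r2 <- findInterval(end_s, rr_t)
    }
    if ("temp" %in% battery) {
      m1 <- findInterval(los, tm_t, left.open = TRUE) + 1L
      m2 <- findInterval(end_s, tm_t)
    }
    if ("eda" %in% battery) {
      e1 <- findInterval(los, eda_t, left.open = TRUE) + 1L
      e2 <- findInterval(end_s, eda_t)
    }
    if ("accel" %in% battery) {
      a1 <- findInterval(los, ac_t, left.open = TRUE) + 1L
      a2 <- findInterval(end_s, ac_t)
    }
    for (wi in seq_along(end_s)) {
      if (los[wi] < t0 - 1e-9) next  # insufficient history
      if (use_rr) {
        if ("hrv_time" %in% battery) {
          out[wi, ci_hrv] <- hrv_time_features(
            if (r2[wi] >= r1[wi]) rr_v[r1[wi]:r2[wi]] else numeric(0))
        }
        if ("hrv_freq" %in% battery) {
          out[wi, ci_frq] <- if (r2[wi] >= r1[wi])
            hrv_freq_features(rr_t[r1[wi]:r2[wi]], rr_v[r1[wi]:r2[wi]])
          else na_features(hrv_freq_names)
        }
      }
      if ("temp" %in% battery) {
        out[wi, ci_tmp] <- temp_features(
          if (m2[wi] >= m1[wi]) tm_v[m1[wi]:m2[wi]] else numeric(0))
      }
      if ("eda" %in% battery) {
        out[wi, ci_eda] <- if (e2[wi] >= e1[wi]) {
          eda_features(eda_v[e1[wi]:e2[wi]], hz = eda_hz,
                       lowpass_hz = eda_lowpass_hz,
                       xf = eda_f[e1[wi]:e2[wi]])
        } else {
          eda_features(numeric(0), hz = eda_hz)
        }
      }
      if ("accel" %in% battery) {
        xw <- if (a2[wi] >= a1[wi]) ac_f[a1[wi]:a2[wi]] else numeric(0)
        out[wi, ci_acc] <- if (length(xw))
          c(mean(xw), count_steps(xw, ac_hz, accel_threshold))
        else na_features(accel_names)
      }
    }
  }
  dplyr::bind_cols(tibble::tibble(end_s = end_s), tibble::as_tibble(out))
}
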