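# Skin-temperature, electrodermal and accelerometer feature extraction.

temp_names <- c("mean", "median", "mode", "min", "range", "rms",
                "zero_cross", "kurtosis", "skew", "q25", "q75")

#' Skin-temperature features
#'
#' IQR-based outlier removal (values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' are dropped) followed by the statistical block: mean, median, mode,
#' minimum, range, RMS, zero-cross about the cleaned-window mean, kurtosis,
#' skew and 25th/75th percentiles.
#'
#' @param x Temperature samples in the window, degrees C.
#' @param include_max Also report the maximum (off by default to keep the
#'   battery's printed feature list).
#' @return Named numeric vector.
#' @export
temp_features <- function(x, include_max = FALSE) {
  x <- x[!is.na(x)]
  nms <- if (include_max) c(temp_names, "max") else temp_names
  if (length(x) == 0) return(na_features(nms))
  q <- sorted_quantile(sort.int(x, method = "quick"), c(0.25, 0.75))
  iqr <- q[2] - q[1]
  x <- x[x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr]
  if (length(x) == 0) return(na_features(nms))
  stat_block(x, include_max = include_max)
}

# Zero-phase filtering with reflection padding to suppress the edge
# transients filtfilt otherwise leaves on short windows.
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * max(length(filt$b), length(filt$a)) * 4L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  as.numeric(signal::filtfilt(filt, xp))[(pad + 1L):(pad + n)]
}

# 1-level Haar approximation at a block scale: means of consecutive
# non-overlapping blocks of `n` samples (trailing partial block dropped).
haar_block_means <- function(x, n) {
  n <- max(1L, as.integer(n))
  k <- length(x) %/% n
  if (k < 1L) return(numeric(0))
  colMeans(matrix(x[seq_len(k * n)], nrow = n))
}

wavelet_stats <- function(g) {
  if (length(g) == 0) {
    return(c(max = NA_real_, mean = NA_real_, sd = NA_real_,
             median = NA_real_, above_zero = NA_real_))
  }
  c(max = max(g), mean = mean(g),
    sd = if (length(g) > 1) sd(g) else 0,
    median = median(g), above_zero = mean(g > 0))
}

eda_names <- local({
  wav <- as.vector(outer(
    c("wav1s_d1", "wav1s_d2", "wavhalf_d1", "wavhalf_d2"),
    c("max", "mean", "sd", "median", "above_zero"), paste, sep = "_"))
  c("raw_amplitude", "raw_max", "raw_min", "raw_mean",
    "filt_amplitude", "filt_max", "filt_min", "filt_mean", sort(wav))
})

#' Electrodermal-activity features
#'
#' Three blocks: raw statistics (amplitude = mean level, max, min, mean);
#' the same statistics after zero-phase low-pass smoothing (4th-order
#' Butterworth, default 1 Hz cutoff); and block-wavelet statistics. For the
#' wavelet block the signal is reduced to Haar approximations (block means)
#' at 1-second and half-second scales; the first and second differences of
#' each approximation series — the Haar detail coefficients at the doubled
#' scale, up to scaling — are summarised by max, mean, SD, median and the
#' fraction above zero.
#'
#' @param x EDA samples in the window, microsiemens.
#' @param hz Sampling rate, Hz (required).
#' @param lowpass_hz Smoothing cutoff for the "filtered" block.
#' @param filt Optional precomputed `signal::butter` filter for the
#'   smoothing step (a per-stream cache used by [extract_features()]).
#' @param xf Optional pre-filtered window (same length as `x`); smoothing
#'   is linear and time-invariant, so callers that filter the whole stream
#'   once can pass the window of the filtered stream instead of paying for
#'   a per-window filter run.
#' @return Named numeric vector of 28 features.
#' @export
eda_features <- function(x, hz, lowpass_hz = 1, filt = NULL, xf = NULL) {
  if (missing(hz) || is.null(hz) || is.na(hz)) abort("EDA sampling rate required.")
  x <- x[!is.na(x)]
  if (length(x) == 0) return(na_features(eda_names))
  raw <- c(raw_amplitude = mean(x), raw_max = max(x), raw_min = min(x),
           raw_mean = mean(x))
  if (is.null(xf)) {
    xf <- if (hz > 2 * lowpass_hz && length(x) > 12) {
      if (is.null(filt)) filt <- signal::butter(4, lowpass_hz / (hz / 2),
                                                type = "low")
      filtfilt_padded(filt, x)
    } else x  # rate too low for the stated cutoff; smoothing is a no-op
  }
  filt_stats <- c(filt_amplitude = mean(xf), filt_max = max(xf),
                  filt_min = min(xf), filt_mean = mean(xf))
  wav <- numeric(0)
  for (nm in c("wav1s", "wavhalf")) {
    blk <- if (nm == "wav1s") 1 else 0.5
    a <- haar_block_means(x, round(hz * blk))
    d1 <- diff(a); d2 <- diff(d1)
    s1 <- wavelet_stats(d1); s2 <- wavelet_stats(d2)
    names(s1) <- paste(nm, "d1", names(s1), sep = "_")
    names(s2) <- paste(nm, "d2", names(s2), sep = "_")
    wav <- c(wav, s1, s2)
  }
  out <- c(raw, filt_stats, wav)
  out[eda_names]
}

#' Low-pass filter an accelerometer-magnitude stream
#'
#' Zero-phase 4th-order Butterworth low-pass. Errors when the sampling rate
#' cannot support the requested cutoff.
#'
#' @param x Magnitude samples, g.
#' @param hz Sampling rate, Hz.
#' @param cutoff_hz Low-pass cutoff, Hz (default 10).
#' @return Filtered numeric vector.
#' @export
accel_filter <- function(x, hz, cutoff_hz = 10) {
  if (hz <= 2 * cutoff_hz) {
    abort(sprintf("Sampling rate %g Hz cannot support a %g Hz low-pass cutoff.",
                  hz, cutoff_hz))
  }
  bf <- signal::butter(4, cutoff_hz / (hz / 2), type = "low")
  filtfilt_padded(bf, x)
}

# Peak count on a (filtered) magnitude window: local maxima exceeding the
# window mean by `threshold`, at least `min_gap_s` apart.
count_steps <- function(xf, hz, threshold = 0.1, min_gap_s = 0.25) {
  n <- length(xf)
  if (n < 3) return(0L)
  thr <- mean(xf) + threshold
  is_peak <- xf[2:(n - 1)] > xf[1:(n - 2)] & xf[2:(n - 1)] >= xf[3:n] &
    xf[2:(n - 1)] > thr
  idx <- which(is_peak) + 1L
  if (length(idx) == 0) return(0L)
  keep <- idx[c(TRUE, diff(idx) >= max(1, round(min_gap_s * hz)))]
  length(keep)
}

accel_names <- c("mean", "steps")

#' Accelerometer features
#'
#' Zero-phase 4th-order Butterworth low-pass at `cutoff_hz`, then the window
#' mean of the filtered magnitude and a step count by peak detection on it
#' (a simple stand-in for a dedicated step counter).
#'
#' @param x Magnitude samples, g.
#' @param hz Sampling rate, Hz.
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @param threshold Peak height above the window mean that counts as a
#'   step, g.
#' @return Named numeric vector `mean`, `steps`.
#' @export
accel_features <- function(x, hz, cutoff_hz = 10, threshold = 0.1) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(na_features(accel_names))
  xf <- accel_filter(x, hz, cutoff_hz)
  c(mean = mean(xf), steps = as.numeric(count_steps(xf, hz, threshold)))
}
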