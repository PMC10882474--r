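# Plain-text persistence of a synthetic cohort: an EMA log, one file per
# participant per stream, and a manifest of streams and sampling rates.
# Timestamps are ISO-8601 UTC relative to a nominal study epoch.

STUDY_EPOCH <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC")

minutes_to_iso <- function(m) {
  format(STUDY_EPOCH + round(m * 60, 3), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

iso_to_minutes <- function(s) {
  s <- as.character(s)
  out <- rep(NA_real_, length(s))
  ok <- !is.na(s) & nzchar(s)
  out[ok] <- as.numeric(difftime(
    as.POSIXct(s[ok], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"),
    STUDY_EPOCH, units = "mins"))
  out
}

#' Write a cohort to delimited text files
#'
#' Writes `ema_log.csv` (one row per notification with ISO-8601 UTC times,
#' response flag, onset time, 13 items and the generator's nonresponse
#' cause), `signals/p<id>_<stream>.csv` files with `(timestamp, value)` rows
#' and a `manifest.csv` listing streams and sampling rates.
#'
#' @param cohort An `ema_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  log <- cohort$events |>
    dplyr::mutate(
      notify_time = minutes_to_iso(.data$notify_minute),
      onset_time = ifelse(is.na(.data$onset_minute), "",
                          minutes_to_iso(.data$onset_minute))
    ) |>
    dplyr::select("participant_id", "notify_time", "responded", "onset_time",
                  dplyr::starts_with("item_"), "cause")
  readr::write_csv(log, file.path(dir, "ema_log.csv"), progress = FALSE)

  manifest <- list()
  for (b in cohort$signals) {
    p <- b$participant_id
    streams <- list(
      rr = dplyr::transmute(b$rr, timestamp = minutes_to_iso(.data$time_s / 60),
                            value = .data$rr_ms),
      eda = dplyr::transmute(b$eda, timestamp = minutes_to_iso(.data$time_s / 60),
                             value = .data$value),
      temperature = dplyr::transmute(b$temperature,
                                     timestamp = minutes_to_iso(.data$time_s / 60),
                                     value = .data$value),
      accel = dplyr::transmute(b$accel,
                               timestamp = minutes_to_iso(.data$time_s / 60),
                               value = .data$value)
    )
    hz <- c(rr = NA_real_, eda = b$rates$eda_hz,
            temperature = b$rates$temp_hz, accel = b$rates$accel_hz)
    for (s in names(streams)) {
      f <- sprintf("signals/p%03d_%s.csv", p, s)
      readr::write_csv(streams[[s]], file.path(dir, f), progress = FALSE)
      manifest[[length(manifest) + 1L]] <-
        tibble::tibble(participant_id = p, stream = s, file = f, hz = hz[[s]])
    }
  }
  readr::write_csv(dplyr::bind_rows(manifest), file.path(dir, "manifest.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `ema_log.csv`, `manifest.csv` and the
#'   signal files.
#' @return An `ema_cohort` (without latent traces, which are generator
#'   bookkeeping and are not persisted).
#' @export
read_cohort <- function(dir) {
  log <- readr::read_csv(
    file.path(dir, "ema_log.csv"), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(notify_time = readr::col_character(),
                            onset_time = readr::col_character(),
                            .default = readr::col_guess()))
  events <- log |>
    dplyr::mutate(
      notify_minute = iso_to_minutes(.data$notify_time),
      onset_minute = ifelse(is.na(.data$onset_time) | .data$onset_time == "",
                            NA_real_, iso_to_minutes(.data$onset_time)),
      latency_s = (.data$onset_minute - .data$notify_minute) * 60
    )
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  bundles <- list()
  for (p in unique(manifest$participant_id)) {
    mf <- manifest[manifest$participant_id == p, ]
    get <- function(stream, col) {
      d <- readr::read_csv(file.path(dir, mf$file[mf$stream == stream]),
                           show_col_types = FALSE, progress = FALSE)
      tibble::tibble(time_s = iso_to_minutes(d$timestamp) * 60,
                     !!col := d$value)
    }
    bundles[[p]] <- structure(list(
      participant_id = p,
      rr = dplyr::rename(get("rr", "value"), rr_ms = "value"),
      eda = get("eda", "value"),
      temperature = get("temperature", "value"),
      accel = get("accel", "value"),
      rates = list(eda_hz = mf$hz[mf$stream == "eda"],
                   temp_hz = mf$hz[mf$stream == "temperature"],
                   accel_hz = mf$hz[mf$stream == "accel"])
    ), class = "signal_bundle")
  }
  structure(list(events = events, signals = bundles, traces = NULL,
                 config = NULL), class = "ema_cohort")
}
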