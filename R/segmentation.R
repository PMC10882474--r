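# Sliding-window segmentation, receptivity/affect pseudo-labelling and
# grouped stratified train/test splitting.

#' Build the 1-minute / 30-second-overlap segment grid
#'
#' Segments are 60-second windows whose starts step by 30 seconds over the
#' contiguous stream span; for a span of `T` seconds the grid has
#' `floor((T - 60) / 30) + 1` segments. Features are computed at every
#' requested lookback (windows ending at the segment end, extending
#' backward), with missing markers where history is insufficient.
#'
#' @param bundle A `signal_bundle`.
#' @param lookback_minutes Lookbacks, minutes (1 = momentary).
#' @param battery,... Passed to [extract_features()].
#' @param end_s Optional restriction: only segments whose end falls in this
#'   set of times are materialised (used by the pipeline to skip segments
#'   that cannot receive a label).
#' @return Tibble: `participant_id`, `start_s`, `end_s` and feature columns.
#' @export
make_segments <- function(bundle, lookback_minutes = c(1, 5, 30, 60),
                          battery = c("hrv_time", "temp", "eda", "accel"),
                          end_s = NULL, ...) {
  spans <- vapply(list(bundle$rr$time_s, bundle$eda$time_s,
                       bundle$temperature$time_s, bundle$accel$time_s),
                  function(t) if (length(t)) max(t) - min(t) else NA_real_,
                  numeric(1))
  T_span <- min(spans, na.rm = TRUE)
  if (!is.finite(T_span) || T_span < 60) {
    warn("Stream span shorter than one segment; empty grid.")
    return(tibble::tibble(participant_id = integer(), start_s = numeric(),
                          end_s = numeric()))
  }
  t0 <- min(vapply(list(bundle$rr$time_s, bundle$eda$time_s,
                        bundle$temperature$time_s, bundle$accel$time_s),
                   function(t) if (length(t)) min(t) else Inf, numeric(1)))
  starts <- t0 + seq(0, T_span - 60, by = 30)
  ends <- starts + 60
  if (!is.null(end_s)) {
    sel <- round(ends, 3) %in% round(end_s, 3)
    starts <- starts[sel]; ends <- ends[sel]
  }
  feats <- extract_features(bundle, ends, lookback_minutes = lookback_minutes,
                            battery = battery, ...)
  dplyr::bind_cols(
    tibble::tibble(participant_id = bundle$participant_id, start_s = starts),
    feats
  )
}

#' Pseudo-label segments from the EMA log
#'
#' Every segment ending within `window_minutes` before (or exactly at) a
#' notification inherits that notification's receptivity label, and — when
#' the notification was responded — its composite affect score. Segments
#' matching no notification are dropped (unlabeled); a segment inside two
#' notifications' windows is assigned to the nearest upcoming notification.
#' Segments after the notification are never labelled.
#'
#' @param segments Output of [make_segments()] for one participant.
#' @param events Scored EMA log (see [score_ema()]) for the same
#'   participant; needs `notify_minute`, `responded`, `composite`.
#' @param window_minutes Label window: 5, 30 (default), 60 or 120 minutes.
#' @return `segments` restricted to labelled rows, with `notification_id`,
#'   `receptivity_label` (`"responded"`/`"no_response"`), `affect_label`
#'   and `label_window_minutes` columns.
#' @export
pseudo_label <- function(segments, events, window_minutes = 30) {
  stopifnot(nrow(events) > 0)
  events <- events[order(events$notify_minute), ]
  if (!"composite" %in% names(events)) events <- score_ema(events)
  if (any(diff(events$notify_minute) <= 0)) {
    abort("Notifications must be strictly ordered in time.")
  }
  if (nrow(segments) == 0) return(segments)
  end_min <- segments$end_s / 60
  nxt <- findInterval(end_min, events$notify_minute, left.open = TRUE) + 1L
  has_next <- nxt <= nrow(events)
  dist <- rep(Inf, length(end_min))
  dist[has_next] <- events$notify_minute[nxt[has_next]] - end_min[has_next]
  hit <- dist >= 0 & dist <= window_minutes
  lab <- segments[hit, , drop = FALSE]
  ev <- events[nxt[hit], ]
  lab$notification_id <- paste0(ev$participant_id, "_",
                                round(ev$notify_minute * 60))
  lab$receptivity_label <- ifelse(ev$responded, "responded", "no_response")
  lab$affect_label <- ifelse(ev$responded, ev$composite, NA_real_)
  if (all(c("pa_mean", "na_mean") %in% names(ev))) {
    lab$pa_mean <- ifelse(ev$responded, ev$pa_mean, NA_real_)
    lab$na_mean <- ifelse(ev$responded, ev$na_mean, NA_real_)
  }
  lab$label_window_minutes <- window_minutes
  lab
}

#' Grouped stratified train/test split
#'
#' Splits at the notification level so all segments of one response or
#' nonresponse stay in the same partition, stratifying by the receptivity
#' label. Participants with fewer than two notification groups in either
#' class are excluded (a single nonresponse cannot be both trained and
#' tested on).
#'
#' @param labeled Labelled segments (needs `participant_id`,
#'   `notification_id`, `receptivity_label`).
#' @param test_fraction Fraction of groups per class assigned to test.
#' @param seed Integer seed for the group sampling.
#' @return List: `assignments` (tibble `participant_id`, `notification_id`,
#'   `receptivity_label`, `partition`), `excluded` (tibble of excluded
#'   participants and reasons), `seed`.
#' @export
grouped_stratified_split <- function(labeled, test_fraction = 0.3, seed = 1L) {
  set.seed(seed)
  groups <- labeled |>
    dplyr::distinct(.data$participant_id, .data$notification_id,
                    .data$receptivity_label)
  assignments <- list(); excluded <- list()
  for (p in unique(groups$participant_id)) {
    g <- groups[groups$participant_id == p, ]
    counts <- table(factor(g$receptivity_label,
                           levels = c("responded", "no_response")))
    if (any(counts < 2)) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        participant_id = p,
        reason = sprintf("class '%s' has %d notification group(s); need >= 2",
                         names(which.min(counts)), min(counts)))
      inform(sprintf("Participant %s excluded from split: %s",
                     p, excluded[[length(excluded)]]$reason))
      next
    }
    g$partition <- "train"
    for (cl in names(counts)) {
      ids <- g$notification_id[g$receptivity_label == cl]
      n_test <- max(1L, round(test_fraction * length(ids)))
      g$partition[g$notification_id %in% sample(ids, n_test)] <- "test"
    }
    assignments[[length(assignments) + 1L]] <- g
  }
  assignments <- dplyr::bind_rows(assignments)
  if (nrow(assignments) > 0) {
    overall <- mean(assignments$receptivity_label == "responded")
    by_part <- tapply(assignments$receptivity_label == "responded",
                      assignments$partition, mean)
    if (any(abs(by_part - overall) > 0.05 + 1e-9)) {
      warn("Partition class proportions deviate by more than 5 points from overall.")
    }
  }
  list(assignments = assignments,
       excluded = if (length(excluded)) dplyr::bind_rows(excluded) else
         tibble::tibble(participant_id = integer(), reason = character()),
       seed = seed)
}
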