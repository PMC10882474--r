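# EMA scoring: the 13-item composite affect score (9 negative items summed
# directly, 4 positive items inverted), receptivity summaries, and the
# mood-versus-response-latency diagnostic.

#' Item names of the affect instrument
#'
#' Nine negative-affect items and four positive-affect items, each answered
#' on a 1-7 scale. Column positions `item_1..item_9` hold the negative
#' items and `item_10..item_13` the positive items; the identities are
#' configurable only through the `negative`/`positive` arguments of the
#' scoring functions.
#' @export
ema_items <- function() {
  list(
    negative = c("worried", "stressed", "anxious", "annoyed", "down",
                 "restless", "tense", "under_pressure", "ashamed"),
    positive = c("relaxed", "cheerful", "confident", "in_control")
  )
}

#' Invert a positive item response
#'
#' Maps a 1-7 response to its mirror (1 becomes 7, 7 becomes 1): `8 - x`.
#'
#' @param x Integer vector of responses in 1-7.
#' @return `8 - x`.
#' @export
invert_positive <- function(x) {
  if (any(!is.na(x) & (x < 1 | x > 7 | x != round(x)))) {
    abort("Item responses must be integers in 1..7.")
  }
  8 - x
}

#' Composite affect score of a 13-item response set
#'
#' Sum of the nine negative items plus the inverted four positive items.
#' Range 13 (most positive state) to 91 (most negative state).
#'
#' @param negative Numeric vector/matrix of the 9 negative items (1-7).
#' @param positive Numeric vector/matrix of the 4 positive items (1-7).
#' @return Integer composite score(s) in 13-91.
#' @export
score_composite <- function(negative, positive) {
  negative <- rbind(negative); positive <- rbind(positive)
  if (ncol(negative) != 9 || ncol(positive) != 4) {
    abort("Need exactly 9 negative and 4 positive items.")
  }
  vals <- cbind(negative, positive)
  if (anyNA(vals)) abort("Missing item responses; cannot score.")
  if (any(vals < 1 | vals > 7)) abort("Item responses must be in 1..7.")
  out <- rowSums(negative) + rowSums(invert_positive(positive))
  as.integer(out)
}

#' Score an EMA log
#'
#' Adds `composite`, `na_mean` (mean of the 9 negative items) and `pa_mean`
#' (mean of the 4 positive items, on their original scale) to every
#' responded event; events with any missing item are treated as
#' nonresponses for labelling purposes (no composite ground truth exists
#' for a partial response).
#'
#' @param events EMA log tibble with `item_1..item_13` columns
#'   (items 1-9 negative, 10-13 positive).
#' @return The input with `composite`, `na_mean`, `pa_mean` columns and
#'   `responded` forced to `FALSE` where items are incomplete.
#' @export
score_ema <- function(events) {
  neg <- as.matrix(events[paste0("item_", 1:9)])
  pos <- as.matrix(events[paste0("item_", 10:13)])
  complete <- stats::complete.cases(neg) & stats::complete.cases(pos)
  incomplete_resp <- events$responded & !complete
  if (any(incomplete_resp)) {
    warn(sprintf("%d responded event(s) with missing items treated as nonresponses.",
                 sum(incomplete_resp)))
    events$responded[incomplete_resp] <- FALSE
  }
  comp <- rep(NA_integer_, nrow(events))
  ok <- events$responded & complete
  if (any(ok)) comp[ok] <- score_composite(neg[ok, , drop = FALSE],
                                           pos[ok, , drop = FALSE])
  events |>
    dplyr::mutate(
      composite = comp,
      na_mean = ifelse(ok, rowMeans(neg), NA_real_),
      pa_mean = ifelse(ok, rowMeans(pos), NA_real_)
    )
}

#' Summarize receptivity of an EMA log
#'
#' @param events EMA log tibble with `responded` and (for responded rows)
#'   `latency_s` = onset minus notification time, seconds.
#' @return One-row tibble: `n_notifications`, `n_responses`,
#'   `response_rate` (4 significant digits), `mean_latency_s`,
#'   `median_latency_s`.
#' @export
summarize_receptivity <- function(events) {
  if (nrow(events) == 0) abort("Empty EMA log.")
  lat <- events$latency_s[events$responded]
  tibble::tibble(
    n_notifications = nrow(events),
    n_responses = sum(events$responded),
    response_rate = signif(sum(events$responded) / nrow(events), 4),
    mean_latency_s = if (length(lat)) mean(lat, na.rm = TRUE) else NA_real_,
    median_latency_s = if (length(lat)) median(lat, na.rm = TRUE) else NA_real_
  )
}

#' Correlation of each mood item with response latency
#'
#' Pearson correlation, per item, between the item response and the
#' notification-to-onset latency over responded events; a diagnostic for
#' whether momentary mood is related to how quickly participants open the
#' survey.
#'
#' @param events Scored EMA log (needs `latency_s` and item columns).
#' @return Tibble with `item`, `r`, `n`, `p_value` and `defined` (FALSE when
#'   the item or latency is constant, in which case `r` is `NA`).
#' @export
mood_latency_correlation <- function(events) {
  resp <- events[events$responded & !is.na(events$latency_s), ]
  if (nrow(resp) < 3) abort("Need at least 3 responded events.")
  purrr::map_dfr(paste0("item_", 1:13), function(col) {
    x <- resp[[col]]; y <- resp$latency_s
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(item = col, r = NA_real_, n = length(x),
                            p_value = NA_real_, defined = FALSE))
    }
    ct <- stats::cor.test(x, y)
    tibble::tibble(item = col, r = unname(ct$estimate), n = length(x),
                   p_value = ct$p.value, defined = TRUE)
  })
}
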