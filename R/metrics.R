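# Model evaluation, uncertainty filtering and uncertainty diagnostics.

#' Classification and regression evaluation metrics
#'
#' Classification: accuracy, precision, recall and F1 with `"responded"`
#' as the positive class. Regression: root mean square error. Supply
#' whichever prediction type is available; with a `participant_id` column
#' the metrics are also summarised as mean (SD) across participants.
#'
#' @param truth Vector of true labels (character) or scores (numeric).
#' @param pred Vector of predictions, same type.
#' @param participant_id Optional grouping for across-participant
#'   summaries.
#' @param positive Positive class for classification.
#' @return Tibble of metrics (`metric`, `value`, and, when grouped,
#'   `mean_across`, `sd_across`).
#' @export
evaluate_predictions <- function(truth, pred, participant_id = NULL,
                                 positive = "responded") {
  if (length(truth) == 0) abort("Empty evaluation input.")
  stopifnot(length(truth) == length(pred))
  one <- function(tr, pr) {
    if (is.numeric(tr)) {
      return(tibble::tibble(metric = "rmse", value = sqrt(mean((tr - pr)^2))))
    }
    tp <- sum(pr == positive & tr == positive)
    fp <- sum(pr == positive & tr != positive)
    fn <- sum(pr != positive & tr == positive)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    tibble::tibble(metric = c("accuracy", "precision", "recall", "f1"),
                   value = c(mean(pr == tr), precision, recall, f1))
  }
  overall <- one(truth, pred)
  if (is.null(participant_id)) return(overall)
  per <- tibble::tibble(participant_id = participant_id,
                        truth = truth, pred = pred) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ one(.x$truth, .x$pred)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean_across = mean(.data$value, na.rm = TRUE),
                     sd_across = sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(overall, per, by = "metric")
}

#' Filter affect predictions by predicted uncertainty
#'
#' Keeps predictions with `sigma` strictly below the cutoff (default 6
#' score points); the kept fraction is reported via a message.
#'
#' @param predictions Tibble with a `sigma` column.
#' @param cutoff Uncertainty cutoff, score points.
#' @param quiet Suppress the kept-fraction message.
#' @return `predictions` with a logical `kept_after_filter` column; rows
#'   are retained so callers can audit the filter.
#' @export
filter_by_uncertainty <- function(predictions, cutoff = 6, quiet = FALSE) {
  predictions$kept_after_filter <- predictions$sigma < cutoff
  if (!quiet) {
    inform(sprintf("Uncertainty filter (sigma < %g): kept %.1f%% (%d/%d).",
                   cutoff, 100 * mean(predictions$kept_after_filter),
                   sum(predictions$kept_after_filter), nrow(predictions)))
  }
  predictions
}

#' Uncertainty diagnostics
#'
#' Participant-centred correlations of the predicted noise scale `sigma`
#' with the absolute prediction error and with the reported affect label —
#' a check that sigma behaves like uncertainty (larger when the model is
#' further from the truth) and a probe of whether uncertainty grows with
#' negative affect.
#'
#' @param predictions Tibble with `participant_id`, `mu`, `sigma`.
#' @param truth Reported composite scores aligned with `predictions`.
#' @return Tibble per participant: `r_sigma_abs_error`, `r_sigma_affect`,
#'   `n`, `defined`.
#' @export
uncertainty_diagnostics <- function(predictions, truth) {
  predictions$truth <- truth
  predictions |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        return(tibble::tibble(r_sigma_abs_error = NA_real_,
                              r_sigma_affect = NA_real_, n = nrow(d),
                              defined = FALSE))
      }
      err <- abs(d$truth - d$mu)
      ok <- sd(d$sigma) > 0
      tibble::tibble(
        r_sigma_abs_error = if (ok && sd(err) > 0) cor(d$sigma, err) else NA_real_,
        r_sigma_affect = if (ok && sd(d$truth) > 0) cor(d$sigma, d$truth) else NA_real_,
        n = nrow(d),
        defined = ok
      )
    }) |>
    dplyr::ungroup()
}
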