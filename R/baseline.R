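# Distribution-matching baseline samplers and their analytic behaviour.

#' Expected true-positive fraction of the label-sampling baseline
#'
#' A classifier that draws labels i.i.d. from the training distribution,
#' scored against an independent test set, produces true positives at rate
#' `p_train * p_test` (the product of the response proportions).
#'
#' @param p_train,p_test Response proportions in train and test.
#' @return Expected fraction of predictions that are true positives.
#' @export
expected_true_positive_fraction <- function(p_train, p_test) {
  stopifnot(p_train >= 0, p_train <= 1, p_test >= 0, p_test <= 1)
  p_train * p_test
}

#' Baseline receptivity classifier
#'
#' Samples labels i.i.d. from the training label distribution.
#'
#' @param train_labels Character vector of training labels.
#' @param test_size Number of predictions to draw.
#' @param seed Integer seed.
#' @return Character vector of sampled labels.
#' @export
baseline_classify <- function(train_labels, test_size, seed = 1L) {
  set.seed(seed)
  tab <- table(train_labels)
  sample(names(tab), test_size, replace = TRUE, prob = as.numeric(tab))
}

#' Baseline affect regressor
#'
#' Draws i.i.d. Normal(mean, SD) values from the training label moments,
#' clipped to the 13-91 composite support.
#'
#' @param train_labels Numeric training scores (>= 2 values).
#' @param test_size Number of predictions.
#' @param seed Integer seed.
#' @return Numeric vector of sampled scores.
#' @export
baseline_regress <- function(train_labels, test_size, seed = 1L) {
  if (length(train_labels) < 2) abort("Need >= 2 training labels.")
  set.seed(seed)
  draws <- rnorm(test_size, mean(train_labels), sd(train_labels))
  pmin(SCORE_MAX, pmax(SCORE_MIN, draws))
}
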