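# Personalised receptivity classification: random forest with inverse
# class-frequency weights and exhaustive grid search under grouped
# stratified cross-validation.

#' Default receptivity hyperparameter grid
#'
#' Mirrors the neighbourhood of the commonly selected optimum (60 trees,
#' depth 3, leaf 2, split 2, sqrt features).
#' @return A data frame of grid permutations.
#' @export
receptivity_grid <- function() {
  expand.grid(n_estimators = c(20, 60, 100),
              max_depth = c(3, 5, NA),
              min_samples_leaf = c(1, 2, 4),
              min_samples_split = c(2, 4),
              max_features = c("sqrt", "all"),
              stringsAsFactors = FALSE)
}

fit_forest_once <- function(x, y, params, class_weights) {
  max_nodes <- if (is.na(params$max_depth)) NULL else 2^params$max_depth
  mtry <- if (params$max_features == "sqrt") max(1, floor(sqrt(ncol(x))))
          else ncol(x)
  # class imbalance handled by inverse-frequency class weights plus a
  # balanced per-tree bootstrap (each tree sees equally many groups of
  # both classes), which behaves far better than priors alone on the
  # small personalised training sets
  tab <- table(y)
  samp <- rep(min(tab), length(tab))
  randomForest::randomForest(
    x = x, y = y, ntree = params$n_estimators, mtry = mtry,
    nodesize = params$min_samples_leaf, maxnodes = max_nodes,
    classwt = class_weights, strata = y, sampsize = samp
  )
}

f1_score <- function(truth, pred, positive = "responded") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# Grouped stratified fold ids at the notification level.
make_group_folds <- function(groups, labels, n_folds) {
  fold <- setNames(integer(length(groups)), groups)
  for (cl in unique(labels)) {
    ids <- sample(groups[labels == cl])
    fold[ids] <- rep_len(seq_len(n_folds), length(ids))
  }
  fold
}

#' Exhaustive grid search for the receptivity forest
#'
#' Every grid permutation is scored by grouped stratified cross-validation
#' within the training set (folds at notification level, so segments of one
#' response never straddle a fold boundary); the permutation with the best
#' mean F1 (responded = positive class) is refit on the full training set
#' with class weights inverse to the training label frequencies.
#'
#' @param x Training feature matrix.
#' @param y Training labels (`"responded"`/`"no_response"`).
#' @param groups Notification id per row.
#' @param grid Data frame of permutations (default [receptivity_grid()]).
#' @param n_folds Inner folds (default 3).
#' @param seed Integer seed.
#' @return A `receptivity_fit`: fitted forest, chosen parameters, class
#'   weights, search log.
#' @export
grid_search_receptivity <- function(x, y, groups, grid = receptivity_grid(),
                                    n_folds = 3L, seed = 1L) {
  set.seed(seed)
  x <- as.matrix(x)
  y <- factor(y, levels = c("no_response", "responded"))
  if (nlevels(droplevels(y)) < 2) abort("Both classes required for training.")
  freq <- table(y) / length(y)
  class_weights <- setNames(as.numeric(1 / freq), names(freq))
  class_weights <- class_weights / sum(class_weights)

  ug <- unique(groups)
  glab <- vapply(ug, function(g) as.character(y[groups == g][1]), character(1))
  fold <- make_group_folds(ug, glab, n_folds)
  log <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- grid[gi, ]
    f1s <- c()
    for (k in seq_len(n_folds)) {
      te <- groups %in% names(fold)[fold == k]
      if (nlevels(droplevels(y[!te])) < 2 || sum(te) == 0) {
        warn(sprintf("Fold %d lacks both classes; skipped.", k))
        next
      }
      fit <- fit_forest_once(x[!te, , drop = FALSE], droplevels(y[!te]),
                             params, class_weights[levels(droplevels(y[!te]))])
      pred <- predict(fit, x[te, , drop = FALSE])
      f1s <- c(f1s, f1_score(y[te], pred))
    }
    log[[gi]] <- dplyr::bind_cols(tibble::as_tibble(params),
                                  tibble::tibble(mean_f1 = mean(f1s),
                                                 n_folds_used = length(f1s)))
  }
  log <- dplyr::bind_rows(log)
  best <- which.max(log$mean_f1)
  fit <- fit_forest_once(x, y, grid[best, ], class_weights)
  structure(list(forest = fit, params = grid[best, ],
                 class_weights = class_weights, search_log = log,
                 feature_names = colnames(x),
                 train_prevalence = unname(freq["no_response"]),
                 seed = seed),
            class = "receptivity_fit")
}

#' Predict receptivity labels
#'
#' @param object A `receptivity_fit`.
#' @param newdata Feature matrix.
#' @param calibrate Use prevalence thresholding: label a segment
#'   `no_response` when its vote fraction ranks it within the training
#'   nonresponse prevalence (quantile thresholding), instead of majority
#'   vote. Balanced-bootstrap forests overstate minority votes; the
#'   calibrated rule restores the expected nonresponse rate while keeping
#'   the forest's ranking.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.receptivity_fit <- function(object, newdata, calibrate = FALSE, ...) {
  if (!calibrate) {
    return(as.character(predict(object$forest, as.matrix(newdata))))
  }
  pr <- predict(object$forest, as.matrix(newdata), type = "prob")
  p_nr <- pr[, "no_response"]
  thr <- quantile(p_nr, 1 - object$train_prevalence)
  ifelse(p_nr > thr, "no_response", "responded")
}

#' @method tidy receptivity_fit
#' @export
tidy.receptivity_fit <- function(x, ...) {
  dplyr::arrange(x$search_log, dplyr::desc(.data$mean_f1))
}

#' @method glance receptivity_fit
#' @export
glance.receptivity_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$params),
                   tibble::tibble(best_cv_f1 = max(x$search_log$mean_f1),
                                  n_permutations = nrow(x$search_log)))
}
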