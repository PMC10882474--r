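# Per-participant feature normalisation and variance-target projection.

#' Fit a per-participant feature normalizer
#'
#' Z-scoring statistics per participant per feature, computed on the given
#' rows only. Zero-variance features get scale 1 (so they pass through
#' centred, as all-zeros).
#'
#' @param features Tibble with `participant_id` and numeric feature columns.
#' @param feature_cols Names of the feature columns.
#' @return A `feature_normalizer`: tibble of participant, feature, location,
#'   scale.
#' @export
fit_normalizer <- function(features, feature_cols) {
  stats_tb <- features |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) abort("Need >= 2 rows per participant to normalize.")
      loc <- vapply(d[feature_cols], function(x) mean(x, na.rm = TRUE), numeric(1))
      sc <- vapply(d[feature_cols], function(x) sd(x, na.rm = TRUE), numeric(1))
      degenerate <- !is.finite(sc) | sc == 0
      if (any(degenerate)) {
        warn(sprintf("%d constant feature(s) pass through with scale 1.",
                     sum(degenerate)))
        sc[degenerate] <- 1
      }
      loc[!is.finite(loc)] <- 0
      tibble::tibble(feature = feature_cols, location = unname(loc),
                     scale = unname(sc))
    }) |>
    dplyr::ungroup()
  structure(list(stats = stats_tb, feature_cols = feature_cols),
            class = "feature_normalizer")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param normalizer A `feature_normalizer`.
#' @param features Tibble with `participant_id` and the fitted feature
#'   columns.
#' @param invert Undo the transform instead of applying it.
#' @return `features` with the feature columns transformed.
#' @export
apply_normalizer <- function(normalizer, features, invert = FALSE) {
  for (p in unique(features$participant_id)) {
    st <- normalizer$stats[normalizer$stats$participant_id == p, ]
    if (nrow(st) == 0) abort(sprintf("No normalizer fitted for participant %s.", p))
    rows <- features$participant_id == p
    for (i in seq_len(nrow(st))) {
      f <- st$feature[i]
      features[[f]][rows] <- if (invert) {
        features[[f]][rows] * st$scale[i] + st$location[i]
      } else {
        (features[[f]][rows] - st$location[i]) / st$scale[i]
      }
    }
  }
  features
}

#' Fit a variance-target orthogonal projection
#'
#' Principal components of the (already normalised) training features; keeps
#' the smallest number of components whose cumulative explained variance
#' reaches `variance_target`.
#'
#' @param x Numeric matrix or tibble of normalised features (rows =
#'   segments).
#' @param variance_target Fraction of variance to retain (default 0.99).
#' @return A `feature_projection`: rotation matrix, centring vector,
#'   `n_components`, `retained_variance`.
#' @export
fit_projection <- function(x, variance_target = 0.99) {
  x <- as.matrix(x)
  if (all(x == 0) || nrow(x) < 2) abort("Degenerate matrix; cannot project.")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) abort("Degenerate matrix; cannot project.")
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= variance_target - 1e-12)[1]
  structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, n_components = k,
                 retained_variance = cum[k],
                 variance_target = variance_target),
            class = "feature_projection")
}

#' Apply a fitted projection
#'
#' @param projection A `feature_projection`.
#' @param x Matrix/tibble with the same columns the projection was fitted
#'   on.
#' @return Matrix of scores, `n_components` columns.
#' @export
apply_projection <- function(projection, x) {
  scale(as.matrix(x), center = projection$center, scale = FALSE) %*%
    projection$rotation
}
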