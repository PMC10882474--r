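# Cluster-based and prediction-based quantification of the
# affect-receptivity relationship, and the trigger-bias estimate.

#' Select clustering features by correlation with receptivity
#'
#' Ranks features by absolute point-biserial correlation with the binary
#' receptivity label and returns the top `m`.
#'
#' @param labeled Labelled segments (needs `receptivity_label` and feature
#'   columns).
#' @param feature_cols Candidate feature columns.
#' @param m Number of features to keep (default 10).
#' @return Tibble `feature`, `abs_r`, ordered; at most `m` rows.
#' @export
select_cluster_features <- function(labeled, feature_cols, m = 10L) {
  y <- as.numeric(labeled$receptivity_label == "responded")
  r <- vapply(feature_cols, function(f) {
    x <- labeled[[f]]
    ok <- is.finite(x)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    abs(cor(x[ok], y[ok]))
  }, numeric(1))
  out <- tibble::tibble(feature = feature_cols, abs_r = unname(r)) |>
    dplyr::filter(is.finite(.data$abs_r)) |>
    dplyr::arrange(dplyr::desc(.data$abs_r))
  if (nrow(out) < m) {
    warn(sprintf("Only %d valid features (requested %d); returning all.",
                 nrow(out), m))
    return(out)
  }
  out[seq_len(m), ]
}

#' Cluster segments on physiological features
#'
#' k-means (maximum 300 iterations, multiple restarts) for each candidate
#' k; the mean silhouette score is computed for each and the candidate with
#' the best silhouette is selected. Deterministic under `seed`.
#'
#' @param x Feature matrix (rows = segments), typically the selected,
#'   normalised clustering features.
#' @param k_candidates Candidate cluster counts (default `2:5`).
#' @param seed Integer seed.
#' @param nstart Restarts per k.
#' @param max_iter Iteration cap per run.
#' @return A `cluster_result`: `assignments`, `k`, `silhouette`,
#'   `by_k` (silhouette per candidate), `centers`, `seed`.
#' @export
cluster_segments <- function(x, k_candidates = 2:5, seed = 1L, nstart = 5L,
                             max_iter = 300L) {
  x <- as.matrix(x)
  if (any(k_candidates >= nrow(x))) {
    abort("Candidate k must be below the number of segments.")
  }
  set.seed(seed)
  d <- stats::dist(x)
  fits <- list(); sil <- numeric(length(k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    fit <- kmeans(x, centers = k, iter.max = max_iter, nstart = nstart)
    s <- cluster::silhouette(fit$cluster, d)
    sil[i] <- mean(s[, "sil_width"])
    fits[[i]] <- fit
  }
  best <- which.max(sil)
  structure(list(assignments = fits[[best]]$cluster - 1L,
                 k = k_candidates[best], silhouette = sil[best],
                 by_k = tibble::tibble(k = k_candidates, silhouette = sil),
                 centers = fits[[best]]$centers, seed = seed),
            class = "cluster_result")
}

#' Profile clusters by receptivity and affect
#'
#' Per-cluster receptivity rate and mean reported PA, NA and composite; a
#' chi-square test of independence of the cluster-by-response contingency
#' table; and a one-way F statistic for the composite across clusters on
#' participant-mean-centred values (the within-participant contrast a
#' repeated-measures design targets).
#'
#' @param result A `cluster_result`.
#' @param labeled Labelled segments aligned with the clustering rows; needs
#'   `participant_id`, `receptivity_label`, `affect_label` and (optionally)
#'   `pa_mean`/`na_mean`.
#' @return A `cluster_profile`: `profile` tibble, `chisq` (statistic, df,
#'   p), `anova` (F, df, p).
#' @export
profile_clusters <- function(result, labeled) {
  stopifnot(length(result$assignments) == nrow(labeled))
  labeled$cluster <- result$assignments
  profile <- labeled |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      receptivity_rate = mean(.data$receptivity_label == "responded"),
      mean_composite = mean(.data$affect_label, na.rm = TRUE),
      sd_composite = sd(.data$affect_label, na.rm = TRUE),
      mean_pa = if ("pa_mean" %in% names(labeled))
        mean(.data$pa_mean, na.rm = TRUE) else NA_real_,
      mean_na = if ("na_mean" %in% names(labeled))
        mean(.data$na_mean, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  if (any(profile$n == 0)) warn("Cluster with no labelled segments.")
  tab <- table(labeled$cluster, labeled$receptivity_label)
  chisq <- if (all(dim(tab) == c(2, 2)) || all(dim(tab) >= 2)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value)
  } else {
    tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  resp <- labeled[!is.na(labeled$affect_label), ]
  anova_tb <- tibble::tibble(statistic = NA_real_, df1 = NA_real_,
                             df2 = NA_real_, p_value = NA_real_)
  if (nrow(resp) > 2 && length(unique(resp$cluster)) > 1) {
    centred <- resp |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(affect_c = .data$affect_label -
                      mean(.data$affect_label)) |>
      dplyr::ungroup()
    if (sd(centred$affect_c) > 0) {
      fit <- stats::oneway.test(affect_c ~ factor(cluster), data = centred,
                                var.equal = TRUE)
      anova_tb <- tibble::tibble(statistic = unname(fit$statistic),
                                 df1 = unname(fit$parameter[1]),
                                 df2 = unname(fit$parameter[2]),
                                 p_value = fit$p.value)
    }
  }
  structure(list(profile = profile, chisq = chisq, anova = anova_tb,
                 contingency = tab),
            class = "cluster_profile")
}

#' @method tidy cluster_profile
#' @export
tidy.cluster_profile <- function(x, ...) x$profile

#' @method glance cluster_profile
#' @export
glance.cluster_profile <- function(x, ...) {
  tibble::tibble(chisq = x$chisq$statistic, chisq_df = x$chisq$df,
                 chisq_p = x$chisq$p_value, f_statistic = x$anova$statistic,
                 f_p = x$anova$p_value)
}

#' Cohen's kappa for two binary label series
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement from the
#' marginal products. Symmetric in its arguments.
#'
#' @param a,b Vectors of equal length (any two-level coding).
#' @return List: `kappa`, `p_observed`, `p_expected`, `n`, `defined`.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  lev <- union(unique(a), unique(b))
  if (length(lev) > 2) abort("Binary labels required.")
  po <- mean(a == b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (1 - pe < 1e-12) {
    return(list(kappa = NA_real_, p_observed = po, p_expected = pe, n = n,
                defined = FALSE))
  }
  list(kappa = (po - pe) / (1 - pe), p_observed = po, p_expected = pe,
       n = n, defined = TRUE)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a binary variable coded 0/1 and a continuous
#' variable.
#'
#' @param binary Two-level vector (logical, 0/1 or two-level character).
#' @param continuous Numeric vector.
#' @return List: `r`, `n`, `defined`.
#' @export
point_biserial <- function(binary, continuous) {
  stopifnot(length(binary) == length(continuous))
  b <- as.numeric(factor(binary)) - 1
  if (length(unique(b)) < 2 || sd(continuous) == 0) {
    return(list(r = NA_real_, n = length(b), defined = FALSE))
  }
  list(r = cor(b, continuous), n = length(b), defined = TRUE)
}

#' Compare reported and predicted affect distributions
#'
#' ECDFs on the 13-91 support for the reported scores at responses and the
#' (uncertainty-filtered) predicted scores at responses and nonresponses;
#' group means/SDs; a rank-based two-sample location comparison between
#' predicted-at-nonresponse and reported-at-response; and the kernel-density
#' mode count of the nonresponse set (a bimodality descriptor).
#'
#' @param reported_response Reported composite scores at responses.
#' @param predicted_response Predicted scores at responses (post filter).
#' @param predicted_nonresponse Predicted scores at nonresponses (post
#'   filter).
#' @return An `affect_distributions`: `ecdf` (long tibble), `summary`,
#'   `location_test` (Wilcoxon), `nonresponse_modes`.
#' @export
compare_affect_distributions <- function(reported_response,
                                         predicted_response,
                                         predicted_nonresponse) {
  sets <- list(reported_response = reported_response,
               predicted_response = predicted_response,
               predicted_nonresponse = predicted_nonresponse)
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0]
  if (length(empty)) {
    abort(paste0("Empty set(s) after the uncertainty filter: ",
                 paste(empty, collapse = ", ")))
  }
  ecdfs <- purrr::imap_dfr(sets, function(x, nm) {
    dplyr::mutate(ecdf_table(x), set = nm, .before = 1)
  })
  summary <- purrr::imap_dfr(sets, function(x, nm) {
    tibble::tibble(set = nm, n = length(x), mean = mean(x), sd = sd(x))
  })
  wt <- suppressWarnings(wilcox.test(predicted_nonresponse, reported_response))
  structure(list(
    ecdf = ecdfs, summary = summary,
    location_test = tibble::tibble(statistic = unname(wt$statistic),
                                   p_value = wt$p.value),
    nonresponse_modes = density_mode_count(predicted_nonresponse)
  ), class = "affect_distributions")
}

#' Estimate the bias of a receptivity-triggered EMA policy
#'
#' Mean predicted affect among segments the receptivity model marks as
#' likely responses versus likely nonresponses. The difference (nonresponse
#' minus response, score points) is the affect a trigger that only prompts
#' at predicted-response moments would fail to sample; it is also expressed
#' in units of the SD of the reported scores. Among true responses, the
#' reported scores are additionally compared between predicted-response and
#' predicted-nonresponse strata.
#'
#' @param predictions Tibble per segment: `receptivity_pred`
#'   (`"responded"`/`"no_response"`), `mu`, `sigma`, `kept_after_filter`,
#'   and for true responses `receptivity_label` and `affect_label`.
#' @param sigma_cutoff Re-filter cutoff if `kept_after_filter` is absent.
#' @return A `trigger_bias` object.
#' @export
trigger_bias <- function(predictions, sigma_cutoff = 6) {
  if (!"kept_after_filter" %in% names(predictions)) {
    predictions <- filter_by_uncertainty(predictions, sigma_cutoff,
                                         quiet = TRUE)
  }
  kept <- predictions[predictions$kept_after_filter, ]
  pr <- kept$mu[kept$receptivity_pred == "responded"]
  pn <- kept$mu[kept$receptivity_pred == "no_response"]
  if (length(pr) == 0 || length(pn) == 0) {
    warn("A predicted-receptivity stratum is empty; bias undefined.")
    return(structure(list(
      mean_pred_response = NA_real_, mean_pred_nonresponse = NA_real_,
      bias_points = NA_real_, bias_sd_units = NA_real_,
      reported = NULL, n = c(response = length(pr), nonresponse = length(pn))
    ), class = "trigger_bias"))
  }
  # with personalised models the bias is a within-participant contrast:
  # average the per-participant stratum difference over participants that
  # have both strata, rather than pooling segments (which would let one
  # participant's prediction volume dominate)
  per_participant <- NULL
  if ("participant_id" %in% names(predictions)) {
    per_participant <- kept |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(
        mean_pred_response =
          mean(.data$mu[.data$receptivity_pred == "responded"]),
        mean_pred_nonresponse =
          mean(.data$mu[.data$receptivity_pred == "no_response"]),
        n_response = sum(.data$receptivity_pred == "responded"),
        n_nonresponse = sum(.data$receptivity_pred == "no_response"),
        .groups = "drop") |>
      dplyr::mutate(bias_points = .data$mean_pred_nonresponse -
                      .data$mean_pred_response)
  }
  reported <- NULL
  pooled_sd <- NA_real_
  if (all(c("receptivity_label", "affect_label") %in% names(predictions))) {
    tr <- kept[!is.na(kept$affect_label) &
                 kept$receptivity_label == "responded", ]
    pooled_sd <- sd(tr$affect_label)
    reported <- tr |>
      dplyr::group_by(.data$receptivity_pred) |>
      dplyr::summarise(mean_reported = mean(.data$affect_label),
                       sd_reported = sd(.data$affect_label),
                       n = dplyr::n(), .groups = "drop")
  }
  if (!is.finite(pooled_sd) || is.na(pooled_sd) || pooled_sd == 0) {
    pooled_sd <- sd(kept$mu)
  }
  if (!is.null(per_participant)) {
    ok <- is.finite(per_participant$bias_points)
    bias <- mean(per_participant$bias_points[ok])
    m_pr <- mean(per_participant$mean_pred_response[ok])
    m_pn <- mean(per_participant$mean_pred_nonresponse[ok])
  } else {
    bias <- mean(pn) - mean(pr)
    m_pr <- mean(pr); m_pn <- mean(pn)
  }
  structure(list(
    mean_pred_response = m_pr, mean_pred_nonresponse = m_pn,
    bias_points = bias, bias_sd_units = bias / pooled_sd,
    reported_sd = pooled_sd, reported = reported,
    per_participant = per_participant,
    n = c(response = length(pr), nonresponse = length(pn))
  ), class = "trigger_bias")
}

#' @export
print.trigger_bias <- function(x, ...) {
  cat("<trigger_bias> predicted affect at predicted nonresponses is ",
      sprintf("%+.2f", x$bias_points), " points (",
      sprintf("%+.3f", x$bias_sd_units), " SD) vs predicted responses\n",
      sep = "")
  invisible(x)
}

#' @method tidy trigger_bias
#' @export
tidy.trigger_bias <- function(x, ...) {
  tibble::tibble(
    mean_pred_response = x$mean_pred_response,
    mean_pred_nonresponse = x$mean_pred_nonresponse,
    bias_points = x$bias_points,
    bias_sd_units = x$bias_sd_units,
    n_pred_response = unname(x$n["response"]),
    n_pred_nonresponse = unname(x$n["nonresponse"])
  )
}
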