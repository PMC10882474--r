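# End-to-end orchestration: simulate -> score -> segment/label -> split ->
# personalised models -> relationship analysis, with per-stage seeds
# derived from one run seed.

#' Configuration of a full pipeline run
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort.
#' @param label_window_minutes Pseudo-label window (5, 30, 60 or 120;
#'   default 30).
#' @param lookback_minutes Feature lookbacks (1 = momentary).
#' @param battery Feature families (see [extract_features()]).
#' @param test_fraction Fraction of notification groups in the test set.
#' @param normalization `"train_stats"` (test normalised with training
#'   statistics; default, leakage-safe) or `"literal"` (each partition
#'   normalised with its own statistics, reproducing the original
#'   evaluation procedure).
#' @param variance_target Retained-variance target of the projection.
#' @param grid Forest hyperparameter grid.
#' @param n_folds Inner CV folds of the grid search.
#' @param nn_hidden,nn_epochs,nn_lr,nn_patience,nn_weight_decay,nn_ensemble
#'   Affect-network training settings (see [fit_affect_nn()]).
#' @param nn_bag_groups Train ensemble members on group-level bootstrap
#'   resamples (see [fit_affect_nn()]'s `groups`).
#' @param rec_calibrate Prevalence-calibrated receptivity prediction
#'   (see [predict.receptivity_fit()]).
#' @param sigma_cutoff Uncertainty cutoff, score points.
#' @param cluster_m Features kept for clustering.
#' @param k_candidates Candidate cluster counts.
#' @param accel_cutoff_hz Accelerometer low-pass cutoff, Hz (must be below
#'   half the accelerometer rate).
#' @param include_baselines Also fit the distribution-sampling baselines.
#' @param seed Run seed; every stochastic stage derives its own seed from
#'   it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       label_window_minutes = 30,
                       lookback_minutes = c(1, 5, 30, 60),
                       battery = c("hrv_time", "temp", "eda", "accel"),
                       test_fraction = 0.3,
                       normalization = c("train_stats", "literal"),
                       variance_target = 0.99,
                       grid = receptivity_grid(),
                       n_folds = 3L,
                       nn_hidden = c(256, 128, 64),
                       nn_epochs = 200L, nn_lr = 1e-3, nn_patience = 20L,
                       nn_weight_decay = 0,
                       nn_ensemble = 1L,
                       nn_bag_groups = FALSE,
                       rec_calibrate = FALSE,
                       sigma_cutoff = 6,
                       cluster_m = 10L,
                       k_candidates = 2L,
                       accel_cutoff_hz = 10,
                       include_baselines = FALSE,
                       seed = 1L) {
  normalization <- match.arg(normalization)
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Desk-scale pipeline configuration
#'
#' A small, fast profile used for simulation studies and examples: 5
#' participants x 2 days at reduced stream rates, the 5-minute label window
#' (with a fifth of the study's prompts per participant, label proximity is
#' worth more than the larger-but-noisier labelled sets of wider windows),
#' momentary + 5-minute lookbacks, a single-permutation forest grid with
#' prevalence-calibrated prediction, and a small strongly-regularised
#' affect-network ensemble. All knobs remain individually overridable.
#'
#' @param coupling_beta Affect-nonresponse coupling (0 for null cohorts).
#' @param seed Run seed (also the cohort seed).
#' @param cohort Optional replacement [cohort_config()] (defaults to the
#'   5-participant, 2-day profile).
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
desk_config <- function(coupling_beta = 0.08, seed = 1L, cohort = NULL, ...) {
  run_config(
    cohort = cohort %||%
      cohort_config(n_participants = 5L, n_days = 2L,
                    coupling_beta = coupling_beta,
                    eda_hz = 4, accel_hz = 16, seed = seed),
    label_window_minutes = 5,
    lookback_minutes = c(1, 5),
    battery = c("hrv_time", "temp", "eda", "accel"),
    grid = data.frame(n_estimators = 60, max_depth = 3,
                      min_samples_leaf = 2, min_samples_split = 2,
                      max_features = "sqrt", stringsAsFactors = FALSE),
    n_folds = 2L,
    nn_hidden = c(8, 4), nn_epochs = 1200L, nn_lr = 3e-3,
    nn_patience = 1200L, nn_weight_decay = 0.3, nn_ensemble = 9L,
    rec_calibrate = TRUE,
    accel_cutoff_hz = 5,
    seed = seed,
    ...
  )
}

# Segment ends (seconds) that can receive a label under the window: kept
# ahead of feature extraction so unlabelable segments are never computed.
labelable_ends <- function(t0, T_span, events, window_minutes) {
  ends <- t0 + seq(60, T_span, by = 30)
  end_min <- ends / 60
  ev <- sort(events$notify_minute)
  nxt <- findInterval(end_min, ev, left.open = TRUE) + 1L
  ok <- nxt <= length(ev)
  dist <- rep(Inf, length(ends))
  dist[ok] <- ev[nxt[ok]] - end_min[ok]
  ends[dist >= 0 & dist <= window_minutes]
}

#' Run the pipeline end to end
#'
#' Stages: `simulate` (synthetic cohort), `score` (composite affect),
#' `label` (segment grid + pseudo-labels), `split` (grouped stratified),
#' `train` (per-participant normaliser, projection, receptivity forest,
#' affect network, optional baselines, test-set predictions), `analyze`
#' (evaluation metrics, agreement statistics, clustering profile, affect
#' distribution comparison, trigger bias).
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, the labelled-segment
#'   table, split plan, predictions and analysis tables are written as
#'   delimited text alongside a dump of the configuration.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_result` list: `events`, `labeled`, `split`,
#'   `predictions`, `metrics`, `agreement`, `cluster_profile`,
#'   `distributions`, `bias`, `config`.
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) inform(sprintf(...))

  # --- simulate + score -------------------------------------------------
  say("simulate: %d participants", config$cohort$n_participants)
  cohort <- generate_cohort(config$cohort)
  events <- score_ema(cohort$events)

  # --- segment + label --------------------------------------------------
  say("label: window = %g min", config$label_window_minutes)
  labeled <- list()
  for (p in seq_along(cohort$signals)) {
    b <- cohort$signals[[p]]
    ev_p <- events[events$participant_id == b$participant_id, ]
    T_span <- min(max(b$rr$time_s), max(b$eda$time_s),
                  max(b$temperature$time_s), max(b$accel$time_s))
    ends <- labelable_ends(0, T_span, ev_p, config$label_window_minutes)
    if (length(ends) == 0) next
    segs <- make_segments(b, lookback_minutes = config$lookback_minutes,
                          battery = config$battery, end_s = ends,
                          accel_cutoff_hz = config$accel_cutoff_hz)
    labeled[[p]] <- pseudo_label(segs, ev_p, config$label_window_minutes)
  }
  labeled <- dplyr::bind_rows(labeled)
  feature_cols <- feature_battery_names(config$battery,
                                        config$lookback_minutes)
  # drop rows with missing features (insufficient history) for modelling
  labeled <- labeled[stats::complete.cases(labeled[feature_cols]), ]

  # --- split ------------------------------------------------------------
  split <- grouped_stratified_split(labeled, config$test_fraction,
                                    seed = derive_seed(config$seed, 2))
  labeled <- dplyr::inner_join(
    labeled,
    dplyr::select(split$assignments, "notification_id", "partition"),
    by = "notification_id")

  # --- per-participant models ------------------------------------------
  preds <- list()
  participants <- unique(labeled$participant_id)
  for (p in participants) {
    say("train: participant %s", p)
    d <- labeled[labeled$participant_id == p, ]
    tr <- d[d$partition == "train", ]; te <- d[d$partition == "test", ]
    if (nrow(tr) < 10 || nrow(te) < 2) next
    if (length(unique(tr$receptivity_label)) < 2) next

    norm <- withCallingHandlers(
      fit_normalizer(tr, feature_cols),
      warning = function(w) invokeRestart("muffleWarning"))
    tr_n <- apply_normalizer(norm, tr)
    te_n <- if (config$normalization == "literal") {
      norm_te <- withCallingHandlers(
        fit_normalizer(te, feature_cols),
        warning = function(w) invokeRestart("muffleWarning"))
      apply_normalizer(norm_te, te)
    } else {
      apply_normalizer(norm, te)
    }

    rf <- grid_search_receptivity(tr_n[feature_cols], tr_n$receptivity_label,
                                  tr_n$notification_id, grid = config$grid,
                                  n_folds = config$n_folds,
                                  seed = derive_seed(config$seed, 100 + p))

    proj <- fit_projection(tr_n[feature_cols], config$variance_target)
    tr_aff <- tr_n[!is.na(tr_n$affect_label), ]
    if (nrow(tr_aff) < 10) next
    nn <- withCallingHandlers(
      fit_affect_nn(apply_projection(proj, tr_aff[feature_cols]),
                    tr_aff$affect_label,
                    hidden = config$nn_hidden, epochs = config$nn_epochs,
                    lr = config$nn_lr, patience = config$nn_patience,
                    weight_decay = config$nn_weight_decay,
                    n_ensemble = config$nn_ensemble,
                    groups = if (isTRUE(config$nn_bag_groups))
                      tr_aff$notification_id else NULL,
                    seed = derive_seed(config$seed, 200 + p)),
      warning = function(w) invokeRestart("muffleWarning"))

    # predictions for every labelled segment: the held-out rows evaluate
    # the models; the full set feeds the relationship analysis, which
    # needs inferred affect at all (especially nonresponse) time points
    all_n <- dplyr::bind_rows(tr_n, te_n)
    all_raw <- dplyr::bind_rows(tr, te)
    aff_pred <- predict(nn, apply_projection(proj, all_n[feature_cols]))
    pp <- tibble::tibble(
      participant_id = p,
      notification_id = all_raw$notification_id,
      start_s = all_raw$start_s,
      partition = all_raw$partition,
      receptivity_label = all_raw$receptivity_label,
      affect_label = all_raw$affect_label,
      receptivity_pred = predict(rf, all_n[feature_cols],
                                 calibrate = isTRUE(config$rec_calibrate)),
      mu = aff_pred$mu, sigma = aff_pred$sigma,
      train_median_composite = median(tr_aff$affect_label)
    )
    if (config$include_baselines) {
      pp$receptivity_baseline <- baseline_classify(
        tr$receptivity_label, nrow(pp), seed = derive_seed(config$seed, 300 + p))
      pp$affect_baseline <- baseline_regress(
        tr_aff$affect_label, nrow(pp), seed = derive_seed(config$seed, 400 + p))
    }
    preds[[length(preds) + 1L]] <- pp
  }
  predictions <- dplyr::bind_rows(preds)
  if (nrow(predictions) == 0) abort("No participant had enough data to model.")
  predictions <- filter_by_uncertainty(predictions, config$sigma_cutoff,
                                       quiet = TRUE)

  # --- analyze ----------------------------------------------------------
  # model quality is judged on the held-out rows only; the relationship
  # and bias analyses use predictions on every labelled segment
  say("analyze: %d predicted segments", nrow(predictions))
  test_pred <- predictions[predictions$partition == "test", ]
  metrics <- list(
    receptivity = evaluate_predictions(test_pred$receptivity_label,
                                       test_pred$receptivity_pred,
                                       test_pred$participant_id),
    affect_rmse = {
      resp <- test_pred[!is.na(test_pred$affect_label) &
                          test_pred$kept_after_filter, ]
      evaluate_predictions(resp$affect_label, resp$mu, resp$participant_id)
    }
  )

  kept <- predictions[predictions$kept_after_filter, ]
  agree_a <- kept$receptivity_pred == "responded"
  agree_b <- kept$mu < kept$train_median_composite  # predicted positive state
  agreement <- tibble::tibble(
    kappa = cohen_kappa(agree_a, agree_b)$kappa,
    point_biserial_r = point_biserial(kept$receptivity_pred, kept$mu)$r,
    n = nrow(kept)
  )

  cl_feats <- select_cluster_features(labeled, feature_cols,
                                      m = config$cluster_m)
  norm_all <- withCallingHandlers(
    fit_normalizer(labeled, cl_feats$feature),
    warning = function(w) invokeRestart("muffleWarning"))
  lab_n <- apply_normalizer(norm_all, labeled)
  clus <- cluster_segments(lab_n[cl_feats$feature],
                           k_candidates = config$k_candidates,
                           seed = derive_seed(config$seed, 5))
  cluster_profile <- profile_clusters(clus, labeled)

  # distribution comparison at the *true* response status: affect is
  # reported at responses and can only be inferred at nonresponses
  distributions <- compare_affect_distributions(
    reported_response = kept$affect_label[!is.na(kept$affect_label)],
    predicted_response = kept$mu[kept$receptivity_label == "responded"],
    predicted_nonresponse = kept$mu[kept$receptivity_label == "no_response"]
  )
  bias <- trigger_bias(predictions, config$sigma_cutoff)

  result <- structure(list(
    events = events, labeled = labeled, split = split,
    predictions = predictions, metrics = metrics, agreement = agreement,
    cluster_features = cl_feats, clustering = clus,
    cluster_profile = cluster_profile, distributions = distributions,
    bias = bias, config = config
  ), class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_csv(x, file.path(outdir, f), progress = FALSE)
  w(dplyr::select(result$events, "participant_id", "notify_minute",
                  "responded", "composite", "pa_mean", "na_mean"),
    "scores.csv")
  w(result$labeled, "labeled_segments.csv")
  w(result$split$assignments, "split_plan.csv")
  w(result$predictions, "predictions.csv")
  w(result$distributions$ecdf, "affect_ecdf.csv")
  w(result$distributions$summary, "affect_summary.csv")
  w(tidy(result$cluster_profile), "cluster_profile.csv")
  w(tidy(result$bias), "trigger_bias.csv")
  w(result$agreement, "agreement.csv")
  dput(unclass(result$config)[setdiff(names(result$config), "grid")],
       file.path(outdir, "run_config.txt"))
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$labeled), " labelled segments (",
      sum(x$predictions$partition == "test"), " held out)\n", sep = "")
  print(x$bias)
  invisible(x)
}

#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  rec <- x$metrics$receptivity
  dplyr::bind_cols(
    tibble::tibble(
      n_labeled = nrow(x$labeled),
      n_test = sum(x$predictions$partition == "test"),
      receptivity_f1 = rec$value[rec$metric == "f1"],
      affect_rmse = x$metrics$affect_rmse$value[1],
      kappa = x$agreement$kappa,
      point_biserial_r = x$agreement$point_biserial_r
    ),
    tidy(x$bias)[c("bias_points", "bias_sd_units")]
  )
}
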