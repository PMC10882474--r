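# Synthetic cohort generation: EMA schedule, latent affect, response
# mechanism, item sets and physiological streams. All sampling uses the
# session RNG; generate_cohort() seeds it once from config$seed so a
# (config, seed) pair reproduces the cohort exactly.

#' Generate the EMA notification schedule
#'
#' Draws `prompts_per_day` notification times per participant-day with
#' consecutive gaps uniform in `[gap_min_minutes, gap_max_minutes]`; the
#' first prompt of each day is placed uniformly in the slack the gaps leave.
#'
#' @param config A [cohort_config()].
#' @return Tibble with `participant_id`, `day`, `prompt` and `notify_minute`
#'   (minutes since study start).
#' @export
generate_schedule <- function(config) {
  validate_cohort_config(config)
  n_gaps <- config$prompts_per_day - 1L
  rows <- vector("list", config$n_participants * config$n_days)
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    for (d in seq_len(config$n_days)) {
      gaps <- runif(n_gaps, config$gap_min_minutes, config$gap_max_minutes)
      span <- sum(gaps)
      start <- runif(1, 0, 1440 - span)
      times <- start + c(0, cumsum(gaps))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        participant_id = p, day = d,
        prompt = seq_len(config$prompts_per_day),
        notify_minute = (d - 1L) * 1440 + times
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a latent affect trace
#'
#' One value per minute on the composite 13-91 scale: an AR(1) process
#' around `affect_mean` plus negative-mood episodes (step elevations of
#' `episode_magnitude` points), clipped to the scale. The raw (pre-clipping)
#' series is kept alongside for diagnostics.
#'
#' @param config A [cohort_config()].
#' @param participant_id Identifier stored with the trace.
#' @return Tibble with `participant_id`, `minute`, `affect_raw` (pre-clip)
#'   and `affect` (clipped to 13-91).
#' @export
generate_affect_trace <- function(config, participant_id = 1L) {
  n <- as.integer(config$n_days * 1440)
  phi <- config$affect_ar_coefficient
  m <- config$affect_mean
  eps <- rnorm(n, 0, config$affect_noise_sd)
  # start at the stationary distribution so the long-run mean holds from t=0
  x0 <- if (phi > 0 && config$affect_noise_sd > 0) {
    rnorm(1, 0, config$affect_noise_sd / sqrt(1 - phi^2))
  } else eps[1]
  dev <- as.numeric(stats::filter(c(x0, eps[-1]), phi, method = "recursive",
                                  init = 0))
  x <- m + dev

  bump <- numeric(n)
  n_ep <- rpois(1, config$episode_rate_per_day * config$n_days)
  if (n_ep > 0) {
    starts <- sort(runif(n_ep, 0, n))
    durs <- runif(n_ep, config$episode_duration_minutes[1],
                  config$episode_duration_minutes[2])
    for (i in seq_len(n_ep)) {
      idx <- which(seq_len(n) >= starts[i] & seq_len(n) < starts[i] + durs[i])
      bump[idx] <- pmax(bump[idx], config$episode_magnitude)
    }
  }
  raw <- x + bump
  tibble::tibble(
    participant_id = participant_id,
    minute = seq_len(n) - 1L,
    affect_raw = raw,
    affect = pmin(SCORE_MAX, pmax(SCORE_MIN, raw))
  )
}

#' Sample the response/nonresponse outcome of prompts
#'
#' Two independent causes of a missed prompt: an affect-driven mechanism with
#' response probability
#' `plogis(base_response_logit - coupling_beta * (affect - affect_mean))`,
#' and an activity-driven mechanism that misses the prompt with probability
#' `activity_nonresponse_prob` regardless of affect. When the affect
#' mechanism misses, the recorded cause is `"affect"`; an activity miss is
#' recorded only when the affect mechanism would have responded.
#'
#' @param affect_value Vector of latent scores at notification times.
#' @param config A [cohort_config()].
#' @return Tibble with `responded` (logical) and `cause`
#'   (`"affect"`, `"activity"` or `"none"`).
#' @export
sample_response <- function(affect_value, config) {
  p <- stats::plogis(config$base_response_logit -
                       config$coupling_beta * (affect_value - config$affect_mean))
  affect_ok <- runif(length(affect_value)) < p
  activity_miss <- runif(length(affect_value)) < config$activity_nonresponse_prob
  responded <- affect_ok & !activity_miss
  cause <- dplyr::case_when(
    !affect_ok ~ "affect",
    activity_miss ~ "activity",
    TRUE ~ "none"
  )
  tibble::tibble(responded = responded, cause = cause)
}

#' Draw a 13-item response vector consistent with a target composite
#'
#' Items are generated on the "scored" scale (negative items as-is, positive
#' items inverted), each in 1-7, so that the recomputed composite equals the
#' rounded target plus symmetric integer noise of at most +/-2 points
#' (clamped to the 13-91 support).
#'
#' @param affect_value Target composite score (13-91).
#' @return Named integer vector of the 13 items (`item_1` .. `item_13`;
#'   items 1-9 negative, 10-13 positive, on their original 1-7 scales).
#' @export
generate_items <- function(affect_value) {
  stopifnot(affect_value >= SCORE_MIN, affect_value <= SCORE_MAX)
  target <- round(affect_value) + sample(-2:2, 1)
  target <- min(SCORE_MAX, max(SCORE_MIN, target))
  y <- pmin(7L, pmax(1L, round(target / 13) + sample(-1:1, 13, replace = TRUE)))
  d <- target - sum(y)
  pick <- function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)
  while (d != 0L) {
    if (d > 0L) {
      i <- pick(which(y < 7L)); y[i] <- y[i] + 1L; d <- d - 1L
    } else {
      i <- pick(which(y > 1L)); y[i] <- y[i] - 1L; d <- d + 1L
    }
  }
  items <- c(y[1:9], 8L - y[10:13])
  names(items) <- paste0("item_", 1:13)
  items
}

#' Synthesize wearable signal streams for one participant
#'
#' Streams follow the latent affect trace: mean heart rate at minute t is
#' `baseline_hr + hr_affect_slope * (affect_t - affect_mean)` with RR
#' intervals drawn around `60000 / HR`; electrodermal activity is a slow
#' tonic drift plus phasic responses whose Poisson rate rises with affect;
#' skin temperature is a slow sinusoid plus noise; accelerometer magnitude
#' is baseline noise with walking-style bouts around activity-driven missed
#' prompts (plus sparse background bouts).
#'
#' All coupling forms are simulation stand-ins chosen for plausibility, not
#' estimates from data.
#'
#' @param trace Output of [generate_affect_trace()].
#' @param config A [cohort_config()].
#' @param activity_minutes Notification minutes of activity-caused
#'   nonresponses; a movement bout is placed around each.
#' @return A `signal_bundle`: list with `rr` (tibble `time_s`, `rr_ms`),
#'   `eda`, `temperature`, `accel` (tibbles `time_s`, `value`) and `rates`.
#' @export
synthesize_signals <- function(trace, config, activity_minutes = numeric()) {
  n_min <- nrow(trace)
  affect <- trace$affect
  hr <- config$baseline_hr + config$hr_affect_slope * (affect - config$affect_mean)
  hr <- pmax(35, pmin(190, hr))

  # --- RR: per-minute beat counts matching the target rate, intervals
  # rescaled to fill each minute (count quantisation ~0.5 bpm, well below
  # the affect-driven rate variation)
  mean_rr <- 60000 / hr
  k <- pmax(20L, as.integer(round(hr)))
  idx <- rep.int(seq_len(n_min), k)
  raw <- pmax(250, rnorm(length(idx), mean_rr[idx], config$rr_sd_ms))
  gsum <- as.numeric(rowsum(raw, idx))
  rr_ms <- raw * (60000 / gsum)[idx]
  cum <- cumsum(rr_ms)
  goff <- c(0, cum[cumsum(k)])[idx]
  time_s <- ((idx - 1L) * 60000 + (cum - goff)) / 1000
  rr <- tibble::tibble(time_s = time_s, rr_ms = rr_ms)

  # --- EDA: tonic drift + affect-rate phasic impulses smoothed by exp decay
  ne <- n_min * 60 * config$eda_hz
  te <- (seq_len(ne) - 1L) / config$eda_hz
  tonic <- 2 + 0.5 * sin(2 * pi * te / (3600 * 4) + runif(1, 0, 2 * pi)) +
    as.numeric(stats::filter(rnorm(ne, 0, 0.003), 0.999, method = "recursive"))
  rate_min <- pmax(0, 0.25 + 0.03 * (affect - config$affect_mean))
  impulses <- rbinom(ne, 1L, pmin(0.5, rate_min[pmin(n_min, floor(te / 60) + 1L)] /
                                    (60 * config$eda_hz))) *
    rlnorm(ne, log(0.3), 0.5)
  decay <- exp(-1 / (2 * config$eda_hz))           # ~2 s SCR recovery
  phasic <- as.numeric(stats::filter(impulses, decay, method = "recursive"))
  eda <- tibble::tibble(time_s = te,
                        value = pmax(0.01, tonic + phasic + rnorm(ne, 0, 0.01)))

  # --- skin temperature: slow sinusoid + noise, clipped to the band
  nt <- n_min * 60 * config$temp_hz
  tt <- (seq_len(nt) - 1L) / config$temp_hz
  temp_val <- 33 + 0.8 * sin(2 * pi * tt / (3600 * 6) + runif(1, 0, 2 * pi)) +
    rnorm(nt, 0, 0.05)
  temp_val <- pmin(config$temp_band[2], pmax(config$temp_band[1], temp_val))
  temperature <- tibble::tibble(time_s = tt, value = temp_val)

  # --- accelerometer magnitude: 1 g + noise, walking bouts ~1.8 Hz
  na_ <- n_min * 60 * config$accel_hz
  ta <- (seq_len(na_) - 1L) / config$accel_hz
  acc <- 1 + rnorm(na_, 0, 0.02)
  bout_minutes <- activity_minutes
  n_bg <- rpois(1, 2 * config$n_days)              # background movement
  if (n_bg > 0) bout_minutes <- c(bout_minutes, runif(n_bg, 0, n_min))
  for (bm in bout_minutes) {
    lo <- max(0, (bm - 10) * 60); hi <- min(n_min * 60, (bm + 2) * 60)
    sel <- ta >= lo & ta < hi
    acc[sel] <- acc[sel] + 0.4 * abs(sin(2 * pi * 1.8 * ta[sel])) +
      rnorm(sum(sel), 0, 0.05)
  }
  accel <- tibble::tibble(time_s = ta, value = acc)

  structure(list(
    participant_id = trace$participant_id[1],
    rr = rr, eda = eda, temperature = temperature, accel = accel,
    rates = list(eda_hz = config$eda_hz, temp_hz = config$temp_hz,
                 accel_hz = config$accel_hz)
  ), class = "signal_bundle")
}

#' Generate a full synthetic cohort
#'
#' Seeds the RNG from `config$seed` and runs schedule, latent affect,
#' response sampling, item generation, onset latency (log-normal, responses
#' exceeding `response_cap_seconds` converted to nonresponses) and signal
#' synthesis for every participant.
#'
#' @param config A [cohort_config()].
#' @param signals Set `FALSE` to skip physiological stream synthesis (EMA
#'   log only; much faster when only the log is needed).
#' @return An `ema_cohort`: list with `events` (one row per notification:
#'   ids, times, `responded`, `cause`, `onset_minute`, `latency_s`,
#'   `affect_latent`, `item_1..item_13`), `signals` (list of
#'   `signal_bundle` keyed by participant), `traces` (list of affect
#'   traces) and `config`.
#' @export
generate_cohort <- function(config, signals = TRUE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  schedule <- generate_schedule(config)
  traces <- list(); bundles <- list(); ev <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    tr <- generate_affect_trace(config, participant_id = p)
    sched_p <- schedule[schedule$participant_id == p, ]
    a <- tr$affect[pmin(nrow(tr), floor(sched_p$notify_minute) + 1L)]
    resp <- sample_response(a, config)
    lat <- rlnorm(nrow(sched_p), config$onset_meanlog, config$onset_sdlog)
    over_cap <- resp$responded & lat > config$response_cap_seconds
    resp$responded[over_cap] <- FALSE       # survey closed before onset
    lat[!resp$responded] <- NA_real_
    items <- matrix(NA_integer_, nrow(sched_p), 13,
                    dimnames = list(NULL, paste0("item_", 1:13)))
    for (i in which(resp$responded)) items[i, ] <- generate_items(a[i])
    ev[[p]] <- dplyr::bind_cols(
      sched_p,
      resp,
      tibble::tibble(latency_s = lat,
                     onset_minute = sched_p$notify_minute + lat / 60,
                     affect_latent = a),
      tibble::as_tibble(items)
    )
    traces[[p]] <- tr
    if (signals) {
      act_min <- sched_p$notify_minute[!resp$responded & resp$cause == "activity"]
      bundles[[p]] <- synthesize_signals(tr, config, activity_minutes = act_min)
    }
  }
  structure(list(events = dplyr::bind_rows(ev),
                 signals = if (signals) bundles else NULL,
                 traces = traces, config = config),
            class = "ema_cohort")
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat("<ema_cohort> ", length(x$traces), " participants, ",
      nrow(x$events), " notifications (",
      sprintf("%.1f%%", 100 * mean(x$events$responded)), " responded)\n",
      sep = "")
  invisible(x)
}
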