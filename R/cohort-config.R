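#' Configuration for a synthetic EMA + wearable cohort
#'
#' Bundles every knob of the synthetic cohort generator. The defaults emulate
#' the structure of a 45-participant, 10-day ambulatory study: 10 prompts per
#' day at random gaps of 15-90 minutes, a 90-second window to begin the
#' survey, a composite affect score on the 13-91 scale concentrated near the
#' positive (low) end, response probability that falls as momentary affect
#' becomes more negative, heart rate positively coupled to the affect score,
#' and a second, activity-driven cause of missed prompts.
#'
#' The latent affect trace is a first-order autoregressive process at
#' 1-minute resolution plus occasional negative-mood episodes (a step
#' elevation of the score lasting `episode_duration_minutes`). The episodes
#' are the generator's stand-in for the distinct high-score states real
#' participants visit; together with the activity-driven misses they make the
#' nonresponse-time affect distribution a two-component mixture.
#'
#' @param n_participants Number of participants.
#' @param n_days Days of observation per participant.
#' @param prompts_per_day EMA notifications per day.
#' @param gap_min_minutes,gap_max_minutes Bounds of the uniform inter-prompt
#'   gap, minutes.
#' @param response_cap_seconds Time allowed to begin the survey; longer
#'   latencies are converted to nonresponses.
#' @param affect_mean Long-run mean of the AR(1) component of the latent
#'   composite score (13-91 scale; higher = more negative).
#' @param affect_ar_coefficient AR(1) coefficient in `[0, 1)` at 1-minute
#'   resolution. The default 0.985 gives a mood half-life of about 46
#'   minutes, consistent with pseudo-labelling windows of tens of minutes
#'   remaining informative.
#' @param affect_noise_sd Innovation SD of the AR(1) process, score points.
#' @param coupling_beta Logit slope of nonresponse per score point: the
#'   affect-driven response probability is
#'   `plogis(base_response_logit - coupling_beta * (affect - affect_mean))`.
#'   Zero decouples receptivity from affect (null cohorts).
#' @param base_response_logit Response logit at mean affect.
#' @param hr_affect_slope Heart-rate change per score point, bpm.
#' @param activity_nonresponse_prob Probability a prompt is missed because
#'   of physical activity, independent of affect.
#' @param episode_rate_per_day Expected negative-mood episodes per day.
#' @param episode_magnitude Score elevation during an episode, points.
#' @param episode_duration_minutes Length-2 range of episode durations.
#' @param baseline_hr Resting heart rate at mean affect, bpm.
#' @param rr_sd_ms Beat-to-beat RR variability, ms.
#' @param eda_hz,temp_hz,accel_hz Sampling rates of the electrodermal,
#'   skin-temperature and accelerometer-magnitude streams, Hz. The study
#'   devices sampled EDA at 256 Hz; lower rates are routinely used for
#'   desk-scale simulation since every downstream feature is rate-aware.
#' @param temp_band Physiologic band for skin temperature, degrees C.
#' @param onset_meanlog,onset_sdlog Log-normal parameters of the notification
#'   to survey-onset latency, seconds.
#' @param seed Integer seed; fixes the whole cohort.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 45L,
                          n_days = 10L,
                          prompts_per_day = 10L,
                          gap_min_minutes = 15,
                          gap_max_minutes = 90,
                          response_cap_seconds = 90,
                          affect_mean = 24.5,
                          affect_ar_coefficient = 0.985,
                          affect_noise_sd = 1,
                          coupling_beta = 0.08,
                          base_response_logit = 1.9,
                          hr_affect_slope = 0.35,
                          activity_nonresponse_prob = 0.08,
                          episode_rate_per_day = 2,
                          episode_magnitude = 20,
                          episode_duration_minutes = c(30, 90),
                          baseline_hr = 70,
                          rr_sd_ms = 25,
                          eda_hz = 4,
                          temp_hz = 1,
                          accel_hz = 16,
                          temp_band = c(28, 40),
                          onset_meanlog = log(8.7),
                          onset_sdlog = 1.3,
                          seed = 1L) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1, cfg$n_days >= 1, cfg$prompts_per_day >= 1,
    cfg$gap_min_minutes > 0,
    cfg$affect_ar_coefficient >= 0, cfg$affect_ar_coefficient < 1,
    cfg$affect_noise_sd >= 0,
    cfg$activity_nonresponse_prob >= 0, cfg$activity_nonresponse_prob <= 1,
    length(cfg$temp_band) == 2, length(cfg$episode_duration_minutes) == 2
  )
  if (cfg$gap_min_minutes >= cfg$gap_max_minutes) {
    abort("`gap_min_minutes` must be strictly below `gap_max_minutes`.")
  }
  # a day must be able to hold all prompts at the minimum gap
  if ((cfg$prompts_per_day - 1) * cfg$gap_min_minutes >= 1440) {
    abort("Day too short to fit `prompts_per_day` prompts at `gap_min_minutes`.")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_participants, " participants x ", x$n_days,
      " days x ", x$prompts_per_day, " prompts/day; coupling_beta = ",
      x$coupling_beta, ", activity_nonresponse_prob = ",
      x$activity_nonresponse_prob, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Affect clipping bounds of the composite scale.
SCORE_MIN <- 13
SCORE_MAX <- 91
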