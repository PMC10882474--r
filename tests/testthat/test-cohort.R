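test_that("schedules respect gap bounds and are reproducible", {
  cfg <- cohort_config(n_participants = 2, n_days = 3, seed = 21)
  set.seed(cfg$seed)
  sch <- generate_schedule(cfg)
  expect_equal(nrow(sch), 2 * 3 * 10)
  gaps <- sch |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(g = list(diff(.data$notify_minute)), .groups = "drop")
  all_gaps <- unlist(gaps$g)
  expect_true(all(all_gaps >= 15 & all_gaps <= 90))
  # all prompts land inside their day
  expect_true(all(sch$notify_minute >= (sch$day - 1) * 1440 &
                    sch$notify_minute < sch$day * 1440))
  set.seed(cfg$seed)
  sch2 <- generate_schedule(cfg)
  expect_identical(sch, sch2)
  expect_error(cohort_config(prompts_per_day = 100, gap_min_minutes = 20,
                             gap_max_minutes = 30), "too short")
  expect_error(cohort_config(gap_min_minutes = 90, gap_max_minutes = 15),
               "strictly below")
})

test_that("inter-prompt gaps are uniform on [15, 90] in the mean", {
  cfg <- cohort_config(n_participants = 10, n_days = 112, seed = 22)
  set.seed(cfg$seed)
  sch <- generate_schedule(cfg)
  gaps <- sch |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(g = list(diff(.data$notify_minute)), .groups = "drop")
  all_gaps <- unlist(gaps$g)   # about 10,000 gaps
  expect_gt(length(all_gaps), 9999)
  se <- sqrt((90 - 15)^2 / 12 / length(all_gaps))
  expect_lt(abs(mean(all_gaps) - 52.5), 4 * se)
})

test_that("latent affect traces are clipped AR(1) with the stated memory", {
  cfg0 <- cohort_config(n_participants = 1, n_days = 1,
                        affect_ar_coefficient = 0, affect_noise_sd = 0,
                        episode_rate_per_day = 0, affect_mean = 30, seed = 23)
  set.seed(23)
  tr0 <- generate_affect_trace(cfg0)
  expect_true(all(tr0$affect == 30))

  cfg <- cohort_config(n_participants = 1, n_days = 7,
                       affect_ar_coefficient = 0.9, affect_noise_sd = 2,
                       episode_rate_per_day = 0, seed = 24)
  set.seed(24)
  tr <- generate_affect_trace(cfg)
  ac <- cor(tr$affect_raw[-1], tr$affect_raw[-nrow(tr)])
  expect_equal(ac, 0.9, tolerance = 0.03)
  expect_true(all(tr$affect >= 13 & tr$affect <= 91))
  expect_equal(mean(tr$affect_raw), cfg$affect_mean, tolerance = 1.5)
})

test_that("response sampling follows the two-cause logistic mechanism", {
  cfg <- cohort_config(coupling_beta = 0, activity_nonresponse_prob = 0,
                       base_response_logit = 1.2, seed = 25)
  set.seed(25)
  r <- sample_response(rep(30, 2e4), cfg)
  expect_equal(mean(r$responded), plogis(1.2), tolerance = 0.01)
  expect_true(all(r$cause[r$responded] == "none"))

  cfg2 <- cohort_config(activity_nonresponse_prob = 1, seed = 25)
  r2 <- sample_response(rep(30, 100), cfg2)
  expect_true(all(!r2$responded))

  # planted coupling: affect higher at nonresponses
  cfg3 <- cohort_config(coupling_beta = 0.08, activity_nonresponse_prob = 0,
                        seed = 26)
  set.seed(26)
  a <- runif(1e4, 14, 60)
  r3 <- sample_response(a, cfg3)
  expect_gt(mean(a[!r3$responded]), mean(a[r3$responded]))
  expect_true(all(r3$cause %in% c("affect", "activity", "none")))
})

test_that("item generation reconstructs the target composite", {
  set.seed(27)
  lo <- generate_items(13)
  expect_true(all(lo[1:9] == 1) || sum(lo[1:9]) + sum(8 - lo[10:13]) <= 15)
  expect_lte(score_composite(lo[1:9], lo[10:13]), 15)
  hi <- generate_items(91)
  expect_gte(score_composite(hi[1:9], hi[10:13]), 89)
  recon <- replicate(1000, {
    it <- generate_items(40)
    score_composite(it[1:9], it[10:13])
  })
  expect_true(all(abs(recon - 40) <= 4))
  expect_lt(abs(mean(recon) - 40), 1)
  expect_error(generate_items(5), "affect_value")
})

test_that("synthesized signals couple heart rate to affect as configured", {
  cfg0 <- cohort_config(n_participants = 1, n_days = 1, hr_affect_slope = 0,
                        eda_hz = 4, accel_hz = 16, seed = 28)
  set.seed(28)
  tr <- generate_affect_trace(cfg0)
  b0 <- synthesize_signals(tr, cfg0)
  minute <- floor(b0$rr$time_s / 60) + 1
  hr_min <- 60000 / tapply(b0$rr$rr_ms, minute, mean)
  n <- min(length(hr_min), nrow(tr))
  expect_lt(abs(cor(hr_min[1:n], tr$affect[1:n])), 0.05)

  cfg1 <- cohort_config(n_participants = 1, n_days = 1, hr_affect_slope = 0.35,
                        eda_hz = 4, accel_hz = 16, seed = 28)
  set.seed(28)
  tr1 <- generate_affect_trace(cfg1)
  b1 <- synthesize_signals(tr1, cfg1)
  minute1 <- floor(b1$rr$time_s / 60) + 1
  hr1 <- 60000 / tapply(b1$rr$rr_ms, minute1, mean)
  n1 <- min(length(hr1), nrow(tr1))
  expect_gt(cor(hr1[1:n1], tr1$affect[1:n1]), 0.5)

  expect_true(all(b1$rr$rr_ms > 0))
  expect_true(all(diff(b1$rr$time_s) > 0))
  expect_true(all(b1$temperature$value >= cfg1$temp_band[1] &
                    b1$temperature$value <= cfg1$temp_band[2]))
  expect_true(all(b1$eda$value > 0))
})

test_that("full cohorts are deterministic and enforce the response cap", {
  cfg <- tiny_cohort_config(n_days = 2L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$signals[[1]]$rr, c2$signals[[1]]$rr)
  ev <- c1$events
  expect_true(all(ev$latency_s[ev$responded] <= cfg$response_cap_seconds))
  expect_true(all(is.na(ev$latency_s[!ev$responded])))
  it <- as.matrix(ev[paste0("item_", 1:13)])
  expect_true(all(is.na(it[!ev$responded, ])))
  expect_true(all(!is.na(it[ev$responded, ])))
})

test_that("cohorts round-trip through the delimited text format", {
  cfg <- tiny_cohort_config()
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "ema_log.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back$events$responded, co$events$responded)
  expect_equal(back$events$notify_minute, co$events$notify_minute,
               tolerance = 1e-4)
  expect_equal(back$events$item_3, co$events$item_3)
  expect_equal(back$signals[[1]]$rr$rr_ms, co$signals[[1]]$rr$rr_ms,
               tolerance = 1e-6)
  expect_equal(back$signals[[1]]$rates$eda_hz, cfg$eda_hz)
})
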