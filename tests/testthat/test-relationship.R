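test_that("cluster-feature selection ranks by correlation with receptivity", {
  set.seed(12)
  n <- 400
  lab <- tibble::tibble(
    receptivity_label = rep(c("responded", "no_response"), each = n / 2),
    f_perfect = as.numeric(rep(c(1, 0), each = n / 2)),
    f_noise1 = rnorm(n), f_noise2 = rnorm(n), f_const = 1
  )
  sel <- suppressWarnings(select_cluster_features(
    lab, c("f_perfect", "f_noise1", "f_noise2", "f_const"), m = 2))
  expect_equal(sel$feature[1], "f_perfect")
  expect_equal(sel$abs_r[1], 1)
  expect_false("f_const" %in% sel$feature)
  expect_warning(
    big <- select_cluster_features(lab, c("f_noise1", "f_noise2"), m = 10),
    "returning all")
  expect_equal(nrow(big), 2)
  # pure noise at large n: small correlations
  set.seed(13)
  lab2 <- tibble::tibble(
    receptivity_label = sample(c("responded", "no_response"), 1e4, TRUE),
    a = rnorm(1e4), b = rnorm(1e4))
  sel2 <- select_cluster_features(lab2, c("a", "b"), m = 2)
  expect_true(all(sel2$abs_r < 0.05))
})

test_that("k-means clustering separates blobs and is seeded", {
  set.seed(14)
  x <- rbind(matrix(rnorm(100, 0, 0.05), 50, 2),
             matrix(rnorm(100, 5, 0.05), 50, 2))
  res <- cluster_segments(x, k_candidates = 2, seed = 3)
  expect_gt(res$silhouette, 0.9)
  blob <- rep(0:1, each = 50)
  agree <- max(mean(res$assignments == blob),
               mean(res$assignments == 1 - blob))
  expect_equal(agree, 1)
  res2 <- cluster_segments(x, k_candidates = 2, seed = 3)
  expect_identical(res$assignments, res2$assignments)
  expect_error(cluster_segments(x[1:3, ], k_candidates = 3), "below")
})

test_that("cluster profiles reproduce chi-square and F oracles", {
  # contingency [[85,15],[78,22]] by construction
  lab <- tibble::tibble(
    participant_id = rep(1:2, 100),
    receptivity_label = c(rep("responded", 85), rep("no_response", 15),
                          rep("responded", 78), rep("no_response", 22)),
    affect_label = NA_real_
  )
  resp_rows <- lab$receptivity_label == "responded"
  lab$affect_label[resp_rows] <- rnorm(sum(resp_rows), 26, 3)
  res <- structure(list(assignments = rep(0:1, each = 100)),
                   class = "cluster_result")
  prof <- profile_clusters(res, lab)
  tab <- matrix(c(85, 15, 78, 22), 2, byrow = TRUE)
  expect_equal(prof$chisq$statistic, oracle_chisq(tab), tolerance = 1e-9)
  expect_equal(round(prof$chisq$statistic, 2), 1.62, tolerance = 0.01)
  expect_equal(prof$chisq$df, 1)

  # identical compositions: chi-square of zero
  lab0 <- lab
  lab0$receptivity_label <- rep(c(rep("responded", 4), "no_response"), 40)
  prof0 <- profile_clusters(res, lab0)
  expect_equal(prof0$chisq$statistic, 0, tolerance = 1e-12)

  # well-separated affect means across clusters: F matches the oracle on
  # participant-centred values and is large
  lab2 <- tibble::tibble(
    participant_id = rep(1:2, each = 100),
    receptivity_label = "responded",
    affect_label = c(rnorm(50, 24, 0.5), rnorm(50, 28, 0.5),
                     rnorm(50, 24, 0.5), rnorm(50, 28, 0.5))
  )
  cl <- rep(rep(0:1, each = 50), 2)
  prof2 <- profile_clusters(structure(list(assignments = cl),
                                      class = "cluster_result"), lab2)
  centred <- unlist(tapply(lab2$affect_label, lab2$participant_id,
                           function(v) v - mean(v)))
  expect_equal(prof2$anova$statistic,
               oracle_oneway_f(centred, cl), tolerance = 1e-6)
  expect_gt(prof2$anova$statistic, 100)
  expect_lt(prof2$anova$p_value, 0.001)
  d <- tidy(prof2)
  expect_gt(d$mean_composite[d$cluster == 1], d$mean_composite[d$cluster == 0])
})

test_that("chi-square is invariant to swapping cluster or response labels", {
  lab <- tibble::tibble(
    participant_id = 1,
    receptivity_label = sample(rep(c("responded", "no_response"), c(70, 30))),
    affect_label = NA_real_)
  cl <- rep(0:1, 50)
  s1 <- profile_clusters(structure(list(assignments = cl),
                                   class = "cluster_result"), lab)
  s2 <- profile_clusters(structure(list(assignments = 1L - cl),
                                   class = "cluster_result"), lab)
  lab3 <- lab
  lab3$receptivity_label <- ifelse(lab$receptivity_label == "responded",
                                   "no_response", "responded")
  s3 <- profile_clusters(structure(list(assignments = cl),
                                   class = "cluster_result"), lab3)
  expect_equal(s1$chisq$statistic, s2$chisq$statistic, tolerance = 1e-12)
  expect_equal(s1$chisq$statistic, s3$chisq$statistic, tolerance = 1e-12)
})

test_that("Cohen's kappa matches hand computations and the exhaustive oracle", {
  expect_equal(cohen_kappa(c(1, 1, 0), c(1, 1, 0))$kappa, 1)
  # 2x2 counts [[20,5],[10,15]]
  a <- c(rep(1, 25), rep(0, 25))
  b <- c(rep(1, 20), rep(0, 5), rep(1, 10), rep(0, 15))
  k <- cohen_kappa(a, b)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
  expect_equal(k$p_observed, 0.7)
  expect_equal(k$p_expected, 0.5)
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
  expect_false(cohen_kappa(rep(1, 4), rep(1, 4))$defined)
  # exhaustive small-instance agreement with the brute-force oracle
  for (i in 1:50) {
    set.seed(i)
    a2 <- sample(0:1, 6, replace = TRUE)
    b2 <- sample(0:1, 6, replace = TRUE)
    k2 <- cohen_kappa(a2, b2)
    if (k2$defined) expect_equal(k2$kappa, oracle_kappa(a2, b2),
                                 tolerance = 1e-12)
  }
  # independent labels at large n: near zero
  set.seed(15)
  expect_lt(abs(cohen_kappa(sample(0:1, 1e4, TRUE),
                            sample(0:1, 1e4, TRUE))$kappa), 0.05)
})

test_that("point-biserial equals Pearson with 0/1 coding", {
  r <- point_biserial(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(r$r, cor(c(0, 0, 1, 1), 1:4), tolerance = 1e-12)
  expect_equal(r$r, 0.894, tolerance = 1e-3)
  for (i in 1:20) {
    set.seed(i)
    b <- sample(c("x", "y"), 10, replace = TRUE)
    v <- rnorm(10)
    if (length(unique(b)) == 2) {
      expect_equal(point_biserial(b, v)$r,
                   cor(as.numeric(factor(b)) - 1, v), tolerance = 1e-12)
    }
  }
  expect_false(point_biserial(rep(1, 5), rnorm(5))$defined)
  expect_false(point_biserial(c(0, 1, 0, 1), rep(2, 4))$defined)
  set.seed(16)
  expect_lt(abs(point_biserial(sample(0:1, 1e4, TRUE), rnorm(1e4))$r), 0.05)
})

test_that("affect distribution comparison reports shifts and modes", {
  set.seed(17)
  a <- rnorm(500, 25, 4)
  same <- compare_affect_distributions(a, a, a)
  s <- same$summary
  expect_equal(diff(range(s$mean)), 0)
  wide <- tidyr::pivot_wider(same$ecdf, names_from = "set",
                             values_from = "cdf")
  expect_equal(wide$reported_response, wide$predicted_nonresponse)

  shifted <- compare_affect_distributions(a, a, a + 5)
  ss <- shifted$summary
  expect_equal(ss$mean[ss$set == "predicted_nonresponse"] -
                 ss$mean[ss$set == "reported_response"], 5, tolerance = 1e-9)
  w2 <- tidyr::pivot_wider(shifted$ecdf, names_from = "set",
                           values_from = "cdf")
  expect_true(all(w2$predicted_nonresponse <= w2$reported_response + 1e-12))

  # 70/30 mixture with a +15 offset: two density modes
  mix <- c(rnorm(700, 24, 2), rnorm(300, 39, 2))
  m <- compare_affect_distributions(a, a, mix)
  expect_equal(m$nonresponse_modes, 2)
  expect_error(compare_affect_distributions(a, numeric(0), a), "Empty")
})

test_that("trigger bias contrasts predicted strata and averages participants", {
  # identical strata: exactly zero
  p0 <- tibble::tibble(
    participant_id = rep(1, 20),
    receptivity_pred = rep(c("responded", "no_response"), 10),
    mu = rep(c(25, 25), 10), sigma = 1,
    receptivity_label = rep("responded", 20),
    affect_label = rnorm(20, 25, 3)
  )
  b0 <- trigger_bias(p0)
  expect_equal(b0$bias_points, 0)
  expect_equal(b0$bias_sd_units, 0)

  # constructed +4 point contrast in every participant
  p1 <- tibble::tibble(
    participant_id = rep(1:3, each = 20),
    receptivity_pred = rep(rep(c("responded", "no_response"), each = 10), 3),
    mu = rep(rep(c(24, 28), each = 10), 3), sigma = 1,
    receptivity_label = "responded",
    affect_label = rep(rnorm(30, 26, 2), each = 2)
  )
  b1 <- trigger_bias(p1)
  expect_equal(b1$bias_points, 4, tolerance = 1e-9)
  expect_equal(b1$bias_sd_units, 4 / sd(p1$affect_label))
  expect_equal(nrow(b1$per_participant), 3)
  expect_true(all(b1$per_participant$bias_points == 4))

  # empty stratum flagged
  p2 <- p1; p2$receptivity_pred <- "responded"
  expect_warning(b2 <- trigger_bias(p2), "empty")
  expect_true(is.na(b2$bias_points))
  expect_equal(unname(tidy(b1)$bias_points), 4, tolerance = 1e-9)
})
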