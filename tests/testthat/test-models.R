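test_that("per-participant normalisation is exact and invertible", {
  set.seed(5)
  d <- tibble::tibble(participant_id = rep(1:2, each = 20),
                      f1 = rnorm(40, 10, 3), f2 = runif(40),
                      f3 = rep(7, 40))
  # one warning per participant with a constant column
  expect_warning(
    expect_warning(norm <- fit_normalizer(d, c("f1", "f2", "f3")),
                   "constant"),
    "constant")
  z <- apply_normalizer(norm, d)
  for (p in 1:2) {
    expect_equal(mean(z$f1[z$participant_id == p]), 0, tolerance = 1e-9)
    expect_equal(sd(z$f1[z$participant_id == p]), 1, tolerance = 1e-9)
    expect_true(all(z$f3[z$participant_id == p] == 0))
  }
  back <- apply_normalizer(norm, z, invert = TRUE)
  expect_equal(back$f1, d$f1, tolerance = 1e-9)
  expect_equal(back$f2, d$f2, tolerance = 1e-9)
  expect_error(fit_normalizer(d[1, ], c("f1")), ">= 2 rows")
})

test_that("projection keeps the smallest basis reaching the variance target", {
  set.seed(6)
  # rank-2 data embedded in 10 dims
  z <- matrix(rnorm(200), 100, 2)
  x <- z %*% matrix(rnorm(20), 2, 10)
  pr <- fit_projection(x, 0.99)
  expect_equal(pr$n_components, 2)
  expect_gte(pr$retained_variance, 0.99)
  # isotropic 5-dim Gaussian needs all 5 components for 99%
  iso <- matrix(rnorm(5000 * 5), 5000, 5)
  expect_equal(fit_projection(iso, 0.99)$n_components, 5)
  # orthonormal basis
  g <- crossprod(pr$rotation)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-8, ignore_attr = TRUE)
  sc <- apply_projection(pr, x)
  expect_equal(ncol(sc), 2)
  expect_error(fit_projection(matrix(0, 5, 3)), "Degenerate")
})

test_that("grid search evaluates every permutation and refits the best", {
  set.seed(7)
  n <- 120
  g <- rep(sprintf("g%02d", 1:12), each = 10)
  y <- ifelse(g %in% sprintf("g%02d", 1:8), "responded", "no_response")
  x <- matrix(rnorm(2 * n), n, 2)
  x[y == "responded", 1] <- x[y == "responded", 1] + 4   # separable
  colnames(x) <- c("a", "b")
  grid <- expand.grid(n_estimators = c(20, 40), max_depth = 3,
                      min_samples_leaf = c(1, 2), min_samples_split = 2,
                      max_features = "all", stringsAsFactors = FALSE)
  fit <- grid_search_receptivity(x, y, g, grid = grid, n_folds = 3, seed = 1)
  expect_s3_class(fit, "receptivity_fit")
  expect_equal(nrow(fit$search_log), nrow(grid))
  expect_true(all(fit$search_log$n_folds_used > 0))
  expect_equal(unname(predict(fit, x)), y)              # separable: exact
  # class weights inverse to label frequencies
  w <- fit$class_weights
  expect_gt(w[["no_response"]], w[["responded"]])
  expect_equal(unname(w[["no_response"]] / w[["responded"]]),
               (8 / 12) / (4 / 12), tolerance = 1e-9)
  # single-permutation grid is chosen trivially
  fit1 <- grid_search_receptivity(x, y, g, grid = grid[1, ], n_folds = 2,
                                  seed = 1)
  expect_equal(fit1$params$n_estimators, grid$n_estimators[1])
  expect_error(grid_search_receptivity(x, rep("responded", n), g,
                                       grid = grid[1, ]), "Both classes")
})

test_that("train-fitted artifacts are untouched by test-partition rows", {
  set.seed(19)
  d <- tibble::tibble(participant_id = 1L,
                      f1 = rnorm(60), f2 = rnorm(60))
  train <- d[1:40, ]; test <- d[41:60, ]
  test_perm <- test[sample(20), ]
  test_perm$f1 <- rev(test_perm$f1)      # corrupt the test partition
  n1 <- fit_normalizer(train, c("f1", "f2"))
  n2 <- fit_normalizer(train, c("f1", "f2"))
  expect_identical(n1$stats, n2$stats)
  p1 <- fit_projection(as.matrix(train[c("f1", "f2")]), 0.99)
  expect_identical(p1$rotation,
                   fit_projection(as.matrix(train[c("f1", "f2")]),
                                  0.99)$rotation)
  # transforming either test set never feeds back into the fit
  z1 <- apply_normalizer(n1, test)
  expect_identical(n1$stats, n2$stats)
  expect_false(identical(z1$f1, apply_normalizer(n1, test_perm)$f1))
})

test_that("class weighting lifts minority recall on an imbalanced separable toy", {
  set.seed(20)
  n <- 200
  y <- factor(rep(c("responded", "no_response"), c(160, 40)),
              levels = c("no_response", "responded"))
  x <- matrix(rnorm(2 * n, sd = 1.2), n, 2)
  x[y == "no_response", 1] <- x[y == "no_response", 1] + 2.2
  colnames(x) <- c("a", "b")
  g <- rep(sprintf("g%03d", 1:40), each = 5)
  fit_w <- grid_search_receptivity(
    x, as.character(y), g,
    grid = data.frame(n_estimators = 60, max_depth = 3,
                      min_samples_leaf = 2, min_samples_split = 2,
                      max_features = "all", stringsAsFactors = FALSE),
    n_folds = 2, seed = 3)
  plain <- randomForest::randomForest(x = x, y = y, ntree = 60)
  recall <- function(pred) {
    sum(pred == "no_response" & y == "no_response") / sum(y == "no_response")
  }
  expect_gte(recall(predict(fit_w, x)), recall(as.character(predict(plain, x))))
})

test_that("heteroscedastic loss matches its calculus", {
  expect_equal(heteroscedastic_loss(5, 5, 0), 0)
  # fixed error e: optimum over sigma at sigma^2 = e^2
  e <- 2
  f <- function(ls) heteroscedastic_loss(0, e, ls)
  opt <- optimize(f, c(-4, 4))
  expect_equal(exp(2 * opt$minimum), e^2, tolerance = 1e-4)
  # sigma = 1 reduces to half the squared error
  expect_equal(heteroscedastic_loss(3, 1, 0), (3 - 1)^2 / 2)
  expect_error(heteroscedastic_loss(NA, 1, 0), "finite")
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(8)
  y <- rnorm(7); mu <- rnorm(7); ls <- rnorm(7, 0, 0.5)
  g <- receptr:::heteroscedastic_grad(y, mu, ls)
  h <- 1e-5
  for (i in 1:7) {
    dmu <- (heteroscedastic_loss(y, replace(mu, i, mu[i] + h), ls) -
              heteroscedastic_loss(y, replace(mu, i, mu[i] - h), ls)) / (2 * h)
    dls <- (heteroscedastic_loss(y, mu, replace(ls, i, ls[i] + h)) -
              heteroscedastic_loss(y, mu, replace(ls, i, ls[i] - h))) / (2 * h)
    expect_equal(g$mu[i], dmu, tolerance = 1e-5)
    expect_equal(g$ln_sigma[i], dls, tolerance = 1e-5)
  }
})

test_that("affect network fits constants, separates noise regimes, and is seeded", {
  set.seed(9)
  x <- matrix(rnorm(400), 200, 2)
  # constant target
  suppressWarnings({
    nn_c <- fit_affect_nn(x, rep(40, 200), hidden = c(8, 4), epochs = 300,
                          lr = 5e-3, patience = 300, seed = 2)
  })
  pc <- predict(nn_c, x)
  expect_equal(mean(pc$mu), 40, tolerance = 0.5)
  expect_lt(median(pc$sigma), 1)

  # two noise regimes: sigma should be higher in the noisy regime
  regime <- x[, 1] > 0
  y <- 30 + 5 * x[, 2] + rnorm(200, 0, ifelse(regime, 8, 0.5))
  suppressWarnings({
    nn_r <- fit_affect_nn(x, y, hidden = c(16, 8), epochs = 600, lr = 5e-3,
                          patience = 600, seed = 3)
  })
  pr <- predict(nn_r, x)
  expect_gt(mean(pr$sigma[regime]), mean(pr$sigma[!regime]))

  # determinism under a fixed seed
  suppressWarnings({
    nn_a <- fit_affect_nn(x, y, hidden = c(8, 4), epochs = 50, seed = 11)
    nn_b <- fit_affect_nn(x, y, hidden = c(8, 4), epochs = 50, seed = 11)
  })
  expect_identical(predict(nn_a, x), predict(nn_b, x))
  expect_equal(nn_a$epochs_run, length(nn_a$trajectory))
})

test_that("ensemble predictions combine mixture moments and widen off-support", {
  set.seed(10)
  x <- matrix(rnorm(300), 150, 2)
  y <- 30 + 4 * x[, 1] + rnorm(150, 0, 1)
  suppressWarnings({
    ens <- fit_affect_nn(x, y, hidden = c(8, 4), epochs = 300, lr = 5e-3,
                         patience = 300, n_ensemble = 4, seed = 5)
  })
  expect_s3_class(ens, "affect_nn_ensemble")
  inx <- predict(ens, x)
  far <- matrix(8, 10, 2)                 # far outside the training cloud
  outx <- predict(ens, far)
  expect_gt(mean(outx$sigma), mean(inx$sigma))
  expect_true(all(outx$mu >= 13 & outx$mu <= 91))
})

test_that("baseline samplers obey their analytic behaviour", {
  expect_equal(expected_true_positive_fraction(0.8, 0.75), 0.6)
  expect_equal(expected_true_positive_fraction(1, 0.7), 0.7)
  # balanced labels: expected accuracy one half
  expect_equal(expected_true_positive_fraction(0.5, 0.5) +
                 expected_true_positive_fraction(0.5, 0.5), 0.5)

  train <- c(rep("responded", 80), rep("no_response", 20))
  pred <- baseline_classify(train, 1e5, seed = 1)
  truth <- sample(c("responded", "no_response"), 1e5, replace = TRUE,
                  prob = c(0.75, 0.25))
  tp <- mean(pred == "responded" & truth == "responded")
  se <- sqrt(0.6 * 0.4 / 1e5)
  expect_lt(abs(tp - 0.8 * 0.75), 3 * se)

  reg <- baseline_regress(c(30, 30, 30), 100, seed = 1)
  expect_true(all(reg == 30))
  reg2 <- baseline_regress(rnorm(1000, 40, 5), 1e5, seed = 2)
  expect_equal(mean(reg2), 40, tolerance = 0.15)
  expect_true(all(reg2 >= 13 & reg2 <= 91))
  expect_error(baseline_regress(30, 10), ">= 2")
})

test_that("evaluation metrics match the confusion-matrix arithmetic", {
  perf <- evaluate_predictions(rep("responded", 5), rep("responded", 5))
  expect_true(all(perf$value[perf$metric %in%
                               c("accuracy", "precision", "recall", "f1")] == 1))
  truth <- c(rep("responded", 9), rep("no_response", 11))
  pred <- c(rep("responded", 8), "no_response",
            rep("responded", 2), rep("no_response", 9))
  m <- evaluate_predictions(truth, pred)
  expect_equal(m$value[m$metric == "precision"], 0.8)
  expect_equal(m$value[m$metric == "recall"], 8 / 9)
  r <- evaluate_predictions(c(20, 30), c(25, 25))
  expect_equal(r$value[r$metric == "rmse"], 5)
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "Empty")
})

test_that("uncertainty filter uses a strict cutoff", {
  p <- tibble::tibble(sigma = c(4, 6, 8), mu = c(20, 25, 30))
  out <- filter_by_uncertainty(p, 6, quiet = TRUE)
  expect_equal(out$kept_after_filter, c(TRUE, FALSE, FALSE))
  expect_equal(sum(out$kept_after_filter), 1)
  all5 <- filter_by_uncertainty(tibble::tibble(sigma = rep(5, 4)), 6,
                                quiet = TRUE)
  expect_true(all(all5$kept_after_filter))
  inf <- filter_by_uncertainty(p, Inf, quiet = TRUE)
  expect_true(all(inf$kept_after_filter))
})

test_that("uncertainty diagnostics report participant-centred correlations", {
  pr <- tibble::tibble(participant_id = rep(1, 10),
                       mu = rep(30, 10), sigma = 1:10)
  truth <- pr$mu + pr$sigma           # |error| equals sigma exactly
  d <- uncertainty_diagnostics(pr, truth)
  expect_equal(d$r_sigma_abs_error, 1)
  cst <- uncertainty_diagnostics(
    tibble::tibble(participant_id = rep(1, 5), mu = rnorm(5),
                   sigma = rep(2, 5)), rnorm(5))
  expect_false(cst$defined)
  small <- uncertainty_diagnostics(
    tibble::tibble(participant_id = 1:2, mu = 1:2, sigma = 1:2), 1:2)
  expect_true(all(!small$defined))
})
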