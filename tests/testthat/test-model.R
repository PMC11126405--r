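test_that("label merging follows the published pairing", {
  expect_equal(as.character(merge_labels(5)), "1/5")
  expect_equal(as.character(merge_labels(2)), "2")
  expect_equal(as.character(merge_labels(10)), "9/10")
  expect_equal(as.character(merge_labels(c(1, 3, 4, 6, 7, 8, 9))),
               c("1/5", "3/8", "4/7", "6", "4/7", "3/8", "9/10"))
  expect_equal(levels(merge_labels(1)), c("1/5", "2", "3/8", "4/7", "6", "9/10"))
  expect_error(merge_labels(11), "1..10")
  expect_error(merge_labels(0), "1..10")
})

test_that("stratified folds partition samples with near-equal class counts", {
  labels <- rep(1:5, each = 10)
  folds <- stratified_folds(labels, k = 5, seed = 2)
  expect_equal(sort(unique(folds)), 1:5)
  tab <- table(labels, folds)
  expect_true(all(tab == 2))

  # unbalanced classes: per-class fold sizes differ by <= 1
  labels2 <- rep(1:3, times = c(7, 11, 13))
  folds2 <- stratified_folds(labels2, k = 5, seed = 2)
  tab2 <- table(labels2, folds2)
  expect_true(all(apply(tab2, 1, function(x) diff(range(x))) <= 1))
  # counting oracle: class of size s puts ceiling(s/k) in (s mod k) folds
  for (i in 1:3) {
    s <- c(7, 11, 13)[i]
    expect_equal(sort(as.integer(tab2[i, ]), decreasing = TRUE),
                 sort(rep(c(ceiling(s / 5), floor(s / 5)),
                          c(s %% 5, 5 - s %% 5)), decreasing = TRUE))
  }

  expect_identical(folds, stratified_folds(labels, k = 5, seed = 2))
  expect_error(stratified_folds(rep(1:2, c(3, 10)), k = 5, seed = 1),
               "class 1")
})

small_xy <- function(n = 60, seed = 47) {
  withr::with_seed(seed, {
    y <- factor(rep(1:3, length.out = n))
    x <- matrix(rnorm(n * 4), n, 4)
    x[, 1] <- x[, 1] + 3 * as.integer(y)
    list(x = x, y = y)
  })
}

fast_space <- function() {
  list(max_depth = c(2L, 4L), eta = c(0.05, 0.3), nrounds = c(5L, 15L),
       subsample = c(0.7, 1), colsample_bytree = c(0.7, 1), lambda = c(0, 2))
}

test_that("random search is seeded, exhaustive over trials, and prefix-monotone", {
  d <- small_xy()
  s1 <- random_search(d$x, d$y, type = "multiclass", k_folds = 3,
                      n_trials = 6, space = fast_space(), seed = 5)
  s2 <- random_search(d$x, d$y, type = "multiclass", k_folds = 3,
                      n_trials = 6, space = fast_space(), seed = 5)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$best, s2$best)

  # sampled configs respect the space
  expect_true(all(s1$trials$max_depth >= 2 & s1$trials$max_depth <= 4))
  expect_true(all(s1$trials$eta >= 0.05 & s1$trials$eta <= 0.3))
  expect_true(all(s1$trials$nrounds >= 5 & s1$trials$nrounds <= 15))

  # prefix-minimum property: more trials from the same stream can only help
  s_short <- random_search(d$x, d$y, type = "multiclass", k_folds = 3,
                           n_trials = 2, space = fast_space(), seed = 5)
  expect_identical(s_short$trials, s1$trials[1:2, ])
  expect_lte(s1$best_objective, s_short$best_objective)

  one <- random_search(d$x, d$y, type = "multiclass", k_folds = 3,
                       n_trials = 1, space = fast_space(), seed = 5)
  expect_identical(one$best, list(
    max_depth = one$trials$max_depth[1], eta = one$trials$eta[1],
    nrounds = one$trials$nrounds[1], subsample = one$trials$subsample[1],
    colsample_bytree = one$trials$colsample_bytree[1],
    lambda = one$trials$lambda[1]))

  # binary mode with RMSE objective
  yb <- as.numeric(as.integer(d$y) > 1)
  sb <- random_search(d$x, yb, type = "binary", k_folds = 3, n_trials = 2,
                      space = fast_space(), seed = 5)
  expect_true(is.finite(sb$best_objective))
  expect_gte(sb$best_objective, 0)
})

test_that("flat 10-class model fits separable data and outputs probabilities", {
  fit <- small_fit()
  m10 <- train_flat10(fit$features, fit$cohort$labels,
                      config = tiny_config(), seed = 2)
  p <- predict(m10, fit$features)
  truth <- fit$cohort$labels$intclust[match(p$sample_id,
                                            fit$cohort$labels$sample_id)]
  expect_equal(mean(p$intclust == truth), 1)
  probs <- as.matrix(p[, paste0("prob_", 1:10)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  p2 <- predict(m10, fit$features)
  expect_identical(p, p2)

  labs9 <- dplyr::filter(fit$cohort$labels, intclust != 4)
  feats9 <- fit$features[fit$features$sample_id %in% labs9$sample_id, ]
  expect_error(train_flat10(feats9, labs9, config = tiny_config()), "missing")
})

test_that("the cascade has one multiclass and four pair models trained on pair subsets", {
  fit <- small_fit()
  b <- fit$bundle
  expect_s3_class(b, "cn_bundle")
  expect_named(b$binaries, c("1/5", "3/8", "4/7", "9/10"))
  expect_equal(length(b$binaries), 4)
  expect_equal(nrow(b$regions), ncol(fit$features) - 1)

  # training recall on separable synthetic data
  p <- predict(b, fit$features)
  truth <- fit$cohort$labels$intclust[match(p$sample_id,
                                            fit$cohort$labels$sample_id)]
  expect_gte(mean(p$intclust == truth), 0.99)

  # pair with an empty side -> error
  labs <- fit$cohort$labels
  labs$intclust[labs$intclust == 5L] <- 1L
  expect_error(train_cascade(fit$features, labs,
                             multiclass_config = tiny_config(),
                             binary_configs = tiny_config()),
               "missing")
})

test_that("cascade predictions obey the decision rules and compose coherently", {
  fit <- small_fit()
  p <- predict(fit$bundle, fit$features)

  # final label always maps back to the 6-class argmax
  expect_equal(as.character(merge_labels(p$intclust)),
               as.character(p$merged_label))

  # singleton argmax -> no binary model involved
  singles <- p[p$merged_label %in% c("2", "6"), ]
  expect_true(all(is.na(singles$binary_prob)))
  expect_equal(singles$intclust, as.integer(as.character(singles$merged_label)))

  # pair argmax -> 0.5 threshold on the binary output, ties to the higher class
  pairs <- intclust_pairs()
  paired <- p[!is.na(p$binary_pair), ]
  for (i in seq_len(nrow(paired))) {
    pair <- pairs[[paired$binary_pair[i]]]
    want <- if (paired$binary_prob[i] >= 0.5) pair[2] else pair[1]
    expect_equal(paired$intclust[i], want)
  }

  # composed 10-class probabilities sum to 1 and agree with the decision path
  probs <- as.matrix(p[, paste0("prob_", 1:10)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-8))
  expect_equal(as.integer(apply(probs, 1, which.max)), p$intclust)

  # guard rails
  unscaled <- cohort_features(fit$cohort$profiles, fit$regions)
  expect_error(predict(fit$bundle, unscaled), "scaled")
})

test_that("prediction tolerates masked features and changes few labels", {
  fit <- small_fit()
  p0 <- predict(fit$bundle, fit$features)
  m <- features_matrix(fit$features)
  withr::with_seed(53, {
    mask <- matrix(runif(length(m)) < 0.1, nrow(m), ncol(m))
  })
  m[mask] <- NA
  masked <- fit$features
  masked[, colnames(m)] <- tibble::as_tibble(m)
  p1 <- predict(fit$bundle, masked)
  # toy cohort with mild separation: most labels must survive the masking
  expect_lte(mean(p1$intclust != p0$intclust), 0.15)
})
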