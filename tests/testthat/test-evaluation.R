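test_that("metrics match hand computation and a reference implementation", {
  cm <- matrix(c(40, 10, 5, 45), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 0.85)
  # Pe = (50*45 + 50*55) / 100^2 = 0.5 -> kappa = 0.35/0.5
  expect_equal(m$kappa, 0.7)
  expect_equal(m$recall_a, 0.8)
  expect_equal(m$recall_b, 0.9)
  # independent cross-check for the chance-corrected agreement
  expect_equal(m$kappa, e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
})

test_that("metric edge cases behave as documented", {
  perfect <- diag(c(10, 20, 5, 8))
  rownames(perfect) <- colnames(perfect) <- grade_levels()
  m <- compute_metrics(perfect)
  expect_equal(unlist(m[c("accuracy", "f1_macro", "gmean_macro", "kappa")]),
               c(accuracy = 1, f1_macro = 1, gmean_macro = 1, kappa = 1))
  # a class never recovered annihilates the macro G-mean
  miss <- matrix(c(10, 0, 9, 1), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  miss[2, ] <- c(10, 0)
  expect_equal(compute_metrics(miss)$gmean_macro, 0)
  expect_error(compute_metrics(matrix(0, 2, 2)), "Empty")
})

test_that("stratified folds partition rows and balance classes", {
  y <- factor(rep(c("a", "b", "c", "d"), c(20, 10, 15, 15)))
  fold <- eegrade:::stratified_folds(y, 5, seed = 3)
  expect_setequal(unique(fold), 1:5)
  for (cls in levels(y)) {
    per_fold <- table(fold[y == cls])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(eegrade:::stratified_folds(factor(rep(c("a", "b"), c(3, 30))),
                                          5, 1),
               "at least as many")
})

test_that("repeated CV reports fold-level metrics and a pooled confusion", {
  feats <- small_features()
  cv <- repeated_stratified_cv(feats, boost_spec(nrounds = 20),
                               folds = 2, repeats = 2, seed = 4)
  td <- tidy(cv)
  expect_equal(nrow(td), 4)
  expect_equal(sum(cv$confusion), 2 * nrow(feats))
  g <- glance(cv)
  expect_equal(g$accuracy, mean(td$accuracy))
  expect_true(all(g[c("accuracy", "f1_macro", "gmean_macro")] <= 1))
  # test folds partition the data within each repeat
  expect_equal(sum(td$n_test[td$repeat_ == 1]), nrow(feats))
})

test_that("label shuffling drops accuracy to the base rate", {
  feats <- small_features()
  shuffled <- feats
  shuffled$grade <- withr::with_seed(10, sample(shuffled$grade))
  cv <- repeated_stratified_cv(shuffled, boost_spec(nrounds = 20),
                               folds = 2, repeats = 2, seed = 5)
  base_rate <- max(table(feats$grade)) / nrow(feats)
  td <- tidy(cv)
  expect_lt(glance(cv)$accuracy,
            base_rate + 3 * sd(td$accuracy) + 1e-9)
})

test_that("CV is reproducible under its seed", {
  feats <- small_features()
  g1 <- glance(repeated_stratified_cv(feats, boost_spec(nrounds = 15),
                                      folds = 2, repeats = 1, seed = 11))
  g2 <- glance(repeated_stratified_cv(feats, boost_spec(nrounds = 15),
                                      folds = 2, repeats = 1, seed = 11))
  expect_identical(g1, g2)
})

test_that("the window sweep reports one row per window with epoch counts", {
  sw <- time_window_sweep(small_cohort(), windows = c(5, 10),
                          spec = boost_spec(nrounds = 15),
                          folds = 2, repeats = 1, seed = 2)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$window_s, c(5, 10))
  expect_equal(sw$epochs_per_subject, c(4, 2))
  expect_equal(sw$n_epochs, c(32, 16))
  expect_true(all(c("accuracy", "accuracy_sd", "kappa_sd") %in% names(sw)))
  expect_error(time_window_sweep(small_cohort(), windows = 30), "exceeds")
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("per-fold tuning stays inside the training fold", {
  feats <- small_features()
  # a 2-eval TPE run must work end to end and respect the printed bounds
  cv <- repeated_stratified_cv(feats, boost_spec(nrounds = 10),
                               folds = 2, repeats = 1, seed = 3,
                               tune = list(max_evals = 2,
                                           space = list(depth = p_uniformint(3, 10))))
  expect_equal(nrow(tidy(cv)), 2)
})
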