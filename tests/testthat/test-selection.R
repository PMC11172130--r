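test_that("a perfectly predictive feature tops the fold-averaged ranking", {
  withr::with_seed(21, {
    x <- matrix(rnorm(300 * 10), ncol = 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- factor(ifelse(x[, 1] > 0, "pos", "neg"))
  })
  imp <- fold_averaged_importance(x, y, boost_spec(nrounds = 20), seed = 2)
  expect_equal(names(which.max(imp)), "f1")
  expect_gt(sum(imp), 0)
})

test_that("all-noise features produce no dominant importance", {
  exceed <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      x <- matrix(rnorm(120 * 8), ncol = 8,
                  dimnames = list(NULL, paste0("f", 1:8)))
      y <- factor(rep(c("a", "b"), each = 60))
    })
    imp <- fold_averaged_importance(x, y, boost_spec(nrounds = 10), seed = s)
    max(imp) > 3 * mean(imp)
  }, logical(1))
  # spurious dominance should be the exception, not the rule
  expect_lt(mean(exceed), 0.5)
})

test_that("a constant metric trace stops after exactly patience + 1 iterations", {
  x <- matrix(rnorm(40 * 30), ncol = 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  y <- factor(rep(c("a", "b"), each = 20))
  constant_eval <- function(x, y, seed) {
    list(metrics = tibble::tibble(accuracy = 0.5, f1_macro = 0.5,
                                  gmean_macro = 0.5, kappa = 0),
         importance = stats::setNames(seq_len(ncol(x)), colnames(x)))
  }
  tr <- rfe_early_stop(x, y = y, patience = 10, eval_fn = constant_eval)
  expect_equal(nrow(tr$trace), 11)
  expect_equal(tr$trace$n_features, 30:20)
  # exactly one feature removed per iteration, lowest importance first
  expect_equal(tr$removed, paste0("f", 1:10))
  expect_error(rfe_early_stop(x, y = y, patience = 0), "patience")
})

test_that("the reported best subset attains the maximum of the trace", {
  x <- matrix(rnorm(40 * 12), ncol = 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  y <- factor(rep(c("a", "b"), each = 20))
  drifting_eval <- local({
    k <- 0
    function(x, y, seed) {
      k <<- k + 1
      acc <- c(0.6, 0.7, 0.9, 0.8, 0.9, 0.6, 0.6, 0.6, 0.6)[min(k, 9)]
      list(metrics = tibble::tibble(accuracy = acc, f1_macro = acc,
                                    gmean_macro = acc, kappa = acc),
           importance = stats::setNames(seq_len(ncol(x)), colnames(x)))
    }
  })
  tr <- rfe_early_stop(x, y = y, patience = 3, eval_fn = drifting_eval)
  expect_equal(glance(tr)$accuracy, max(tr$trace$accuracy))
  # ties on the maximum resolve to the smaller subset (iteration 5, not 3)
  expect_equal(tr$best_iteration, 5)
  expect_equal(length(tr$best_features), 12 - 4)
})

test_that("planted informative features survive recursive elimination", {
  hits <- vapply(1:5, function(s) {
    withr::with_seed(3000 + s, {
      n <- 500
      x <- matrix(rnorm(n * 50), ncol = 50,
                  dimnames = list(NULL, paste0("f", 1:50)))
      cls <- (x[, 1] > 0) + (x[, 2] > 0) + (x[, 3] + x[, 4] > 0) +
        (x[, 5] > 0)
      y <- factor(grade_levels()[pmin(cls, 3) + 1], levels = grade_levels())
    })
    tr <- rfe_early_stop(x, y = y, spec = boost_spec(nrounds = 30),
                         patience = 10, seed = s)
    sum(paste0("f", 1:5) %in% tr$best_features)
  }, numeric(1))
  expect_gte(median(hits), 4)
})
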