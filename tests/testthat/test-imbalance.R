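test_that("sphere radius follows the energy accounting on a 1-D instance", {
  # minority {0}, majority {0.1, 5}: reaching 0.1 costs 0.1, after which
  # expansion costs 2 per unit; energy 0.5 gives r = 0.1 + 0.4/2 = 0.3
  x <- matrix(c(0, 0.1, 5), ncol = 1)
  y <- c("min", "maj", "maj")
  out <- ccr_clean(x, y, "min", energy = 0.5)
  expect_equal(out$radii, 0.3)
  expect_equal(out$x[2, 1], 0.3)
  expect_equal(out$x[3, 1], 5)
  expect_equal(out$x[1, 1], 0)
})

test_that("cleaning is the identity when no majority point is reachable", {
  x <- matrix(c(0, 0, 10, 10, -10, 10), ncol = 2, byrow = TRUE)
  y <- c("min", "maj", "maj")
  out <- ccr_clean(x, y, "min", energy = 1)
  expect_equal(out$x, x)
  expect_false(any(out$moved))
})

test_that("no majority point remains strictly inside any minority sphere", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(40, 0, 0.5), ncol = 2),
               matrix(rnorm(120, 1, 1), ncol = 2))
    y <- rep(c("min", "maj"), c(20, 60))
  })
  out <- ccr_clean(x, y, "min", energy = 0.8)
  min_idx <- which(y == "min")
  for (a in seq_along(min_idx)) {
    d <- sqrt(colSums((t(out$x[y == "maj", ]) - out$x[min_idx[a], ])^2))
    expect_true(all(d >= out$radii[a] - 1e-9))
  }
  expect_equal(out$x[min_idx, ], x[min_idx, ])
})

test_that("oversampling respects quotas, spheres, and the zero case", {
  withr::with_seed(9, {
    x <- rbind(matrix(rnorm(10), ncol = 2), matrix(rnorm(32, 3), ncol = 2))
    y <- rep(c("min", "maj"), c(5, 16))
    cl <- ccr_clean(x, y, "min", energy = 0.5)
    none <- ccr_oversample(cl$x, y, "min", cl$radii, target_count = 5)
    expect_equal(nrow(none$x_new), 0)
    os <- ccr_oversample(cl$x, y, "min", cl$radii, target_count = 16)
    expect_equal(nrow(os$x_new), 11)
    d <- sqrt(rowSums((os$x_new - cl$x[os$seed_of, , drop = FALSE])^2))
    expect_true(all(d <= cl$radii[match(os$seed_of, cl$minority_idx)] + 1e-9))
    expect_error(ccr_oversample(cl$x, y, "min", cl$radii, target_count = 3),
                 "below")
  })
})

test_that("balance policy equalizes multiclass counts, rarest first", {
  withr::with_seed(3, {
    x <- matrix(rnorm(300 * 3), ncol = 3)
    y <- rep(c("a", "b", "c", "d"), c(100, 25, 100, 75))
  })
  out <- ccr_resample(x, y, ccr_config(seed = 4))
  expect_equal(as.integer(table(out$y)[c("a", "b", "c", "d")]),
               rep(100, 4))
  # original rows of every resampled class survive unchanged
  expect_equal(out$x[which(y == "b"), ], x[which(y == "b"), ])
  expect_equal(out$x[which(y == "d"), ], x[which(y == "d"), ])
  # determinism under the seed
  out2 <- ccr_resample(x, y, ccr_config(seed = 4))
  expect_identical(out, out2)
})

test_that("already-balanced well-separated classes pass through untouched", {
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 20), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  out <- ccr_resample(x, y, ccr_config(seed = 1))
  expect_equal(out$x, x)
  expect_equal(out$y, y)
  expect_error(ccr_resample(x, rep("a", 40), ccr_config()), "two classes")
})

test_that("multiplier policy scales minority counts as configured", {
  withr::with_seed(8, {
    x <- matrix(rnorm(120 * 2), ncol = 2)
    y <- rep(c("maj", "mild"), c(100, 20))
  })
  out <- ccr_resample(x, y, ccr_config(policy = "multiplier",
                                       multiplier = 4, seed = 2))
  expect_equal(sum(out$y == "mild"), 80)
  expect_equal(sum(out$y == "maj"), 100)
})

test_that("the tidy wrapper flags synthetic rows and keeps metadata", {
  feats <- small_features()[, 1:24]  # few features keep geometry cheap
  sub <- dplyr::filter(feats, grade %in% c("normal", "severe"))
  sub <- sub[c(1:4, 5:6), ]  # 4 normal vs 2 severe
  out <- ccr_balance(sub, ccr_config(seed = 6))
  expect_equal(sum(out$grade == "severe"), 4)
  expect_equal(sum(out$.synthetic), 2)
  expect_true(all(is.na(out$subject_id[out$.synthetic])))
})
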