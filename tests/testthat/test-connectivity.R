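test_that("analytic phase advances at the tone frequency", {
  t <- seq(0, 4 - 1 / 125, by = 1 / 125)
  ph <- analytic_phase(cos(2 * pi * 10 * t))
  unwrapped <- cumsum(c(ph[1], {
    d <- diff(ph)
    d - 2 * pi * round(d / (2 * pi))
  }))
  slope <- coef(lm(unwrapped ~ t))[[2]]
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01)
})

test_that("sine lags cosine by a constant quarter cycle", {
  t <- seq(0, 4 - 1 / 125, by = 1 / 125)
  core <- 50:450
  d <- analytic_phase(cos(2 * pi * 8 * t)) - analytic_phase(sin(2 * pi * 8 * t))
  d <- d - 2 * pi * round(d / (2 * pi))
  expect_equal(unname(d[core]), rep(pi / 2, length(core)), tolerance = 1e-6)
})

test_that("degenerate series are rejected", {
  expect_error(analytic_phase(rep(0, 100)), "Constant")
  expect_error(analytic_phase(rep(2.5, 100)), "Constant")
  expect_error(analytic_phase(c(1, 2, 3)), "short")
  expect_error(pli(rnorm(100), rnorm(99)), "equal length")
})

test_that("PLI endpoints: identical signals 0, constant lag 1", {
  t <- seq(0, 2 - 1 / 125, by = 1 / 125)
  x <- sin(2 * pi * 9 * t) + 0.3 * sin(2 * pi * 17 * t)
  expect_equal(pli(x, x), 0)
  expect_equal(pli(cos(2 * pi * 8 * t), cos(2 * pi * 8 * t - pi / 3)), 1)
})

test_that("PLI equals |fraction leading - fraction lagging|", {
  # constructed phase pair: positive wrapped difference on 60% of samples
  ph1 <- rep(0, 200)
  ph2 <- c(rep(-0.4, 120), rep(0.4, 80))
  expect_equal(eegrade:::pli_from_phase(ph1, ph2), 0.2)
})

test_that("production PLI matches the naive per-sample loop oracle", {
  withr::with_seed(42, {
    for (rep in 1:8) {
      x1 <- cumsum(rnorm(200))
      x2 <- cumsum(rnorm(200))
      expect_equal(pli(x1, x2), pli_naive(x1, x2), tolerance = 1e-12)
    }
  })
})

test_that("PLI is amplitude invariant and symmetric in its arguments", {
  withr::with_seed(7, {
    x1 <- as.numeric(arima.sim(list(ar = 0.9), 300))
    x2 <- as.numeric(arima.sim(list(ar = 0.9), 300))
  })
  expect_equal(pli(3 * x1, 0.2 * x2), pli(x1, x2), tolerance = 1e-12)
  expect_equal(pli(x2, x1), pli(x1, x2), tolerance = 1e-12)
})

test_that("instantaneous mixing of independent sources stays at null level", {
  withr::with_seed(11, {
    n <- 1500
    m <- 0.4
    pli_mixed <- pli_indep <- numeric(10)
    for (k in seq_len(10)) {
      s1 <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), n))
      s2 <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), n))
      s3 <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), n))
      pli_mixed[k] <- pli((1 - m) * s1 + m * s2, (1 - m) * s2 + m * s1)
      pli_indep[k] <- pli(s1, s3)
    }
    expect_lt(mean(pli_mixed), mean(pli_indep) + 0.05)
    expect_lt(mean(pli_mixed), 0.1)
  })
})

test_that("PLI matrices are symmetric with zero diagonal and null off-diagonals for noise", {
  ep <- noise_epoch()
  pm <- pli_matrix(ep$data)
  expect_identical(pm, t(pm))
  expect_equal(unname(diag(pm)), rep(0, 16))
  expect_lt(mean(pm[upper.tri(pm)]), 0.1)
  dup <- ep$data
  dup[2, ] <- dup[1, ]
  expect_equal(pli_matrix(dup)[1, 2], 0)
})

test_that("feature indexing is the documented bijection", {
  idx <- feature_index()
  expect_equal(nrow(idx), 480)
  expect_equal(idx$feature[1], "theta_FP1_FP2")
  expect_equal(idx$feature[480], "beta_T5_T6")
  expect_equal(as.integer(table(idx$band)[band_names()]), rep(120, 4))
  # decode(encode) round-trips for every index
  dec <- decode_features(idx$index)
  expect_equal(dec$feature, idx$feature)
  expect_equal(decode_features(idx$feature)$index, idx$index)
})

test_that("feature vectors align with the index map", {
  be <- band_decompose(noise_epoch())
  fv <- feature_vector(be)
  expect_length(fv, 480)
  expect_equal(names(fv), feature_index()$feature)
  expect_true(all(fv >= 0 & fv <= 1))
  # spot-check one entry against a direct pairwise computation
  expect_equal(unname(fv["alpha2_C3_P4"]),
               pli(be$bands$alpha2["C3", ], be$bands$alpha2["P4", ]))
  be$bands$beta <- NULL
  expect_error(feature_vector(be), "Missing band")
})

test_that("extract_features emits one labeled row per epoch", {
  feats <- small_features()
  expect_equal(nrow(feats), 16)  # 8 subjects x 2 epochs
  expect_equal(ncol(feats), 484)
  expect_setequal(unique(feats$grade), grade_levels())
  avg <- extract_features(small_cohort(), window_s = 10,
                          average_epochs = TRUE)
  expect_equal(nrow(avg), 8)
  one <- dplyr::filter(feats, subject_id == "sub_001")
  expect_equal(avg$theta_FP1_FP2[avg$subject_id == "sub_001"],
               mean(one$theta_FP1_FP2))
})
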