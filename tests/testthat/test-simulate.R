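test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_per_class = c(0, 1, 1, 1)), "at least one")
  expect_error(sim_config(mixing_strength = 1), "mixing_strength")
  expect_error(sim_config(edges = planted_edges(kappas = c(0, 0, 0, 1.2))),
               "kappa")
  expect_warning(sim_config(edges = planted_edges(kappas = c(0, 0, 0, 0.5),
                                                  delta = pi)),
                 "invisible")
})

test_that("recordings have the configured shape and labels", {
  cfg <- sim_config(n_per_class = c(1, 1, 1, 1), duration_s = 12, seed = 5)
  rec <- simulate_recording("moderate", cfg, seed = 9)
  expect_equal(dim(rec$data), c(16, 12 * 250))
  expect_equal(rownames(rec$data), montage_channels())
  expect_true(rec$hama >= 18 && rec$hama <= 24)
  expect_true(all(is.finite(rec$data)))
})

test_that("cohorts are reproducible and match configured class counts", {
  cfg <- sim_config(n_per_class = c(3, 1, 2, 2), duration_s = 4, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(length(c1), 8)
  expect_identical(c1, c2)
  man <- tidy(c1)
  expect_equal(as.integer(table(factor(man$grade, grade_levels()))),
               c(3, 1, 2, 2))
  expect_identical(as.character(hama_to_grade(man$hama)), man$grade)
})

test_that("without coupling, PLI sits at the phase-shuffled null level", {
  cfg <- sim_config(n_per_class = c(1, 1, 1, 1), duration_s = 10,
                    edges = planted_edges(kappas = c(0, 0, 0, 0)),
                    mixing_strength = 0, seed = 21)
  rec <- simulate_recording("severe", cfg, seed = 3)
  ep <- preprocess_recording(rec, window_s = 10)[[1]]
  beta <- band_decompose(ep)$bands$beta
  pm <- pli_matrix(beta)
  observed_mean <- mean(pm[upper.tri(pm)])
  # surrogate null: phase-randomize each channel independently
  null_means <- withr::with_seed(17, {
    replicate(19, {
      shuf <- t(apply(beta, 1, function(ch) {
        spec <- fft(ch)
        n <- length(ch)
        half <- 2:ceiling(n / 2)
        ph <- runif(length(half), 0, 2 * pi)
        spec[half] <- abs(spec[half]) * exp(1i * ph)
        spec[n - half + 2] <- Conj(spec[half])
        Re(fft(spec, inverse = TRUE) / n)
      }))
      ps <- pli_matrix(shuf)
      mean(ps[upper.tri(ps)])
    })
  })
  expect_lt(observed_mean, quantile(null_means, 0.95) * 1.5)
})

test_that("a planted edge dominates the non-planted beta PLI distribution", {
  cfg <- sim_config(
    n_per_class = c(1, 1, 1, 1), duration_s = 10, mixing_strength = 0,
    edges = tibble::tibble(grade = "severe", chan_i = "F3", chan_j = "T3",
                           band = "beta", kappa = 0.9, delta = pi / 4),
    seed = 8
  )
  rec <- simulate_recording("severe", cfg, seed = 12)
  ep <- preprocess_recording(rec, window_s = 10)[[1]]
  pm <- pli_matrix(band_decompose(ep)$bands$beta)
  planted <- pm["F3", "T3"]
  others <- pm[upper.tri(pm)]
  others <- others[others != planted]
  expect_gt(planted, quantile(others, 0.99))
})

test_that("pure zero-lag mixing does not create phase-lag coupling", {
  cfg <- sim_config(n_per_class = c(1, 1, 1, 1), duration_s = 10,
                    edges = planted_edges(kappas = c(0, 0, 0, 0)),
                    mixing_strength = 0.4, seed = 31)
  rec <- simulate_recording("severe", cfg, seed = 14)
  ep <- preprocess_recording(rec, window_s = 10)[[1]]
  pm <- pli_matrix(band_decompose(ep)$bands$beta)
  # independent-phase null scale is ~T^(-1/2); allow a generous factor
  expect_lt(mean(pm[upper.tri(pm)]), 3 / sqrt(ncol(ep$data)))
})

test_that("strong planted edges rank in the top decile of their band", {
  cfg <- sim_config(n_per_class = c(1, 1, 1, 1), duration_s = 30, seed = 41,
                    edges = planted_edges(kappas = c(0, 0.3, 0.6, 0.9)))
  rec <- simulate_recording("severe", cfg, seed = 6)
  eps <- preprocess_recording(rec, window_s = 10)
  pms <- lapply(eps, function(e) pli_matrix(band_decompose(e)$bands$beta))
  pm <- Reduce(`+`, pms) / length(pms)
  vals <- pm[upper.tri(pm)]
  for (pair in list(c("F3", "T3"), c("F4", "T4"), c("F7", "T5"),
                    c("F8", "T6"))) {
    expect_gte(pm[pair[1], pair[2]], quantile(vals, 0.9))
  }
})
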