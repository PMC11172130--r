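# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small cohort with a strongly planted beta frontal-temporal structure:
# 2 subjects per grade, 20 s each (two 10 s epochs after preprocessing).
small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(sim_config(n_per_class = c(2, 2, 2, 2), duration_s = 20,
                               seed = 301))
  })
}

small_features <- function() {
  fixture("small_features", function() {
    extract_features(small_cohort(), window_s = 10)
  })
}

# White-noise epoch at the working rate; deterministic.
noise_epoch <- function(n = 1250, fs = 125, seed = 99) {
  withr::with_seed(seed, {
    structure(
      list(subject_id = "noise", grade = "normal", window_s = n / fs,
           fs = fs, epoch = 1L,
           data = matrix(rnorm(16 * n), nrow = 16,
                         dimnames = list(montage_channels(), NULL))),
      class = "eeg_epoch"
    )
  })
}

# A sinusoidal multichannel recording for filter tests.
tone_recording <- function(freq_hz, duration_s = 20, fs = 250, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  data <- matrix(rep(amp * sin(2 * pi * freq_hz * t), each = 16),
                 nrow = 16, byrow = FALSE,
                 dimnames = list(montage_channels(), NULL))
  structure(list(subject_id = "tone", fs = fs, data = data,
                 grade = "normal", hama = 1L),
            class = "eeg_recording")
}

rms <- function(x) sqrt(mean(x^2))

# Naive per-definition PLI: explicit per-sample loop, kept deliberately
# independent of the production implementation.
pli_naive <- function(x1, x2) {
  ph1 <- Arg(analytic_signal_oracle(x1))
  ph2 <- Arg(analytic_signal_oracle(x2))
  total <- 0
  for (i in seq_along(ph1)) {
    d <- ph1[i] - ph2[i]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    total <- total + sign(d)
  }
  abs(total / length(ph1))
}

# FFT Hilbert oracle written from the textbook definition.
analytic_signal_oracle <- function(x) {
  n <- length(x)
  spec <- fft(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(spec * h, inverse = TRUE) / n
}

# Per-definition multiclass metrics via explicit loops (independent oracle).
metrics_naive <- function(cm) {
  C <- nrow(cm)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  f1s <- numeric(C)
  recalls <- numeric(C)
  for (c in seq_len(C)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    f1s[c] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    recalls[c] <- if (sum(cm[c, ]) > 0) tp / sum(cm[c, ]) else 0
  }
  pe <- 0
  for (c in seq_len(C)) pe <- pe + sum(cm[c, ]) * sum(cm[, c])
  pe <- pe / n^2
  list(accuracy = acc,
       f1_macro = mean(f1s),
       gmean_macro = prod(recalls)^(1 / C),
       kappa = if (abs(1 - pe) < 1e-15) 0 else (acc - pe) / (1 - pe),
       recall = recalls)
}
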