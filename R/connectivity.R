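#' Instantaneous phase via the analytic signal
#'
#' Builds the analytic signal z(t) = x(t) + i H\[x\](t) with a
#' frequency-domain discrete Hilbert transform and returns its argument,
#' the instantaneous phase in (-pi, pi].
#'
#' @param x Real numeric series, length >= 8, not constant.
#' @return Numeric vector of phases, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 125)
#' ph <- analytic_phase(cos(2 * pi * 10 * t))
#' @export
analytic_phase <- function(x) {
  Arg(analytic_signal(x))
}

# Frequency-domain analytic signal (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 8) stop("Series too short for a stable Hilbert transform.",
                  call. = FALSE)
  if (!all(is.finite(x))) stop("Series contains non-finite values.",
                               call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("Constant series has no defined instantaneous phase.", call. = FALSE)
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Wrap angles into (-pi, pi].
wrap_phase <- function(d) {
  d - 2 * pi * ceiling((d - pi) / (2 * pi))
}

#' Phase Lag Index of two signals
#'
#' PLI = | < sign(delta_phi(t)) >_t | where delta_phi is the wrapped
#' instantaneous phase difference of the two analytic signals. It is 0 when
#' phase differences are symmetric around zero (in particular for identical
#' or purely zero-lag mixed signals, since sign(0) = 0) and 1 when one
#' signal consistently leads the other; zero-lag (volume-conducted) coupling
#' therefore does not inflate it.
#'
#' @param x1,x2 Real numeric series of equal length.
#' @return A value in \[0, 1\].
#' @examples
#' t <- seq(0, 2, by = 1 / 125)
#' pli(cos(2 * pi * 8 * t), cos(2 * pi * 8 * t - pi / 3))
#' @export
pli <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    stop("Signals must have equal length.", call. = FALSE)
  }
  pli_from_phase(analytic_phase(x1), analytic_phase(x2))
}

pli_from_phase <- function(ph1, ph2) {
  abs(mean(sign(wrap_phase(ph1 - ph2))))
}

#' Pairwise PLI matrix for one band-filtered epoch
#'
#' @param band_epoch A 16 x T numeric matrix (rownames = channels) of one
#'   band-filtered epoch.
#' @return Symmetric 16 x 16 matrix with zero diagonal; a degenerate
#'   (constant) channel zeroes its pairs with a warning.
#' @export
pli_matrix <- function(band_epoch) {
  stopifnot(is.matrix(band_epoch))
  n_ch <- nrow(band_epoch)
  degenerate <- apply(band_epoch, 1, stats::sd) == 0
  if (any(degenerate)) {
    warning("Degenerate (constant) channel(s): ",
            paste(rownames(band_epoch)[degenerate], collapse = ", "),
            "; their PLI entries are set to 0.", call. = FALSE)
  }
  phases <- matrix(NA_real_, nrow = n_ch, ncol = ncol(band_epoch))
  for (ch in which(!degenerate)) {
    phases[ch, ] <- analytic_phase(band_epoch[ch, ])
  }
  out <- matrix(0, n_ch, n_ch,
                dimnames = list(rownames(band_epoch), rownames(band_epoch)))
  for (i in seq_len(n_ch - 1)) {
    for (j in (i + 1):n_ch) {
      v <- if (degenerate[i] || degenerate[j]) 0 else {
        pli_from_phase(phases[i, ], phases[j, ])
      }
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' The 480-dimensional connectivity feature index
#'
#' Fixes the bijection between feature position and (band, electrode pair):
#' bands in canonical order (theta, alpha1, alpha2, beta), and within each
#' band the 120 unordered pairs (i, j), i < j, lexicographic in montage
#' order. Feature names follow the pattern `band_chA_chB`.
#'
#' @return Tibble with columns `index` (1-480), `feature`, `band`, `chan_i`,
#'   `chan_j`, `region_i`, `region_j`.
#' @examples
#' feature_index()
#' @export
feature_index <- function() {
  chans <- montage_channels()
  pairs <- t(utils::combn(length(chans), 2))
  purrr::map_dfr(band_names(), function(b) {
    tibble::tibble(
      band = b,
      chan_i = chans[pairs[, 1]],
      chan_j = chans[pairs[, 2]]
    )
  }) |>
    dplyr::mutate(
      index = dplyr::row_number(),
      feature = paste(.data$band, .data$chan_i, .data$chan_j, sep = "_"),
      region_i = channel_region(.data$chan_i),
      region_j = channel_region(.data$chan_j)
    ) |>
    dplyr::select("index", "feature", "band", "chan_i", "chan_j",
                  "region_i", "region_j")
}

#' PLI feature vector of one band-decomposed epoch
#'
#' @param band_epochs An `eeg_band_epochs` from [band_decompose()].
#' @return Named numeric vector of 480 PLI values ordered per
#'   [feature_index()].
#' @export
feature_vector <- function(band_epochs) {
  stopifnot(inherits(band_epochs, "eeg_band_epochs"))
  missing <- setdiff(band_names(), names(band_epochs$bands))
  if (length(missing) > 0) {
    stop("Missing band(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- feature_index()
  vals <- purrr::map(band_names(), function(b) {
    m <- pli_matrix(band_epochs$bands[[b]])
    m[upper.tri(m)][order_upper_tri(nrow(m))]
  })
  out <- unlist(vals)
  names(out) <- idx$feature
  out
}

# upper.tri() extracts column-major; reorder to row-major (i, j) i<j
# lexicographic order so positions match feature_index().
order_upper_tri <- function(n) {
  pos <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  order(pos[, "row"], pos[, "col"])
}

#' Extract the PLI feature table from a cohort
#'
#' Runs the full preprocessing chain (broadband filter, decimate to 125 Hz,
#' epoch at `window_s`, band-decompose) and computes one 480-feature PLI row
#' per epoch (or per subject when `average_epochs = TRUE`).
#'
#' @param cohort An `eeg_cohort` (or list of `eeg_recording`s).
#' @param window_s Epoch length in seconds.
#' @param average_epochs If TRUE, average each subject's epoch-level feature
#'   vectors into one row per subject.
#' @param pre_clean Optional raw-data cleaning hook, see
#'   [broadband_filter()].
#' @return A tibble with columns `subject_id`, `grade`, `window_s`, `epoch`
#'   and the 480 named feature columns.
#' @export
extract_features <- function(cohort, window_s = 10, average_epochs = FALSE,
                             pre_clean = identity) {
  rows <- purrr::map_dfr(cohort, function(rec) {
    epochs <- preprocess_recording(rec, window_s = window_s,
                                   pre_clean = pre_clean)
    purrr::map_dfr(epochs, function(ep) {
      fv <- feature_vector(band_decompose(ep))
      tibble::as_tibble_row(c(
        list(subject_id = ep$subject_id, grade = ep$grade,
             window_s = window_s, epoch = ep$epoch),
        as.list(fv)
      ))
    })
  })
  if (average_epochs) {
    rows <- rows |>
      dplyr::group_by(.data$subject_id, .data$grade, .data$window_s) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                       !dplyr::any_of("epoch"), mean),
                       .groups = "drop") |>
      dplyr::mutate(epoch = NA_integer_, .after = "window_s")
  }
  rows
}

# Split a feature table into the numeric matrix X and label factor y.
split_xy <- function(features) {
  meta <- intersect(c("subject_id", "grade", "window_s", "epoch"),
                    names(features))
  x <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  y <- factor(features$grade, levels = grade_levels())
  y <- droplevels(y)
  list(x = x, y = y)
}
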