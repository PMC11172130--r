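# Forward-backward filtering with odd-reflection end padding, so filter
# start-up transients decay inside the discarded pad rather than in the
# data. Pad length: 3 s (capped at n - 1).
zero_phase_filter <- function(flt, x, fs) {
  n <- length(x)
  p <- min(n - 1, ceiling(3 * fs))
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  signal::filtfilt(flt, ext)[(p + 1):(p + n)]
}

#' Zero-phase broadband filtering of a recording
#'
#' Applies a 4th-order Butterworth band-pass (4-30 Hz by default) to every
#' channel, forward and backward (`signal::filtfilt`) so the net phase
#' response is zero. Phase-lag connectivity is only meaningful if filtering
#' does not distort phase, hence the zero-phase contract.
#'
#' @param recording An `eeg_recording`.
#' @param lo_hz,hi_hz Pass-band edges in Hz.
#' @param pre_clean Optional function `matrix -> matrix` applied to the raw
#'   channel matrix before filtering. Intended for artifact removal on real
#'   recordings (e.g. an ICA-based cleaner); defaults to identity, which is
#'   appropriate for synthetic artifact-free data.
#' @return The recording with filtered `data`; shape preserved.
#' @export
broadband_filter <- function(recording, lo_hz = 4, hi_hz = 30,
                             pre_clean = identity) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (recording$fs < 100) {
    stop("Sampling rate must be at least 100 Hz for a 4-30 Hz band-pass.",
         call. = FALSE)
  }
  if (!all(is.finite(recording$data))) {
    stop("Recording contains non-finite samples.", call. = FALSE)
  }
  data <- pre_clean(recording$data)
  flt <- signal::butter(4, c(lo_hz, hi_hz) / (recording$fs / 2), type = "pass")
  out <- t(apply(data, 1, function(ch) {
    zero_phase_filter(flt, ch, recording$fs)
  }))
  rownames(out) <- rownames(recording$data)
  recording$data <- out
  recording$filtered <- TRUE
  recording
}

#' Decimate a recording by an integer factor
#'
#' Keeps every `factor`-th sample; halves 250 Hz to the pipeline's working
#' rate of 125 Hz by default. The recording must already be band-limited
#' (see [broadband_filter()]) so decimation cannot alias; calling this on an
#' unfiltered recording triggers a warning, not an error, since the caller
#' may have band-limited the data elsewhere.
#'
#' @param recording An `eeg_recording`.
#' @param factor Integer decimation factor.
#' @return The recording at `fs / factor`.
#' @export
downsample <- function(recording, factor = 2L) {
  stopifnot(inherits(recording, "eeg_recording"))
  factor <- as.integer(factor)
  if (factor < 1) stop("Decimation factor must be a positive integer.",
                       call. = FALSE)
  if (!isTRUE(recording$filtered)) {
    warning("Downsampling a recording that has not passed broadband_filter(); ",
            "the contract is filter-then-decimate.", call. = FALSE)
  }
  fs_post <- recording$fs / factor
  if (fs_post < 60) {
    stop("Post-decimation rate must stay above 2 x 30 Hz.", call. = FALSE)
  }
  recording$data <- recording$data[, seq(1, ncol(recording$data), by = factor),
                                   drop = FALSE]
  recording$fs <- fs_post
  recording
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Consecutive windows of `window_s` seconds; a trailing remainder shorter
#' than one window is discarded, so the epoch count is
#' `floor(duration / window_s)`.
#'
#' @param recording An `eeg_recording` (typically filtered and decimated).
#' @param window_s Window length in seconds; `window_s * fs` must be a whole
#'   number of samples.
#' @return List of `eeg_epoch` objects (`subject_id`, `grade`, `window_s`,
#'   `fs`, `epoch` index, `data` 16 x samples).
#' @export
segment <- function(recording, window_s) {
  stopifnot(inherits(recording, "eeg_recording"))
  samples <- window_s * recording$fs
  if (abs(samples - round(samples)) > 1e-9) {
    stop("window_s * fs must be an integer number of samples.", call. = FALSE)
  }
  samples <- as.integer(round(samples))
  n_epochs <- floor(ncol(recording$data) / samples)
  if (n_epochs < 1) {
    stop("Recording is shorter than one window.", call. = FALSE)
  }
  purrr::map(seq_len(n_epochs), function(k) {
    idx <- ((k - 1) * samples + 1):(k * samples)
    structure(
      list(subject_id = recording$subject_id, grade = recording$grade,
           window_s = window_s, fs = recording$fs, epoch = k,
           data = recording$data[, idx, drop = FALSE]),
      class = "eeg_epoch"
    )
  })
}

#' Decompose an epoch into the four canonical rhythms
#'
#' Each band copy is a zero-phase 4th-order Butterworth band-pass of the
#' epoch (theta 4-8, alpha1 8-10, alpha2 10-13, beta 13-30 Hz).
#'
#' @param epoch An `eeg_epoch`.
#' @return An `eeg_band_epochs`: epoch metadata plus a named list `bands` of
#'   four filtered 16 x T matrices.
#' @export
band_decompose <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (ncol(epoch$data) < 12) {
    stop("Epoch too short for stable 4th-order band filtering.", call. = FALSE)
  }
  bands <- eeg_bands()
  out <- purrr::map(seq_len(nrow(bands)), function(b) {
    flt <- signal::butter(4, c(bands$lo_hz[b], bands$hi_hz[b]) / (epoch$fs / 2),
                          type = "pass")
    filtered <- t(apply(epoch$data, 1, function(ch) {
      zero_phase_filter(flt, ch, epoch$fs)
    }))
    rownames(filtered) <- rownames(epoch$data)
    filtered
  })
  names(out) <- bands$band
  structure(
    list(subject_id = epoch$subject_id, grade = epoch$grade,
         window_s = epoch$window_s, fs = epoch$fs, epoch = epoch$epoch,
         bands = out),
    class = "eeg_band_epochs"
  )
}

#' Standard preprocessing chain for one recording
#'
#' [broadband_filter()] at the native rate, [downsample()] to 125 Hz, then
#' [segment()] into `window_s` epochs.
#'
#' @inheritParams broadband_filter
#' @inheritParams segment
#' @param factor Decimation factor passed to [downsample()].
#' @return List of `eeg_epoch`s at the decimated rate.
#' @export
preprocess_recording <- function(recording, window_s, factor = 2L,
                                 pre_clean = identity) {
  recording |>
    broadband_filter(pre_clean = pre_clean) |>
    downsample(factor = factor) |>
    segment(window_s = window_s)
}
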