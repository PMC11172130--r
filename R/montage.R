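#' Canonical 16-channel 10-20 montage
#'
#' The pipeline works on a fixed montage of 16 scalp electrodes named after
#' the international 10-20 system, in a canonical order that also fixes the
#' ordering of connectivity features. Each electrode maps to one of five
#' lobes (frontal, central, parietal, occipital, temporal) via its 10-20
#' name prefix.
#'
#' @return A tibble with columns `channel` (ordered electrode label),
#'   `region` (lobe) and `x`, `y` (schematic 2-D scalp coordinates used by
#'   the simulator's volume-conduction kernel; head radius 1, nose up).
#' @examples
#' montage_1020()
#' @export
montage_1020 <- function() {
  tibble::tibble(
    channel = c(
      "FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
      "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6"
    ),
    region = c(
      "frontal", "frontal", "frontal", "frontal", "central", "central",
      "parietal", "parietal", "occipital", "occipital", "frontal", "frontal",
      "temporal", "temporal", "temporal", "temporal"
    ),
    # schematic unit-head layout; only relative distances matter
    x = c(-0.31, 0.31, -0.35, 0.35, -0.45, 0.45, -0.35, 0.35,
          -0.31, 0.31, -0.76, 0.76, -0.95, 0.95, -0.76, 0.76),
    y = c(0.95, 0.95, 0.55, 0.55, 0.00, 0.00, -0.55, -0.55,
          -0.95, -0.95, 0.59, 0.59, 0.00, 0.00, -0.59, -0.59)
  )
}

#' @rdname montage_1020
#' @export
montage_channels <- function() montage_1020()$channel

#' Map electrodes to lobes
#'
#' @param channels Character vector of 10-20 electrode labels from the
#'   canonical montage.
#' @return Character vector of lobes, same length as `channels`.
#' @examples
#' channel_region(c("FP1", "T3"))
#' @export
channel_region <- function(channels) {
  m <- montage_1020()
  idx <- match(channels, m$channel)
  if (anyNA(idx)) {
    stop("Unknown electrode label(s): ",
         paste(unique(channels[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  m$region[idx]
}

#' Canonical EEG rhythm definitions
#'
#' Four canonical bands tile 4-30 Hz: theta 4-8 Hz, alpha1 8-10 Hz,
#' alpha2 10-13 Hz, beta 13-30 Hz.
#'
#' @return A tibble with columns `band`, `lo_hz`, `hi_hz`, `center_hz`
#'   (geometric band center used for phase-lag-to-time-shift conversion).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("theta", "alpha1", "alpha2", "beta"),
    lo_hz = c(4, 8, 10, 13),
    hi_hz = c(8, 10, 13, 30),
    center_hz = sqrt(c(4, 8, 10, 13) * c(8, 10, 13, 30))
  )
}

#' @rdname eeg_bands
#' @export
band_names <- function() eeg_bands()$band

#' Four-level anxiety grade labels, in severity order
#' @return Character vector `c("normal", "mild", "moderate", "severe")`.
#' @export
grade_levels <- function() c("normal", "mild", "moderate", "severe")

#' Grade a HAMA score into the four severity levels
#'
#' Total Hamilton Anxiety Rating Scale (HAMA) scores map to four grades:
#' below 7 is normal, 7-17 mild, 18-24 moderate, above 24 severe. Both
#' boundaries of the mild and moderate intervals are inclusive.
#'
#' @param score Vector of non-negative integer HAMA total scores.
#' @return Factor of grades with levels `grade_levels()`.
#' @examples
#' hama_to_grade(c(2, 7, 17, 18, 24, 25))
#' @export
hama_to_grade <- function(score) {
  if (length(score) == 0) {
    return(factor(character(), levels = grade_levels()))
  }
  if (any(!is.finite(score)) || any(score < 0) || any(score != round(score))) {
    stop("HAMA scores must be non-negative integers.", call. = FALSE)
  }
  grade <- dplyr::case_when(
    score < 7 ~ "normal",
    score <= 17 ~ "mild",
    score <= 24 ~ "moderate",
    TRUE ~ "severe"
  )
  factor(grade, levels = grade_levels())
}
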