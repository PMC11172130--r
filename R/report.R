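#' Decode selected features into connectivity edges
#'
#' Maps feature indices or names back to their (band, electrode pair,
#' lobes) attribution via the canonical [feature_index()] bijection. Rank
#' reflects the order of `subset` (e.g. an importance ranking).
#'
#' @param subset Integer feature indices (1-480) or feature names.
#' @return Tibble with `rank`, `index`, `feature`, `band`, `chan_i`,
#'   `chan_j`, `region_i`, `region_j`.
#' @examples
#' decode_features(c("beta_F3_T3", "theta_FP1_FP2"))
#' @export
decode_features <- function(subset) {
  if (length(subset) == 0) stop("Empty feature subset.", call. = FALSE)
  idx <- feature_index()
  pos <- if (is.numeric(subset)) {
    if (any(subset < 1 | subset > nrow(idx) | subset != round(subset))) {
      stop("Feature indices must be integers in 1..", nrow(idx), ".",
           call. = FALSE)
    }
    as.integer(subset)
  } else {
    p <- match(subset, idx$feature)
    if (anyNA(p)) {
      stop("Unknown feature name(s): ",
           paste(subset[is.na(p)], collapse = ", "), call. = FALSE)
    }
    p
  }
  out <- idx[pos, ]
  out$rank <- seq_along(pos)
  dplyr::select(out, "rank", dplyr::everything())
}

#' Rhythm distribution of a feature subset
#'
#' How many selected connectivity features fall in each canonical band;
#' counts sum to the subset size.
#'
#' @inheritParams decode_features
#' @return Tibble with `band` (all four, in canonical order) and `n`.
#' @export
rhythm_distribution <- function(subset) {
  dec <- decode_features(subset)
  dec |>
    dplyr::count(band = factor(.data$band, levels = band_names()),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(band = as.character(.data$band))
}

#' Brain-region distribution of a feature subset
#'
#' Each selected edge credits one endpoint count to each of its two lobes
#' (an intra-lobe edge credits that lobe twice), so counts sum to
#' 2 x subset size.
#'
#' @inheritParams decode_features
#' @return Tibble with `region` (all five lobes) and `n` endpoint counts.
#' @export
region_distribution <- function(subset) {
  dec <- decode_features(subset)
  lobes <- c("frontal", "central", "parietal", "occipital", "temporal")
  tibble::tibble(region = factor(c(dec$region_i, dec$region_j),
                                 levels = lobes)) |>
    dplyr::count(.data$region, .drop = FALSE, name = "n") |>
    dplyr::mutate(region = as.character(.data$region))
}

#' Region-by-rhythm attribution cross-table
#'
#' Endpoint counts split by band, so either marginal reading (per band, per
#' region, or the joint) is recoverable.
#'
#' @inheritParams decode_features
#' @return Tibble with `region`, `band`, `n`; `n` sums to 2 x subset size.
#' @export
region_rhythm_table <- function(subset) {
  dec <- decode_features(subset)
  lobes <- c("frontal", "central", "parietal", "occipital", "temporal")
  tibble::tibble(
    region = factor(c(dec$region_i, dec$region_j), levels = lobes),
    band = factor(c(dec$band, dec$band), levels = band_names())
  ) |>
    dplyr::count(.data$region, .band = .data$band, .drop = FALSE,
                 name = "n") |>
    dplyr::rename(band = ".band") |>
    dplyr::mutate(region = as.character(.data$region),
                  band = as.character(.data$band))
}
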