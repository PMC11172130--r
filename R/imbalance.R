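#' Configuration for combined cleaning and resampling (CCR)
#'
#' @param energy Per-minority-point energy budget used to grow cleaning
#'   spheres, in feature-space distance units. `NULL` (default) sets it to
#'   0.25 x the median pairwise distance of the training set, a scale-aware
#'   default since no canonical value exists.
#' @param policy `"balance"` raises every non-largest class to the largest
#'   class count; `"multiplier"` multiplies each processed class count by
#'   `multiplier`.
#' @param multiplier Oversampling multiplier (>= 1) for the multiplier
#'   policy.
#' @param seed Integer seed for synthetic-point generation.
#' @return A `ccr_config` list.
#' @export
ccr_config <- function(energy = NULL, policy = c("balance", "multiplier"),
                       multiplier = 4, seed = 1L) {
  policy <- match.arg(policy)
  if (!is.null(energy) && energy <= 0) {
    stop("energy must be positive.", call. = FALSE)
  }
  if (multiplier < 1) stop("multiplier must be >= 1.", call. = FALSE)
  structure(list(energy = energy, policy = policy, multiplier = multiplier,
                 seed = as.integer(seed)),
            class = "ccr_config")
}

# 0.25 x median pairwise distance; large n is thinned deterministically.
default_ccr_energy <- function(x) {
  n <- nrow(x)
  if (n > 400) x <- x[round(seq(1, n, length.out = 400)), , drop = FALSE]
  0.25 * stats::median(stats::dist(x))
}

# Energy-limited sphere radius around one minority point: expanding the
# radius costs (k + 1) per unit once k majority points are inside.
ccr_radius <- function(dists, energy) {
  d <- sort(dists)
  r <- 0
  e <- energy
  k <- 0
  for (dk in d) {
    cost <- (k + 1) * (dk - r)
    if (e >= cost) {
      e <- e - cost
      r <- dk
      k <- k + 1
    } else {
      return(r + e / (k + 1))
    }
  }
  r + e / (k + 1)
}

#' CCR cleaning step
#'
#' Grows an energy-limited sphere around every minority point and pushes
#' majority points strictly inside a sphere radially onto its surface,
#' cleaning the class boundary. Minority points never move. When spheres
#' overlap, a point is moved along the radial direction of its deepest
#' sphere far enough to leave every sphere that ray crosses, so no
#' majority point remains strictly inside any sphere.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Vector of class labels aligned with `x`.
#' @param minority_class The class whose neighborhood is cleaned.
#' @param energy Per-minority-point energy budget; `NULL` for the
#'   scale-aware default.
#' @param movable Logical vector marking rows that may be displaced
#'   (default: every non-minority row). Rows not movable still resist
#'   sphere growth but stay in place.
#' @return List with `x` (cleaned matrix), `radii` (per minority point),
#'   `minority_idx`, and `moved` (logical, rows displaced).
#' @export
ccr_clean <- function(x, y, minority_class, energy = NULL, movable = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (!all(is.finite(x))) stop("Features must be finite.", call. = FALSE)
  min_idx <- which(y == minority_class)
  maj_idx <- which(y != minority_class)
  if (length(min_idx) == 0) {
    stop("Minority class absent from the data.", call. = FALSE)
  }
  if (is.null(energy)) energy <- default_ccr_energy(x)
  if (is.null(movable)) movable <- y != minority_class

  radii <- numeric(length(min_idx))
  if (length(maj_idx) == 0) {
    radii[] <- energy
    return(list(x = x, radii = radii, minority_idx = min_idx,
                moved = rep(FALSE, nrow(x))))
  }
  for (a in seq_along(min_idx)) {
    d <- sqrt(colSums((t(x[maj_idx, , drop = FALSE]) - x[min_idx[a], ])^2))
    radii[a] <- ccr_radius(d, energy)
  }

  moved <- rep(FALSE, nrow(x))
  mov_idx <- intersect(maj_idx, which(movable))
  eps <- 1e-12
  margin <- 1e-9
  if (length(mov_idx) > 0) {
    centers <- x[min_idx, , drop = FALSE]
    # spheres may overlap, so pushing to one surface can land inside
    # another; move each violating point along the radial ray of its
    # deepest sphere to just past the farthest exit over all spheres on
    # that ray, which clears the whole union in one step
    for (row in mov_idx) {
      d <- sqrt(colSums((t(centers) - x[row, ])^2))
      depth <- radii - d
      worst <- which.max(depth)
      if (depth[worst] <= eps) next
      if (d[worst] < eps) {
        # coincident point: push along a deterministic axis direction
        dir <- c(1, numeric(ncol(x) - 1))
      } else {
        dir <- (x[row, ] - centers[worst, ]) / d[worst]
      }
      t_exit <- 0
      for (s in seq_len(nrow(centers))) {
        rel <- centers[s, ] - x[row, ]
        b <- sum(rel * dir)
        disc <- b^2 - (sum(rel^2) - radii[s]^2)
        if (disc > 0) t_exit <- max(t_exit, b + sqrt(disc))
      }
      x[row, ] <- x[row, ] + dir * (t_exit + margin)
      moved[row] <- TRUE
    }
  }
  list(x = x, radii = radii, minority_idx = min_idx, moved = moved)
}

#' CCR oversampling step
#'
#' Draws synthetic minority points uniformly inside the cleaning spheres.
#' Each minority point's quota is proportional to the inverse of its sphere
#' radius (normalized over minority points): small spheres mark unsafe
#' points close to the majority and receive more synthetics.
#'
#' @param x Cleaned feature matrix.
#' @param y Labels aligned with `x`.
#' @param minority_class Class to oversample.
#' @param radii Sphere radii from [ccr_clean()], aligned with the minority
#'   rows in order.
#' @param target_count Desired total minority count (>= current).
#' @return List with `x_new` (matrix of synthetic rows, possibly 0-row) and
#'   `seed_of` (minority row index each synthetic was drawn around).
#' @export
ccr_oversample <- function(x, y, minority_class, radii, target_count) {
  min_idx <- which(y == minority_class)
  stopifnot(length(radii) == length(min_idx))
  n_min <- length(min_idx)
  if (target_count < n_min) {
    stop("target_count is below the current minority count.", call. = FALSE)
  }
  n_syn <- target_count - n_min
  d <- ncol(x)
  if (n_syn == 0) {
    return(list(x_new = matrix(numeric(0), 0, d), seed_of = integer(0)))
  }
  w <- (1 / radii) / sum(1 / radii)
  quota <- floor(n_syn * w)
  rem <- n_syn - sum(quota)
  if (rem > 0) {
    frac <- n_syn * w - quota
    quota[order(-frac, seq_along(frac))[seq_len(rem)]] <-
      quota[order(-frac, seq_along(frac))[seq_len(rem)]] + 1
  }
  x_new <- matrix(NA_real_, n_syn, d)
  seed_of <- integer(n_syn)
  k <- 0
  for (a in seq_along(min_idx)) {
    if (quota[a] == 0) next
    for (s in seq_len(quota[a])) {
      dir <- stats::rnorm(d)
      dir <- dir / sqrt(sum(dir^2))
      rad <- radii[a] * stats::runif(1)^(1 / d)
      k <- k + 1
      x_new[k, ] <- x[min_idx[a], ] + dir * rad
      seed_of[k] <- min_idx[a]
    }
  }
  list(x_new = x_new, seed_of = seed_of)
}

#' Combined cleaning and resampling for a multiclass training set
#'
#' Applies CCR cleaning + oversampling to every non-largest class, rarest
#' class first (one-vs-rest). Cleaning spheres grow against all points of
#' other classes, but only points of the largest class(es) — the ones never
#' themselves resampled — are displaced, so every resampled class's
#' original rows survive unchanged. Intended for training folds only; never apply it to
#' evaluation data.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels aligned with `x`.
#' @param config A [ccr_config()].
#' @return List with `x`, `y` (augmented data) and `synthetic` (logical,
#'   TRUE for generated rows).
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(10) + 4, 5))
#' y <- rep(c("a", "b"), c(20, 5))
#' out <- ccr_resample(x, y, ccr_config(seed = 1))
#' table(out$y)
#' @export
ccr_resample <- function(x, y, config = ccr_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.character(y)
  counts <- table(y)
  if (length(counts) < 2) {
    stop("CCR needs at least two classes.", call. = FALSE)
  }
  energy <- if (is.null(config$energy)) default_ccr_energy(x) else config$energy

  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  orig_counts <- counts
  max_count <- max(counts)
  # every non-largest class, rarest first
  process <- names(sort(counts[counts < max_count]))

  synthetic <- rep(FALSE, length(y))
  for (cls in process) {
    target <- switch(config$policy,
      balance = max_count,
      multiplier = ceiling(config$multiplier * orig_counts[[cls]])
    )
    # only classes that are never themselves resampled may be displaced,
    # so every resampled class's original rows survive unchanged
    movable <- !synthetic & y != cls & orig_counts[y] == max_count
    cleaned <- ccr_clean(x, y, cls, energy = energy, movable = movable)
    x <- cleaned$x
    os <- ccr_oversample(x, y, cls, cleaned$radii, target)
    if (nrow(os$x_new) > 0) {
      x <- rbind(x, os$x_new)
      y <- c(y, rep(cls, nrow(os$x_new)))
      synthetic <- c(synthetic, rep(TRUE, nrow(os$x_new)))
    }
  }
  rownames(x) <- NULL
  list(x = x, y = y, synthetic = synthetic)
}

#' Tidy wrapper: CCR-balance a feature table
#'
#' @param features Feature tibble as from [extract_features()] (metadata
#'   columns plus numeric features, labels in `grade`).
#' @param config A [ccr_config()].
#' @return Tibble with the same columns plus `.synthetic`; synthetic rows
#'   carry `NA` metadata.
#' @export
ccr_balance <- function(features, config = ccr_config()) {
  xy <- split_xy(features)
  out <- ccr_resample(xy$x, as.character(xy$y), config)
  n_orig <- nrow(features)
  n_new <- length(out$y) - n_orig
  feat_cols <- colnames(xy$x)
  base <- features
  base[, feat_cols] <- out$x[seq_len(n_orig), , drop = FALSE]
  if (n_new > 0) {
    extra <- tibble::as_tibble(out$x[(n_orig + 1):length(out$y), ,
                                     drop = FALSE])
    extra$grade <- out$y[(n_orig + 1):length(out$y)]
    add <- dplyr::bind_rows(base[0, ], extra)
    base <- dplyr::bind_rows(base, add)
  }
  base$.synthetic <- out$synthetic
  base
}
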