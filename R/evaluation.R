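#' Confusion matrix with fixed class order
#'
#' @param truth,estimate Vectors of true and predicted labels; factor
#'   levels (union) fix the class order, rows are truth, columns are
#'   predictions.
#' @return C x C integer matrix.
#' @export
confusion_matrix <- function(truth, estimate) {
  lv <- union(levels(as.factor(truth)), levels(as.factor(estimate)))
  truth <- factor(truth, levels = lv)
  estimate <- factor(estimate, levels = lv)
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length.", call. = FALSE)
  }
  unclass(table(truth = truth, estimate = estimate))
}

#' Multiclass metrics from a confusion matrix
#'
#' Computes accuracy (trace over total), macro F1 (mean over classes of
#' 2TP / (2TP + FP + FN)), macro G-mean (geometric mean of per-class
#' recalls — zero as soon as one class is never recovered), Cohen's kappa
#' ((Po - Pe) / (1 - Pe) with the multiclass chance agreement
#' Pe = sum_c row_c * col_c / total^2), and per-class recall (diagonal over
#' row sum — the per-group "accuracy" of a grading report). A class with no
#' true and no predicted members contributes F1 = 0; a class with no true
#' members has recall 0; a degenerate matrix with Pe = 1 gets kappa 0.
#'
#' @param cm Square confusion matrix (rows = truth).
#' @return One-row tibble: `accuracy`, `f1_macro`, `gmean_macro`, `kappa`,
#'   plus one `recall_<class>` column per class.
#' @examples
#' cm <- confusion_matrix(rep(c("a", "b"), c(50, 50)),
#'                        rep(c("a", "b", "a", "b"), c(40, 10, 5, 45)))
#' compute_metrics(cm)
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0) stop("Empty confusion matrix.", call. = FALSE)
  tp <- diag(cm)
  row_s <- rowSums(cm)
  col_s <- colSums(cm)
  fp <- col_s - tp
  fn <- row_s - tp

  recall <- ifelse(row_s > 0, tp / row_s, 0)
  f1_den <- 2 * tp + fp + fn
  f1 <- ifelse(f1_den > 0, 2 * tp / f1_den, 0)

  po <- sum(tp) / total
  pe <- sum(row_s * col_s) / total^2
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)

  out <- tibble::tibble(
    accuracy = po,
    f1_macro = mean(f1),
    gmean_macro = prod(recall)^(1 / nrow(cm)),
    kappa = kappa
  )
  rec <- tibble::as_tibble_row(stats::setNames(as.list(recall),
                                               paste0("recall_", rownames(cm))))
  dplyr::bind_cols(out, rec)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("Every class needs at least as many rows as folds.", call. = FALSE)
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Inner 80/20 stratified tuning split + TPE over the backend's space;
# the outer test fold never reaches the objective.
tune_fold <- function(spec, x, y, tune, seed) {
  space <- tune$space %||% search_space(spec$backend)
  max_evals <- tune$max_evals %||% 30
  k_inner <- max(2, min(5, min(table(y))))
  inner <- stratified_folds(y, k_inner, seed)
  tr <- inner != 1
  objective <- function(params) {
    s <- spec
    s$params <- utils::modifyList(s$params, params)
    fit <- fit_boost(s, x[tr, , drop = FALSE], y[tr])
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    compute_metrics(confusion_matrix(y[!tr], pred))$f1_macro
  }
  res <- tpe_search(space, objective, max_evals = max_evals, seed = seed)
  res$best_params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Repeated stratified K-fold cross-validation
#'
#' The pipeline's evaluation protocol: stratified 5-fold cross-validation
#' repeated 3 times, results averaged over all test folds. CCR resampling,
#' TPE tuning and any feature subset are applied strictly inside each
#' training fold; evaluation rows never reach them.
#'
#' @param features Feature tibble as from [extract_features()] (metadata
#'   columns `subject_id`, `grade`, `window_s`, `epoch` plus numeric
#'   feature columns).
#' @param spec A [boost_spec()].
#' @param folds,repeats Cross-validation geometry.
#' @param seed Master seed; each repeat derives its own fold seed.
#' @param ccr `NULL`, or a [ccr_config()] applied to every training fold.
#' @param tune `NULL`, or a list with optional `space` and `max_evals`
#'   driving a per-fold TPE search (objective: inner-split macro F1).
#' @param features_subset `NULL`, or character vector of feature columns to
#'   restrict the model to.
#' @return A `cv_result`: per-fold metric tibble, pooled confusion matrix,
#'   and mean/sd summary; see [tidy()][tidy.cv_result] and
#'   [glance()][glance.cv_result].
#' @export
repeated_stratified_cv <- function(features, spec = boost_spec(),
                                   folds = 5, repeats = 3, seed = 1L,
                                   ccr = NULL, tune = NULL,
                                   features_subset = NULL) {
  xy <- split_xy(features)
  x <- xy$x
  y <- xy$y
  if (!is.null(features_subset)) {
    x <- x[, features_subset, drop = FALSE]
  }
  fold_rows <- list()
  cms <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds, derive_seed(seed, 1000 + r))
    for (f in seq_len(folds)) {
      tr <- fold != f
      x_tr <- x[tr, , drop = FALSE]
      y_tr <- y[tr]
      s <- spec
      s$seed <- as.integer(derive_seed(seed, 100 * r + f) %% 1e6)
      if (!is.null(tune)) {
        best <- tune_fold(s, x_tr, y_tr, tune,
                          seed = as.integer(derive_seed(seed, 7000 + 10 * r + f) %% 1e6))
        s$params <- utils::modifyList(s$params, best)
      }
      if (!is.null(ccr)) {
        cc <- ccr
        cc$seed <- as.integer(derive_seed(seed, 9000 + 10 * r + f) %% 1e6)
        rs <- ccr_resample(x_tr, as.character(y_tr), cc)
        x_tr <- rs$x
        y_tr <- factor(rs$y, levels = levels(y))
        colnames(x_tr) <- colnames(x)
      }
      fit <- fit_boost(s, x_tr, y_tr)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      cm <- confusion_matrix(factor(y[!tr], levels = levels(y)),
                             factor(pred, levels = levels(y)))
      cms[[length(cms) + 1]] <- cm
      fold_rows[[length(fold_rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = r, fold = f, n_test = sum(!tr)),
        compute_metrics(cm)
      )
    }
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  structure(
    list(fold_metrics = fold_metrics,
         confusion = Reduce(`+`, cms),
         confusion_by_fold = cms,
         spec = spec, folds = folds, repeats = repeats, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat("<cv_result>", x$repeats, "x", x$folds, "-fold CV\n")
  cat(sprintf("  accuracy %.3f +/- %.3f | F1-macro %.3f | Gmean %.3f | kappa %.3f\n",
              g$accuracy, g$accuracy_sd, g$f1_macro, g$gmean_macro, g$kappa))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per (repeat, fold).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$fold_metrics

#' Fold-averaged cross-validation summary
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: mean of every metric over folds plus `<metric>_sd`
#'   columns.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  m <- x$fold_metrics |>
    dplyr::select(-dplyr::all_of(c("repeat_", "fold", "n_test")))
  means <- dplyr::summarise(m, dplyr::across(dplyr::everything(), mean))
  sds <- dplyr::summarise(m, dplyr::across(dplyr::everything(),
                                           stats::sd, .names = "{.col}_sd"))
  dplyr::bind_cols(means, sds)
}

#' Time-window sweep over the full pipeline
#'
#' Re-runs feature extraction and repeated cross-validation for each window
#' length, producing the material for a window-length performance trend
#' plot.
#'
#' @param cohort An `eeg_cohort`.
#' @param windows Window lengths in seconds.
#' @param spec A [boost_spec()].
#' @inheritParams repeated_stratified_cv
#' @return A `sweep_result` tibble: one row per window with epoch counts
#'   and mean/sd of each metric; plot with [autoplot()].
#' @export
time_window_sweep <- function(cohort, windows = c(2, 4, 6, 8, 10, 12, 14),
                              spec = boost_spec(), folds = 5, repeats = 3,
                              seed = 1L, ccr = NULL, tune = NULL) {
  dur <- min(purrr::map_dbl(cohort, ~ ncol(.x$data) / .x$fs))
  if (max(windows) > dur) {
    stop("Longest window exceeds the shortest recording.", call. = FALSE)
  }
  rows <- purrr::map_dfr(windows, function(w) {
    feats <- extract_features(cohort, window_s = w)
    cv <- repeated_stratified_cv(feats, spec, folds = folds,
                                 repeats = repeats,
                                 seed = as.integer(derive_seed(seed, w) %% 1e6),
                                 ccr = ccr, tune = tune)
    dplyr::bind_cols(
      tibble::tibble(window_s = w, n_epochs = nrow(feats),
                     epochs_per_subject = floor(dur / w)),
      glance(cv)
    )
  })
  class(rows) <- c("sweep_result", class(rows))
  rows
}
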