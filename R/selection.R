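#' Fold-averaged feature importance
#'
#' Fits the model on each of `k` stratified training folds and averages the
#' per-fold gain importances, giving a ranking less tied to one particular
#' split.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels.
#' @param spec A [boost_spec()].
#' @param k Number of folds.
#' @param seed Fold seed.
#' @return Named numeric vector of averaged importances (training-feature
#'   order).
#' @export
fold_averaged_importance <- function(x, y, spec = boost_spec(), k = 5,
                                     seed = 1L) {
  fold <- stratified_folds(y, k, seed)
  imps <- purrr::map(seq_len(k), function(f) {
    fit <- fit_boost(spec, x[fold != f, , drop = FALSE], y[fold != f])
    feature_importance(fit)
  })
  Reduce(`+`, imps) / k
}

# One RFE iteration: k-fold fits give both test-fold metrics and the
# fold-averaged importance, mirroring the two uses of the same folds.
rfe_evaluate <- function(x, y, spec, folds, seed, ccr = NULL) {
  fold <- stratified_folds(y, folds, seed)
  cms <- list()
  imps <- list()
  for (f in seq_len(folds)) {
    tr <- fold != f
    x_tr <- x[tr, , drop = FALSE]
    y_tr <- y[tr]
    if (!is.null(ccr)) {
      cc <- ccr
      cc$seed <- as.integer(derive_seed(seed, f) %% 1e6)
      rs <- ccr_resample(x_tr, as.character(y_tr), cc)
      x_tr <- rs$x
      colnames(x_tr) <- colnames(x)
      y_tr <- factor(rs$y, levels = levels(y))
    }
    fit <- fit_boost(spec, x_tr, y_tr)
    imps[[f]] <- feature_importance(fit)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    cms[[f]] <- confusion_matrix(factor(y[!tr], levels = levels(y)),
                                 factor(pred, levels = levels(y)))
  }
  list(metrics = compute_metrics(Reduce(`+`, cms)),
       importance = Reduce(`+`, imps) / folds)
}

#' Recursive feature elimination with early stopping
#'
#' Starting from the full feature set, each iteration (1) fits the model on
#' `folds` stratified folds, records the pooled cross-validated metrics and
#' the fold-averaged importances, and (2) removes the single
#' lowest-importance feature. Iteration stops when `patience` consecutive
#' iterations each fail to strictly improve on the iteration before them,
#' or when one feature remains. The optimal subset is the one with the
#' highest stopping metric seen anywhere in the trace; metric ties go to
#' the smaller subset. (A constant metric trace therefore stops after
#' exactly `patience + 1` iterations; comparing against the immediately
#' preceding iteration rather than the best-so-far keeps the stopping
#' horizon tied to the information in the trace instead of the discrete
#' granularity of a cross-validated accuracy.)
#'
#' @param features Feature tibble as from [extract_features()], or a
#'   numeric matrix (then supply `y`).
#' @param spec A [boost_spec()].
#' @param y Labels, only when `features` is a matrix.
#' @param patience Consecutive non-improving iterations tolerated (>= 1).
#' @param metric Stopping/selection metric column, default `"accuracy"`.
#' @param folds Folds of the internal CV; the fold seed schedule is fixed
#'   by `seed` so traces are reproducible.
#' @param seed Integer seed.
#' @param ccr `NULL`, or a [ccr_config()] applied inside each training fold
#'   before importance fitting.
#' @param eval_fn Advanced hook replacing the internal evaluation: a
#'   function `(x, y, seed) -> list(metrics = one-row tibble,
#'   importance = named vector)`. Used for testing the stopping
#'   bookkeeping with constructed models.
#' @return An `rfe_trace`: list with `trace` (tibble: iteration,
#'   n_features, metrics), `best_features` (character), `best_metrics`
#'   (one-row tibble), `best_iteration`, `removed` (elimination order).
#' @export
rfe_early_stop <- function(features, spec = boost_spec(), y = NULL,
                           patience = 10, metric = "accuracy", folds = 5,
                           seed = 1L, ccr = NULL, eval_fn = NULL) {
  if (patience < 1) stop("patience must be >= 1.", call. = FALSE)
  if (is.matrix(features)) {
    x <- features
    stopifnot(!is.null(y))
    y <- droplevels(as.factor(y))
  } else {
    xy <- split_xy(features)
    x <- xy$x
    y <- xy$y
  }
  if (ncol(x) < 2) stop("Need at least two features.", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  active <- colnames(x)
  trace <- list()
  subsets <- list()
  removed <- character(0)
  prev <- -Inf
  stale <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    res <- if (is.null(eval_fn)) {
      rfe_evaluate(x[, active, drop = FALSE], y, spec, folds,
                   seed = derive_seed(seed, iter), ccr = ccr)
    } else {
      eval_fn(x[, active, drop = FALSE], y, derive_seed(seed, iter))
    }
    m <- res$metrics[[metric]]
    trace[[iter]] <- dplyr::bind_cols(
      tibble::tibble(iteration = iter, n_features = length(active)),
      res$metrics
    )
    subsets[[iter]] <- active
    if (m > prev) {
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    prev <- m
    if (stale >= patience || length(active) == 1) break
    # drop the lowest-importance feature; exact ties (typically the
    # zero-gain bulk) are broken by a seeded draw — features are indexed
    # band-contiguously, so any index-based rule would bias the surviving
    # set toward one band
    imp <- res$importance[active]
    ties <- which(imp == min(imp))
    pick <- if (length(ties) == 1) ties else {
      old_rng <- .Random.seed_exists()
      set.seed(as.integer(derive_seed(seed, 5000 + iter) %% 1e6))
      s <- ties[sample.int(length(ties), 1)]
      .Random.seed_restore(old_rng)
      s
    }
    drop <- active[pick]
    removed <- c(removed, drop)
    active <- setdiff(active, drop)
  }
  trace <- dplyr::bind_rows(trace)
  scores <- trace[[metric]]
  best_iter <- which(scores == max(scores))
  best_iter <- best_iter[which.min(trace$n_features[best_iter])]
  structure(
    list(trace = trace,
         best_features = subsets[[best_iter]],
         best_metrics = trace[best_iter, ],
         best_iteration = best_iter,
         removed = removed,
         metric = metric),
    class = "rfe_trace"
  )
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat("<rfe_trace>", nrow(x$trace), "iterations | optimal subset:",
      length(x$best_features), "features |", x$metric, "=",
      signif(x$best_metrics[[x$metric]], 4), "\n")
  invisible(x)
}

#' Iteration trace of an RFE run
#' @param x An `rfe_trace`.
#' @param ... Unused.
#' @return Tibble with one row per iteration.
#' @method tidy rfe_trace
#' @export
tidy.rfe_trace <- function(x, ...) x$trace

#' Optimal-subset summary of an RFE run
#' @param x An `rfe_trace`.
#' @param ... Unused.
#' @return One-row tibble: best iteration, subset size and its metrics.
#' @method glance rfe_trace
#' @export
glance.rfe_trace <- function(x, ...) x$best_metrics
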