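#' Specify a gradient-boosted-tree classifier
#'
#' One interface over three boosting backends. `xgboost` ships with the
#' package's dependencies and is the default; `lightgbm` and `catboost` are
#' optional backends used only if their R packages are installed.
#'
#' @param backend One of `"xgboost"`, `"lightgbm"`, `"catboost"`.
#' @param params Named list of backend hyperparameters, using the names of
#'   the backend's search space (see [search_space()]); anything not given
#'   keeps the library default.
#' @param nrounds Number of boosting rounds. The default (50) saturates
#'   training loss at the feature-table sizes this pipeline produces;
#'   raise it for larger cohorts.
#' @param seed Integer seed for the backend's internal randomness.
#' @return A `boost_spec`.
#' @examples
#' boost_spec("xgboost", params = list(depth = 4, learning_rate = 0.05))
#' @export
boost_spec <- function(backend = c("xgboost", "lightgbm", "catboost"),
                       params = list(), nrounds = 50, seed = 1L) {
  backend <- match.arg(backend)
  structure(list(backend = backend, params = params,
                 nrounds = as.integer(nrounds), seed = as.integer(seed)),
            class = "boost_spec")
}

#' @export
print.boost_spec <- function(x, ...) {
  cat("<boost_spec>", x$backend, "| nrounds:", x$nrounds, "\n")
  if (length(x$params)) {
    cat("  ", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit a boosted-tree classifier
#'
#' @param spec A [boost_spec()].
#' @param x Numeric feature matrix (column names required).
#' @param y Factor (or coercible) of class labels; at least two classes.
#' @return A fitted `boost_fit` exposing [predict()][predict.boost_fit] and
#'   [feature_importance()].
#' @export
fit_boost <- function(spec, x, y) {
  stopifnot(inherits(spec, "boost_spec"), is.matrix(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop("Features must be finite.", call. = FALSE)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    stop("Training labels contain a single class.", call. = FALSE)
  }
  fit <- switch(spec$backend,
    xgboost = fit_xgboost(spec, x, y),
    lightgbm = ,
    catboost = fit_optional_backend(spec, x, y)
  )
  structure(list(backend = spec$backend, model = fit, levels = levels(y),
                 features = colnames(x), spec = spec),
            class = "boost_fit")
}

# Translate search-space parameter names to native xgboost names.
xgb_params <- function(params) {
  rename <- c(learning_rate = "eta", depth = "max_depth")
  names(params) <- ifelse(names(params) %in% names(rename),
                          rename[names(params)], names(params))
  params
}

fit_xgboost <- function(spec, x, y) {
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  params <- c(
    xgb_params(spec$params),
    list(objective = "multi:softprob", num_class = nlevels(y),
         nthread = 1, verbosity = 0, seed = spec$seed)
  )
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = spec$nrounds,
                     verbose = 0)
}

fit_optional_backend <- function(spec, x, y) {
  if (!requireNamespace(spec$backend, quietly = TRUE)) {
    stop("Backend '", spec$backend, "' requires the R package of the same ",
         "name, which is not installed. Use backend = \"xgboost\".",
         call. = FALSE)
  }
  if (spec$backend == "lightgbm") {
    lgb <- getNamespace("lightgbm")
    dtrain <- lgb$lgb.Dataset(x, label = as.integer(y) - 1L)
    lgb$lgb.train(
      params = c(spec$params,
                 list(objective = "multiclass", num_class = nlevels(y),
                      verbosity = -1, num_threads = 1, seed = spec$seed)),
      data = dtrain, nrounds = spec$nrounds, verbose = -1
    )
  } else {
    cb <- getNamespace("catboost")
    pool <- cb$catboost.load_pool(as.data.frame(x),
                                  label = as.integer(y) - 1L)
    cb$catboost.train(pool, params = c(spec$params,
      list(loss_function = "MultiClass", iterations = spec$nrounds,
           random_seed = spec$seed, logging_level = "Silent",
           thread_count = 1)))
  }
}

#' @export
print.boost_fit <- function(x, ...) {
  cat("<boost_fit>", x$backend, "|", length(x$features), "features |",
      length(x$levels), "classes\n")
  invisible(x)
}

#' Predict class labels or probabilities
#'
#' @param object A `boost_fit`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param type `"class"` for labels, `"prob"` for a probability matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or an n x C probability matrix.
#' @export
predict.boost_fit <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  newdata <- newdata[, object$features, drop = FALSE]
  prob <- switch(object$backend,
    xgboost = {
      p <- stats::predict(object$model,
                          xgboost::xgb.DMatrix(newdata, nthread = 1))
      matrix(p, nrow = nrow(newdata), byrow = !is.matrix(p),
             ncol = length(object$levels))
    },
    lightgbm = {
      p <- stats::predict(object$model, newdata)
      matrix(p, nrow = nrow(newdata), ncol = length(object$levels))
    },
    catboost = {
      cb <- getNamespace("catboost")
      cb$catboost.predict(object$model,
                          cb$catboost.load_pool(as.data.frame(newdata)),
                          prediction_type = "Probability")
    }
  )
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' Per-feature importance of a fitted booster
#'
#' Gain-based importance, reported for every training feature (zero for
#' features the trees never split on). Non-negative by construction.
#'
#' @param fit A `boost_fit`.
#' @return Named numeric vector, one entry per training feature.
#' @export
feature_importance <- function(fit) {
  stopifnot(inherits(fit, "boost_fit"))
  out <- stats::setNames(numeric(length(fit$features)), fit$features)
  imp <- switch(fit$backend,
    xgboost = {
      # aggregate split gains from the text dump; the C-level importance
      # accessor aborts on boosters whose trees never split
      dump <- xgboost::xgb.dump(fit$model, with_stats = TRUE)
      splits <- regmatches(dump,
                           regexec("\\[([^]<]+)<[^]]*\\].*gain=([-0-9.eE+]+)",
                                   dump))
      splits <- splits[lengths(splits) == 3]
      if (length(splits) == 0) numeric(0) else {
        gains <- tapply(
          vapply(splits, function(s) as.numeric(s[3]), 0),
          vapply(splits, function(s) s[2], ""),
          sum
        )
        gains / sum(gains)
      }
    },
    lightgbm = {
      lgb <- getNamespace("lightgbm")
      tab <- lgb$lgb.importance(fit$model)
      stats::setNames(tab$Gain, tab$Feature)
    },
    catboost = {
      cb <- getNamespace("catboost")
      v <- cb$catboost.get_feature_importance(fit$model)
      stats::setNames(as.numeric(v), fit$features)
    }
  )
  out[names(imp)] <- imp
  out
}

#' Printed hyperparameter search space of each backend
#'
#' The tuned parameters and their ranges for the three backends:
#' LightGBM (`num_leaves` uniformint \[16, 96\], `min_data_in_leaf`
#' uniformint \[2, 60\], `feature_fraction` uniform \[0.75, 1\],
#' `learning_rate` loguniform \[log(5e-3), log(0.1)\]); Xgboost
#' (`learning_rate` loguniform \[log(5e-3), log(0.1)\], `depth` uniformint
#' \[3, 10\], `min_child_weight` uniformint \[1, 5\], `colsample_bytree`
#' uniform \[0.5, 1\]); Catboost (`max_depth` uniformint \[5, 8\],
#' `l2_leaf_reg` uniform \[1, 5\], `learning_rate` loguniform
#' \[log(5e-3), log(0.1)\]).
#'
#' @param backend Backend name.
#' @return Named list of parameter distributions for [tpe_search()].
#' @export
search_space <- function(backend = c("xgboost", "lightgbm", "catboost")) {
  backend <- match.arg(backend)
  lr <- p_loguniform(log(5e-3), log(0.1))
  switch(backend,
    lightgbm = list(
      num_leaves = p_uniformint(16, 96),
      min_data_in_leaf = p_uniformint(2, 60),
      feature_fraction = p_uniform(0.75, 1),
      learning_rate = lr
    ),
    xgboost = list(
      learning_rate = lr,
      depth = p_uniformint(3, 10),
      min_child_weight = p_uniformint(1, 5),
      colsample_bytree = p_uniform(0.5, 1.0)
    ),
    catboost = list(
      max_depth = p_uniformint(5, 8),
      l2_leaf_reg = p_uniform(1, 5),
      learning_rate = lr
    )
  )
}
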