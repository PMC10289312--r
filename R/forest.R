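# Random-forest regression of E-score deductions, day-wise sequential
# split, importance-based feature selection and the single-feature baseline.

#' Day-wise sequential train/test split
#'
#' Holds out every performance from the `n_test_days` chronologically last
#' session days and trains on the rest, so that day-level conditions cannot
#' leak between the sets (an athlete's form varies by day; random splits
#' would teach it to the model).
#'
#' @param records data frame with a `day` column.
#' @param n_test_days number of final days to hold out.
#' @return list(train, test) of disjoint row subsets covering `records`.
#' @export
sequential_split <- function(records, n_test_days = 2L) {
  days <- sort(unique(records$day))
  if (length(days) <= n_test_days) {
    wv_stop("split_error",
            "need more distinct days than test days (train would be empty)")
  }
  test_days <- utils::tail(days, n_test_days)
  in_test <- records$day %in% test_days
  list(train = records[!in_test, , drop = FALSE],
       test = records[in_test, , drop = FALSE],
       train_days = setdiff(days, test_days), test_days = test_days)
}

#' Train the random-forest deduction model
#'
#' Bagged regression CARTs with mean-squared-error splits.  Defaults follow
#' common library behaviour for regression forests where the source method
#' left them unstated: 100 trees, unlimited depth, all features considered
#' at every split, bootstrap resampling of the training rows.  Feature
#' importances are mean decrease in impurity: per-tree SSE decreases summed
#' per feature, normalised to sum 1 within each tree, then averaged across
#' trees.
#'
#' @param train data frame holding the feature columns and `mean_deduction`.
#' @param n_trees number of trees.
#' @param mtry candidate features per split (default: all).
#' @param min_split minimum node size to split.
#' @param seed RNG seed; the fit is deterministic given it.
#' @param features feature columns (default [feature_names()]).
#' @return a `deduction_model`: trees, importances, training metadata.
#' @export
train_forest <- function(train, n_trees = 100L, mtry = NULL, min_split = 2L,
                         seed = 0L, features = feature_names()) {
  if (nrow(train) < 2) wv_stop("model_error", "need at least 2 training records")
  X <- as.matrix(train[, features, drop = FALSE])
  y <- train$mean_deduction
  if (is.null(mtry)) mtry <- ncol(X)
  degenerate <- stats::var(y) < 1e-24
  trees <- with_rng(seed, function() {
    lapply(seq_len(n_trees), function(b) {
      idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
      fit_tree(X[idx, , drop = FALSE], y[idx], min_split = min_split,
               mtry = mtry)
    })
  })
  imp_mat <- vapply(trees, function(tr) {
    raw <- tree_importance_raw(tr)
    tot <- sum(raw)
    if (tot > 0) raw / tot else raw
  }, numeric(length(features)))
  importances <- rowMeans(imp_mat)
  structure(list(trees = trees, feature_importances = importances,
                 features = features, n_trees = n_trees, mtry = mtry,
                 seed = seed, degenerate_importances = degenerate,
                 oob = NULL),
            class = "deduction_model")
}

#' @export
predict.deduction_model <- function(object, newdata, ...) {
  preds <- vapply(object$trees, function(tr) predict(tr, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' @export
print.deduction_model <- function(x, ...) {
  cat(sprintf("deduction_model: %d trees, mtry %d\n", x$n_trees, x$mtry))
  top <- sort(x$feature_importances, decreasing = TRUE)[1:5]
  cat("top importances:\n")
  for (nm in names(top)) cat(sprintf("  %-24s %.3f\n", nm, top[nm]))
  invisible(x)
}

#' Test-set metrics
#'
#' RMSE and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the test-target mean.
#' With zero test-target variance `r2` is `NA` and flagged.
#'
#' @param model anything with a `predict` method (or a numeric prediction
#'   vector).
#' @param test data frame with the feature columns and `mean_deduction`.
#' @return list(rmse, r2, r2_defined, n).
#' @export
evaluate <- function(model, test) {
  if (nrow(test) == 0) wv_stop("model_error", "empty test set")
  pred <- if (is.numeric(model)) model else predict(model, test)
  y <- test$mean_deduction
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2_defined <- ss_tot > 1e-24
  list(rmse = sqrt(mean((y - pred)^2)),
       r2 = if (r2_defined) 1 - ss_res / ss_tot else NA_real_,
       r2_defined = r2_defined, n = length(y))
}

#' Importance-threshold feature selection
#'
#' Features whose mean-decrease-in-impurity importance is at least
#' `threshold` (inclusive), sorted by decreasing importance.
#'
#' @param model a `deduction_model`.
#' @param threshold importance cutoff in `[0, 1]`.
#' @return character vector of selected feature names.
#' @export
select_features <- function(model, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold <= 1)
  imp <- sort(model$feature_importances, decreasing = TRUE)
  sel <- imp[imp >= threshold & imp > 0]
  names(sel)
}

#' Single-feature baseline
#'
#' Regresses the mean deduction on one feature only — ordinary least squares
#' by default, or a single-feature forest — using the same train/test split,
#' and reports the test metrics.  Quantifies how much the remaining features
#' add beyond, e.g., time on the wheel alone.
#'
#' @param records full record table.
#' @param feature feature name.
#' @param split a [sequential_split()] result (default: 2 test days).
#' @param method `"ols"` or `"forest"`.
#' @param seed seed for the forest method.
#' @return list(rmse, r2, r2_defined, n, method, degenerate).
#' @export
fit_single_feature_baseline <- function(records, feature = "time_on_wheel",
                                        split = NULL,
                                        method = c("ols", "forest"),
                                        seed = 0L) {
  method <- match.arg(method)
  if (!feature %in% names(records)) {
    wv_stop("feature_error", paste("unknown feature:", feature))
  }
  if (is.null(split)) split <- sequential_split(records)
  train <- split$train; test <- split$test
  degenerate <- stats::var(train[[feature]]) < 1e-24
  if (method == "ols") {
    df <- data.frame(x = train[[feature]], y = train$mean_deduction)
    fit <- stats::lm(y ~ x, data = df)
    pred <- stats::predict(fit, data.frame(x = test[[feature]]))
    res <- evaluate(as.numeric(pred), test)
  } else {
    model <- train_forest(train, seed = seed, features = feature)
    res <- evaluate(model, test)
  }
  c(res, list(method = method, feature = feature, degenerate = degenerate))
}
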