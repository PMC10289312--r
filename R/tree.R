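# Regression CART: binary trees grown with the mean-squared-error criterion
# (variance reduction), exhaustive split search over midpoints, no depth
# limit.  Stored as a flat data frame of nodes for cheap prediction and
# rule extraction.

# vectorised best-split search for one node: for each feature, sort, take
# cumulative sums of y and y^2, and evaluate the SSE decrease at every
# boundary between distinct consecutive values.
best_split <- function(X, y, feat_idx) {
  n <- length(y)
  best <- list(score = -Inf)
  sse_parent <- sum(y^2) - sum(y)^2 / n
  for (f in feat_idx) {
    x <- X[, f]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0) next
    cy <- cumsum(ys); cy2 <- cumsum(ys^2)
    nl <- distinct
    sse_l <- cy2[nl] - cy[nl]^2 / nl
    nr <- n - nl
    sy_r <- cy[n] - cy[nl]
    sse_r <- (cy2[n] - cy2[nl]) - sy_r^2 / nr
    dec <- sse_parent - (sse_l + sse_r)
    k <- which.max(dec)
    if (dec[k] > best$score + 1e-12) {
      thr <- (xs[distinct[k]] + xs[distinct[k] + 1]) / 2
      # midpoints of adjacent floats can round up to the right value, which
      # would send every sample left; fall back to the left value
      if (!(thr < xs[distinct[k] + 1])) thr <- xs[distinct[k]]
      best <- list(score = dec[k], feature = f, threshold = thr,
                   decrease = dec[k])
    }
  }
  if (!is.finite(best$score)) NULL else best
}

#' Fit a regression tree
#'
#' CART with mean-squared-error splits: each node is split by the
#' (feature, threshold) pair maximising the decrease in the sum of squared
#' errors; `x <= threshold` goes left.  Grown until nodes are pure or
#' smaller than `min_split`.
#'
#' @param X numeric matrix (rows = samples, named columns = features).
#' @param y numeric response.
#' @param min_split minimum node size to attempt a split.
#' @param mtry number of features drawn (without replacement) as candidates
#'   at each split; default all features.
#' @return an object of class `wv_tree`: a node table plus feature names.
#' @export
fit_tree <- function(X, y, min_split = 2L, mtry = ncol(X)) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  cap <- 2L * nrow(X) + 1L
  e <- new.env()
  e$n_nodes <- 0L
  e$n <- integer(cap); e$value <- numeric(cap)
  e$feature <- rep(NA_integer_, cap); e$threshold <- rep(NA_real_, cap)
  e$left <- rep(NA_integer_, cap); e$right <- rep(NA_integer_, cap)
  e$decrease <- numeric(cap)
  grow <- function(idx) {
    id <- e$n_nodes <- e$n_nodes + 1L
    e$n[id] <- length(idx)
    e$value[id] <- mean(y[idx])
    split <- NULL
    if (length(idx) >= min_split && stats::var(y[idx]) > 1e-24) {
      feats <- if (mtry >= ncol(X)) seq_len(ncol(X)) else
        sample.int(ncol(X), mtry)
      split <- best_split(X[idx, , drop = FALSE], y[idx], feats)
    }
    if (!is.null(split) && split$decrease > 1e-12) {
      go_left <- X[idx, split$feature] <= split$threshold
      if (all(go_left) || !any(go_left)) split <- NULL
    }
    if (!is.null(split) && split$decrease > 1e-12) {
      e$feature[id] <- split$feature
      e$threshold[id] <- split$threshold
      e$decrease[id] <- split$decrease
      e$left[id] <- grow(idx[go_left])
      e$right[id] <- grow(idx[!go_left])
    }
    id
  }
  grow(seq_len(nrow(X)))
  k <- seq_len(e$n_nodes)
  tab <- data.frame(id = k, n = e$n[k], value = e$value[k],
                    feature = e$feature[k], threshold = e$threshold[k],
                    left = e$left[k], right = e$right[k],
                    decrease = e$decrease[k])
  structure(list(nodes = tab, feature_names = colnames(X),
                 n_samples = nrow(X)),
            class = "wv_tree")
}

#' @export
predict.wv_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  tab <- object$nodes
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    while (!is.na(tab$feature[id])) {
      id <- if (X[i, tab$feature[id]] <= tab$threshold[id]) tab$left[id]
            else tab$right[id]
    }
    tab$value[id]
  }, numeric(1))
}

# un-normalised impurity-decrease importance: sum of SSE decreases per
# feature (equivalently n * weighted impurity decrease)
tree_importance_raw <- function(tree) {
  imp <- stats::setNames(numeric(length(tree$feature_names)),
                         tree$feature_names)
  tab <- tree$nodes
  internal <- which(!is.na(tab$feature))
  for (id in internal) {
    f <- tree$feature_names[tab$feature[id]]
    imp[f] <- imp[f] + tab$decrease[id]
  }
  imp
}

#' Enumerate root-to-leaf decision paths
#'
#' One `rule_path` per leaf, depth-first (left/`<=` branch before
#' right/`>`): ordered conditions `(feature, comparator, threshold)` with
#' comparators in `{<=, >}`, the leaf's predicted deduction and its sample
#' count.
#'
#' @param tree a `wv_tree`.
#' @return list of `rule_path` objects.
#' @export
extract_rules <- function(tree) {
  tab <- tree$nodes
  out <- list()
  walk <- function(id, conds) {
    if (is.na(tab$feature[id])) {
      out[[length(out) + 1L]] <<- structure(
        list(conditions = if (length(conds)) do.call(rbind, conds) else
          data.frame(feature = character(), comparator = character(),
                     threshold = numeric()),
          leaf_prediction = tab$value[id], n_samples = tab$n[id]),
        class = "rule_path")
      return(invisible())
    }
    f <- tree$feature_names[tab$feature[id]]
    walk(tab$left[id],
         c(conds, list(data.frame(feature = f, comparator = "<=",
                                  threshold = tab$threshold[id]))))
    walk(tab$right[id],
         c(conds, list(data.frame(feature = f, comparator = ">",
                                  threshold = tab$threshold[id]))))
  }
  walk(1L, list())
  out
}

#' @export
format.rule_path <- function(x, ...) {
  conds <- if (nrow(x$conditions) == 0) "(root)" else
    paste(sprintf("%s %s %.4g", x$conditions$feature, x$conditions$comparator,
                  x$conditions$threshold), collapse = " & ")
  sprintf("%s -> %.4g (n=%d)", conds, x$leaf_prediction, x$n_samples)
}

#' @export
print.rule_path <- function(x, ...) cat(format(x), "\n")
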