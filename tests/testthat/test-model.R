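# naive exhaustive best-split oracle used against the vectorised CART search
oracle_best_split <- function(X, y) {
  n <- length(y)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- list(dec = -Inf)
  for (f in seq_len(ncol(X))) {
    for (cut in sort(unique(X[, f]))) {
      l <- y[X[, f] <= cut]; r <- y[X[, f] > cut]
      if (!length(l) || !length(r)) next
      dec <- sse(y) - sse(l) - sse(r)
      if (dec > best$dec + 1e-12) best <- list(dec = dec, f = f)
    }
  }
  best
}

test_that("single trees reproduce exhaustive split search and predict exactly", {
  set.seed(20)
  for (rep in 1:10) {
    X <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- X[, 1] * 2 + stats::rnorm(20, sd = 0.3)
    tr <- fit_tree(X, y)
    o <- oracle_best_split(X, y)
    expect_equal(tr$nodes$decrease[1], o$dec, tolerance = 1e-9)
    expect_equal(tr$nodes$feature[1], o$f)
    # full-depth tree on distinct targets interpolates the training data
    expect_equal(predict(tr, as.data.frame(X)), y, tolerance = 1e-12)
  }
})

test_that("rule extraction enumerates exactly the leaves, consistently", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(0, 0, 1, 1, 0, 1))
  tr <- fit_tree(X, c(0, 0, 0, 1, 1, 1))
  rules <- extract_rules(tr)
  expect_length(rules, 2)                   # depth-1 tree -> 2 paths
  expect_equal(rules[[1]]$conditions$comparator, "<=")
  expect_equal(rules[[2]]$conditions$comparator, ">")

  set.seed(30)
  X2 <- matrix(stats::rnorm(100), 25, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  y2 <- stats::rnorm(25)
  tr2 <- fit_tree(X2, y2)
  rules2 <- extract_rules(tr2)
  expect_length(rules2, sum(is.na(tr2$nodes$feature)))
  # every path's conditions are mutually consistent: some point satisfies all
  for (rp in rules2) {
    lo <- stats::setNames(rep(-Inf, 4), colnames(X2))
    hi <- stats::setNames(rep(Inf, 4), colnames(X2))
    ok <- TRUE
    for (k in seq_len(nrow(rp$conditions))) {
      f <- rp$conditions$feature[k]; thr <- rp$conditions$threshold[k]
      if (rp$conditions$comparator[k] == "<=") hi[f] <- min(hi[f], thr)
      else lo[f] <- max(lo[f], thr)
      if (lo[f] >= hi[f]) ok <- FALSE
    }
    expect_true(ok)
    # routing a point inside the box down the tree reaches this leaf
    mid <- ifelse(is.finite(lo) & is.finite(hi), (lo + hi) / 2,
                  ifelse(is.finite(hi), hi,          # <= bound is inclusive
                         ifelse(is.finite(lo), lo + 1, 0)))
    probe <- as.data.frame(as.list(stats::setNames(mid, colnames(X2))))
    expect_equal(predict(tr2, probe), rp$leaf_prediction)
  }
})

test_that("sequential split holds out the last days and partitions records", {
  rec <- data.frame(day = rep(1:8, each = 3), x = 1:24,
                    mean_deduction = stats::runif(24))
  sp <- sequential_split(rec, 2)
  expect_setequal(unique(sp$test$day), c(7, 8))
  expect_setequal(unique(sp$train$day), 1:6)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(rec))
  expect_length(intersect(sp$train$x, sp$test$x), 0)
  expect_error(sequential_split(rec, 8), class = "split_error")
  set.seed(2)
  for (rep in 1:10) {
    rec2 <- data.frame(day = sample(1:5, 30, replace = TRUE), x = 1:30,
                       mean_deduction = stats::runif(30))
    sp2 <- sequential_split(rec2, 2)
    expect_equal(nrow(sp2$train) + nrow(sp2$test), 30)
    expect_true(max(sp2$train$day) < min(sp2$test$day))
  }
})

test_that("forest training is deterministic and importances sum to one", {
  cfg <- tiny_config(seed = 31, n_days = 3, performances_per_day = 6)
  rec <- synth_records(cfg)
  sp <- sequential_split(rec, 1)
  m1 <- train_forest(sp$train, n_trees = 25, seed = 7)
  m2 <- train_forest(sp$train, n_trees = 25, seed = 7)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
  expect_equal(sum(m1$feature_importances), 1, tolerance = 1e-9)
  expect_true(all(m1$feature_importances >= 0))
  m3 <- train_forest(sp$train, n_trees = 25, seed = 8)
  expect_false(identical(predict(m1, sp$test), predict(m3, sp$test)))

  # ensemble averaging: forest training rmse <= mean single-tree rmse
  ptrees <- vapply(m1$trees, function(tr) predict(tr, sp$train),
                   numeric(nrow(sp$train)))
  rmse <- function(p) sqrt(mean((p - sp$train$mean_deduction)^2))
  expect_lte(rmse(rowMeans(ptrees)), mean(apply(ptrees, 2, rmse)) + 1e-12)
})

test_that("evaluate matches the direct formulas", {
  y <- c(1, 2, 3, 4)
  test <- data.frame(mean_deduction = y)
  expect_equal(evaluate(y, test)$rmse, 0)
  expect_equal(evaluate(y, test)$r2, 1)
  expect_equal(evaluate(rep(mean(y), 4), test)$r2, 0)
  set.seed(8)
  for (rep in 1:10) {
    yy <- stats::rnorm(15); pp <- stats::rnorm(15)
    ev <- evaluate(pp, data.frame(mean_deduction = yy))
    expect_equal(ev$rmse, sqrt(mean((yy - pp)^2)))
    expect_equal(ev$r2, 1 - sum((yy - pp)^2) / sum((yy - mean(yy))^2))
  }
  ev0 <- evaluate(c(1, 1), data.frame(mean_deduction = c(2, 2)))
  expect_false(ev0$r2_defined)
})

test_that("feature selection is inclusive at the threshold and monotone", {
  cfg <- tiny_config(seed = 33, n_days = 3, performances_per_day = 6)
  m <- train_forest(sequential_split(synth_records(cfg), 1)$train,
                    n_trees = 25, seed = 0)
  imp <- m$feature_importances
  thr <- sort(imp[imp > 0], decreasing = TRUE)[2]
  sel <- select_features(m, thr)
  expect_true(names(sort(imp, decreasing = TRUE))[2] %in% sel)  # inclusive >=
  expect_identical(select_features(m, 0),
                   names(sort(imp[imp > 0], decreasing = TRUE)))
  sizes <- vapply(c(0, 0.05, 0.1, 0.3, 0.9), function(t) {
    length(select_features(m, t))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_length(select_features(m, 1), 0)
})

test_that("the single-feature baseline behaves at the extremes", {
  rec <- data.frame(day = rep(1:4, each = 5),
                    mean_deduction = stats::runif(20))
  rec$self <- rec$mean_deduction
  b <- fit_single_feature_baseline(rec, "self")
  expect_equal(b$r2, 1, tolerance = 1e-9)
  expect_equal(b$rmse, 0, tolerance = 1e-9)

  set.seed(44)
  rec2 <- data.frame(day = rep(1:10, each = 60),
                     mean_deduction = stats::rnorm(600),
                     noise = stats::rnorm(600))
  b2 <- fit_single_feature_baseline(rec2, "noise")
  expect_lt(abs(b2$r2), 0.05)
  expect_error(fit_single_feature_baseline(rec2, "nope"),
               class = "feature_error")
  rec2$const <- 1
  expect_true(fit_single_feature_baseline(rec2, "const")$degenerate)
})
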