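# Threshold-group construction and the hypothesis tests used to validate
# forest branching conditions: Dunnett many-to-one comparisons of the
# condition groups and Mann-Whitney U for the single-condition splits.

#' Build a feature condition
#'
#' @param feature feature name.
#' @param comparator one of `"<="`, `">"`, `"<"`, `">="`.
#' @param threshold numeric cutoff.
#' @return a `condition` list usable by [assign_groups()].
#' @export
feature_condition <- function(feature, comparator, threshold) {
  stopifnot(comparator %in% c("<=", ">", "<", ">="))
  structure(list(feature = feature, comparator = comparator,
                 threshold = threshold), class = "wv_condition")
}

eval_condition <- function(cond, records) {
  if (!cond$feature %in% names(records)) {
    wv_stop("feature_error", paste("unknown feature:", cond$feature))
  }
  x <- records[[cond$feature]]
  switch(cond$comparator,
         "<=" = x <= cond$threshold,
         ">"  = x >  cond$threshold,
         "<"  = x <  cond$threshold,
         ">=" = x >= cond$threshold)
}

#' Assign performances to the four condition groups
#'
#' Group I meets both conditions, II only the first, III only the second,
#' IV neither.  The default comparator senses follow the printed rules:
#' time on the wheel *within* a threshold is inclusive (`<=`), a knee angle
#' *over* a threshold is exclusive (`>`).
#'
#' @param records record table.
#' @param cond_a,cond_b [feature_condition()]s.
#' @return factor of labels I--IV (one per record), with attribute
#'   `"conditions"`.
#' @export
assign_groups <- function(records, cond_a, cond_b) {
  a <- eval_condition(cond_a, records)
  b <- eval_condition(cond_b, records)
  lab <- ifelse(a & b, "I", ifelse(a & !b, "II", ifelse(!a & b, "III", "IV")))
  structure(factor(lab, levels = c("I", "II", "III", "IV")),
            conditions = list(a = cond_a, b = cond_b))
}

# --------------------------------------------------------------------------
# Mann-Whitney U
# --------------------------------------------------------------------------

#' Mann-Whitney U test
#'
#' U statistic by rank summation with midrank ties.  Without ties and when
#' `choose(nx + ny, nx) <= exact_cap`, the p-value is exact (from the
#' Wilcoxon rank-sum null distribution, equivalent to full enumeration of
#' the rank assignments) using the symmetric-extremes two-sided convention
#' `p = 2 * min(P(U <= u), P(U >= u))` capped at 1; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @param exact_cap maximum number of enumerated combinations for the exact
#'   branch.
#' @return a `test_result` list: method, statistic (U of `x`), p_value,
#'   group sizes, alternative, exact flag.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           exact_cap = 1e6) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) {
    wv_stop("input_error", "both samples must be nonempty")
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # U statistic of x
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && choose(nx + ny, nx) <= exact_cap
  if (u == nx * ny / 2 && alternative == "two.sided") {
    p <- 1
  } else if (exact) {
    # P(U <= u) and P(U >= u) under the exact null
    p_le <- stats::pwilcox(u, nx, ny)
    p_ge <- 1 - stats::pwilcox(u - 1, nx, ny)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else {
      z_le <- (u - mu + 0.5) / sigma
      z_ge <- (u - mu - 0.5) / sigma
      p <- switch(alternative,
                  two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                             1 - stats::pnorm(z_ge))),
                  less = stats::pnorm(z_le),
                  greater = 1 - stats::pnorm(z_ge))
    }
  }
  structure(list(method = "Mann-Whitney U",
                 statistic = c(U = unname(u)), p_value = p,
                 group_sizes = c(nx = nx, ny = ny),
                 alternative = alternative, exact = exact),
            class = "test_result")
}

# --------------------------------------------------------------------------
# Dunnett many-to-one comparisons
# --------------------------------------------------------------------------

#' Dunnett's test
#'
#' Compares each treatment-group mean against the control mean with pooled-
#' variance t statistics and the multivariate-t family-wise adjustment.
#' Adjusted p-values integrate the k-variate t distribution with the
#' standard Dunnett correlation structure, either analytically (`"mvt"`,
#' via quasi-Monte-Carlo integration of the multivariate t) or by plain
#' Monte-Carlo simulation of the max-|T| null with a fixed seed and a
#' reported standard error.
#'
#' @param control numeric control sample (>= 2 observations).
#' @param treatments list of numeric treatment samples (each >= 2).
#' @param alpha family-wise level (reported alongside the decisions).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (treatment vs
#'   control).
#' @param method `"mvt"` or `"mc"`.
#' @param mc_draws Monte-Carlo draws for `method = "mc"`.
#' @param seed seed for the Monte-Carlo backend.
#' @return list of `test_result`, one per treatment, each with the adjusted
#'   and unadjusted p-value.
#' @export
dunnett_test <- function(control, treatments, alpha = 0.05,
                         alternative = c("two.sided", "less", "greater"),
                         method = c("mvt", "mc"), mc_draws = 1e5, seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!is.list(treatments)) treatments <- list(treatments)
  k <- length(treatments)
  ns <- vapply(treatments, length, integer(1))
  n0 <- length(control)
  if (n0 < 2 || any(ns < 2)) {
    wv_stop("input_error", "every group needs at least 2 observations")
  }
  groups <- c(list(control), treatments)
  N <- n0 + sum(ns)
  df <- N - (k + 1)
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  if (s2 <= 0) wv_stop("degenerate_error", "zero pooled variance")
  tstat <- vapply(seq_len(k), function(i) {
    (mean(treatments[[i]]) - mean(control)) / sqrt(s2 * (1 / ns[i] + 1 / n0))
  }, numeric(1))
  lam <- sqrt(ns / (ns + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1

  p_family <- function(ti) {
    # P(some |T_j| (or T_j) beyond |ti|) under the k-variate t null
    if (method == "mvt") {
      pv <- switch(alternative,
        two.sided = 1 - mvtnorm::pmvt(lower = rep(-abs(ti), k),
                                      upper = rep(abs(ti), k),
                                      df = df, corr = corr)[1],
        greater = 1 - mvtnorm::pmvt(lower = rep(-Inf, k),
                                    upper = rep(ti, k),
                                    df = df, corr = corr)[1],
        less = 1 - mvtnorm::pmvt(lower = rep(ti, k),
                                 upper = rep(Inf, k),
                                 df = df, corr = corr)[1])
      c(p = max(0, min(1, pv)), se = NA_real_)
    } else {
      draws <- mc_max_t(k, df, corr, mc_draws, seed)
      stat <- switch(alternative,
                     two.sided = abs(ti) <= draws$maxabs,
                     greater = ti <= draws$max,
                     less = ti >= draws$min)
      p <- mean(stat)
      c(p = p, se = sqrt(p * (1 - p) / mc_draws))
    }
  }

  lapply(seq_len(k), function(i) {
    pf <- p_family(tstat[i])
    p_unadj <- switch(alternative,
                      two.sided = 2 * stats::pt(-abs(tstat[i]), df),
                      greater = 1 - stats::pt(tstat[i], df),
                      less = stats::pt(tstat[i], df))
    structure(list(method = sprintf("Dunnett (%s)", method),
                   statistic = c(t = tstat[i]), p_value = unname(pf["p"]),
                   p_unadjusted = p_unadj, p_se = unname(pf["se"]),
                   df = df, alpha = alpha,
                   group_sizes = c(control = n0, treatment = ns[i]),
                   alternative = alternative,
                   reject = unname(pf["p"]) < alpha),
              class = "test_result")
  })
}

# draws of the joint Dunnett null: T = Z / sqrt(W/df) with Z ~ N(0, corr)
mc_max_t <- function(k, df, corr, n_draws, seed) {
  with_rng(seed, function() {
    L <- chol(corr)
    Z <- matrix(stats::rnorm(n_draws * k), n_draws, k) %*% L
    W <- sqrt(stats::rchisq(n_draws, df) / df)
    Tm <- Z / W
    list(maxabs = apply(abs(Tm), 1, max),
         max = apply(Tm, 1, max),
         min = apply(Tm, 1, min))
  })
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (%s)\n", x$method,
              names(x$statistic)[1], x$statistic[1], x$p_value,
              x$alternative))
  invisible(x)
}
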