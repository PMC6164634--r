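#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Rank-sum test with average-rank handling of ties. For small samples
#' (default: when `choose(m + n, m) <= max_enum`) the two-sided p-value is
#' computed by exhaustive enumeration of the permutation distribution of the
#' rank-sum statistic, which remains exact in the presence of ties; larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger), or
#'   `"less"`.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param max_enum enumeration budget for `method = "auto"`.
#' @return list with `statistic` (U for x), `p.value`, `method`.
#' @export
mann_whitney_test <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              method = c("auto", "exact", "normal"),
                              max_enum = 200000) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot_contract(length(x) >= 3 && length(y) >= 3,
                     "each group needs at least 3 observations")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])            # rank sum of x
  U <- W - m * (m + 1) / 2           # Mann-Whitney U for x
  if (method == "auto") {
    method <- if (choose(m + n, m) <= max_enum) "exact" else "normal"
  }
  if (method == "exact") {
    combos <- combn(m + n, m)
    sums <- colSums(matrix(r[combos], nrow = m))
    tol <- 1e-9
    p <- switch(alternative,
      two.sided = min(1, 2 * min(mean(sums <= W + tol),
                                 mean(sums >= W - tol))),
      greater = mean(sums >= W - tol),
      less = mean(sums <= W + tol))
  } else {
    mu <- m * n / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
    sigma2 <- m * n / 12 * ((m + n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z_num <- switch(alternative,
        two.sided = abs(U - mu) - 0.5,
        greater = U - mu - 0.5,
        less = -(U - mu) - 0.5)
      z <- z_num / sqrt(sigma2)
      p <- switch(alternative,
        two.sided = min(1, 2 * pnorm(z, lower.tail = FALSE)),
        greater = pnorm(z, lower.tail = FALSE),
        less = pnorm(z, lower.tail = FALSE))
    }
  }
  list(statistic = U, p.value = p, method = method)
}

#' Pairwise group comparison with the Mann-Whitney test
#'
#' Computes two-sided Mann-Whitney p-values for every pair of groups and a
#' logical significance grid at the requested level, mirroring the matrix
#' layout used to report between-group differences.
#'
#' @param values numeric vector of parameter values.
#' @param groups factor or character vector of group labels, same length.
#' @param level significance level for the grid (default 0.05).
#' @param ... passed to [mann_whitney_test()].
#' @return list with `p` (symmetric matrix of p-values, `NA` diagonal) and
#'   `significant` (logical matrix, `p <= level`).
#' @export
group_compare <- function(values, groups, level = 0.05, ...) {
  groups <- as.factor(groups)
  stopifnot_contract(length(values) == length(groups),
                     "values and groups must have the same length")
  lev <- levels(droplevels(groups))
  stopifnot_contract(length(lev) >= 2, "need at least 2 groups")
  sizes <- table(groups)[lev]
  stopifnot_contract(all(sizes >= 3),
                     "each group needs at least 3 observations")
  k <- length(lev)
  p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- mann_whitney_test(values[groups == lev[i]],
                               values[groups == lev[j]], ...)
      p[i, j] <- p[j, i] <- res$p.value
    }
  }
  list(p = p, significant = !is.na(p) & p <= level, level = level)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t distribution with `n - 2` degrees of freedom. Suitable for relating
#' movement parameters to ordinal clinical scores.
#'
#' @param x,y paired numeric observations (n >= 5, finite).
#' @return list with `rho`, `p.value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot_contract(length(x) == length(y), "x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot_contract(n >= 5, "need at least 5 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_aq("araquant_error_degenerate",
             "zero variance: rank correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p.value = p, n = n)
}
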