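#' @importFrom stats pnorm p.adjust median quantile var sd rlnorm rnorm
#'   rbinom rnbinom rgeom runif setNames complete.cases kruskal.test
#'   wilcox.test loess predict uniroot dist
NULL

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' stable under input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When both groups have at most `exactMax`
#' observations the p-value is computed by exact enumeration of all group
#' assignments (ties handled through mid-ranks); otherwise a normal
#' approximation with tie correction is used.
#'
#' @param x,y numeric vectors.
#' @param exactMax largest per-group size for exact enumeration (default 8).
#' @return list with `U` (statistic for `x`), `p`, and `method`.
#' @export
mannWhitney <- function(x, y, exactMax = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups need at least one observation")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exactMax && n2 <= exactMax) {
    ## exact permutation distribution of U
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tiecorr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecorr)
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (u - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}

## Dunn's pairwise z-tests after Kruskal-Wallis, Bonferroni-style
## multiplicity adjustment (p * number of comparisons, capped at 1).
.dunnPairwise <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tieterm <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tieterm) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    out$z[i] <- z
    out$p[i] <- p
    out$p_adj[i] <- min(1, p * m)
  }
  out
}

#' Group comparison of cohort-level values
#'
#' Nonparametric comparison of a numeric outcome across groups, as used for
#' per-sample subset or checkpoint summaries. Two groups: two-sided
#' Mann-Whitney (exact enumeration when both groups have <= 8 observations,
#' else normal approximation with tie correction); more than two groups:
#' Kruskal-Wallis with tie correction followed by Dunn's pairwise z-tests
#' with Bonferroni-style adjustment over all pairwise comparisons. With
#' `paired = TRUE` and two groups a Wilcoxon signed-rank test is used.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param paired paired two-group comparison (signed-rank) instead of the
#'   unpaired test.
#' @return list with `test` ("mann-whitney", "kruskal-dunn" or
#'   "wilcoxon-signed-rank"), the global `statistic` and `p`, and for the
#'   multi-group case a `pairwise` data.frame (group1, group2, z, p, p_adj).
#' @export
groupCompare <- function(values, groups, paired = FALSE) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (any(sizes == 0)) {
    warning("dropping empty group(s): ",
            paste(names(sizes)[sizes == 0], collapse = ", "))
    groups <- droplevels(groups)
  }
  k <- nlevels(groups)
  if (k < 2) stop("need at least two non-empty groups")
  if (length(values) < 2) stop("need at least two observations")
  if (paired) {
    if (k != 2) stop("paired comparison supports exactly two groups")
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    if (length(a) != length(b)) stop("paired groups must have equal sizes")
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
    return(list(test = "wilcoxon-signed-rank",
                statistic = unname(wt$statistic), p = wt$p.value))
  }
  if (k == 2) {
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    mw <- mannWhitney(a, b)
    return(list(test = "mann-whitney", statistic = mw$U, p = mw$p,
                method = mw$method))
  }
  ## identical values in every group: no between-group variance
  if (length(unique(values)) == 1)
    return(list(test = "kruskal-dunn", statistic = 0, p = 1,
                pairwise = .dunnPairwise(values, groups)))
  kw <- kruskal.test(values, groups)
  list(test = "kruskal-dunn", statistic = unname(kw$statistic),
       p = kw$p.value, pairwise = .dunnPairwise(values, groups))
}
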