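## Cross-entity pattern analysis: quarterly deviation matrices,
## hierarchical clustering, heatmap intensity scores and severity
## association tests.

#' Entities x quarters deviation matrix
#'
#' Assembles quarterly point-estimate deviations into a matrix with one row
#' per entity and chronologically ordered quarter columns; every entity
#' must have every requested quarter.
#'
#' @param deviations deviations table containing quarterly rows
#'   (`timeframe_type == "quarter"`).
#' @param quarterNames quarter labels to use as columns (default: all
#'   quarters present, chronological).
#' @return numeric matrix, rownames entity ids, colnames quarter labels.
#' @export
quarterlyMatrix <- function(deviations, quarterNames = NULL) {
  q <- deviations[deviations$timeframe_type == "quarter", , drop = FALSE]
  if (is.null(quarterNames)) quarterNames <- sort(unique(q$timeframe))
  ids <- unique(q$entity_id)
  M <- matrix(NA_real_, length(ids), length(quarterNames),
              dimnames = list(ids, quarterNames))
  idx <- cbind(match(q$entity_id, ids), match(q$timeframe, quarterNames))
  keep <- !is.na(idx[, 2])
  M[idx[keep, , drop = FALSE]] <- q$delta[keep]
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("entity %s is missing quarter %s", ids[miss[1]],
                 quarterNames[miss[2]]), call. = FALSE)
  }
  M
}

#' Hierarchical clustering of deviation trajectories
#'
#' Agglomerative clustering with pairwise Euclidean distances and complete
#' (maximum) linkage; labels are obtained by cutting the dendrogram into
#' `k` groups when `k` is given.
#'
#' @param M numeric matrix (entities x features), no missing values.
#' @param k optional number of clusters (2..nrow(M)).
#' @return list with `hclust` (the [stats::hclust] tree), `order` (leaf
#'   order), `merge`, `height`, and `labels` (named cluster assignment, or
#'   `NULL` when `k` is not given).
#' @export
hierarchicalCluster <- function(M, k = NULL) {
  if (!is.matrix(M) || nrow(M) < 2) stop("need >= 2 rows", call. = FALSE)
  if (anyNA(M)) stop("matrix contains missing values", call. = FALSE)
  hc <- stats::hclust(stats::dist(M, method = "euclidean"),
                      method = "complete")
  labels <- NULL
  if (!is.null(k)) {
    if (k > nrow(M)) stop("k exceeds number of rows", call. = FALSE)
    labels <- stats::cutree(hc, k = k)
  }
  list(hclust = hc, order = hc$order, merge = hc$merge, height = hc$height,
       labels = labels)
}

#' Export a dendrogram as Newick text
#'
#' @param cluster result of [hierarchicalCluster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDendrogramNewick <- function(cluster, path) {
  ape::write.tree(ape::as.phylo(cluster$hclust), file = path)
  invisible(path)
}

#' Signed heatmap intensity of a deviation
#'
#' The product of the deviation magnitude and the negative log10 of its
#' adjusted p-value (floored at 1e-10), signed by the deviation:
#' `sign(delta) * |delta| * (-log10(max(p_adjusted, 1e-10)))`.
#'
#' @param delta deviation point estimate(s).
#' @param pAdjusted adjusted p-value(s) in (0, 1].
#' @return signed intensity, zero when `pAdjusted == 1` or `delta == 0`.
#' @examples
#' heatmapIntensity(-0.5, 0.01)  # -1
#' @export
heatmapIntensity <- function(delta, pAdjusted) {
  if (any(pAdjusted <= 0) || any(pAdjusted > 1))
    stop("pAdjusted must lie in (0, 1]", call. = FALSE)
  sign(delta) * abs(delta) * (-log10(pmax(pAdjusted, 1e-10)))
}

#' Univariable severity regression
#'
#' Ordinary least squares of deviations on ordinal severity ranks; reports
#' the slope (change in deviation per unit severity) and its two-sided
#' t-test p-value.
#'
#' @param deviations numeric deviations, one per entity.
#' @param ranks matching severity ranks (1 = least severe .. 5).
#' @return list (`test = "ols_slope"`) with `slope`, `statistic` (t),
#'   `p_value`, `n`.
#' @export
severityRegression <- function(deviations, ranks) {
  if (length(deviations) != length(ranks) || length(ranks) < 3)
    stop("need >= 3 paired observations", call. = FALSE)
  if (var(ranks) == 0) stop("zero rank variance", call. = FALSE)
  fit <- lm(deviations ~ ranks)
  sm <- summary(fit)$coefficients
  list(test = "ols_slope", slope = unname(sm["ranks", "Estimate"]),
       statistic = unname(sm["ranks", "t value"]),
       p_value = unname(sm["ranks", "Pr(>|t|)"]), n = length(ranks))
}

#' Wilcoxon rank-sum (Mann-Whitney U) test between two groups
#'
#' Exact two-sided p by enumeration when `m + n <= 12` and there are no
#' ties, otherwise the normal approximation with tie correction.
#'
#' @param groupA,groupB numeric deviations of the two groups (non-empty).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` applies the size/tie rule above.
#' @return list (`test = "wilcoxon_rank_sum"`) with `statistic` (U for
#'   `groupA`), `p_value`, `n`.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
rankSumTest <- function(groupA, groupB, exact = NULL) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  if (is.null(exact))
    exact <- (length(groupA) + length(groupB)) <= 12 && !ties
  else if (exact && ties) exact <- FALSE
  wt <- suppressWarnings(wilcox.test(groupA, groupB, exact = exact,
                                     correct = !exact))
  p <- wt$p.value
  ## fully tied data: zero rank variance, no separation
  if (is.na(p)) p <- 1
  list(test = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
       p_value = p, n = length(groupA) + length(groupB))
}

#' Kruskal-Wallis test across severity groups
#'
#' Tie-corrected H statistic with a chi-squared reference on
#' `length(groups) - 1` degrees of freedom.  When all values are tied
#' across all groups the statistic is undefined after tie correction and is
#' reported as `H = 0`, `p = 1`.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list (`test = "kruskal_wallis"`) with `statistic` (H),
#'   `p_value`, `n`.
#' @examples
#' kruskalWallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2 || any(!lengths(groups)))
    stop("need >= 2 non-empty groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    return(list(test = "kruskal_wallis", statistic = 0, p_value = 1,
                n = length(x)))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  list(test = "kruskal_wallis", statistic = unname(kt$statistic),
       p_value = kt$p.value, n = length(x))
}

#' Pearson correlation between hiatus and post-hiatus deviations
#'
#' Convenience summary over entity deviation pairs.
#'
#' @param hiatus,postHiatus paired per-entity deviations.
#' @return list with `r`, `p_value`, `n`.
#' @export
hiatusPostHiatusCorrelation <- function(hiatus, postHiatus) {
  ct <- cor.test(hiatus, postHiatus, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(hiatus))
}
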