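#' Per-gene two-sample t-tests between relapse and relapse-free patients
#'
#' Computes, for every gene (row), the two-sided two-sample t statistic
#' comparing relapse vs relapse-free samples. The default is the
#' pooled-variance Student's t, the classic microarray screening choice; the
#' Welch (unequal-variance) form is available via `var_equal = FALSE`. The
#' sign convention is relapse minus relapse-free: positive t means higher
#' expression in relapsed patients. Genes with zero variance in both classes
#' and equal means get `t = 0`, `p = 1` (never significant).
#'
#' @param x genes x samples matrix.
#' @param labels two-class labels (logical TRUE = relapse, 0/1, or
#'   `"relapse"`/`"relapse-free"`), one per column of `x`.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return data frame `gene_id`, `t_statistic`, `p_value`.
#' @seealso [differential_expression()] for the Bonferroni-screened wrapper.
#' @export
two_class_ttest <- function(x, labels, var_equal = TRUE) {
  assert_expression(x)
  labels <- as_relapse(labels, ncol(x))
  check_two_classes(labels)
  x1 <- x[, labels, drop = FALSE]   # relapse
  x0 <- x[, !labels, drop = FALSE]  # relapse-free
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- row_vars(x1); v0 <- row_vars(x0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0 & m1 == m0
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  # zero pooled variance with distinct means: infinite t, p -> 0
  p[se == 0 & m1 != m0] <- 0
  data.frame(gene_id = rownames(x), t_statistic = tstat, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni family-wise p-value adjustment
#'
#' `adjusted = min(1, m * p)` with `m = length(p)`; order-preserving and
#' clipped at 1. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "bonferroni")
}

#' Differential expression screen with Bonferroni control
#'
#' Runs [two_class_ttest()], Bonferroni-adjusts the p-values, and flags genes
#' with adjusted p strictly below `alpha`.
#'
#' @inheritParams two_class_ttest
#' @param alpha family-wise significance threshold (default 0.01).
#' @return data frame `gene_id`, `t_statistic`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
differential_expression <- function(x, labels, alpha = 0.01, var_equal = TRUE) {
  res <- two_class_ttest(x, labels, var_equal = var_equal)
  res$p_adjusted <- bonferroni_adjust(res$p_value)
  res$significant <- res$p_adjusted < alpha
  res
}

#' Select differentially expressed genes
#'
#' Genes with Bonferroni-adjusted p strictly below `alpha` (boundary values
#' excluded), sorted by raw p ascending with ties broken by gene id.
#'
#' @param results output of [differential_expression()] (or any data frame
#'   with `gene_id`, `p_value`, `p_adjusted`).
#' @param alpha threshold on the adjusted p-value.
#' @return character vector of gene ids (possibly empty).
#' @export
select_differential <- function(results, alpha = 0.01) {
  stopifnot(all(c("gene_id", "p_value", "p_adjusted") %in% colnames(results)))
  hit <- results[results$p_adjusted < alpha, , drop = FALSE]
  hit <- hit[order(hit$p_value, hit$gene_id), , drop = FALSE]
  hit$gene_id
}

#' Hierarchical clustering of samples (Euclidean, complete linkage)
#'
#' Agglomerative clustering of the sample columns on Euclidean distance with
#' complete linkage, cut to `k` groups. Cluster labels are Roman numerals in
#' order of first appearance in the sample ordering, so the labelling is
#' deterministic given the input; exact merge-distance ties are resolved by
#' [stats::hclust()]'s ordering of the input, i.e. by the (lexicographic)
#' position of the samples.
#'
#' @param x genes x samples matrix.
#' @param k number of clusters (default 2).
#' @return list of class `sample_clustering`: `assignment` (data frame
#'   `sample_id`, `cluster`), `hclust` (the dendrogram), `k`.
#' @export
hierarchical_cluster <- function(x, k = 2) {
  assert_expression(x)
  check_scalar(k, "k", lower = 1, integer = TRUE)
  if (k > ncol(x)) stop("k exceeds the number of samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = k)
  roman <- as.character(utils::as.roman(seq_len(k)))
  assignment <- data.frame(sample_id = colnames(x),
                           cluster = roman[match(cl, unique(cl))],
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, hclust = hc, k = k,
                 linkage = "complete", distance = "euclidean"),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("Sample clustering (%s distance, %s linkage), k = %d\n",
              x$distance, x$linkage, x$k))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Chi-square association between cluster assignment and relapse status
#'
#' Pearson chi-square test on the cluster-by-class contingency table, without
#' continuity correction by default (matching the uncorrected statistic
#' conventionally reported for cluster/class agreement); Yates' correction is
#' available via `correct = TRUE`.
#'
#' @param clusters a `sample_clustering` object or a vector of cluster labels.
#' @param labels relapse labels, aligned with the cluster assignment.
#' @param correct apply the continuity correction (default FALSE).
#' @return list `statistic`, `df`, `p_value`, `table`.
#' @export
cluster_class_association <- function(clusters, labels, correct = FALSE) {
  if (inherits(clusters, "sample_clustering")) {
    clusters <- clusters$assignment$cluster
  }
  labels <- as_relapse(labels, length(clusters))
  tab <- table(cluster = clusters,
               class = ifelse(labels, "relapse", "relapse-free"))
  if (any(rowSums(tab) == 0)) stop("empty cluster", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}
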