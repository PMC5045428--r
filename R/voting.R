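#' Signal-to-noise statistic per gene
#'
#' For each gene, `S = (mu_relapse - mu_relapse_free) / (sd_relapse +
#' sd_relapse_free)` with per-class means and sample (n-1) SDs. Positive S
#' means higher expression in the relapse class; swapping the labels negates
#' S without changing the |S| ranking. A gene whose two class SDs are both
#' zero would have an infinite statistic; instead a small epsilon (1e-12) is
#' added to the denominator and a warning is emitted so degenerate fixtures
#' do not abort cross-validation.
#'
#' @param x genes x samples matrix.
#' @param labels two-class labels (TRUE/1/"relapse" = relapse).
#' @return named numeric vector of S, one per gene.
#' @export
signal_to_noise <- function(x, labels) {
  assert_expression(x)
  labels <- as_relapse(labels, ncol(x))
  check_two_classes(labels)
  x1 <- x[, labels, drop = FALSE]
  x0 <- x[, !labels, drop = FALSE]
  denom <- sqrt(row_vars(x1)) + sqrt(row_vars(x0))
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero class SDs; epsilon added to the ",
            "signal-to-noise denominator", call. = FALSE)
    denom[zero] <- denom[zero] + 1e-12
  }
  (rowMeans(x1) - rowMeans(x0)) / denom
}

#' Classification boundary per gene
#'
#' The midpoint of the two class means, `b = (mu_relapse +
#' mu_relapse_free) / 2`; invariant under label swap.
#'
#' @inheritParams signal_to_noise
#' @return named numeric vector of boundaries, one per gene.
#' @export
class_boundary <- function(x, labels) {
  assert_expression(x)
  labels <- as_relapse(labels, ncol(x))
  check_two_classes(labels)
  (rowMeans(x[, labels, drop = FALSE]) + rowMeans(x[, !labels, drop = FALSE])) / 2
}

# Rank gene ids by |S| descending, exact ties by gene id (lexicographic).
rank_by_s2n <- function(s) {
  names(s)[order(-abs(s), names(s), method = "radix")]
}

#' Fit a top-N weighted-voting classifier
#'
#' Ranks genes by the absolute signal-to-noise statistic (ties broken by
#' gene id) and retains the top `n_top` together with their signal-to-noise
#' weight `S` and classification boundary `b`. Prediction sums the per-gene
#' votes `V_i = S_i * (e_i - b_i)` over the model genes: a positive total
#' votes the sample into the relapse class.
#'
#' @inheritParams signal_to_noise
#' @param n_top model size N, between 1 and the number of genes; default all
#'   genes.
#' @return object of class `voting_model` with element `genes` (data frame
#'   `gene_id`, `s2n`, `boundary`, in rank order) and `n_top`.
#' @examples
#' x <- matrix(c(2, 4, 0, 2), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
#' m <- voting_model(rbind(x, g2 = c(0, 0.1, 0, 0.1)), c(1, 1, 0, 0), n_top = 1)
#' predict(m, cbind(snew = c(g1 = 4, g2 = 0)))
#' @export
voting_model <- function(x, labels, n_top = nrow(x)) {
  assert_expression(x)
  check_scalar(n_top, "n_top", lower = 1, integer = TRUE)
  if (n_top > nrow(x)) stop("n_top exceeds the number of genes", call. = FALSE)
  s <- signal_to_noise(x, labels)
  b <- class_boundary(x, labels)
  ranked <- rank_by_s2n(s)[seq_len(n_top)]
  structure(list(
    genes = data.frame(gene_id = ranked, s2n = unname(s[ranked]),
                       boundary = unname(b[ranked]), stringsAsFactors = FALSE),
    n_top = as.integer(n_top)
  ), class = "voting_model")
}

#' @export
print.voting_model <- function(x, ...) {
  cat(sprintf("Weighted-voting classifier, top %d gene(s)\n", x$n_top))
  print(utils::head(x$genes, 10), row.names = FALSE)
  if (nrow(x$genes) > 10) cat("  ...\n")
  invisible(x)
}

#' Classify samples with a weighted-voting model
#'
#' Each model gene casts the vote `V_i = S_i * (e_i - b_i)`; the summed vote
#' decides the class: relapse if the total is strictly positive,
#' relapse-free otherwise (a total of exactly 0 is resolved to relapse-free
#' and counted in the `ties` attribute). Every model gene must be present in
#' `newdata`.
#'
#' @param object a [voting_model()].
#' @param newdata genes x samples matrix (or a named vector for one sample).
#' @param type `"class"` for the per-sample summary, `"votes"` to also return
#'   the per-gene vote matrix.
#' @param ... unused.
#' @return data frame `sample_id`, `total_vote`, `class` (with attribute
#'   `ties` counting zero totals); for `type = "votes"`, a list with `votes`
#'   (genes x samples) and the summary.
#' @export
predict.voting_model <- function(object, newdata, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample_1"))
  }
  missing_genes <- setdiff(object$genes$gene_id, rownames(newdata))
  if (length(missing_genes)) {
    stop("expression missing for model gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  e <- newdata[object$genes$gene_id, , drop = FALSE]
  votes <- object$genes$s2n * (e - object$genes$boundary)
  total <- colSums(votes)
  out <- data.frame(sample_id = colnames(newdata), total_vote = unname(total),
                    class = ifelse(total > 0, "relapse", "relapse-free"),
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- sum(total == 0)
  if (type == "votes") list(votes = votes, summary = out) else out
}

#' Binary classification metrics with the relapse class positive
#'
#' Accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and, when a
#' continuous score is supplied, the ROC AUC computed by the rank (Mann-
#' Whitney) statistic with tied scores counted 0.5. "Relapse" is the positive
#' class throughout. With a single-class truth vector the AUC is undefined
#' and returned as `NA`.
#'
#' @param truth true labels.
#' @param predicted predicted labels, aligned with `truth`.
#' @param scores optional continuous scores (e.g. total votes) for the AUC.
#' @return list `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `confusion` (2x2 table of counts TP/FP/FN/TN).
#' @export
classification_metrics <- function(truth, predicted, scores = NULL) {
  truth <- as_relapse(truth)
  predicted <- as_relapse(predicted, length(truth))
  tp <- sum(truth & predicted); fn <- sum(truth & !predicted)
  tn <- sum(!truth & !predicted); fp <- sum(!truth & predicted)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(scores) != length(truth)) stop("scores misaligned", call. = FALSE)
    n1 <- sum(truth); n0 <- sum(!truth)
    if (n1 > 0 && n0 > 0) {
      r <- rank(scores)  # midranks handle score ties (0.5 per tied pair)
      auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       auc = auc,
       confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                          dimnames = list(truth = c("relapse", "relapse-free"),
                                          predicted = c("relapse", "relapse-free"))))
}
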