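#' Random fold partitions for repeated k-fold cross-validation
#'
#' Generates `repeats` independent random partitions of the samples into
#' `folds` non-overlapping sets whose sizes differ by at most one. By default
#' the partition is stratified by class so every training fold contains both
#' classes (without which class means, and hence the signal-to-noise
#' statistic, can be undefined); the per-class remainders are rotated across
#' folds so the overall fold sizes stay balanced. Fully reproducible from
#' `seed`.
#'
#' @param labels two-class labels, one per sample.
#' @param folds number of folds k.
#' @param repeats number of random partitions.
#' @param seed integer RNG seed.
#' @param stratify stratify folds by class (default TRUE).
#' @return list of length `repeats`; each element an integer vector of fold
#'   ids in `1..folds`, one per sample.
#' @export
cv_folds <- function(labels, folds = 5, repeats = 100, seed = 1L,
                     stratify = TRUE) {
  labels <- as_relapse(labels)
  check_scalar(folds, "folds", lower = 2, integer = TRUE)
  check_scalar(repeats, "repeats", lower = 1, integer = TRUE)
  n <- length(labels)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  if (stratify && (sum(labels) < folds || sum(!labels) < folds)) {
    stop("stratified CV needs >= `folds` samples per class", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lapply(seq_len(repeats), function(r) {
    assign <- integer(n)
    if (stratify) {
      offset <- 0L
      for (cls in c(TRUE, FALSE)) {
        idx <- which(labels == cls)
        nc <- length(idx)
        sizes <- rep(nc %/% folds, folds)
        rem <- nc %% folds
        if (rem > 0) {
          extra <- ((offset + seq_len(rem) - 1L) %% folds) + 1L
          sizes[extra] <- sizes[extra] + 1L
          offset <- (offset + rem) %% folds
        }
        assign[sample(idx)] <- rep(seq_len(folds), times = sizes)
      }
    } else {
      sizes <- rep(n %/% folds, folds)
      rem <- n %% folds
      if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      assign[sample.int(n)] <- rep(seq_len(folds), times = sizes)
    }
    assign
  })
}

#' Repeated k-fold cross-validation of the weighted-voting classifier
#'
#' The model-size selection engine: for each random partition (default 100
#' repeats of 5 folds) and each held-out fold, a weighted-voting model is
#' built on the remaining folds for every model size `N = 1..n_genes`, the
#' held-out patients are classified, and misclassifications are counted. The
#' reported learning-error curve is
#' `averageerror_N = (total misclassified over all folds x repeats) / repeats`,
#' i.e. the mean number of misclassified patients per complete k-fold pass.
#' The per-training-fold |S| rankings are retained for the frequency-based
#' signature selection of [select_signature()].
#'
#' @inheritParams cv_folds
#' @param x genes x samples matrix of candidate genes.
#' @return object of class `cv_voting`: `avg_error` (named numeric, one per
#'   N), `rankings` (list of `folds * repeats` ranked gene-id vectors),
#'   `folds`, `repeats`, `seed`, `n_samples`.
#' @seealso [select_optimal_n()], [select_signature()]
#' @export
cv_voting <- function(x, labels, folds = 5, repeats = 100, seed = 1L,
                      stratify = TRUE) {
  assert_expression(x)
  labels <- as_relapse(labels, ncol(x))
  partitions <- cv_folds(labels, folds = folds, repeats = repeats, seed = seed,
                         stratify = stratify)
  n_genes <- nrow(x)
  errors <- numeric(n_genes)
  rankings <- vector("list", folds * repeats)
  r_i <- 0L
  for (part in partitions) {
    for (f in seq_len(folds)) {
      train <- part != f
      s <- signal_to_noise(x[, train, drop = FALSE], labels[train])
      b <- class_boundary(x[, train, drop = FALSE], labels[train])
      ranked <- rank_by_s2n(s)
      r_i <- r_i + 1L
      rankings[[r_i]] <- ranked
      e <- x[ranked, !train, drop = FALSE]
      votes <- s[ranked] * (e - b[ranked])
      # running total vote for every model size N at once
      totals <- apply(votes, 2, cumsum)
      if (n_genes == 1L) totals <- matrix(totals, nrow = 1L)
      pred_relapse <- totals > 0           # tie (exactly 0) -> relapse-free
      truth <- matrix(labels[!train], n_genes, sum(!train), byrow = TRUE)
      errors <- errors + rowSums(pred_relapse != truth)
    }
  }
  structure(list(avg_error = stats::setNames(errors / repeats, seq_len(n_genes)),
                 rankings = rankings, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 stratify = stratify, n_samples = ncol(x),
                 gene_ids = rownames(x)),
            class = "cv_voting")
}

#' @export
print.cv_voting <- function(x, ...) {
  cat(sprintf("Weighted-voting CV: %d-fold x %d repeats on %d samples, %d candidate genes\n",
              x$folds, x$repeats, x$n_samples, length(x$avg_error)))
  best <- which.min(x$avg_error)
  cat(sprintf("  minimum learning error %.2f misclassified patients at N = %d\n",
              x$avg_error[best], best))
  invisible(x)
}

#' @export
plot.cv_voting <- function(x, ...) {
  graphics::plot(seq_along(x$avg_error), x$avg_error, type = "b", pch = 16,
                 xlab = "model size N (top-ranked genes)",
                 ylab = "average misclassified patients", ...)
  invisible(x)
}

#' Choose the optimal model size from a CV error curve
#'
#' The smallest N whose average learning error is within `tolerance`
#' misclassified patients of the curve minimum -- the parsimony rule that
#' formalizes "a balance between accuracy and the number of genes". With a
#' flat curve this returns 1.
#'
#' @param cv a `cv_voting` object (or a bare numeric error curve).
#' @param tolerance allowed excess over the minimum, in expected
#'   misclassified patients (default 1).
#' @return integer, the optimal N.
#' @export
select_optimal_n <- function(cv, tolerance = 1) {
  curve <- if (inherits(cv, "cv_voting")) cv$avg_error else as.numeric(cv)
  if (!length(curve)) stop("empty error curve", call. = FALSE)
  check_scalar(tolerance, "tolerance", lower = 0)
  as.integer(which(curve <= min(curve) + tolerance)[1])
}

#' Frequency-based signature selection over the training-fold rankings
#'
#' Counts, for every candidate gene, how often it appears in the top `opn`
#' of the |S| ranking of each training fold (`folds * repeats` rankings, 500
#' under the defaults), then returns the `opn` most frequent genes. Ties in
#' frequency are broken by the smaller mean ranking position, then by gene
#' id.
#'
#' @param cv a `cv_voting` object.
#' @param opn signature size; defaults to [select_optimal_n()] of the curve.
#' @param tolerance passed to [select_optimal_n()] when `opn` is missing.
#' @return object of class `signature_selection`: `selected` (gene ids),
#'   `opn`, and `table` (data frame `gene_id`, `frequency`, `mean_rank`,
#'   `selected`, sorted by the selection order).
#' @export
select_signature <- function(cv, opn = NULL, tolerance = 1) {
  stopifnot(inherits(cv, "cv_voting"))
  if (is.null(opn)) opn <- select_optimal_n(cv, tolerance)
  check_scalar(opn, "opn", lower = 1, integer = TRUE)
  genes <- cv$gene_ids
  if (opn > length(genes)) stop("opn exceeds the number of candidate genes",
                                call. = FALSE)
  freq <- stats::setNames(integer(length(genes)), genes)
  rank_sum <- stats::setNames(numeric(length(genes)), genes)
  for (rk in cv$rankings) {
    top <- rk[seq_len(min(opn, length(rk)))]
    freq[top] <- freq[top] + 1L
    rank_sum[rk] <- rank_sum[rk] + seq_along(rk)
  }
  mean_rank <- rank_sum / length(cv$rankings)
  ord <- order(-freq, mean_rank, genes, method = "radix")
  tab <- data.frame(gene_id = genes[ord], frequency = as.integer(freq[ord]),
                    mean_rank = unname(mean_rank[ord]),
                    selected = seq_along(genes) <= opn,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(selected = tab$gene_id[seq_len(opn)], opn = as.integer(opn),
                 table = tab, n_rankings = length(cv$rankings)),
            class = "signature_selection")
}

#' @export
print.signature_selection <- function(x, ...) {
  cat(sprintf("Signature: top %d genes by frequency over %d training-fold rankings\n",
              x$opn, x$n_rankings))
  print(utils::head(x$table, x$opn), row.names = FALSE)
  invisible(x)
}
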