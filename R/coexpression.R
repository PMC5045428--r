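#' Top-percentile positively co-expressed mRNA partners of lncRNAs
#'
#' For each lncRNA profile, computes the Pearson correlation with every
#' candidate mRNA and retains the top `fraction` (default 1%) by correlation
#' coefficient -- a positive-correlation ranking, so anti-correlated mRNAs
#' never enter the partner set. The partner-set size is
#' `ceiling(fraction * n_candidates)`. mRNAs with zero variance have an
#' undefined correlation and are excluded with a warning. Ties in r are
#' broken by mRNA id.
#'
#' @param lnc genes x samples matrix of lncRNA profiles (or a named vector /
#'   single row for one lncRNA).
#' @param mrna genes x samples matrix of candidate mRNAs, same samples in the
#'   same order.
#' @param fraction selection fraction in (0, 1], default 0.01.
#' @return data frame `lncRNA`, `mRNA`, `r`, `rank`, one block per lncRNA,
#'   each block sorted by r descending.
#' @export
pearson_partners <- function(lnc, mrna, fraction = 0.01) {
  if (is.null(dim(lnc))) lnc <- matrix(lnc, nrow = 1, dimnames = list("lnc_1", names(lnc)))
  assert_expression(mrna)
  check_scalar(fraction, "fraction", lower = 0, upper = 1)
  if (fraction == 0) stop("fraction must be > 0", call. = FALSE)
  if (ncol(lnc) != ncol(mrna)) stop("sample mismatch between lnc and mrna", call. = FALSE)
  if (ncol(mrna) < 3) stop("need >= 3 samples for a correlation", call. = FALSE)
  n_sel <- ceiling(fraction * nrow(mrna))
  out <- lapply(rownames(lnc), function(id) {
    r <- suppressWarnings(as.vector(stats::cor(t(mrna), lnc[id, ])))
    names(r) <- rownames(mrna)
    undef <- !is.finite(r)
    if (any(undef)) {
      warning("zero-variance series excluded for ", id, ": ",
              paste(names(r)[undef], collapse = ", "), call. = FALSE)
      r <- r[!undef]
    }
    ord <- order(-r, names(r), method = "radix")
    take <- utils::head(ord, n_sel)
    data.frame(lncRNA = id, mRNA = names(r)[take], r = unname(r[take]),
               rank = seq_along(take), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Union of co-expression partner sets
#'
#' Deduplicated, sorted list of mRNAs that partner with at least one lncRNA.
#'
#' @param partners output of [pearson_partners()] (a data frame with an
#'   `mRNA` column), or a list of such data frames / character vectors.
#' @return sorted character vector of unique mRNA ids.
#' @export
union_partners <- function(partners) {
  ids <- if (is.data.frame(partners)) {
    partners$mRNA
  } else if (is.list(partners)) {
    unlist(lapply(partners, function(p) if (is.data.frame(p)) p$mRNA else p))
  } else {
    as.character(partners)
  }
  if (!length(ids)) stop("no partner sets given", call. = FALSE)
  sort(unique(ids))
}
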