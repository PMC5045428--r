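# Internal helpers shared across modules. Not exported.

# Validate a genes x samples expression matrix: numeric, finite, unique
# dimnames on both margins.
assert_expression <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric genes x samples matrix", arg), call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have gene rownames and sample colnames", arg), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("duplicate gene ids in `%s`: %s", arg,
                 paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("duplicate sample ids in `%s`: %s", arg,
                 paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}

# Coerce two-class relapse labels to logical (TRUE = relapse).  Accepts
# logical, 0/1 numeric, or character/factor with levels "relapse" and
# "relapse-free".
as_relapse <- function(labels, n = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("relapse", "relapse-free"))
    if (length(bad)) {
      stop("character labels must be 'relapse' or 'relapse-free'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    labels <- labels == "relapse"
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0 (relapse-free) or 1 (relapse)", call. = FALSE)
    }
    labels <- labels == 1
  } else if (!is.logical(labels)) {
    stop("labels must be logical, 0/1, or 'relapse'/'relapse-free'", call. = FALSE)
  }
  if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  if (!is.null(n) && length(labels) != n) {
    stop(sprintf("expected %d labels, got %d", n, length(labels)), call. = FALSE)
  }
  labels
}

check_two_classes <- function(labels, min_per_class = 2L) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < min_per_class || n0 < min_per_class) {
    stop(sprintf(
      "each class needs >= %d samples (relapse: %d, relapse-free: %d)",
      min_per_class, n1, n0), call. = FALSE)
  }
  invisible(c(relapse = n1, `relapse-free` = n0))
}

# Row-wise sample variance (n-1 denominator) without apply() overhead.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need >= 2 columns for a variance", call. = FALSE)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite scalar", name), call. = FALSE)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop(sprintf("`%s` = %s is outside its valid range", name, format(x)), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}
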