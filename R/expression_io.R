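#' Read a genes x samples expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row holds `gene_id`
#' followed by the sample ids, one gene per row, `.` decimal separator.
#' Duplicate gene or sample ids and non-numeric cells are hard errors; the
#' error for a non-numeric cell names its row and column so malformed exports
#' can be located.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression table needs a gene_id column plus >= 1 sample",
                          call. = FALSE)
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(num)) stop("expression table contains missing values", call. = FALSE)
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: header `gene_id` then sample ids,
#' tab-separated, no quoting.
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_table <- function(x, path) {
  assert_expression(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_columns <- c("sample_id", "relapse", "rfs_time", "event", "age",
                      "gender", "stage", "smoking", "vital_status")

#' Read or write a per-sample clinical annotation table
#'
#' The clinical TSV dialect has columns `sample_id`, `relapse` (0/1),
#' `rfs_time` (years), `event` (0/1), `age`, `gender` (M/F), `stage`
#' (I--IV), `smoking` (ever/never/unknown) and `vital_status` (Alive/Dead).
#' Reading validates domains and uniqueness of sample ids.
#'
#' @param path file path.
#' @return `read_clinical_table`: a data frame with the columns above.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  missing_cols <- setdiff(clinical_columns, colnames(df))
  if (length(missing_cols)) {
    stop("clinical table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[clinical_columns]
  for (col in c("relapse", "event", "age")) df[[col]] <- as.integer(df[[col]])
  df$rfs_time <- as.numeric(df$rfs_time)
  validate_annotation(df)
  df
}

#' @rdname read_clinical_table
#' @param annotation clinical data frame to write.
#' @export
write_clinical_table <- function(annotation, path) {
  validate_annotation(annotation)
  utils::write.table(annotation[clinical_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_annotation <- function(annotation) {
  if (!is.data.frame(annotation) || nrow(annotation) == 0L) {
    stop("annotation must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(clinical_columns, colnames(annotation))
  if (length(missing_cols)) {
    stop("annotation missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annotation$sample_id)) {
    stop("duplicate sample ids in annotation", call. = FALSE)
  }
  if (!all(annotation$relapse %in% c(0, 1))) stop("relapse must be 0/1", call. = FALSE)
  if (!all(annotation$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (any(annotation$rfs_time < 0) || anyNA(annotation$rfs_time)) {
    stop("rfs_time must be >= 0", call. = FALSE)
  }
  if (!all(annotation$stage %in% c("I", "II", "III", "IV"))) {
    stop("stage must be one of I, II, III, IV", call. = FALSE)
  }
  if (!all(annotation$smoking %in% c("ever", "never", "unknown"))) {
    stop("smoking must be ever/never/unknown", call. = FALSE)
  }
  invisible(annotation)
}

#' Z-score standardize an expression matrix
#'
#' Standardizes intensities as `z = (e - mean) / sd`. The default margin is
#' `"sample"`: each array (column) is centered and scaled over its probes, so
#' every column of the result has mean 0 and sample SD 1 (the convention used
#' to harmonize arrays from heterogeneous datasets before cross-dataset
#' modelling). A per-gene margin is available for row-wise standardization.
#' The SD uses the n-1 (sample) denominator.
#'
#' @param x numeric genes x samples matrix.
#' @param margin `"sample"` (default, per column) or `"gene"` (per row).
#' @return matrix of the same shape, standardized along the chosen margin.
#'   A zero-SD column (or row) is an error naming the offender.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 6, 8), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' zscore_standardize(m)
#' @export
zscore_standardize <- function(x, margin = c("sample", "gene")) {
  assert_expression(x)
  margin <- match.arg(margin)
  if (margin == "gene") {
    return(t(zscore_standardize(t(x), margin = "sample")))
  }
  if (nrow(x) < 2L) stop("need >= 2 genes to standardize a sample", call. = FALSE)
  mu <- colMeans(x)
  sdv <- sqrt(colSums((x - rep(mu, each = nrow(x)))^2) / (nrow(x) - 1))
  zero <- sdv == 0
  if (any(zero)) {
    stop("zero standard deviation in sample(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Collapse probe-level rows to gene-level expression
#'
#' Averages (unweighted arithmetic mean) all probe rows mapping to the same
#' gene, per sample. Every probe row must appear in the map; unmapped probes
#' are an error listing them. Output genes are ordered lexicographically.
#'
#' @param x probe-level matrix (probes x samples).
#' @param map data frame with columns `probe_id` and `gene_id`, many probes
#'   to one gene, each probe mapped exactly once.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(x, map) {
  assert_expression(x)
  if (!is.data.frame(map) || !all(c("probe_id", "gene_id") %in% colnames(map)) ||
      nrow(map) == 0L) {
    stop("map must be a non-empty data frame with probe_id and gene_id",
         call. = FALSE)
  }
  if (anyDuplicated(map$probe_id)) {
    stop("probes mapped more than once: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(rownames(x), map$probe_id)
  if (length(unmapped)) {
    stop("unmapped probes: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  gene <- map$gene_id[match(rownames(x), map$probe_id)]
  sums <- rowsum(x, group = gene)           # sorted by group label
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Summarize a cohort's clinical covariates as counts and percentages
#'
#' Produces the usual "n (%)" clinical-characteristics table: for each
#' covariate (relapse status, vital status, gender, tumor stage, smoking
#' status, and age dichotomized at 65 years) the per-level count and the
#' percentage of the cohort, rounded to one decimal place.
#'
#' @param annotation clinical data frame (see [read_clinical_table()]).
#' @return data frame with columns `covariate`, `level`, `n`, `pct`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 80, n_genes = 20, seed = 3))
#' summarize_cohort(coh$annotation)
#' @export
summarize_cohort <- function(annotation) {
  validate_annotation(annotation)
  n <- nrow(annotation)
  levels_of <- list(
    `Age (years)` = ifelse(annotation$age > 65, ">65", "<=65"),
    Gender = ifelse(annotation$gender == "M", "Male", "Female"),
    `Vital status` = annotation$vital_status,
    `Relapse status` = ifelse(annotation$relapse == 1, "Relapse", "Not relapse"),
    `Tumor stage` = annotation$stage,
    `Smoking status` = annotation$smoking
  )
  out <- do.call(rbind, lapply(names(levels_of), function(cv) {
    tab <- table(levels_of[[cv]])
    data.frame(covariate = cv, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
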