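#' Split a cohort into discovery (favorable + fatal) and testing sets
#'
#' Applies the extreme-phenotype selection rule used to form a clean
#' discovery set: *favorable* patients are alive, relapse-free and followed
#' beyond the horizon (`rfs_time > horizon`, strict); *fatal* patients died
#' within the horizon (`rfs_time < horizon`, strict) with recorded relapse.
#' Everyone else -- including patients exactly at the horizon boundary --
#' goes to the testing set, so the three sets always partition the cohort.
#'
#' @param annotation clinical data frame with `sample_id`, `relapse`,
#'   `rfs_time`, `vital_status`.
#' @param horizon selection horizon in years (default 5).
#' @return list `favorable`, `fatal`, `discovery` (favorable + fatal),
#'   `testing` -- character vectors of sample ids.
#' @export
split_discovery <- function(annotation, horizon = 5) {
  validate_annotation(annotation)
  if (anyNA(annotation$vital_status)) stop("missing vital status", call. = FALSE)
  alive <- annotation$vital_status == "Alive"
  favorable <- alive & annotation$relapse == 0 & annotation$rfs_time > horizon
  fatal <- !alive & annotation$relapse == 1 & annotation$rfs_time < horizon
  list(favorable = annotation$sample_id[favorable],
       fatal = annotation$sample_id[fatal],
       discovery = annotation$sample_id[favorable | fatal],
       testing = annotation$sample_id[!(favorable | fatal)])
}

# Shared survival evaluation of a scored, grouped cohort.
evaluate_survival <- function(scores, groups, time, event, horizon = 5) {
  km_rates <- lapply(split(seq_along(groups), groups), function(idx) {
    km <- kaplan_meier(time[idx], event[idx])
    c(rate_3y = survival_at(km, 3), rate_5y = survival_at(km, 5))
  })
  lr <- if (length(unique(groups)) >= 2) {
    log_rank(groups, time, event)
  } else {
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }
  troc <- tryCatch(time_dependent_roc(scores, time, event, horizon = horizon),
                   error = function(e) NULL)
  cidx <- tryCatch(harrell_c(scores, time, event), error = function(e) NULL)
  list(km_rates = km_rates, log_rank = lr,
       auc_horizon = if (is.null(troc)) NA_real_ else troc$auc,
       time_roc = troc,
       c_index = if (is.null(cidx)) NA_real_ else cidx$c_index)
}

#' Run the full discovery workflow on a cohort
#'
#' Chains the stages of the signature-discovery analysis: optional probe
#' collapsing, per-array Z-score standardization, favorable/fatal discovery
#' selection, Bonferroni-screened differential expression between the fatal
#' (relapse) and favorable (relapse-free) patients, repeated stratified
#' 5-fold cross-validation of the weighted-voting classifier over the
#' differential genes, optimal-N and frequency-based signature selection,
#' the multivariate Cox risk-score model with its frozen median cutoff, and
#' the survival evaluation of the scored discovery cohort. All randomness
#' (fold partitions) derives from `seed`, so a rerun with the same inputs
#' and seed reproduces the report exactly.
#'
#' If no gene passes the differential screen the pipeline stops gracefully:
#' the returned report has `status = "no_differential_genes"` and carries
#' the screen results only.
#'
#' @param expression genes x samples matrix (raw or probe-level).
#' @param annotation clinical data frame aligned with the columns.
#' @param probe_map optional probe-to-gene map (see [collapse_probes()]).
#' @param alpha Bonferroni-adjusted significance threshold (default 0.01).
#' @param folds,repeats cross-validation design (default 5 x 100).
#' @param opt_tolerance tolerance of [select_optimal_n()], in misclassified
#'   patients.
#' @param opn optional fixed signature size; when `NULL` (default) the size
#'   is chosen from the CV error curve by [select_optimal_n()]. Capped at
#'   the number of differential genes.
#' @param horizon discovery-selection and ROC horizon in years (default 5).
#' @param seed RNG seed for the fold partitions.
#' @param standardize Z-score standardize per sample (default TRUE; set
#'   FALSE when the matrix is already standardized).
#' @return object of class `pipeline_report`; see Details for components.
#' @details The report contains `status`, `differential` (screen table),
#'   `de_genes`, `cv` (`cv_voting` object), `opn`, `signature`
#'   (`signature_selection`), `voting` (final `voting_model`),
#'   `classification` (resubstitution metrics on discovery), `risk_model`,
#'   `risk_groups` (discovery assignments), `survival` (KM rates, log-rank,
#'   AUC at the horizon, C-index), `ids` (the discovery/testing split),
#'   `seed` and `params`.
#' @seealso [run_validation()], [write_report()]
#' @export
run_discovery <- function(expression, annotation, probe_map = NULL,
                          alpha = 0.01, folds = 5, repeats = 100,
                          opt_tolerance = 1, opn = NULL, horizon = 5,
                          seed = 1L, standardize = TRUE) {
  assert_expression(expression)
  validate_annotation(annotation)
  if (!identical(colnames(expression), annotation$sample_id)) {
    stop("expression columns and annotation sample_id must match in order",
         call. = FALSE)
  }
  if (!is.null(probe_map)) expression <- collapse_probes(expression, probe_map)
  if (standardize) expression <- zscore_standardize(expression)

  ids <- split_discovery(annotation, horizon = horizon)
  if (length(ids$favorable) < 2 || length(ids$fatal) < 2) {
    stop("discovery selection yields fewer than 2 patients in a class",
         call. = FALSE)
  }
  disc <- match(ids$discovery, annotation$sample_id)
  x_disc <- expression[, ids$discovery, drop = FALSE]
  labels <- ids$discovery %in% ids$fatal   # fatal = relapse class

  de <- differential_expression(x_disc, labels, alpha = alpha)
  de_genes <- select_differential(de, alpha = alpha)
  params <- list(alpha = alpha, folds = folds, repeats = repeats,
                 opt_tolerance = opt_tolerance, horizon = horizon)
  if (!length(de_genes)) {
    return(structure(list(status = "no_differential_genes", differential = de,
                          de_genes = character(0), ids = ids, seed = seed,
                          params = params),
                     class = "pipeline_report"))
  }

  cv <- cv_voting(x_disc[de_genes, , drop = FALSE], labels, folds = folds,
                  repeats = repeats, seed = seed)
  if (is.null(opn)) opn <- select_optimal_n(cv, tolerance = opt_tolerance)
  opn <- min(opn, length(de_genes))
  sig <- select_signature(cv, opn = opn)

  voting <- voting_model(x_disc[sig$selected, , drop = FALSE], labels,
                         n_top = opn)
  pred <- predict(voting, x_disc)
  cls <- classification_metrics(labels, pred$class == "relapse",
                                scores = pred$total_vote)

  rm <- fit_risk_model(x_disc, annotation$rfs_time[disc],
                       annotation$event[disc], sig$selected)
  groups <- predict(rm, x_disc)
  surv <- evaluate_survival(groups$score, groups$group,
                            annotation$rfs_time[disc],
                            annotation$event[disc], horizon = horizon)

  structure(list(status = "ok", differential = de, de_genes = de_genes,
                 cv = cv, opn = opn, signature = sig, voting = voting,
                 classification = cls, risk_model = rm, risk_groups = groups,
                 survival = surv, ids = ids, seed = as.integer(seed),
                 params = params, expression = expression),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Relapse-signature discovery report\n")
  if (x$status != "ok") {
    cat(sprintf("  status: %s (no gene passed the Bonferroni screen at alpha = %g)\n",
                x$status, x$params$alpha))
    return(invisible(x))
  }
  cat(sprintf("  discovery: %d patients (%d fatal, %d favorable); testing held out: %d\n",
              length(x$ids$discovery), length(x$ids$fatal),
              length(x$ids$favorable), length(x$ids$testing)))
  cat(sprintf("  differential genes (adj. p < %g): %d\n",
              x$params$alpha, length(x$de_genes)))
  cat(sprintf("  optimal model size: %d; signature: %s\n", x$opn,
              paste(x$signature$selected, collapse = ", ")))
  cat(sprintf("  discovery classification: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
              100 * x$classification$accuracy, 100 * x$classification$sensitivity,
              100 * x$classification$specificity, x$classification$auc))
  cat(sprintf("  risk-score cutoff (discovery median): %.4f\n", x$risk_model$cutoff))
  cat(sprintf("  log-rank high vs low risk: chi2 = %.2f, p = %.3g\n",
              x$survival$log_rank$statistic, x$survival$log_rank$p_value))
  cat(sprintf("  AUC at %g years: %.3f; C-index: %.3f\n",
              x$params$horizon, x$survival$auc_horizon, x$survival$c_index))
  invisible(x)
}

#' Validate a frozen risk model on a new dataset
#'
#' Scores a dataset with an already-fitted risk model (weights and median
#' cutoff frozen at discovery -- nothing is refitted), assigns high-/low-risk
#' groups, and computes the survival evaluation suite: 3-/5-year KM rates
#' per group, log-rank test, univariate/multivariate Cox adjustment table,
#' time-dependent AUC at the horizon, and Harrell's C. Signature genes
#' absent from the dataset are an error listing them.
#'
#' @param model a [fit_risk_model()] object (or a `pipeline_report`, whose
#'   `risk_model` is used).
#' @param expression genes x samples matrix of the validation dataset.
#' @param annotation clinical data frame aligned with the columns.
#' @param horizon ROC horizon in years (default 5).
#' @param standardize Z-score standardize per sample first (default TRUE).
#' @return list of class `validation_report`: `assignments`, `survival`,
#'   `cox_table`, `cutoff`.
#' @export
run_validation <- function(model, expression, annotation, horizon = 5,
                           standardize = TRUE) {
  if (inherits(model, "pipeline_report")) model <- model$risk_model
  stopifnot(inherits(model, "risk_model"))
  assert_expression(expression)
  validate_annotation(annotation)
  if (!identical(colnames(expression), annotation$sample_id)) {
    stop("expression columns and annotation sample_id must match in order",
         call. = FALSE)
  }
  missing_genes <- setdiff(names(model$weights), rownames(expression))
  if (length(missing_genes)) {
    stop("validation dataset is missing signature gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (standardize) expression <- zscore_standardize(expression)
  cutoff_before <- model$cutoff
  assignments <- predict(model, expression)
  stopifnot(identical(cutoff_before, model$cutoff))  # frozen-cutoff contract
  surv <- evaluate_survival(assignments$score, assignments$group,
                            annotation$rfs_time, annotation$event,
                            horizon = horizon)
  cox_table <- tryCatch(
    multivariable_adjustment(annotation, assignments$group),
    error = function(e) NULL)
  structure(list(assignments = assignments, survival = surv,
                 cox_table = cox_table, cutoff = model$cutoff,
                 horizon = horizon),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Risk-model validation report\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s n=%d", names(table(x$assignments$group)),
                            table(x$assignments$group)), collapse = ", ")))
  cat(sprintf("  log-rank: chi2 = %.2f, p = %.3g\n",
              x$survival$log_rank$statistic, x$survival$log_rank$p_value))
  cat(sprintf("  AUC at %g years: %.3f; C-index: %.3f\n",
              x$horizon, x$survival$auc_horizon, x$survival$c_index))
  invisible(x)
}

#' Write the tabular artifacts of a report to a directory
#'
#' Persists the main tables as TSV: the differential screen, the CV error
#' curve, the signature frequency table, the voting model (gene, S,
#' boundary, rank), the risk model (gene, weight; cutoff and seed in a
#' metadata file) and the risk-group assignments.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(wt(report$differential, "differential.tsv"))
  if (report$status == "ok") {
    curve <- data.frame(N = seq_along(report$cv$avg_error),
                        average_error = unname(report$cv$avg_error))
    model_tab <- cbind(report$voting$genes, rank = seq_len(nrow(report$voting$genes)))
    risk_tab <- data.frame(gene_id = names(report$risk_model$weights),
                           weight = unname(report$risk_model$weights))
    paths <- c(paths,
               wt(curve, "cv_error_curve.tsv"),
               wt(report$signature$table, "signature_frequency.tsv"),
               wt(model_tab, "voting_model.tsv"),
               wt(risk_tab, "risk_model.tsv"),
               wt(report$risk_groups, "risk_groups.tsv"))
    meta <- c(sprintf("cutoff=%.15g", report$risk_model$cutoff),
              sprintf("seed=%d", report$seed),
              sprintf("standardization=%s", report$risk_model$standardization))
    writeLines(meta, file.path(dir, "risk_model_meta.txt"))
    paths <- c(paths, file.path(dir, "risk_model_meta.txt"))
  }
  invisible(paths)
}
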