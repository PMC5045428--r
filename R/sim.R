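#' Configuration for the synthetic relapse cohort generator
#'
#' Bundles and validates every knob of the generative model used by
#' [simulate_cohort()]. The defaults emulate the discovery-cohort design the
#' package targets: 121 lung adenocarcinoma patients of whom about 27% belong
#' to the relapse class, nine informative genes separating the classes by two
#' standardized units, and recurrence-free survival generated under a
#' proportional-hazards model with administrative censoring and uniform
#' dropout.
#'
#' @param n_patients number of patients.
#' @param n_genes total number of genes on the (synthetic) array.
#' @param n_informative number of genes whose class means differ; these are
#'   the first `n_informative` gene ids and are reported in the cohort truth.
#' @param effect_size mean expression difference between the relapse and
#'   relapse-free classes for informative genes, in standardized units
#'   (classes sit at `+/- effect_size/2`).
#' @param within_class_sd expression noise SD within a class (> 0).
#' @param relapse_fraction expected proportion of patients in the relapse
#'   class, strictly between 0 and 1.
#' @param baseline_hazard baseline event rate in events per year (> 0).
#' @param beta_link numeric vector of log-hazard weights, one per informative
#'   gene; the linear predictor is `sum(beta_link * x[informative])`.
#'   Defaults to `rep(0.35, n_informative)`, which with the default effect
#'   size makes the relapse class relapse within a few years and leaves the
#'   relapse-free class mostly event-free.
#' @param censor_horizon administrative censoring time in years (> 0);
#'   independent dropout is drawn Uniform(0, `censor_horizon`).
#' @param probes_per_gene number of array probes per gene (>= 1), used by
#'   [simulate_probe_level()].
#' @param probe_jitter_sd SD of the probe-level jitter around the gene value.
#' @param seed integer RNG seed; the whole cohort is deterministic given the
#'   seed and the other parameters.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_probe_level()]
#' @export
sim_config <- function(n_patients = 121, n_genes = 200, n_informative = 9,
                       effect_size = 2, within_class_sd = 1,
                       relapse_fraction = 33 / 121, baseline_hazard = 0.08,
                       beta_link = NULL, censor_horizon = 10,
                       probes_per_gene = 1, probe_jitter_sd = 0.1,
                       seed = 1L) {
  check_scalar(n_patients, "n_patients", lower = 1, integer = TRUE)
  check_scalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar(n_informative, "n_informative", lower = 0, integer = TRUE)
  if (n_informative > n_genes) stop("n_informative must be <= n_genes", call. = FALSE)
  check_scalar(effect_size, "effect_size", lower = 0)
  check_scalar(within_class_sd, "within_class_sd", lower = 0, strict = TRUE, upper = Inf)
  check_scalar(relapse_fraction, "relapse_fraction", lower = 0, upper = 1, strict = TRUE)
  check_scalar(baseline_hazard, "baseline_hazard", lower = 0, strict = TRUE, upper = Inf)
  check_scalar(censor_horizon, "censor_horizon", lower = 0, strict = TRUE, upper = Inf)
  check_scalar(probes_per_gene, "probes_per_gene", lower = 1, integer = TRUE)
  check_scalar(probe_jitter_sd, "probe_jitter_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  if (is.null(beta_link)) beta_link <- rep(0.35, n_informative)
  if (!is.numeric(beta_link) || length(beta_link) != n_informative ||
      !all(is.finite(beta_link))) {
    stop("beta_link must be a finite numeric vector of length n_informative",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    within_class_sd = within_class_sd, relapse_fraction = relapse_fraction,
    baseline_hazard = baseline_hazard, beta_link = beta_link,
    censor_horizon = censor_horizon,
    probes_per_gene = as.integer(probes_per_gene),
    probe_jitter_sd = probe_jitter_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  patients: %d  genes: %d (%d informative)\n",
              x$n_patients, x$n_genes, x$n_informative))
  cat(sprintf("  effect size: %g SD units, within-class SD: %g\n",
              x$effect_size, x$within_class_sd))
  cat(sprintf("  relapse fraction: %.3f, baseline hazard: %g /year\n",
              x$relapse_fraction, x$baseline_hazard))
  cat(sprintf("  censor horizon: %g years, seed: %d\n", x$censor_horizon, x$seed))
  invisible(x)
}

# Clinical covariate marginals mirrored from the discovery-cohort summary the
# generator emulates (stage I 76.9%, age <= 65 76.9%, male 45.6%, ever-smoker
# 48.8%). Ages are drawn uniformly within the dichotomized bands.
draw_covariates <- function(n) {
  over65 <- stats::runif(n) < 0.231
  age <- ifelse(over65,
                sample(66:80, n, replace = TRUE),
                sample(45:65, n, replace = TRUE))
  gender <- ifelse(stats::runif(n) < 0.456, "M", "F")
  stage <- ifelse(stats::runif(n) < 0.769, "I", "II")
  smoking <- ifelse(stats::runif(n) < 0.488, "ever", "never")
  data.frame(age = age, gender = gender, stage = stage, smoking = smoking,
             stringsAsFactors = FALSE)
}

#' Simulate an expression + survival cohort with known informative genes
#'
#' Generates a two-class cohort with the statistical structure the signature
#' workflow assumes. A latent relapse class is drawn per patient
#' (`Bernoulli(relapse_fraction)`); informative genes are
#' `Normal(+effect_size/2, within_class_sd)` in the relapse class and
#' `Normal(-effect_size/2, within_class_sd)` otherwise, non-informative genes
#' `Normal(0, within_class_sd)` in both. Recurrence-free survival times are
#' exponential with rate `baseline_hazard * exp(sum(beta_link * x))` over the
#' informative genes, right-censored by independent Uniform(0, horizon)
#' dropout and administrative censoring at the horizon. The recorded relapse
#' label is the latent class; with the default parameters the relapse class
#' relapses early so label and observed event agree for almost all patients,
#' which makes the favorable/fatal discovery selection rule of
#' [split_discovery()] applicable.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_cohort`: a list with
#'   * `expression`: genes x samples matrix,
#'   * `annotation`: per-sample clinical data frame (`sample_id`, `relapse`,
#'     `rfs_time` in years, `event`, `age`, `gender`, `stage`, `smoking`,
#'     `vital_status`),
#'   * `truth`: informative gene ids and their `beta_link` weights,
#'   * `config`: the configuration used.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 60, n_genes = 50, seed = 7))
#' table(coh$annotation$relapse, coh$annotation$event)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_patients
  g <- config$n_genes
  relapse <- stats::runif(n) < config$relapse_fraction

  gene_ids <- sprintf("g%04d", seq_len(g))
  sample_ids <- sprintf("s%04d", seq_len(n))
  x <- matrix(stats::rnorm(g * n, sd = config$within_class_sd), g, n,
              dimnames = list(gene_ids, sample_ids))
  if (config$n_informative > 0) {
    shift <- ifelse(relapse, config$effect_size / 2, -config$effect_size / 2)
    idx <- seq_len(config$n_informative)
    x[idx, ] <- x[idx, , drop = FALSE] +
      matrix(shift, config$n_informative, n, byrow = TRUE)
  }

  lp <- if (config$n_informative > 0) {
    colSums(config$beta_link * x[seq_len(config$n_informative), , drop = FALSE])
  } else {
    rep(0, n)
  }
  event_time <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  dropout <- stats::runif(n, 0, config$censor_horizon)
  censor_time <- pmin(dropout, config$censor_horizon)
  rfs_time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)

  cov <- draw_covariates(n)
  annotation <- data.frame(
    sample_id = sample_ids,
    relapse = as.integer(relapse),
    rfs_time = rfs_time,
    event = event,
    age = cov$age,
    gender = cov$gender,
    stage = cov$stage,
    smoking = cov$smoking,
    vital_status = ifelse(event == 1L, "Dead", "Alive"),
    stringsAsFactors = FALSE
  )
  structure(list(
    expression = x,
    annotation = annotation,
    truth = list(informative = gene_ids[seq_len(config$n_informative)],
                 beta_link = config$beta_link),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d patients (seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$config$seed))
  cat(sprintf("  relapse class: %d / %d, observed events: %d\n",
              sum(x$annotation$relapse), nrow(x$annotation),
              sum(x$annotation$event)))
  cat(sprintf("  informative genes: %s\n",
              paste(utils::head(x$truth$informative, 5), collapse = ", ")))
  invisible(x)
}

#' Simulate probe-level expression with a probe-to-gene map
#'
#' Expands each gene of a simulated cohort into `probes_per_gene` probe rows,
#' each equal to the gene value plus independent Normal(0, `probe_jitter_sd`)
#' jitter, together with a many-to-one probe-to-gene map covering every probe
#' exactly once. Collapsing the probe matrix with [collapse_probes()] (mean
#' over probes) recovers the gene matrix up to the jitter.
#'
#' @param config a [sim_config()] object; `probes_per_gene` and
#'   `probe_jitter_sd` control the expansion.
#' @return list with `probes` (probe-level matrix), `map` (data frame
#'   `probe_id`, `gene_id`) and `cohort` (the underlying
#'   [simulate_cohort()] result).
#' @export
simulate_probe_level <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cohort <- simulate_cohort(config)
  k <- config$probes_per_gene
  g <- nrow(cohort$expression)
  gene_ids <- rownames(cohort$expression)
  probe_ids <- paste0(rep(gene_ids, each = k), "_p", rep(seq_len(k), times = g))
  probes <- cohort$expression[rep(seq_len(g), each = k), , drop = FALSE]
  if (config$probe_jitter_sd > 0) {
    probes <- probes + matrix(
      stats::rnorm(length(probes), sd = config$probe_jitter_sd),
      nrow(probes), ncol(probes))
  }
  rownames(probes) <- probe_ids
  map <- data.frame(probe_id = probe_ids,
                    gene_id = rep(gene_ids, each = k),
                    stringsAsFactors = FALSE)
  list(probes = probes, map = map, cohort = cohort)
}

#' Write a synthetic cohort to disk as plain TSV files
#'
#' Writes `expression.tsv` and `clinical.tsv` in the package's TSV dialects
#' (see [write_expression_table()] and [write_clinical_table()]) plus a
#' `config.txt` of `key=value` lines recording every generator parameter,
#' including the seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             config = file.path(dir, "config.txt"))
  write_expression_table(cohort$expression, paths[["expression"]])
  write_clinical_table(cohort$annotation, paths[["clinical"]])
  cfg <- cohort$config
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s=%s", k, paste(format(cfg[[k]], digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, paths[["config"]])
  invisible(paths)
}
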