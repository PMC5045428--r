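#' Cox proportional-hazards fit returning a hazard-ratio table
#'
#' Fits `Surv(time, event) ~ .` over the supplied covariates by partial-
#' likelihood maximization with the Efron tie approximation
#' ([survival::coxph()]), and returns one row per term: coefficient, SE,
#' hazard ratio `exp(coef)` with its Wald 95% CI, and the Wald p-value.
#' Non-convergence (e.g. monotone likelihood under complete separation) is
#' surfaced as a warning on the returned table, never silently clipped.
#'
#' @param time follow-up times (years), `>= 0`.
#' @param event event indicator, 0/1, at least one event.
#' @param covariates data frame (or matrix / single vector) of explanatory
#'   variables.
#' @return data frame `term`, `coef`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`; the `coxph` fit is attached as attribute `"fit"`.
#' @export
fit_cox <- function(time, event, covariates) {
  if (any(time < 0)) stop("negative follow-up times", call. = FALSE)
  if (!any(event == 1)) stop("no events observed", call. = FALSE)
  if (is.null(dim(covariates))) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w))) {
        warning("Cox fit did not converge cleanly: ", conditionMessage(w),
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  co <- sm$coefficients
  hr <- hr_from_coef(co[, "coef"], co[, "se(coef)"])
  out <- data.frame(term = rownames(co), coef = unname(co[, "coef"]),
                    se = unname(co[, "se(coef)"]), hr = hr$hr,
                    ci_lower = hr$ci_lower, ci_upper = hr$ci_upper,
                    p_value = unname(co[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Hazard ratio and 95% CI from a Cox coefficient
#'
#' `HR = exp(coef)`; when an SE is given, the Wald interval
#' `exp(coef -/+ 1.96 * se)`.
#'
#' @param coef log hazard ratio(s).
#' @param se standard error(s), optional.
#' @return data frame `hr`, `ci_lower`, `ci_upper` (CIs `NA` without `se`).
#' @examples
#' hr_from_coef(1.058, 0.19)  # hr = exp(1.058) = 2.881
#' @export
hr_from_coef <- function(coef, se = NULL) {
  if (is.null(se)) se <- rep(NA_real_, length(coef))
  if (any(se < 0, na.rm = TRUE)) stop("se must be >= 0", call. = FALSE)
  data.frame(hr = exp(coef), ci_lower = exp(coef - 1.96 * se),
             ci_upper = exp(coef + 1.96 * se), row.names = NULL)
}

#' Univariate Cox regression for each gene
#'
#' One single-covariate Cox fit per gene of the matrix, with RFS as the
#' outcome; the per-gene analogue of the multivariate fit in
#' [fit_risk_model()].
#'
#' @param x genes x samples matrix.
#' @param time,event survival outcome aligned with the columns of `x`.
#' @return data frame, one row per gene, with the [fit_cox()] columns.
#' @export
univariate_cox <- function(x, time, event) {
  assert_expression(x)
  out <- do.call(rbind, lapply(rownames(x), function(g) {
    row <- fit_cox(time, event, data.frame(expr = x[g, ]))
    row$term <- g
    row
  }))
  rownames(out) <- NULL
  out
}

#' Linear risk score
#'
#' `score = sum_i Exp_i * w_i` over the signature genes; linear in the
#' expression values, independent of gene order. Every weighted gene must be
#' present in the matrix.
#'
#' @param weights named numeric vector of per-gene weights (typically
#'   multivariate Cox coefficients).
#' @param x genes x samples matrix (or a named vector for one sample).
#' @return named numeric vector of per-sample scores.
#' @export
risk_score <- function(weights, x) {
  if (is.null(names(weights))) stop("weights must be named by gene id", call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample_1"))
  missing_genes <- setdiff(names(weights), rownames(x))
  if (length(missing_genes)) {
    stop("expression missing for signature gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  colSums(x[names(weights), , drop = FALSE] * weights)
}

#' Fit the Cox-weighted risk-score model on a discovery cohort
#'
#' Fits the signature genes jointly in a multivariate Cox model of
#' recurrence-free survival, takes the regression coefficients as the
#' risk-score weights, scores the discovery patients, and freezes the median
#' discovery score as the dichotomization cutoff. The frozen cutoff is reused
#' unchanged when the model is applied to any other dataset -- validation
#' never refits weights or cutoff. Expression entering the model is expected
#' to be standardized by the same convention as discovery (see
#' [zscore_standardize()]); [predict.risk_model()] warns when scoring data
#' that do not look column-standardized.
#'
#' @param x genes x samples standardized expression matrix.
#' @param time,event recurrence-free survival outcome for the columns of `x`.
#' @param genes character vector of signature gene ids, all present in `x`.
#' @return object of class `risk_model`: `weights` (named coefficients),
#'   `cutoff` (discovery median score), `cox` (the multivariate fit table),
#'   `discovery_scores`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 80, n_genes = 30, seed = 11))
#' z <- zscore_standardize(coh$expression)
#' rm <- fit_risk_model(z, coh$annotation$rfs_time, coh$annotation$event,
#'                      coh$truth$informative[1:3])
#' head(predict(rm, z))
#' @export
fit_risk_model <- function(x, time, event, genes) {
  assert_expression(x)
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes)) {
    stop("signature gene(s) absent from the matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  covar <- as.data.frame(t(x[genes, , drop = FALSE]))
  colnames(covar) <- genes
  cox <- fit_cox(time, event, covar)
  weights <- stats::setNames(cox$coef, cox$term)
  scores <- risk_score(weights, x)
  structure(list(weights = weights, cutoff = stats::median(scores),
                 cox = cox, discovery_scores = scores,
                 standardization = "zscore-per-sample"),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Cox risk-score model: %d genes, cutoff %.4f (discovery median)\n",
              length(x$weights), x$cutoff))
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$weights

#' Score samples and assign high-/low-risk groups with a frozen cutoff
#'
#' Computes the linear risk score for every sample and dichotomizes at the
#' model's frozen cutoff: strictly greater than the cutoff is high-risk,
#' equal or below is low-risk. Warns when the matrix does not look
#' column-standardized (the cutoff only transfers across datasets under a
#' shared standardization convention).
#'
#' @param object a [fit_risk_model()] object.
#' @param newdata genes x samples matrix.
#' @param ... unused.
#' @return data frame `sample_id`, `score`, `group` ("high-risk"/"low-risk").
#' @export
predict.risk_model <- function(object, newdata, ...) {
  assert_expression(newdata)
  if (nrow(newdata) >= 10 &&
      (max(abs(colMeans(newdata))) > 0.2 ||
       max(abs(sqrt(row_vars(t(newdata))) - 1)) > 0.5)) {
    warning("expression does not look Z-score standardized per sample; ",
            "the frozen cutoff assumes the discovery standardization",
            call. = FALSE)
  }
  scores <- risk_score(object$weights, newdata)
  data.frame(sample_id = colnames(newdata), score = unname(scores),
             group = ifelse(scores > object$cutoff, "high-risk", "low-risk"),
             stringsAsFactors = FALSE)
}

#' @rdname predict.risk_model
#' @param model a `risk_model`.
#' @param x genes x samples matrix.
#' @export
assign_groups <- function(model, x) predict(model, x)

#' Univariate and multivariate Cox regression of RFS on the signature and
#' clinical covariates
#'
#' Reproduces the conventional adjustment table: each variable (risk group,
#' age dichotomized at 65, gender, tumor stage with stage I as the
#' reference, smoking status) fitted alone (univariate) and jointly
#' (multivariate) against recurrence-free survival. Multi-level stage
#' contributes one row per non-reference level, plus an explicit reference
#' row with HR printed as 1.
#'
#' @param annotation clinical data frame with `rfs_time`, `event`, `age`,
#'   `gender`, `stage`, `smoking`.
#' @param groups risk-group labels ("high-risk"/"low-risk"), aligned with
#'   `annotation` rows, e.g. from [predict.risk_model()].
#' @return data frame `variable`, `contrast`, and for each of the univariate
#'   and multivariate fits the HR, 95% CI bounds and p-value.
#' @export
multivariable_adjustment <- function(annotation, groups) {
  validate_annotation(annotation)
  if (length(groups) != nrow(annotation)) stop("groups misaligned", call. = FALSE)
  dat <- data.frame(
    signature = factor(groups, levels = c("low-risk", "high-risk")),
    age = factor(ifelse(annotation$age > 65, ">65", "<=65"),
                 levels = c("<=65", ">65")),
    gender = factor(annotation$gender, levels = c("F", "M")),
    stage = factor(annotation$stage,
                   levels = intersect(c("I", "II", "III", "IV"),
                                      unique(annotation$stage))),
    smoking = factor(annotation$smoking, levels = c("never", "ever", "unknown"))
  )
  dat$smoking <- droplevels(dat$smoking)
  keep <- vapply(dat, function(v) nlevels(droplevels(v)) > 1, logical(1))
  vars <- names(dat)[keep]
  uni <- lapply(vars, function(v) {
    fit_cox(annotation$rfs_time, annotation$event, dat[v])
  })
  multi <- fit_cox(annotation$rfs_time, annotation$event, dat[vars])
  contrasts <- list(
    signature = "High risk vs. Low risk", age = ">65 vs. <=65",
    gender = "Male vs. Female", smoking = "Ever vs. Never")
  rows <- list()
  for (i in seq_along(vars)) {
    v <- vars[i]
    u <- uni[[i]]
    for (j in seq_len(nrow(u))) {
      term <- u$term[j]
      m <- multi[multi$term == term, , drop = FALSE]
      lab <- if (v == "stage") {
        sub("^stage", "", term)
      } else {
        contrasts[[v]] %||% term
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, contrast = lab,
        hr_uni = u$hr[j], ci_lower_uni = u$ci_lower[j],
        ci_upper_uni = u$ci_upper[j], p_uni = u$p_value[j],
        hr_multi = m$hr, ci_lower_multi = m$ci_lower,
        ci_upper_multi = m$ci_upper, p_multi = m$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if ("stage" %in% vars && nlevels(dat$stage) > 2) {
    ref <- data.frame(variable = "stage", contrast = "I (reference)",
                      hr_uni = 1, ci_lower_uni = NA, ci_upper_uni = NA,
                      p_uni = NA, hr_multi = 1, ci_lower_multi = NA,
                      ci_upper_multi = NA, p_multi = NA,
                      stringsAsFactors = FALSE)
    first_stage <- which(out$variable == "stage")[1]
    out <- rbind(out[seq_len(first_stage - 1L), ], ref,
                 out[first_stage:nrow(out), ])
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
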