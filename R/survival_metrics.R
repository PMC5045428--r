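#' Kaplan-Meier curve and fixed-time survival rates
#'
#' Product-limit estimate of the recurrence-free survival function via
#' [survival::survfit()]. `survival_at()` evaluates the right-continuous
#' step function at time `t` (so 3- and 5-year rates are read at exactly
#' t = 3, t = 5 with the post-jump value).
#'
#' @param time follow-up times, `>= 0`.
#' @param event event indicator, 0/1.
#' @return `kaplan_meier`: object of class `km_curve` with `time`, `surv`,
#'   `n_risk`, `n_event` and the underlying `survfit`.
#' @examples
#' km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' survival_at(km, 2.5)  # 0.5
#' @export
kaplan_meier <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up times", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, fit = fit),
            class = "km_curve")
}

#' @rdname kaplan_meier
#' @param curve a `km_curve`.
#' @param t time point(s) at which to read the survival rate.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(tt) {
    if (tt < 0) stop("t must be >= 0", call. = FALSE)
    idx <- which(curve$time <= tt)
    if (!length(idx)) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve\n")
  print(x$fit)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$fit, xlab = "years", ylab = "recurrence-free survival", ...)
  invisible(x)
}

#' Two-sided log-rank test between survival groups
#'
#' Standard log-rank chi-square ([survival::survdiff()], hypergeometric
#' variance, no continuity correction) with `df = groups - 1`; the p-value is
#' the upper chi-square tail. Invariant under monotone rescaling of the time
#' axis.
#'
#' @param groups group labels (>= 2 non-empty groups).
#' @param time,event survival outcome aligned with `groups`.
#' @return list `statistic`, `df`, `p_value`, `n` (per-group sizes).
#' @export
log_rank <- function(groups, time, event) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("log-rank needs >= 2 groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = table(groups))
}

# Left-continuous Kaplan-Meier estimate of the censoring survival G(t-),
# used for inverse-probability-of-censoring weights.
censoring_survival <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t, minus = FALSE) {
    vapply(t, function(tt) {
      idx <- if (minus) which(fit$time < tt) else which(fit$time <= tt)
      if (!length(idx)) 1 else fit$surv[max(idx)]
    }, numeric(1))
  }
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC for predicting event occurrence by
#' the horizon: cases are patients with an observed event at or before the
#' horizon, controls are patients still event-free beyond it. Censoring is
#' handled by inverse-probability-of-censoring weights derived from the
#' Kaplan-Meier estimate of the censoring distribution (cases weighted by
#' `1/G(T-)`, controls by `1/G(horizon)`), which makes the weighted
#' sensitivity/specificity staircase monotone and reduces exactly to the
#' plain binary ROC when no censoring occurs before the horizon. The AUC is
#' the area under the staircase (equivalently the weighted rank statistic
#' with tied scores counted 0.5).
#'
#' @param scores risk scores, higher = higher predicted risk.
#' @param time,event survival outcome aligned with `scores`.
#' @param horizon evaluation time in years (default 5).
#' @return object of class `time_roc`: `horizon`, `auc`, and `curve` (data
#'   frame `threshold`, `sensitivity`, `specificity`).
#' @export
time_dependent_roc <- function(scores, time, event, horizon = 5) {
  check_scalar(horizon, "horizon", lower = 0, strict = TRUE, upper = Inf)
  stopifnot(length(scores) == length(time), length(time) == length(event))
  case <- time <= horizon & event == 1
  control <- time > horizon
  if (!any(case) || !any(control)) {
    stop("need at least one case and one control at the horizon", call. = FALSE)
  }
  G <- censoring_survival(time, event)
  w <- numeric(length(scores))
  w[case] <- 1 / G(time[case], minus = TRUE)
  w[control] <- 1 / G(horizon)
  if (any(!is.finite(w[case | control]))) {
    stop("censoring weights are unstable at the horizon (G = 0)", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(c) {
    sum(w[case & scores >= c]) / sum(w[case])
  }, numeric(1))
  spec <- vapply(thr, function(c) {
    sum(w[control & scores < c]) / sum(w[control])
  }, numeric(1))
  # weighted rank AUC over case/control pairs, ties 0.5
  sc <- scores[case]; wc <- w[case]
  sk <- scores[control]; wk <- w[control]
  gt <- outer(sc, sk, ">"); eq <- outer(sc, sk, "==")
  ww <- outer(wc, wk)
  auc <- sum(ww * (gt + 0.5 * eq)) / sum(ww)
  structure(list(horizon = horizon, auc = auc,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "time_roc")
}

#' @export
print.time_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at %g years: AUC = %.3f\n", x$horizon, x$auc))
  invisible(x)
}

#' @export
plot.time_roc <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Harrell's concordance index
#'
#' The probability that, of a usable patient pair, the patient with the
#' higher risk score experiences the event earlier. A pair is usable when
#' the ordering of the event times is determinable: the earlier time is an
#' observed event and the times differ (both-censored pairs, pairs censored
#' before the other's event, and tied-time pairs are excluded from the
#' denominator). Tied scores count 0.5. C = 0.5 is chance, C = 1 perfect
#' discrimination.
#'
#' @param scores risk scores, higher = higher predicted risk.
#' @param time,event survival outcome aligned with `scores`.
#' @return list `c_index`, `usable_pairs`.
#' @examples
#' harrell_c(scores = 4:1, time = 1:4, event = rep(1, 4))  # c_index = 1
#' @export
harrell_c <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  earlier <- outer(time, time, "<")           # [i, j]: t_i < t_j
  has_event <- matrix(event == 1, n, n)       # event of the row patient
  usable <- which(earlier & has_event)        # i earlier with event
  if (!length(usable)) stop("no usable pairs", call. = FALSE)
  i <- ((usable - 1L) %% n) + 1L
  j <- ((usable - 1L) %/% n) + 1L
  conc <- sum(scores[i] > scores[j]) + 0.5 * sum(scores[i] == scores[j])
  list(c_index = conc / length(usable), usable_pairs = length(usable))
}

#' Per-stratum log-rank tests
#'
#' Runs [log_rank()] of `groups` within each level of a stratification
#' variable (e.g. age band or tumor stage). Strata smaller than `min_n`, or
#' in which only one group level is present, are reported as skipped with a
#' reason rather than tested -- mirroring the usual exclusion of tiny strata
#' from stratified analyses.
#'
#' @param strata stratum labels, one per patient.
#' @param groups group labels (e.g. "high-risk"/"low-risk").
#' @param time,event survival outcome.
#' @param min_n minimum stratum size to test (default 10).
#' @return data frame `stratum`, `n`, `statistic`, `df`, `p_value`,
#'   `skipped`, `reason`.
#' @export
stratified_logrank_by <- function(strata, groups, time, event, min_n = 10) {
  stopifnot(length(strata) == length(groups))
  out <- lapply(unique(as.character(strata)), function(s) {
    idx <- which(as.character(strata) == s)
    base <- data.frame(stratum = s, n = length(idx), statistic = NA_real_,
                       df = NA_integer_, p_value = NA_real_, skipped = TRUE,
                       reason = "", stringsAsFactors = FALSE)
    if (length(idx) < min_n) {
      base$reason <- sprintf("stratum size %d below minimum %d", length(idx), min_n)
      return(base)
    }
    if (length(unique(groups[idx])) < 2) {
      base$reason <- "only one group present in stratum"
      return(base)
    }
    lr <- log_rank(groups[idx], time[idx], event[idx])
    base$statistic <- lr$statistic
    base$df <- lr$df
    base$p_value <- lr$p_value
    base$skipped <- FALSE
    base
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
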