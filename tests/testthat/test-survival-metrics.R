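test_that("Kaplan-Meier matches the hand product-limit estimate", {
  # no censoring, events at 1..4: S(2.5) = 0.5
  km <- kaplan_meier(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(survival_at(km, 2.5), 0.5)
  # all censored: S(t) = 1 everywhere
  km_c <- kaplan_meier(c(1, 2, 3), rep(0, 3))
  expect_equal(survival_at(km_c, c(0, 2, 10)), c(1, 1, 1))
  # mixed fixture: events at 1 and 3, censored at 2 (n = 4 with a late censor)
  time <- c(1, 2, 3, 6); event <- c(1, 0, 1, 0)
  km_m <- kaplan_meier(time, event)
  expect_equal(survival_at(km_m, 1), 3 / 4)
  expect_equal(survival_at(km_m, 4), (3 / 4) * (1 / 2))
  expect_equal(survival_at(km_m, 4), oracle_km_at(time, event, 4))
  # right-continuity: the value at an event time is the post-jump value
  expect_equal(survival_at(km, 1), 0.75)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(18)
  t0 <- rexp(60, 0.3)
  km <- kaplan_meier(t0, rep(1, 60))
  for (tt in quantile(t0, c(0.2, 0.5, 0.9))) {
    expect_equal(survival_at(km, tt), mean(t0 > tt))
  }
})

test_that("log-rank separates distinct hazards and is invariant to time units", {
  # identical groups: statistic 0, p = 1
  t0 <- c(1, 2, 3, 4, 5); e0 <- c(1, 1, 0, 1, 0)
  lr0 <- log_rank(rep(c("a", "b"), each = 5), c(t0, t0), c(e0, e0))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # exponential groups with hazard ratio 10, n = 100/arm
  set.seed(19)
  t1 <- c(rexp(100, 1), rexp(100, 0.1))
  grp <- rep(c("hi", "lo"), each = 100)
  lr1 <- log_rank(grp, t1, rep(1, 200))
  expect_lt(lr1$p_value, 1e-6)
  expect_equal(lr1$df, 1)
  # years -> months rescaling leaves the statistic unchanged
  lr_m <- log_rank(grp, t1 * 12, rep(1, 200))
  expect_equal(lr1$statistic, lr_m$statistic)
  expect_error(log_rank(rep("a", 5), t0, e0), "2 groups")
})

test_that("time-dependent ROC behaves at its analytic endpoints", {
  set.seed(20)
  t0 <- rexp(80, 0.3)
  # score = -(event time), no censoring: perfect ranking, AUC = 1
  roc <- time_dependent_roc(-t0, t0, rep(1, 80), horizon = 2)
  expect_equal(roc$auc, 1)
  # score independent of outcome: AUC ~ 0.5
  coh <- simulate_cohort(sim_config(n_patients = 400, n_genes = 5,
                                    n_informative = 0, beta_link = numeric(0),
                                    baseline_hazard = 0.2, seed = 29))
  roc0 <- time_dependent_roc(rnorm(400), coh$annotation$rfs_time,
                             coh$annotation$event, horizon = 5)
  expect_lt(abs(roc0$auc - 0.5), 0.06)
  expect_error(time_dependent_roc(1:3, c(1, 2, 3), c(0, 0, 0), horizon = 5),
               "case")
})

test_that("without censoring before the horizon the AUC is the binary AUC", {
  set.seed(21)
  n <- 70
  time <- rexp(n, 0.25)
  score <- -time + rnorm(n)
  roc <- time_dependent_roc(score, time, rep(1, n), horizon = 3)
  expect_equal(roc$auc, oracle_auc(score, time <= 3))
  # the weighted staircase is monotone
  expect_true(all(diff(roc$curve$sensitivity) >= -1e-12))
  expect_true(all(diff(roc$curve$specificity) <= 1e-12))
  # affine transformation of the score leaves the AUC unchanged
  roc2 <- time_dependent_roc(2.5 * score + 7, time, rep(1, n), horizon = 3)
  expect_equal(roc2$auc, roc$auc)
})

test_that("Harrell's C matches pair enumeration and its endpoints", {
  # perfectly anti-ranked scores on uncensored times: C = 1
  expect_equal(harrell_c(50:1, 1:50, rep(1, 50))$c_index, 1)
  # 3 uncensored patients with one discordant pair of three: C = 2/3
  expect_equal(harrell_c(c(3, 1, 2), c(1, 2, 3), c(1, 1, 1))$c_index, 2 / 3)
  # reversal: 1 - C when scores have no ties
  set.seed(22)
  time <- rexp(40); event <- rbinom(40, 1, 0.7); sc <- rnorm(40)
  c1 <- harrell_c(sc, time, event)$c_index
  expect_equal(harrell_c(-sc, time, event)$c_index, 1 - c1)
  # enumeration oracle, with censoring and tied scores
  sc_t <- round(rnorm(40), 1)
  expect_equal(harrell_c(sc_t, time, event)$c_index,
               oracle_harrell_c(sc_t, time, event))
  # agreement with the survival package on tie-free data
  conc <- survival::concordance(survival::Surv(time, event) ~ sc, reverse = TRUE)
  expect_equal(c1, unname(conc$concordance))
  expect_error(harrell_c(1:3, c(5, 5, 5), c(1, 1, 1)), "usable")
})

test_that("stratified log-rank tests within strata and skips degenerate ones", {
  set.seed(23)
  n <- 120
  strata <- rep(c("young", "old"), each = n / 2)
  grp <- rep(c("high-risk", "low-risk"), times = n / 2)
  lp <- ifelse(grp == "high-risk", 1.5, 0)
  time <- rexp(n, 0.2 * exp(lp)); event <- rep(1, n)
  res <- stratified_logrank_by(strata, grp, time, event)
  expect_equal(sort(res$stratum), c("old", "young"))
  expect_true(all(!res$skipped))
  expect_true(all(res$p_value < 0.05))
  # direct within-stratum oracle
  young <- strata == "young"
  expect_equal(res$p_value[res$stratum == "young"],
               log_rank(grp[young], time[young], event[young])$p_value)

  # a stratum identical to the grouping variable is skipped (single group)
  res2 <- stratified_logrank_by(grp, grp, time, event)
  expect_true(all(res2$skipped))
  expect_match(res2$reason[1], "one group")
  # undersized strata are listed as skipped
  strata3 <- c(rep("big", n - 4), rep("tiny", 4))
  res3 <- stratified_logrank_by(strata3, grp, time, event)
  expect_true(res3$skipped[res3$stratum == "tiny"])
  expect_match(res3$reason[res3$stratum == "tiny"], "below minimum")
})
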