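test_that("hr_from_coef is exp() with a Wald interval", {
  expect_equal(hr_from_coef(0)$hr, 1)
  out <- hr_from_coef(c(1.058, -0.783), c(0.2, 0.1))
  expect_equal(out$hr, exp(c(1.058, -0.783)))
  expect_equal(out$ci_lower, exp(c(1.058, -0.783) - 1.96 * c(0.2, 0.1)))
  # identity on positive reals: hr_from_coef(log(h)) == h
  h <- c(0.25, 1, 3.7)
  expect_equal(hr_from_coef(log(h))$hr, h)
  expect_error(hr_from_coef(1, -0.1), "se")
})

test_that("fit_cox maximizes the partial likelihood (grid-search oracle)", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  x <- c(1, 0, 1, 0, 0, 1)
  fit <- fit_cox(time, event, data.frame(x = x))
  expect_equal(fit$coef, oracle_cox1(time, event, x), tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$coef))
  expect_true(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper)
  expect_error(fit_cox(c(-1, 2), c(1, 0), data.frame(x = 1:2)), "negative")
  expect_error(fit_cox(c(1, 2), c(0, 0), data.frame(x = 1:2)), "events")
})

test_that("fit_cox recovers a null coefficient", {
  coh <- simulate_cohort(sim_config(n_patients = 500, n_genes = 3,
                                    n_informative = 1, beta_link = 0,
                                    baseline_hazard = 0.2, seed = 23))
  fit <- fit_cox(coh$annotation$rfs_time, coh$annotation$event,
                 data.frame(g = coh$expression[1, ]))
  expect_lt(abs(fit$coef) / fit$se, 2.5)
})

test_that("univariate_cox gives one fit per gene", {
  coh <- simulate_cohort(sim_config(n_patients = 100, n_genes = 4,
                                    n_informative = 2, seed = 24))
  tab <- univariate_cox(coh$expression, coh$annotation$rfs_time,
                        coh$annotation$event)
  expect_equal(tab$term, rownames(coh$expression))
  g1 <- fit_cox(coh$annotation$rfs_time, coh$annotation$event,
                data.frame(x = coh$expression[1, ]))
  expect_equal(tab$coef[1], g1$coef)
})

test_that("risk_score is the dot product and is linear", {
  w <- c(gA = -1.049, gB = 0.93, gC = 0.015)
  x0 <- make_expr(matrix(0, 3, 2), genes = names(w))
  expect_equal(unname(risk_score(w, x0)), c(0, 0))
  # unit expression on one gene returns its weight
  e1 <- c(gA = 0, gB = 1, gC = 0)
  expect_equal(unname(risk_score(w, e1)), 0.93)
  # brute-force dot product, order independence, linearity
  set.seed(16)
  xr <- make_expr(matrix(rnorm(12), 3, 4), genes = names(w))
  expect_equal(unname(risk_score(w, xr)),
               as.vector(t(xr[names(w), ]) %*% w))
  expect_equal(risk_score(w, xr), risk_score(w[c(2, 3, 1)], xr))
  y <- make_expr(matrix(rnorm(12), 3, 4), genes = names(w))
  expect_equal(risk_score(w, xr + y), risk_score(w, xr) + risk_score(w, y))
  expect_error(risk_score(w, xr[1:2, ]), "gC")
})

test_that("fit_risk_model freezes the discovery-median cutoff", {
  coh <- simulate_cohort(sim_config(n_patients = 101, n_genes = 30, seed = 25))
  z <- zscore_standardize(coh$expression)
  ann <- coh$annotation
  rm1 <- fit_risk_model(z, ann$rfs_time, ann$event, coh$truth$informative[1:3])
  # single-gene signature: weight equals the univariate coefficient
  rm_single <- fit_risk_model(z, ann$rfs_time, ann$event, "g0001")
  uni <- fit_cox(ann$rfs_time, ann$event, data.frame(g = z["g0001", ]))
  expect_equal(unname(rm_single$weights), uni$coef)

  # odd cohort: cutoff is the middle score; even: mean of the middle two
  expect_equal(rm1$cutoff, unname(sort(rm1$discovery_scores))[51])
  z_even <- z[, 1:100]
  rm_even <- fit_risk_model(z_even, ann$rfs_time[1:100], ann$event[1:100],
                            coh$truth$informative[1:3])
  ss <- sort(rm_even$discovery_scores)
  expect_equal(rm_even$cutoff, mean(ss[50:51]))

  # frozen-cutoff contract: prediction on new data leaves the cutoff bit-identical
  cutoff_before <- rm1$cutoff
  new <- zscore_standardize(make_expr(matrix(rnorm(30 * 10), 30, 10),
                                      genes = rownames(z)))
  invisible(predict(rm1, new))
  expect_identical(rm1$cutoff, cutoff_before)
  expect_error(fit_risk_model(z, ann$rfs_time, ann$event, "missing_gene"),
               "missing_gene")
})

test_that("group assignment uses score > cutoff with equality low-risk", {
  w <- c(g1 = 1)
  model <- structure(list(weights = w, cutoff = 0.5,
                          standardization = "zscore-per-sample"),
                     class = "risk_model")
  x <- make_expr(matrix(c(0.5, 0.5000001, 0.2), 1, 3), genes = "g1")
  out <- suppressWarnings(predict(model, x))
  expect_equal(out$group, c("low-risk", "high-risk", "low-risk"))
  expect_equal(assign_groups(model, x)$score, out$score)

  # adding +c to one gene moves every score by exactly c * w_i
  coh <- simulate_cohort(sim_config(n_patients = 40, n_genes = 10, seed = 26))
  z <- zscore_standardize(coh$expression)
  rm2 <- fit_risk_model(z, coh$annotation$rfs_time, coh$annotation$event,
                        c("g0001", "g0002"))
  z2 <- z; z2["g0002", ] <- z2["g0002", ] + 3
  expect_equal(suppressWarnings(predict(rm2, z2))$score,
               predict(rm2, z)$score + 3 * rm2$weights[["g0002"]])

  # splitting discovery at its own median balances groups within 1
  groups <- predict(rm2, z)$group
  expect_lte(abs(diff(unname(table(groups)))), 1)
})

test_that("multivariable adjustment reproduces coxph contrasts and stage reference", {
  coh <- simulate_cohort(sim_config(n_patients = 200, n_genes = 20, seed = 27))
  z <- zscore_standardize(coh$expression)
  rm3 <- fit_risk_model(z, coh$annotation$rfs_time, coh$annotation$event,
                        coh$truth$informative[1:2])
  grp <- predict(rm3, z)$group
  tab <- multivariable_adjustment(coh$annotation, grp)
  expect_true(all(c("signature", "age", "gender", "stage", "smoking")
                  %in% tab$variable))
  expect_equal(tab$contrast[tab$variable == "signature"],
               "High risk vs. Low risk")
  # null covariates hover near HR 1
  expect_true(all(abs(log(tab$hr_uni[tab$variable %in%
                                       c("gender", "smoking")])) < 1))

  # multi-level stage gets an explicit reference row
  ann4 <- coh$annotation
  ann4$stage <- sample(c("I", "II", "III"), nrow(ann4), replace = TRUE)
  tab4 <- multivariable_adjustment(ann4, grp)
  ref <- tab4[tab4$contrast == "I (reference)", ]
  expect_equal(nrow(ref), 1)
  expect_equal(ref$hr_uni, 1)
  expect_equal(ref$hr_multi, 1)
})

test_that("adjustment attenuates a confounded signature effect (2-covariate oracle)", {
  set.seed(28)
  n <- 300
  stage2 <- rbinom(n, 1, 0.3)
  score <- rnorm(n, mean = stage2)           # score correlated with stage
  lp <- 1.2 * stage2 + 0.5 * score
  time <- rexp(n, 0.1 * exp(lp))
  event <- as.integer(time < 8); time <- pmin(time, 8)
  ann <- make_annotation(n, rfs_time = time, event = event,
                         stage = ifelse(stage2 == 1, "II", "I"))
  grp <- ifelse(score > median(score), "high-risk", "low-risk")
  tab <- multivariable_adjustment(ann, grp)
  hr_uni <- tab$hr_uni[tab$variable == "signature"]
  hr_multi <- tab$hr_multi[tab$variable == "signature"]
  expect_lt(hr_multi, hr_uni)  # adjustment removes the stage confounding
  # oracle: hand-coded 2-covariate partial likelihood maximized by optim
  xs <- cbind(sig = as.numeric(grp == "high-risk"), st = stage2)
  nll <- function(beta) {
    lp2 <- as.vector(xs %*% beta)
    -sum(vapply(which(event == 1), function(i) {
      lp2[i] - log(sum(exp(lp2[time >= time[i]])))
    }, numeric(1)))
  }
  beta_hat <- optim(c(0, 0), nll, method = "BFGS")$par
  fit2 <- fit_cox(time, event, data.frame(sig = xs[, 1], st = xs[, 2]))
  expect_equal(fit2$coef, beta_hat, tolerance = 1e-3)
})
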