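test_that("simulation is deterministic given seed and validates its config", {
  cfg <- sim_config(n_patients = 40, n_genes = 30, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(sim_config(n_patients = 40, n_genes = 30, seed = 124))
  expect_false(identical(a$expression, c2$expression))

  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(relapse_fraction = 1), "relapse_fraction")
  expect_error(sim_config(n_genes = 5, n_informative = 9), "n_informative")
  expect_error(sim_config(beta_link = c(1, 2)), "beta_link")
})

test_that("cohort structure honors its invariants", {
  coh <- simulate_cohort(sim_config(n_patients = 60, n_genes = 40, seed = 2))
  expect_identical(colnames(coh$expression), coh$annotation$sample_id)
  expect_true(all(coh$truth$informative %in% rownames(coh$expression)))
  expect_true(all(coh$annotation$rfs_time >= 0))
  expect_true(all(coh$annotation$rfs_time <= coh$config$censor_horizon))
  expect_true(all(coh$annotation$event %in% 0:1))
})

test_that("a null cohort (effect_size = 0, beta_link = 0) carries no signal", {
  cfg <- sim_config(n_patients = 100, n_genes = 1000, n_informative = 9,
                    effect_size = 0, beta_link = rep(0, 9), seed = 31)
  coh <- simulate_cohort(cfg)
  de <- differential_expression(coh$expression, coh$annotation$relapse)
  # type-I error calibration at the nominal level
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.02)
  # family-wise control: no Bonferroni hits
  expect_equal(sum(de$significant), 0)
  # any gene-based score is unrelated to survival
  sc <- coh$expression[1, ]
  cc <- harrell_c(sc, coh$annotation$rfs_time, coh$annotation$event)
  expect_lt(abs(cc$c_index - 0.5), 0.1)
})

test_that("informative genes occupy the top |S| ranks at strong effect", {
  cfg <- sim_config(n_patients = 200, n_genes = 100, n_informative = 9,
                    effect_size = 2, within_class_sd = 1, seed = 77)
  coh <- simulate_cohort(cfg)
  s <- signal_to_noise(coh$expression, coh$annotation$relapse)
  # oracle: recompute S by the direct formula and sort
  s_oracle <- oracle_s2n(coh$expression, coh$annotation$relapse == 1)
  expect_equal(s, s_oracle)
  top9 <- names(sort(abs(s), decreasing = TRUE))[1:9]
  expect_setequal(top9, coh$truth$informative)
})

test_that("realized event fraction does not decrease with baseline hazard", {
  fracs <- vapply(c(0.02, 0.08, 0.3, 1), function(h) {
    coh <- simulate_cohort(sim_config(n_patients = 150, n_genes = 10,
                                      n_informative = 2, beta_link = c(0.2, 0.2),
                                      baseline_hazard = h, seed = 55))
    mean(coh$annotation$event)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("univariate Cox recovers a known beta on a single informative gene", {
  cfg <- sim_config(n_patients = 500, n_genes = 5, n_informative = 1,
                    effect_size = 0, beta_link = 0.8, baseline_hazard = 0.2,
                    seed = 999)
  coh <- simulate_cohort(cfg)
  fit <- fit_cox(coh$annotation$rfs_time, coh$annotation$event,
                 data.frame(g = coh$expression[coh$truth$informative, ]))
  expect_true(fit$coef - 1.96 * fit$se < 0.8 && 0.8 < fit$coef + 1.96 * fit$se)
})

test_that("probe-level simulation collapses back to the gene matrix", {
  # jitter 0: collapsing reproduces the gene matrix exactly, any probe count
  for (k in c(1, 3)) {
    cfg <- sim_config(n_patients = 15, n_genes = 8, n_informative = 3,
                      probes_per_gene = k, probe_jitter_sd = 0, seed = 10)
    pl <- simulate_probe_level(cfg)
    expect_equal(nrow(pl$probes), 8 * k)
    expect_setequal(pl$map$probe_id, rownames(pl$probes))
    expect_equal(anyDuplicated(pl$map$probe_id), 0L)
    collapsed <- collapse_probes(pl$probes, pl$map)
    genes <- rownames(pl$cohort$expression)
    expect_equal(collapsed[sort(genes), ],
                 pl$cohort$expression[sort(genes), ])
  }
  # with duplicated probes (jitter 0) standardizing before or after collapse
  # differs only by the n-1 duplication factor of the per-array SD
  cfg0 <- sim_config(n_patients = 12, n_genes = 20, n_informative = 3,
                     probes_per_gene = 3, probe_jitter_sd = 0, seed = 13)
  pl0 <- simulate_probe_level(cfg0)
  a <- zscore_standardize(collapse_probes(pl0$probes, pl0$map))
  b <- collapse_probes(zscore_standardize(pl0$probes), pl0$map)
  k <- 3; n <- 20
  expect_equal(b, a * sqrt((k * n - 1) / (k * (n - 1))))

  # jitter > 0: collapsed value is the hand mean of the generated probe rows
  cfg <- sim_config(n_patients = 6, n_genes = 4, n_informative = 2,
                    probes_per_gene = 2, probe_jitter_sd = 0.1, seed = 11)
  pl <- simulate_probe_level(cfg)
  g1_probes <- pl$map$probe_id[pl$map$gene_id == "g0001"]
  hand <- (pl$probes[g1_probes[1], ] + pl$probes[g1_probes[2], ]) / 2
  expect_equal(collapse_probes(pl$probes, pl$map)["g0001", ], hand)
})

test_that("write_cohort emits readable TSVs with the seed recorded", {
  coh <- simulate_cohort(sim_config(n_patients = 10, n_genes = 6,
                                    n_informative = 2, seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_equal(read_expression_table(paths[["expression"]]), coh$expression)
  expect_equal(read_clinical_table(paths[["clinical"]]), coh$annotation)
  expect_true(any(grepl("^seed=21$", readLines(paths[["config"]]))))
})
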