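---
title: "Relapse-signature discovery: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relapse-signature discovery: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsig)
```

This vignette is the package's account of its statistics: the models it
fits, the conventions it adopts where the underlying methodology leaves
room, and what its synthetic test bed does and does not demonstrate.

## The analysis model

The workflow assumes a two-class cohort — patients who relapse after
resection and patients who stay relapse-free — observed through a
genes × samples expression matrix and recurrence-free survival (RFS)
follow-up. RFS is the composite time to recurrence or death from any cause;
a patient contributes an event at recurrence/death and is censored at last
follow-up otherwise. Three models are fitted in sequence:

* a **differential screen**: per-gene two-sample t-tests with Bonferroni
  family-wise control, which cuts the feature space to the genes that
  plausibly separate the classes;
* the **weighted-voting classifier**: per-gene signal-to-noise weights
  `S = (μ₁ − μ₀)/(σ₁ + σ₀)` and boundaries `b = (μ₁ + μ₀)/2`, votes
  `V = S·(e − b)` summed over the top-N genes. N is chosen by repeated
  stratified cross-validation; the final gene set is picked by frequency
  across training folds, which rewards genes whose ranking is stable under
  resampling rather than merely good on the full data;
* the **Cox risk score**: the selected genes fitted jointly in a
  proportional-hazards model of RFS, the coefficients reused as linear
  weights, patients dichotomized at the median discovery score. The cutoff
  is part of the fitted model and is frozen: external validation scores new
  patients and compares against it without any refitting.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.01 | adjusted p | strict family-wise screen; microarray-era convention for headline gene lists |
| `folds` | 5 | — | balance between training-set size and fold variance; cheaper than leave-one-out at equal stability |
| `repeats` | 100 | — | smooths the error curve to fractional-patient resolution (error granularity 1/100) |
| `opt_tolerance` | 1 | misclassified patients | the parsimony margin: an extra gene must buy at least one expected patient to justify itself |
| `horizon` | 5 | years | the clinical landmark for favorable/fatal selection and the time-dependent ROC |
| `min_n` (stratified log-rank) | 10 | patients | strata smaller than this are reported as skipped, not tested |
| `fraction` (co-expression) | 0.01 | — | top-percentile partner selection per signature gene |

## Numerical conventions

Where the methodology is silent the package fixes a convention, documents
it, and (where reasonable) exposes the alternative behind a flag:

* **Z-score axis**: each array (sample column) is centered and scaled over
  its probes — the harmonization view of standardization, appropriate when
  datasets from different batches must be made comparable. A per-gene
  margin exists (`margin = "gene"`) but is not the default. SDs use the
  n−1 denominator throughout.
* **Probe collapsing order**: collapse to gene level first, then
  standardize. With zero probe jitter the two orders agree up to a single
  constant per dataset (duplicated probe rows change only the n−1 SD
  denominator, a factor `sqrt((kn−1)/(k(n−1)))` for k probes over n genes;
  tested), so ranks, correlations and signal-to-noise orderings are
  unaffected; with real probe noise the residual difference is far below
  the screen's resolution.
* **t-test variant**: pooled-variance Student's t by default, Welch via
  `var_equal = FALSE`. A gene with zero variance in both classes and equal
  means gets `t = 0, p = 1`.
* **Signal-to-noise degeneracy**: `σ₁ + σ₀ = 0` would give an infinite S;
  an epsilon (1e-12) is added with a warning so that degenerate fixtures
  survive cross-validation instead of crashing it.
* **Ranking ties**: equal |S| breaks lexicographically by gene id;
  equal selection frequency breaks by mean ranking position, then id —
  every ranking the package emits is reproducible.
* **Vote tie**: a total vote of exactly 0 predicts relapse-free (the
  majority class in the intended cohorts) and is counted in a diagnostics
  attribute.
* **Fold stratification**: folds are stratified by class, with per-class
  remainders rotated so overall fold sizes still differ by at most one.
  Unstratified partitions are available (`stratify = FALSE`).
* **Optimal N**: smallest N whose average error is within `opt_tolerance`
  of the curve minimum. A flat curve yields N = 1.
* **Fold-ranking frequency**: "frequency" counts membership in the
  *top-OPN* of each training fold's ranking (500 rankings under the
  defaults), not position-weighted scores; the full rankings are kept on
  the `cv_voting` object so other summaries can be derived.
* **Cox ties**: Efron approximation — it matters for synthetic data with
  tied times and is the accepted default.
* **Risk-group boundary**: score strictly greater than the cutoff is
  high-risk; equality is low-risk.
* **Risk-score inputs**: Z-scored expression, the same convention as the
  rest of the pipeline; `predict()` warns when a matrix does not look
  column-standardized, because a frozen cutoff only transfers between
  datasets under a shared standardization.
* **Univariate vs multivariate weights**: the per-gene univariate Cox
  table (`univariate_cox()`) is reported for interpretation, but the risk
  score always uses the joint multivariate coefficients.
* **Time-dependent ROC**: cumulative-case/dynamic-control at the horizon
  with inverse-probability-of-censoring weights from the Kaplan–Meier
  estimate of the censoring distribution. This estimator is monotone by
  construction and reduces exactly to the binary ROC when no one is
  censored before the horizon. Incident/dynamic variants are out of scope.
* **Harrell's C**: usable pairs are those whose event order is
  determinable (earlier time an observed event, times distinct); tied
  scores count 0.5. Cross-checked against `survival::concordance()` on
  tie-free data.
* **KM rates**: 3-/5-year rates are the right-continuous step-function
  values at exactly t = 3, 5.
* **Chi-square (cluster vs class)**: uncorrected Pearson statistic by
  default; Yates' correction behind `correct = TRUE`.

## The synthetic cohort generator

The generator is the package's study design, not a tuning device. Each
patient draws a latent relapse class (`Bernoulli(relapse_fraction)`, default
33/121 ≈ 0.27). Informative genes are `Normal(±effect_size/2,
within_class_sd)` by class; the rest are class-independent noise. RFS is
exponential with rate `baseline_hazard · exp(Σ β·x)` over the informative
genes, censored by independent `Uniform(0, horizon)` dropout and
administratively at the horizon (default 10 years). Clinical covariates are
drawn from fixed marginals matching a stage-I-dominated resected
adenocarcinoma cohort (76.9% stage I, 76.9% age ≤ 65, 45.6% male, 48.8%
ever-smokers).

The recorded relapse label is the latent class. An alternative — defining
relapse as the observed event — is circular here, because expression is
generated conditional on class while events depend on expression; it would
also break the null case (with β ≠ 0, genes would associate with the event
label even at zero effect size). With the default parameters the point is
moot: the relapse class has a hazard several dozen times the relapse-free
class, so label and observed event agree for all but a few patients per
cohort, and the favorable/fatal selection rule behaves as in a real cohort.

Defaults: 121 patients, 200 genes, 9 informative, effect size 2 (in
within-class SD units), `β = 0.35` per informative gene, baseline hazard
0.08/year. Two hundred genes — rather than the thousands on a real array —
keeps every example and test desk-sized while leaving the multiplicity
correction non-trivial; the Bonferroni behavior at array scale is exercised
separately at m = 1000–2313 in the tests.

What the generator deliberately does **not** emulate: probe-level
background/normalization artifacts, batch effects, correlated gene blocks
(genes are independent given the class), heavy-tailed expression noise,
informative censoring, and competing risks. Consequently, passing tests
demonstrate the correctness and internal consistency of the algorithms —
not that the signature discovered on any real cohort is biologically right,
nor that real data satisfy the proportional-hazards or
independent-censoring assumptions.

## Evaluation conventions in the tests

Truth-recovery checks ask whether the frequency-based selection, told to
pick as many genes as were planted (nine), recovers at least eight — the
parsimony rule itself may legitimately settle on fewer genes when a
smaller model already classifies within tolerance, and several of the
bundled examples show exactly that. Cross-validation equivalence is checked
exactly against a brute-force reimplementation on cohorts of 8–12 samples;
Cox coverage uses 200 replicates of 500 patients; concordance calibration
uses a 2000-patient cohort. These sizes are the package's chosen balance
between statistical resolution and an example suite that runs in well under
a minute per file.

## Known limitations

* The discovery selection needs enough favorable *and* fatal patients;
  cohorts with short follow-up starve the discovery set, and
  `run_discovery()` refuses classes smaller than two.
* The weighted-voting model is axis-aligned and linear per gene; it cannot
  express interactions between signature genes.
* Cox fits with near-perfect group separation have monotone partial
  likelihoods; the package surfaces the `coxph` warning rather than
  regularizing (no penalized Cox in this version).
* The frequency-selection interpretation (top-OPN membership) is one of
  several defensible readings of ranking "frequency"; the retained
  rankings make other definitions computable downstream.
* No plotting fidelity is attempted beyond base-graphics diagnostics
  (`plot()` on the CV curve, KM curves via `survival`, ROC staircases).
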