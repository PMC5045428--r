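Package: lncsig
Title: Relapse-Related lncRNA Signatures by Weighted Voting and Cox Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of tumor-relapse expression signatures
    from lncRNA (or any gene-level) expression matrices, following the
    microarray-era supervised workflow: per-array Z-score standardization and
    probe-to-gene collapsing, Bonferroni-screened two-sample t-tests between
    relapse and relapse-free patients, a signal-to-noise weighted-voting
    classifier whose model size is chosen by repeated stratified 5-fold
    cross-validation with frequency-based gene selection, a Cox-coefficient
    weighted risk score dichotomized at the discovery-median cutoff, and a
    survival evaluation suite (Kaplan-Meier rates, log-rank tests,
    time-dependent ROC at a fixed horizon, Harrell's concordance index,
    stratified analyses). Includes a synthetic cohort generator with known
    informative genes and proportional-hazards survival so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
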