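# Independent straight-line oracles used to check the vectorized
# implementations. Deliberately written with explicit loops and the textbook
# formulas, sharing no code with R/.

make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

make_annotation <- function(n, rfs_time = rep(1, n), event = rep(1, n),
                            relapse = rep(0L, n), age = rep(60, n),
                            gender = rep("F", n), stage = rep("I", n),
                            smoking = rep("never", n),
                            vital_status = NULL) {
  if (is.null(vital_status)) vital_status <- ifelse(event == 1, "Dead", "Alive")
  data.frame(sample_id = sprintf("s%04d", seq_len(n)), relapse = relapse,
             rfs_time = rfs_time, event = event, age = age, gender = gender,
             stage = stage, smoking = smoking, vital_status = vital_status,
             stringsAsFactors = FALSE)
}

# Signal-to-noise by direct per-gene arithmetic.
oracle_s2n <- function(x, relapse) {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    a <- x[i, relapse]; b <- x[i, !relapse]
    out[i] <- (mean(a) - mean(b)) / (sd(a) + sd(b))
  }
  names(out) <- rownames(x)
  out
}

# Weighted-voting cross-validation by brute-force loops over the supplied
# fold partitions (the straight-line transcription of the algorithm: rank by
# |S| on the training folds, vote on the held-out fold, count errors per N).
oracle_cv_errors <- function(x, relapse, partitions) {
  n_genes <- nrow(x)
  errors <- numeric(n_genes)
  for (part in partitions) {
    for (f in sort(unique(part))) {
      tr <- which(part != f); te <- which(part == f)
      s <- numeric(n_genes); b <- numeric(n_genes)
      for (i in seq_len(n_genes)) {
        a1 <- x[i, intersect(tr, which(relapse))]
        a0 <- x[i, intersect(tr, which(!relapse))]
        s[i] <- (mean(a1) - mean(a0)) / (sd(a1) + sd(a0))
        b[i] <- (mean(a1) + mean(a0)) / 2
      }
      ord <- order(-abs(s), rownames(x))
      for (N in seq_len(n_genes)) {
        top <- ord[seq_len(N)]
        for (j in te) {
          total <- 0
          for (i in top) total <- total + s[i] * (x[i, j] - b[i])
          pred <- total > 0
          if (pred != relapse[j]) errors[N] <- errors[N] + 1
        }
      }
    }
  }
  errors
}

# Harrell's C by explicit enumeration of all unordered pairs.
oracle_harrell_c <- function(scores, time, event) {
  conc <- 0; usable <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- i; b <- j
      if (time[b] < time[a]) { a <- j; b <- i }
      if (time[a] == time[b] || event[a] != 1) next
      usable <- usable + 1
      if (scores[a] > scores[b]) conc <- conc + 1
      else if (scores[a] == scores[b]) conc <- conc + 0.5
    }
  }
  conc / usable
}

# Binary ROC AUC over all case/control pairs.
oracle_auc <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Cox partial log-likelihood for a single covariate, Breslow form (valid for
# untied event times); maximized by grid refinement, independent of coxph.
oracle_cox1 <- function(time, event, x, lower = -5, upper = 5) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[rs])))
    }
    ll
  }
  grid <- seq(lower, upper, length.out = 401)
  for (k in 1:4) {
    vals <- vapply(grid, loglik, numeric(1))
    best <- grid[which.max(vals)]
    span <- (grid[2] - grid[1]) * 2
    grid <- seq(best - span, best + span, length.out = 401)
  }
  best
}

# Product-limit estimator by the textbook running product.
oracle_km_at <- function(time, event, t) {
  s <- 1
  for (tt in sort(unique(time[event == 1 & time <= t]))) {
    d <- sum(time == tt & event == 1)
    n_risk <- sum(time >= tt)
    s <- s * (1 - d / n_risk)
  }
  s
}
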