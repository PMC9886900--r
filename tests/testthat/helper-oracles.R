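# Independent oracles, written as deliberately naive loops so they share no
# code path with the package implementations they check.

# value-weighted chi-square, straight from the O/E definition
oracle_chi2 <- function(X, y) {
  classes <- sort(unique(y))
  out <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    total <- 0
    for (s in seq_len(nrow(X))) total <- total + X[s, j]
    if (total == 0) { out[j] <- 0; next }
    score <- 0
    for (k in classes) {
      O <- 0; nk <- 0
      for (s in seq_len(nrow(X))) {
        if (y[s] == k) { O <- O + X[s, j]; nk <- nk + 1 }
      }
      E <- (nk / nrow(X)) * total
      score <- score + (O - E)^2 / E
    }
    out[j] <- score
  }
  out
}

# Mann-Whitney AUC by explicit pair counting
oracle_auc <- function(score, positive) {
  pos <- which(positive); neg <- which(!positive)
  wins <- 0
  for (i in pos) for (j in neg) {
    if (score[i] > score[j]) wins <- wins + 1
    else if (score[i] == score[j]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# tiny deterministic cohort used across files: 2 classes x 2 samples
make_toy_cohort <- function() {
  snv <- snv_records(
    sample_id = c("P1", "P1", "P1", "P2", "P3"),
    gene      = c("TP53", "TP53", "KRAS", "TP53", "BRCA1"),
    effect    = c("deleterious", "tolerated", "deleterious_low_conf",
                  "tolerated_low_conf", "deleterious"),
    strength  = c(0.5, 0.2, 0.4, 0.9, 0.1),
    impact    = c("high", "low", "moderate", "modifier", "high"))
  genes <- c("TP53", "KRAS", "BRCA1")
  cnv <- matrix(c(2L, 0L, -2L,
                  1L, -1L, 0L,
                  0L, 0L, 1L,
                  -2L, 2L, 0L), nrow = 3,
                dimnames = list(genes, c("P1", "P2", "P3", "P4")))
  cohort(snv, cnv,
         labels = c(P1 = 0L, P2 = 0L, P3 = 1L, P4 = 1L),
         class_names = c("typeA", "typeB"))
}

# one shared reference cohort for the statistical tests (the stated world:
# 3 classes x 50 samples, 500 genes, 10 planted genes/class, rates 0.6/0.05)
reference_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(sim_config(seed = 7))
    coh
  }
})

# one shared BFV context: key generation is deterministic and takes ~2 s,
# so every test file reuses the same keys
shared_he_ctx <- local({
  ctx <- NULL
  function() {
    if (is.null(ctx)) ctx <<- he_setup(fp_params(), seed = 42)
    ctx
  }
})
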