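test_that("per-class SNV frequency ranking counts multiple SNVs and unions per-class tops", {
  # class A: geneX 3 SNVs, geneY 1; class B: geneZ 2
  snv <- snv_records(
    sample_id = c("A1", "A1", "A2", "A1", "B1", "B2"),
    gene      = c("geneX", "geneX", "geneX", "geneY", "geneZ", "geneZ"),
    effect    = rep("deleterious", 6),
    strength  = rep(0.5, 6),
    impact    = rep("high", 6))
  cnv <- matrix(0L, 3, 4, dimnames = list(c("geneX", "geneY", "geneZ"),
                                          c("A1", "A2", "B1", "B2")))
  coh <- cohort(snv, cnv, labels = c(A1 = 0L, A2 = 0L, B1 = 1L, B2 = 1L),
                class_names = c("A", "B"))
  expect_equal(rank_genes_by_snv_frequency(coh, 1), c("geneX", "geneZ"))
  # top_k covering everything returns all mutated genes, class-major order
  expect_equal(rank_genes_by_snv_frequency(coh, 10),
               c("geneX", "geneY", "geneZ"))
  expect_error(rank_genes_by_snv_frequency(coh, 0), "at least 1")
})

test_that("frequency ranking union matches an independent recount on the synthetic cohort", {
  coh <- reference_cohort()
  top_k <- 25
  got <- rank_genes_by_snv_frequency(coh, top_k)
  # brute-force recount: tabulate per class with plain loops
  recount <- character(0)
  for (k in 0:(length(coh$class_names) - 1)) {
    members <- names(coh$labels)[coh$labels == k]
    counts <- c(table(coh$snv$gene[coh$snv$sample_id %in% members]))
    ord <- names(counts)[order(-counts, names(counts))]
    recount <- c(recount, head(ord, top_k))
  }
  expect_equal(got, unique(recount))
})

test_that("encoders reproduce the published code values", {
  coh <- make_toy_cohort()
  genes <- c("TP53", "KRAS", "BRCA1")

  pres <- encode_presence(coh, genes)
  expect_true(all(pres %in% c(0, 1)))
  expect_equal(pres["P1", "TP53"], 1)   # two SNVs still give presence 1
  expect_equal(pres["P4", "TP53"], 0)

  # effect codes [1.0, 0.75, 0.5, 0.25]; feature = sum of m * strength
  es <- encode_effect_strength(coh, genes)
  expect_equal(es["P1", "KRAS"], 0.75 * 0.4)           # m = 0.75, s = 0.4
  expect_equal(es["P1", "TP53"], 1.0 * 0.5 + 0.25 * 0.2)  # sum over SNVs
  expect_equal(es["P2", "TP53"], 0.5 * 0.9)
  expect_equal(es["P4", "TP53"], 0)

  # impact codes [1, 0.4, 0.7, 0.1]; sums; no mutation -> 0
  ic <- encode_impact_confidence(coh, genes)
  expect_equal(ic["P1", "KRAS"], 0.4)                  # one moderate SNV
  expect_equal(ic["P1", "TP53"], 1 + 0.1)              # high + low on one gene
  expect_equal(ic["P2", "BRCA1"], 0)

  # CNV affine map -2..2 -> 0..4
  cv <- encode_cnv(coh)
  expect_equal(cv["P1", "TP53"], 4)    # +2 -> 4
  expect_equal(cv["P3", "BRCA1"], 3)
  expect_equal(cv["P2", "TP53"], 3)
  expect_equal(cv["P1", "BRCA1"], 0)   # -2 -> 0
  expect_equal(cv["P3", "TP53"], 2)    #  0 -> 2 (midpoint)
  expect_true(all(cv %in% 0:4))

  # combined SNV value = effect*strength sum + impact sum
  comb <- encode_snv_combined(coh, genes)
  expect_equal(comb, es + ic, ignore_attr = TRUE)

  # presence matrix matches hand enumeration of the record table
  expect_equal(unname(pres[, "TP53"]), c(1, 1, 0, 0))
  expect_equal(unname(pres[, "BRCA1"]), c(0, 0, 1, 0))
})

test_that("every encoder output is nonnegative and finite", {
  coh <- reference_cohort()
  genes <- rank_genes_by_snv_frequency(coh, 100)
  for (fm in list(encode_presence(coh, genes),
                  encode_effect_strength(coh, genes),
                  encode_impact_confidence(coh, genes),
                  encode_snv_combined(coh, genes),
                  encode_cnv(coh))) {
    expect_true(all(is.finite(fm)))
    expect_true(all(fm >= 0))
  }
})

test_that("category-to-code maps are validated and bijective", {
  sch <- encoding_scheme()
  expect_equal(sort(unname(sch$effect_codes)), c(0.25, 0.5, 0.75, 1.0))
  expect_equal(sort(unname(sch$impact_codes)), c(0.1, 0.4, 0.7, 1.0))
  # each enum level maps to exactly one distinct code
  expect_equal(anyDuplicated(sch$effect_codes), 0)
  expect_equal(anyDuplicated(sch$impact_codes), 0)
  expect_error(encoding_scheme(effect_codes = c(deleterious = 1.5,
                                                deleterious_low_conf = 0.75,
                                                tolerated_low_conf = 0.5,
                                                tolerated = 0.25)),
               "\\(0, 1\\]")
})

test_that("concatenation tags origins and keeps sample order", {
  coh <- make_toy_cohort()
  snv_fm <- encode_effect_strength(coh, c("TP53", "KRAS"))
  cnv_fm <- encode_cnv(coh)
  both <- concatenate_features(snv_fm, cnv_fm)
  expect_equal(ncol(both), 2 + 3)
  # the same gene appears once per origin
  expect_true(all(c("TP53.snv", "TP53.cnv") %in% colnames(both)))
  # empty SNV block: output equals the CNV block
  empty <- snv_fm[, 0, drop = FALSE]
  attr(empty, "origin") <- character(0)
  alone <- concatenate_features(empty, cnv_fm)
  expect_equal(unname(alone), unname(cnv_fm))
  # mismatched samples rejected
  expect_error(concatenate_features(snv_fm[c(2, 1, 3, 4), ], cnv_fm),
               "sample order")
})

test_that("value-weighted chi-square matches its O/E definition exactly", {
  # constant feature across balanced classes scores 0
  X <- cbind(const = rep(2, 20), aligned = rep(c(1, 0), each = 10))
  y <- rep(c(0, 1), each = 10)
  sc <- chi_square_scores(X, y)
  expect_equal(unname(sc$score["const"]), 0)
  # fully aligned binary feature, 10+10 samples: O = (10, 0), E = (5, 5)
  # -> 25/5 + 25/5 = 10 (hand contingency arithmetic)
  expect_equal(unname(sc$score["aligned"]), 10)
  # permutation invariance
  perm <- sample(seq_along(y))
  sc2 <- chi_square_scores(X[perm, ], y[perm])
  expect_equal(sc2$score, sc$score)
  # all-zero column scores 0
  sc3 <- chi_square_scores(cbind(z = rep(0, 20)), y)
  expect_equal(unname(sc3$score), 0)
  # negative values rejected
  expect_error(chi_square_scores(cbind(x = c(-1, rep(1, 19))), y),
               "nonnegative")
})

test_that("chi-square equals the brute-force oracle on exhaustive small binary instances", {
  # every binary feature over 6 samples, 2 balanced classes: exact agreement
  y <- c(0, 0, 0, 1, 1, 1)
  combos <- as.matrix(expand.grid(rep(list(0:1), 6)))
  X <- t(combos)                      # 6 samples x 64 features
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  got <- chi_square_scores(X, y)$score
  expect_equal(unname(got), oracle_chi2(X, y), tolerance = 1e-14)
  # and on random valued (non-binary) instances
  set.seed(21)
  Xr <- matrix(rpois(8 * 30, 3) * runif(8 * 30), 8, 30)
  yr <- c(0, 0, 0, 1, 1, 2, 2, 2)
  expect_equal(unname(chi_square_scores(Xr, yr)$score), oracle_chi2(Xr, yr),
               tolerance = 1e-12)
})

test_that("mutual information and F-score behave as estimators should", {
  set.seed(4)
  y <- rep(c(0, 1), each = 30)
  indep <- rbinom(60, 1, 0.5)
  determ <- as.numeric(y == 1)
  X <- cbind(indep = indep, determ = determ, const = rep(1, 60))
  mi <- mutual_information_scores(X, y)$score
  expect_lt(mi["indep"], 0.05)
  # class-determined feature: MI equals the entropy of the class prior
  expect_equal(unname(mi["determ"]), log(2), tolerance = 1e-12)
  expect_equal(unname(mi["const"]), 0)
  fs <- f_scores(X, y)$score
  expect_equal(unname(fs["const"]), 0)
  expect_true(is.infinite(fs["determ"]))   # zero within-class variance
  expect_lt(fs["indep"], 5)
})

test_that("top-feature selection is deterministic, name-tie-broken, and prefix-nested", {
  sc <- setNames(c(3, 1, 2), c("a", "b", "c"))
  expect_equal(unname(select_top_features(sc, 2)), c(1L, 3L))
  # all-equal scores: first n by name order
  eq <- setNames(rep(1, 3), c("z", "m", "a"))
  expect_equal(names(select_top_features(eq, 2)), c("a", "m"))
  # n = f returns a permutation
  expect_setequal(unname(select_top_features(sc, 3)), 1:3)
  expect_error(select_top_features(sc, 0), "at least 1")
  expect_error(select_top_features(sc, 4), "exceeds")
  # prefix property on random scores with ties
  set.seed(9)
  r <- setNames(sample(1:5, 40, replace = TRUE), sprintf("g%02d", 1:40))
  for (n in 1:39)
    expect_equal(select_top_features(r, n),
                 select_top_features(r, n + 1)[1:n])
})

test_that("a wider planted/background gap never worsens the median chi-square rank of planted genes", {
  gaps <- c(0.15, 0.35, 0.6)
  med_rank <- vapply(gaps, function(pr) {
    coh <- generate_cohort(sim_config(planted_snv_rate = pr,
                                      background_snv_rate = 0.05, seed = 13))
    genes <- rank_genes_by_snv_frequency(coh, nrow(coh$cnv_matrix))
    fm <- encode_snv_combined(coh, genes)
    sc <- chi_square_scores(fm, coh$labels[rownames(fm)])$score
    rk <- rank(-sc)[unique(unlist(coh$planted))]
    median(rk, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(med_rank) <= 0))
})
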