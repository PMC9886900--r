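#' Encoding scheme for somatic SNVs
#'
#' Maps the qualitative effect call of an SNV to a numeric code `m` in
#' `(0, 1]` -- `[deleterious, deleterious (low confidence), tolerated (low
#' confidence), tolerated]` to `[1.0, 0.75, 0.5, 0.25]`, equidistant values
#' giving detrimental effects the largest weight -- and the impact-confidence
#' class `[high, moderate, modifier, low]` to `[1, 0.4, 0.7, 0.1]`.
#'
#' @param mode which per-gene SNV value the encoder family produces:
#'   binary presence, the sum of `m * strength` products, or the sum of
#'   impact-confidence codes.
#' @param effect_codes,impact_codes named numeric code maps; all codes must
#'   lie in `(0, 1]`.
#' @return An object of class `"encoding_scheme"`.
#' @export
encoding_scheme <- function(mode = c("presence", "effect_strength",
                                     "impact_confidence"),
                            effect_codes = c(deleterious = 1.0,
                                             deleterious_low_conf = 0.75,
                                             tolerated_low_conf = 0.5,
                                             tolerated = 0.25),
                            impact_codes = c(high = 1, moderate = 0.4,
                                             modifier = 0.7, low = 0.1)) {
  mode <- match.arg(mode)
  stopifnot(setequal(names(effect_codes), EFFECT_LEVELS),
            setequal(names(impact_codes), IMPACT_LEVELS))
  if (any(effect_codes <= 0 | effect_codes > 1) ||
      any(impact_codes <= 0 | impact_codes > 1))
    stop("all category codes must lie in (0, 1]")
  structure(list(mode = mode, effect_codes = effect_codes,
                 impact_codes = impact_codes),
            class = "encoding_scheme")
}

feature_matrix <- function(values, origin) {
  attr(values, "origin") <- rep(origin, length.out = ncol(values))
  values
}

cohort_samples <- function(coh) names(coh$labels)

# samples x genes matrix of an aggregated per-(sample, gene) statistic
aggregate_snv <- function(coh, genes, values) {
  stopifnot(inherits(coh, "helr_cohort"))
  if (length(genes) == 0) stop("gene list must be non-empty")
  samples <- cohort_samples(coh)
  snv <- coh$snv
  keep <- snv$gene %in% genes & snv$sample_id %in% samples
  m <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  if (any(keep)) {
    si <- match(snv$sample_id[keep], samples)
    gi <- match(snv$gene[keep], genes)
    v <- values[keep]
    agg <- rowsum(v, group = (gi - 1) * length(samples) + si)
    m[as.integer(rownames(agg))] <- agg[, 1]
  }
  m
}

#' Rank genes by per-class SNV frequency and keep the top of each class
#'
#' For each cancer type, genes are ranked by their total SNV count within
#' that class (a gene with several SNVs in one patient counts each of them),
#' the top `top_k_per_class` are kept, and the per-class lists are combined
#' into one deterministic union: classes in label order, genes in rank
#' order, first occurrence wins.  Ties in count are broken by gene name.
#'
#' @param coh a `"helr_cohort"`.
#' @param top_k_per_class genes retained per class.
#' @return Character vector of gene symbols.
#' @export
rank_genes_by_snv_frequency <- function(coh, top_k_per_class) {
  stopifnot(inherits(coh, "helr_cohort"))
  if (top_k_per_class < 1) stop("top_k_per_class must be at least 1")
  snv <- coh$snv
  cls <- coh$labels[snv$sample_id]
  out <- character(0)
  for (k in sort(unique(unname(coh$labels)))) {
    sub <- snv$gene[cls == k]
    if (length(sub) == 0) next
    counts <- table(sub)
    ord <- order(-as.numeric(counts), names(counts))
    top <- names(counts)[ord][seq_len(min(top_k_per_class, length(counts)))]
    out <- c(out, top)
  }
  unique(out)
}

#' Gene-level SNV and CNV feature encoders
#'
#' All encoders return a nonnegative samples-by-genes matrix:
#' * `encode_presence()`: 1 if the sample carries at least one SNV on the
#'   gene, else 0;
#' * `encode_effect_strength()`: the sum over the gene's SNVs of
#'   `m * strength`, `m` the effect code of the call;
#' * `encode_impact_confidence()`: the sum of the impact-confidence codes of
#'   the gene's SNVs (a gene with no mutation scores 0);
#' * `encode_snv_combined()`: the sum of the two value encodings, giving one
#'   SNV feature per gene (the default-model preset);
#' * `encode_cnv()`: copy-number states shifted from `-2..2` to `0..4`,
#'   since downstream statistical feature selection requires nonnegative
#'   values.
#'
#' @param coh a `"helr_cohort"`.
#' @param genes character vector of genes to encode (SNV encoders).
#' @param scheme an [encoding_scheme()] supplying the code maps.
#' @return Numeric matrix (samples x genes) with an `"origin"` attribute.
#' @export
encode_presence <- function(coh, genes) {
  m <- aggregate_snv(coh, genes, rep(1, nrow(coh$snv)))
  feature_matrix((m > 0) + 0, "snv")
}

#' @rdname encode_presence
#' @export
encode_effect_strength <- function(coh, genes, scheme = encoding_scheme()) {
  v <- scheme$effect_codes[coh$snv$effect] * coh$snv$strength
  feature_matrix(aggregate_snv(coh, genes, v), "snv")
}

#' @rdname encode_presence
#' @export
encode_impact_confidence <- function(coh, genes, scheme = encoding_scheme()) {
  v <- unname(scheme$impact_codes[coh$snv$impact])
  feature_matrix(aggregate_snv(coh, genes, v), "snv")
}

#' @rdname encode_presence
#' @export
encode_snv_combined <- function(coh, genes, scheme = encoding_scheme()) {
  v <- scheme$effect_codes[coh$snv$effect] * coh$snv$strength +
    scheme$impact_codes[coh$snv$impact]
  feature_matrix(aggregate_snv(coh, genes, unname(v)), "snv")
}

#' @rdname encode_presence
#' @export
encode_cnv <- function(coh) {
  stopifnot(inherits(coh, "helr_cohort"))
  m <- coh$cnv_matrix
  if (any(m < -2 | m > 2)) stop("copy-number states must lie in -2..2")
  samples <- cohort_samples(coh)
  out <- t(m[, samples, drop = FALSE]) + 2
  storage.mode(out) <- "double"
  feature_matrix(out, "cnv")
}

#' Concatenate SNV and CNV feature blocks
#'
#' Binds the two blocks column-wise after tagging feature names with their
#' origin (`gene.snv`, `gene.cnv`), so the same gene may contribute one
#' feature of each kind.  Sample order must agree.
#'
#' @param snv_fm,cnv_fm feature matrices from the encoders.
#' @return The concatenated feature matrix.
#' @export
concatenate_features <- function(snv_fm, cnv_fm) {
  if (ncol(snv_fm) == 0) return(tag_features(cnv_fm))
  if (ncol(cnv_fm) == 0) return(tag_features(snv_fm))
  if (!identical(rownames(snv_fm), rownames(cnv_fm)))
    stop("sample order of the SNV and CNV blocks differs")
  a <- tag_features(snv_fm); b <- tag_features(cnv_fm)
  out <- cbind(a, b)
  attr(out, "origin") <- c(attr(a, "origin"), attr(b, "origin"))
  out
}

tag_features <- function(fm) {
  org <- attr(fm, "origin")
  if (is.null(org)) stop("feature matrix lacks an origin attribute")
  untagged <- !grepl("\\.(snv|cnv)$", colnames(fm))
  colnames(fm)[untagged] <- paste0(colnames(fm)[untagged], ".", org[untagged])
  fm
}

#' Univariate feature scores against the class labels
#'
#' `chi_square_scores()` implements the value-weighted chi-square statistic
#' used for feature selection: for feature `j`, the observed value `O_i` is
#' the sum of the (nonnegative) feature over samples of class `i`, the
#' expected value `E_i` apportions the feature's column total by the class
#' frequencies, and the score is `sum_i (O_i - E_i)^2 / E_i`.  Features with
#' zero column total score 0.  `mutual_information_scores()` (plug-in
#' estimate on up-to-8-level discretized features, in nats) and `f_scores()`
#' (one-way ANOVA F) are alternative rankings.
#'
#' @param X nonnegative feature matrix, samples in rows.
#' @param y class labels (integer ids or factor), at least two classes.
#' @return An object of class `"feature_scores"`.
#' @export
chi_square_scores <- function(X, y) {
  X <- as.matrix(X)
  if (any(X < 0))
    stop("chi-square feature selection requires nonnegative feature values")
  y <- as_class_ids(y)
  if (length(unique(y)) < 2) stop("need at least two classes")
  O <- rowsum(X, group = y)                     # K x f observed sums
  n_i <- as.numeric(table(y)[rownames(O)])
  tot <- colSums(X)
  E <- outer(n_i / sum(n_i), tot)               # expected under independence
  term <- (O - E)^2
  term <- ifelse(E > 0, term / ifelse(E > 0, E, 1), 0)
  sc <- colSums(term)
  sc[tot == 0] <- 0
  structure(list(score = setNames(as.numeric(sc), colnames(X)),
                 method = "chi2", observed = O, expected = E),
            class = "feature_scores")
}

as_class_ids <- function(y) {
  if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
}

#' @rdname chi_square_scores
#' @param max_bins discretization levels for the mutual-information estimate.
#' @export
mutual_information_scores <- function(X, y, max_bins = 8L) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("feature values must be nonnegative")
  y <- as_class_ids(y)
  if (length(unique(y)) < 2) stop("need at least two classes")
  sc <- apply(X, 2, function(v) {
    u <- unique(v)
    b <- if (length(u) <= max_bins) match(v, u) else {
      br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = max_bins + 1)))
      if (length(br) < 2) return(0)
      as.integer(cut(v, br, include.lowest = TRUE))
    }
    joint <- table(b, y) / length(v)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  })
  structure(list(score = setNames(as.numeric(sc), colnames(X)),
                 method = "mutual_info"),
            class = "feature_scores")
}

#' @rdname chi_square_scores
#' @export
f_scores <- function(X, y) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("feature values must be nonnegative")
  y <- as_class_ids(y)
  K <- length(unique(y))
  if (K < 2) stop("need at least two classes")
  N <- nrow(X)
  gm <- colMeans(X)
  grp <- factor(y)
  n_i <- as.numeric(table(grp))
  means <- rowsum(X, grp) / n_i
  ssb <- colSums(n_i * (sweep(means, 2, gm))^2)
  ssw <- colSums((X - means[as.integer(grp), , drop = FALSE])^2)
  f <- ifelse(ssb == 0, 0, (ssb / (K - 1)) / ifelse(ssw > 0, ssw / (N - K), NA))
  f[ssb > 0 & ssw == 0] <- Inf
  structure(list(score = setNames(as.numeric(f), colnames(X)),
                 method = "f_score"),
            class = "feature_scores")
}

#' @export
print.feature_scores <- function(x, ...) {
  cat(sprintf("Feature scores (%s): %d features\n", x$method, length(x$score)))
  top <- utils::head(sort(x$score, decreasing = TRUE), 5)
  cat("  top:", paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Select the highest-scoring features
#'
#' Returns the indices of the `n_top` largest scores in decreasing order.
#' Ties are broken by ascending feature name, making the selection
#' deterministic; the selection at `n` is always a prefix of the selection
#' at `n + 1`.
#'
#' @param scores a `"feature_scores"` object or a named numeric vector.
#' @param n_top how many features to keep.
#' @return Integer vector of feature indices (with feature names).
#' @export
select_top_features <- function(scores, n_top) {
  sc <- if (inherits(scores, "feature_scores")) scores$score else scores
  if (n_top < 1) stop("n_top must be at least 1")
  if (n_top > length(sc)) stop("n_top exceeds the number of features")
  nm <- names(sc)
  if (is.null(nm)) nm <- sprintf("f%06d", seq_along(sc))
  ord <- order(-sc, nm)
  setNames(ord[seq_len(n_top)], nm[ord[seq_len(n_top)]])
}

#' Encode a cohort with the default-model preset
#'
#' The pipeline the shipped model uses: rank genes by per-class SNV
#' frequency, encode one combined SNV value per selected gene
#' (effect-strength plus impact-confidence sums), concatenate with the
#' CNV block over all genes, and return the nonnegative feature matrix.
#'
#' @param coh a `"helr_cohort"`.
#' @param top_k_per_class genes kept per class in the frequency ranking.
#' @param scheme an [encoding_scheme()].
#' @return Feature matrix (samples x features) with origin-tagged names.
#' @export
build_feature_matrix <- function(coh, top_k_per_class = 10000L,
                                 scheme = encoding_scheme()) {
  genes <- rank_genes_by_snv_frequency(coh, top_k_per_class)
  snv_fm <- encode_snv_combined(coh, genes, scheme)
  cnv_fm <- encode_cnv(coh)
  concatenate_features(snv_fm, cnv_fm)
}
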