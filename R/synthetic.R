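#' Configuration of the synthetic-cohort generator
#'
#' The generator plants class-specific driver genes into an otherwise
#' exchangeable background, emulating the statistical structure the
#' prediction method relies on: per-class gene mutation enrichment,
#' VEP-style categorical effect/impact labels with real strengths in
#' `[0, 1)`, and integer copy-number states in `-2..2`.  Defaults match the
#' reference experiment used throughout the test-suite: 3 classes of 50
#' samples, 500 genes, 10 planted genes per class, SNV rates 0.6 (planted)
#' versus 0.05 (background).
#'
#' @param n_samples_per_class samples per class.
#' @param n_classes number of cancer types `K`.
#' @param n_genes size of the gene universe.
#' @param planted_genes_per_class driver genes planted per class.
#' @param background_snv_rate per-gene SNV probability off the planted set.
#' @param planted_snv_rate per-gene SNV probability on a class's planted
#'   genes for samples of that class; must exceed the background rate.
#' @param planted_cnv_shift_prob probability that a planted gene's
#'   copy-number state is drawn from its class-conditional shifted
#'   distribution rather than the background; 0 disables the CNV channel.
#' @param planted_effect_bias draw effect/impact categories on planted genes
#'   from deleterious/high-biased distributions.  Set `FALSE` (together with
#'   equal SNV rates and a zero CNV shift) for a true null cohort in which
#'   planted genes are statistically indistinguishable from background.
#' @param snv_multiplicity_lambda Poisson rate of extra SNVs on a mutated
#'   gene (0 = exactly one SNV per mutated gene).
#' @param allow_overlap may different classes plant the same gene.
#' @param seed master seed; each component (planting, SNV, CNV) draws from
#'   its own derived stream so adding one component never perturbs the
#'   draws of another.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_samples_per_class = 50L, n_classes = 3L,
                       n_genes = 500L, planted_genes_per_class = 10L,
                       background_snv_rate = 0.05, planted_snv_rate = 0.6,
                       planted_cnv_shift_prob = 0.5,
                       planted_effect_bias = TRUE,
                       snv_multiplicity_lambda = 0,
                       allow_overlap = FALSE, seed = 1L) {
  for (r in c(background_snv_rate, planted_snv_rate))
    if (!is.finite(r) || r <= 0 || r >= 1)
      stop("rates must lie strictly inside (0, 1)")
  if (!is.finite(planted_cnv_shift_prob) || planted_cnv_shift_prob < 0 ||
      planted_cnv_shift_prob >= 1)
    stop("planted_cnv_shift_prob must lie in [0, 1)")
  if (planted_snv_rate < background_snv_rate)
    stop("planted_snv_rate must not be below background_snv_rate")
  if (!allow_overlap &&
      n_classes * planted_genes_per_class > n_genes)
    stop("not enough genes for disjoint planted sets")
  structure(list(
    n_samples_per_class = as.integer(n_samples_per_class),
    n_classes = as.integer(n_classes),
    n_genes = as.integer(n_genes),
    planted_genes_per_class = as.integer(planted_genes_per_class),
    background_snv_rate = background_snv_rate,
    planted_snv_rate = planted_snv_rate,
    planted_cnv_shift_prob = planted_cnv_shift_prob,
    planted_effect_bias = isTRUE(planted_effect_bias),
    snv_multiplicity_lambda = snv_multiplicity_lambda,
    allow_overlap = isTRUE(allow_overlap),
    seed = as.integer(seed)), class = "sim_config")
}

# copy-number state distributions over -2..2
CNV_BG_PROBS   <- c(0.05, 0.10, 0.70, 0.10, 0.05)
CNV_GAIN_PROBS <- c(0.02, 0.03, 0.15, 0.30, 0.50)
CNV_LOSS_PROBS <- rev(CNV_GAIN_PROBS)

# categorical distributions for effect / impact labels
EFFECT_PROBS_PLANTED <- c(0.70, 0.15, 0.10, 0.05)   # deleterious-biased
EFFECT_PROBS_BG      <- c(0.15, 0.20, 0.30, 0.35)
IMPACT_PROBS_PLANTED <- c(0.60, 0.25, 0.10, 0.05)   # high-biased
IMPACT_PROBS_BG      <- c(0.10, 0.30, 0.35, 0.25)

#' Generate a synthetic somatic-mutation cohort with planted drivers
#'
#' For each class `k`, every gene in its planted set carries an SNV with
#' probability `planted_snv_rate` in class-`k` samples and
#' `background_snv_rate` elsewhere.  SNV strengths are Uniform`[0, 1)`;
#' effect/impact categories are drawn from distributions biased toward
#' deleterious/high on planted genes.  Copy-number states follow a
#' background multinomial over `-2..2` with a class-conditional shift
#' (amplification- or deletion-biased, fixed per planted gene) applied with
#' probability `planted_cnv_shift_prob`.  Identical seeds reproduce
#' identical cohorts.
#'
#' @param cfg a [sim_config()].
#' @return A `"helr_cohort"` whose `planted` field lists the ground-truth
#'   planted gene set per class (plus the per-gene CNV shift directions in
#'   `attr(,"cnv_direction")`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_classes
  npc <- cfg$n_samples_per_class
  G <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  samples <- sprintf("S%04d", seq_len(K * npc))
  labels <- setNames(rep(seq_len(K) - 1L, each = npc), samples)
  class_names <- sprintf("cancer_%s", LETTERS[seq_len(K)])

  # independent RNG streams per component, derived once from the master seed
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)

  # --- planted gene sets (+ per-gene CNV shift direction)
  set.seed(sub[1])
  P <- cfg$planted_genes_per_class
  if (cfg$allow_overlap) {
    planted <- lapply(seq_len(K), function(k) sample(genes, P))
  } else {
    chosen <- sample(genes, K * P)
    planted <- split(chosen, rep(seq_len(K), each = P))
  }
  names(planted) <- class_names
  all_planted <- unique(unlist(planted))
  direction <- setNames(sample(c(-1L, 1L), length(all_planted), replace = TRUE),
                        all_planted)

  # --- SNV records
  set.seed(sub[2])
  rec <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(labels == k - 1L)
    pr <- rep(cfg$background_snv_rate, G)
    pr[match(planted[[k]], genes)] <- cfg$planted_snv_rate
    hit <- matrix(stats::rbinom(length(idx) * G, 1L, rep(pr, each = length(idx))),
                  nrow = length(idx))
    hits <- which(hit == 1L, arr.ind = TRUE)
    if (nrow(hits) == 0) { rec[[k]] <- NULL; next }
    count <- 1L + if (cfg$snv_multiplicity_lambda > 0)
      stats::rpois(nrow(hits), cfg$snv_multiplicity_lambda) else 0L
    sample_id <- rep(samples[idx][hits[, 1]], count)
    gene <- rep(genes[hits[, 2]], count)
    on_planted <- cfg$planted_effect_bias & gene %in% planted[[k]]
    n_rec <- length(gene)
    eff_idx <- integer(n_rec); imp_idx <- integer(n_rec)
    for (pl in c(TRUE, FALSE)) {
      sel <- which(on_planted == pl)
      if (length(sel) == 0) next
      ep <- if (pl) EFFECT_PROBS_PLANTED else EFFECT_PROBS_BG
      ip <- if (pl) IMPACT_PROBS_PLANTED else IMPACT_PROBS_BG
      eff_idx[sel] <- sample.int(4L, length(sel), replace = TRUE, prob = ep)
      imp_idx[sel] <- sample.int(4L, length(sel), replace = TRUE, prob = ip)
    }
    rec[[k]] <- data.frame(
      sample_id = sample_id, gene = gene,
      effect = EFFECT_LEVELS[eff_idx],
      strength = stats::runif(n_rec),
      impact = IMPACT_LEVELS[imp_idx],
      stringsAsFactors = FALSE)
  }
  snv <- do.call(rbind, rec)
  rownames(snv) <- NULL

  # --- CNV matrix
  set.seed(sub[3])
  states <- -2:2
  cnv <- matrix(sample(states, G * length(samples), replace = TRUE,
                       prob = CNV_BG_PROBS),
                nrow = G, dimnames = list(genes, samples))
  for (k in seq_len(K)) {
    idx <- which(labels == k - 1L)
    for (g in planted[[k]]) {
      shifted <- stats::runif(length(idx)) < cfg$planted_cnv_shift_prob
      if (!any(shifted)) next
      probs <- if (direction[g] > 0) CNV_GAIN_PROBS else CNV_LOSS_PROBS
      cnv[g, idx[shifted]] <- sample(states, sum(shifted), replace = TRUE,
                                     prob = probs)
    }
  }
  storage.mode(cnv) <- "integer"
  attr(planted, "cnv_direction") <- direction
  cohort(snv, cnv, labels, class_names, planted = planted)
}

#' Random inference instance within the protocol's input contract
#'
#' Draws an input matrix with entries uniform in `[0, 256)` (the protocol's
#' 8-bit raw input interval), weights uniform in `(-1, 1)` and biases
#' uniform in `(-1, 1)`, deterministically from `seed`.
#'
#' @param n_inputs number of input rows `|X|`.
#' @param f number of features.
#' @param n_outputs number of outputs `|Y|`.
#' @param seed integer seed.
#' @param zero_weights if `TRUE`, all weights are zero (bias-only model).
#' @return A list with `X` (`n_inputs` x `f`), `W` (`f` x `n_outputs`), `b`.
#' @export
generate_random_inference_instance <- function(n_inputs, f, n_outputs, seed,
                                               zero_weights = FALSE) {
  stopifnot(n_inputs >= 1, f >= 1, n_outputs >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  X <- matrix(stats::runif(n_inputs * f, 0, 256), n_inputs, f)
  W <- if (zero_weights) matrix(0, f, n_outputs) else
    matrix(stats::runif(f * n_outputs, -1, 1), f, n_outputs)
  b <- stats::runif(n_outputs, -1, 1)
  list(X = X, W = W, b = b)
}
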