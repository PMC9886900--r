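---
title: "Privacy-preserving cancer-type prediction: model, encoding, and encrypted inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving cancer-type prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helr)
```

## The problem

A patient's somatic mutation profile — which genes carry single-nucleotide
variants (SNVs) and how their copy numbers (CNVs) deviate — is predictive of
the cancer type, but it is also among the most identifying data a person
has. When a hospital sends a profile to a cloud-hosted classifier, the
honest-but-curious server learns both the profile and the diagnosis. This
package implements the full alternative pipeline: a compact gene-level
encoding of the mutation data, statistical feature selection, an
L1-penalized multinomial logistic regression, and an inference path that
evaluates the trained model on *encrypted* inputs under the BFV
homomorphic-encryption scheme, so the server computes the prediction without
ever seeing the data. The client sends one encrypted query and receives one
encrypted response; there is no interactive protocol.

## Feature encoding

Raw mutation tables have one row per variant — millions of potential
features. The encoders compress them to one value per *gene*:

* **Presence** (`encode_presence`): 1 if the gene carries at least one SNV.
* **Effect x strength** (`encode_effect_strength`): each SNV's qualitative
  call is coded as `m` in {deleterious = 1.0, deleterious (low confidence)
  = 0.75, tolerated (low confidence) = 0.5, tolerated = 0.25} — equidistant
  values in (0, 1], detrimental effects largest — and multiplied by the
  real-valued strength `s` in `[0, 1)`; a gene's feature is the sum of
  `m * s` over its SNVs.
* **Impact confidence** (`encode_impact_confidence`): the VEP-style impact
  class is coded as {high = 1, moderate = 0.4, modifier = 0.7, low = 0.1}
  and summed per gene; a gene with no mutation scores 0.
* **CNV** (`encode_cnv`): integer copy states `-2..2` are shifted to
  `0..4`, because the downstream selection statistics require nonnegative
  values.

The shipped preset (`build_feature_matrix`) first ranks genes by per-class
SNV frequency (multiple SNVs per gene all count) and keeps the top `k` per
class, then uses **one** SNV feature per selected gene — the sum of the two
value encodings — concatenated with the CNV block over all genes, each
feature name tagged `.snv`/`.cnv`. One value per gene is the only reading
consistent with the arithmetic of the published feature count (SNV genes +
CNV genes = total features); since the source description is ambiguous about
whether the two value encodings stay separate, both separate encoders remain
exported and any combination can be concatenated explicitly.

## Feature selection

`chi_square_scores` implements the value-weighted chi-square used for
ranking: for feature `j`, `O_i` is the feature's sum over samples of class
`i`, `E_i` apportions the column total by class frequencies, and the score
is `sum_i (O_i - E_i)^2 / E_i`. This is the natural generalization of the
contingency chi-square to nonnegative real-valued features (identical to the
convention used by scikit-learn's `chi2`). Note one subtlety: on a binary
feature this statistic is *not* the classical 2x2 Pearson chi-square — it
omits the feature = 0 row — so the test-suite oracle checks the O/E
definition itself, by brute-force enumeration. Mutual information (plug-in
estimate on discretized features) and the one-way ANOVA F statistic are
provided as alternative rankings. `select_top_features` sorts decreasingly
with ties broken by feature name, so selections are deterministic and
prefix-nested.

## The classifier

`train_multiclass_lr` fits a multinomial logistic regression with a Lasso
penalty `lambda * sum |beta|` via glmnet. With far more features than
samples, the L1 penalty is the principal overfitting control: uninformative
features are driven to exactly zero. `lambda` is chosen by stratified
5-fold cross-validated accuracy on an 11-point log-spaced grid `10^-3..10^2`
(the source states no grid; ties go to the stronger penalty). Evaluation
reports accuracy, macro precision/recall/F1, per-class one-vs-rest ROC AUC
and the micro-average AUC over pooled (sample, class) score pairs, all
computed from the linear scores `z = W x + b` — the softmax is monotone, so
`z` orders samples exactly as the probabilities would. That same monotonicity
is what the encrypted path exploits: the predicted class is
`argmax(W x + b)`, a purely linear computation. One-vs-rest binary models
(`train_binary_models`) reuse the machinery per class.

## Fixed-point encoding and the CRT pair

BFV computes over integers modulo a plaintext modulus `t`. Inputs (all
encoders produce values far below `2^8`) are scaled by `2^s_x`, `s_x = 6`;
weights, normalized into `(-1, 1)` by an argmax-invariant common rescale,
are scaled by `2^s_w`, `s_w = 14`; biases by `2^(s_x+s_w)`. Rounding is to
nearest, ties away from zero (symmetric and deterministic; the source is
silent). A dot product over `f` features then needs
`8 + s_x + s_w + ceil(log2 f)` bits — 44 bits at `f = 40,960` — more than
any single secure plaintext modulus provides. Every value therefore travels
as a CRT residue pair under `t0 = 1,073,872,897` (30 usable bits) and
`t1 = 114,689` (16 bits), both primes congruent to 1 mod `2n` so slot
batching works; the signed result is recovered as the centered
representative, exact whenever `|value| < t0*t1/2 ~ 2^46.8`. Signed weights
are represented by modular negatives (centered lift) — the source describes
weights in `[0, 1)`, but trained LR coefficients are signed, and modular
arithmetic carries signs through the circuit exactly. Overflow beyond the
CRT range is a hard error, never a silent wrap.

`simulate_packed_matmul` mirrors the encrypted circuit *bit-exactly* in
plaintext — same chunking, same rotation ladder, same masking and
compression, modulo the same two moduli — and is the oracle the encrypted
engine is tested against; the simulator in turn must equal a direct integer
matrix product. `quantization_error_bound` gives a per-sample bound on
|fixed-point - float| logits; when the top-two float logit gap exceeds twice
the bound, the quantized (hence encrypted) argmax provably matches the float
argmax.

## The encrypted engine

No homomorphic-encryption library ships with this environment, so the
package implements the BFV operations it needs from scratch (C++ via Rcpp):

* ring `Z_q[x]/(x^n + 1)`, `n = 8192`, `q` a product of six 31-bit
  NTT-friendly primes (`log2 q ~ 186`, under the 218-bit cap of the
  homomorphic-encryption standard for 128-bit classical security at this
  degree — degrees whose chain would be insecure are refused);
* slot batching via negacyclic number-theoretic transforms modulo each
  plaintext modulus, with the standard two-half slot layout;
* ternary secret key, centered-binomial errors (sigma ~ 3.2), and Galois
  keys only for the power-of-two rotation ladder plus the half swap —
  exactly the `log2(n) = 13` rotations a packed dot product needs;
* key switching by RNS decomposition (one digit per prime), with lazy-
  reduction NTT butterflies and 128-bit accumulation in the hot path.

A packed dot product multiplies the `ceiling(f/n)` encrypted input chunks
slot-wise by the matching encoded weight chunks (ciphertext x plaintext
only — the circuit never multiplies ciphertexts, so no relinearization),
sums the chunks, runs the rotate-and-add ladder so every slot holds the dot
product, masks the slot assigned to the (input, output) pair, and compresses
the results additively. The slot layout is row-major, position
`(i-1)*|Y| + (j-1) mod n` — chosen so one patient's outputs decode
contiguously; a new output ciphertext is appended when `|X|*|Y| > n`. Work
per pair is independent, so execution order cannot change results;
execution here is single-threaded. Biases are added at the assigned slots;
double addition is rejected by the API. After the full 40,960-feature
circuit about 45 bits of noise budget remain at default parameters, and the
client refuses to return values if the budget is exhausted.

The client/server split is explicit: `he_public_blob` exports the public
and rotation keys only, `he_evaluation_context` rebuilds a server context
that can compute but provably cannot decrypt, and the query/response
envelopes (`write_query`, `write_response`) carry the public values
`{n, T, s_x}` and `s_w` the protocol specifies.

**Security caveats.** Randomness comes from a seeded splitmix64 stream so
experiments are reproducible; it is not a cryptographically secure
generator, and no constant-time or side-channel hardening is attempted.
This is a faithful research implementation of the scheme, not a hardened
library.

## The synthetic cohort

Real tumor mutation profiles are access-controlled, so the generator
(`generate_cohort`) produces cohorts with the statistical structure the
method relies on: each class plants a set of driver genes that carry SNVs at
rate 0.6 in their class versus 0.05 elsewhere (the defaults; 3 classes x 50
samples, 500 genes, 10 planted genes per class), strengths Uniform `[0, 1)`
(maximizing coverage of the encoding map, as no distribution is stated),
effect/impact categories biased toward deleterious/high on planted genes,
and copy-number states from a background multinomial over `-2..2` with a
class-conditional gain- or loss-biased shift (probability 0.5, direction
fixed per gene) on planted genes. Each component draws from its own
seed-derived RNG stream, so adding a component never perturbs another's
draws.  The three planted channels (SNV rate, category bias, CNV shift) are
independently switchable — equal rates with `planted_effect_bias = FALSE`
and a zero shift give a true null cohort for calibration experiments. What the generator does *not* emulate: mutational signatures,
gene-gene linkage, per-gene mutation-rate heterogeneity, and cohort
imbalance. A green recovery test therefore establishes that the selection
and training machinery works on well-separated planted signal — not that
the published real-data accuracy is reproducible, which would require the
original access-controlled dataset.

## Numerical and design choices

* Rounding: nearest, ties away from zero everywhere in quantization; raw
  inputs at the very top of the 8-bit range saturate at the largest code so
  scaled inputs always occupy the stated 14 bits.
* Argmax ties: lowest class index, deterministically.
* Ranking ties (gene frequency, feature scores): ascending name.
* The union after per-class gene ranking: classes in label order, rank
  order within class, first occurrence kept.
* Batching index maps and rotation semantics are fixed by the engine and
  mirrored exactly by the simulator; tests compare slots verbatim.
* `lambda` grid, fold count and seeds are explicit arguments; identical
  seeds give identical folds, cohorts, keys and ciphertext-level results.
* Degenerate inputs: single-class labels, empty gene lists, out-of-range
  strengths/copy-states, CRT overflow and noise-budget exhaustion all raise
  errors rather than degrade silently.

## Known limitations

* The PRNG caveat above; also keys in the CLI are regenerated from a stored
  seed, so the seed file *is* the secret key.
* The naive standard-matmul baseline in `he_benchmark` packs samples along
  slots and is reported for shape comparison only; absolute timings are
  hardware-dependent and never asserted.
* Published real-data headline numbers (accuracy/MAUC on the 11-type
  cohort) are out of scope by design: they require the original dataset.
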