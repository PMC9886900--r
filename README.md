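# helr — privacy-preserving cancer-type prediction from somatic mutations

`helr` is for computational-biology and applied-cryptography practitioners
who want to classify a patient's cancer type from somatic mutation profiles
(gene-level SNVs and copy-number states) **without revealing the profile to
the server that hosts the model**. It implements the complete pipeline:

1. **Gene-level encoding** of variant tables: SNV presence; effect codes
   `m ∈ {1.0, 0.75, 0.5, 0.25}` (deleterious → tolerated) times the
   real-valued strength `s ∈ [0,1)`, summed per gene; impact-confidence
   codes `{high: 1, moderate: 0.4, modifier: 0.7, low: 0.1}`, summed per
   gene; copy-number states mapped `-2..2 → 0..4`.
2. **Feature selection** by the value-weighted chi-square
   `χ² = Σᵢ (Oᵢ − Eᵢ)²/Eᵢ` (per-class observed sums vs class-frequency
   expectations), with mutual-information and ANOVA-F alternatives.
3. An **L1-penalized multinomial logistic regression** (glmnet backend,
   λ by stratified 5-fold CV); since softmax is monotone, inference is
   `k̂ = argmax(Wx + b)` — purely linear.
4. **Encrypted inference** under a from-scratch BFV implementation (Rcpp):
   fixed-point scaling (`s_x = 6`, `s_w = 14`, bias scale `2^{s_x+s_w}`),
   a CRT plaintext pair `t₀ = 1,073,872,897`, `t₁ = 114,689` covering the
   `8 + s_x + s_w + ⌈log₂ f⌉`-bit outputs (44 bits at `f = 40,960`), slot
   packing of `n = 8192` features per ciphertext, and a packed
   matrix-multiplication circuit needing only `log₂ n = 13` rotations per
   dot product. A bit-exact plaintext simulator of the circuit doubles as
   the engine's test oracle.
5. A **synthetic-cohort generator** with planted per-class driver genes, so
   the whole pipeline is testable without access-controlled patient data.

## Worked example

```r
library(helr)

## a synthetic cohort: 3 cancer types x 50 patients, 500 genes,
## 10 planted driver genes per type (SNV rates 0.6 planted vs 0.05 background)
coh <- generate_cohort(sim_config(seed = 7))
fm  <- build_feature_matrix(coh, top_k_per_class = 500)
sel <- select_top_features(chi_square_scores(fm, coh$labels), 90)
mean(unique(unlist(coh$planted)) %in% sub("\\.(snv|cnv)$", "", names(sel)))
#> [1] 1                       # all 30 planted drivers inside the top 90

## train and evaluate on a held-out fold
fold <- stratified_folds(coh$labels, 5, seed = 1)
m <- train_multiclass_lr(fm[fold != 1, sel], coh$labels[fold != 1],
                         k_folds = 3, seed = 1, class_names = coh$class_names)
evaluate_model(m, fm[fold == 1, sel], coh$labels[fold == 1])
#> accuracy 1.0000 | macro P 1.000 R 1.000 F1 1.000 | MAUC 0.9956

## encrypted inference for two patients
params <- fp_params()                      # s_x 6, s_w 14, t0/t1, n = 8192
ctx  <- he_setup(params, seed = 42)        # keys: ~186-bit q, 128-bit secure
prep <- prepare_model_for_encryption(m, params)
res  <- he_infer(fm[fold == 1, sel][1:2, ], t(prep$model$weights),
                 prep$model$bias, ctx)
res$classes                                # == plaintext argmax predictions
res$noise_budget                           # bits to spare after the circuit
```

The decrypted scores equal the plaintext fixed-point simulator slot for
slot, and descale to the float logits within the derived quantization bound
(`quantization_error_bound`), so predictions agree with the plaintext model
whenever the top-two logit gap clears that bound.

A command-line workflow covering simulate → featurize → select → train →
infer (plain | fixed | encrypted, including the split
keygen/encrypt/compute/decrypt protocol) ships as `inst/cli/helr`; run it
with `Rscript $(Rscript -e 'cat(system.file("cli","helr",package="helr"))')`.

## Acceptance script

`scripts/acceptance.R` recomputes the protocol's worked-example quantities
by running the installed package — the output precision required at
`f = 40,960` with the default scales, the effect code assigned to a
deleterious (low-confidence) SNV, the impact code of a moderate SNV, and
the encoded CNV value of a `+2` copy state — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
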