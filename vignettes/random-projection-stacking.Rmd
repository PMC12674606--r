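---
title: "Random-projection stacking: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-projection stacking: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bulk RNA-seq subtype classification is a small-n, large-d problem: cohorts
of a few hundred to ~1,300 tumours described by 10^3^–10^4^ genes.
Classifiers fitted directly in that space overfit, and classical selection
pipelines (differential-expression filters, lasso) commit early to a single
gene subset. `rpstack` takes a different route: compress the transcriptome
with *several independent Gaussian random projections*, concatenate the
compressed views, and let a stacked ensemble of heterogeneous classifiers —
integrated by a multilayer-perceptron meta-learner — make the call.

## The model

Let $X \in \mathbb{R}^{n \times d}$ be the log-scale expression matrix and
$\ell = \{1, \dots, C\}$ the label set. One random projection is
$Y = X R$ with $R \in \mathbb{R}^{d \times k}$, $r_{ij} \sim
\mathcal{N}(0, 1/k)$ i.i.d. With this variance the projection is an
approximate isometry in expectation ($\mathbb{E}\,\lVert xR \rVert^2 =
\lVert x \rVert^2$), which is the Johnson–Lindenstrauss setting: pairwise
Euclidean distances are preserved up to a relative error of order
$\sqrt{\log n / k}$. `distance_preservation()` quantifies this empirically
as the Pearson correlation between the $n(n-1)/2$ paired distances of the
original and reduced representations, and accepts any externally reduced
matrix (PCA scores, UMAP embeddings, ...) for the same comparison.

*Feature fusion.* $m$ independent projections (seeds $s, s+1, \dots,
s+m-1$) are concatenated column-wise into an $n \times mk$ block. The
alternative — training one model per projection and averaging the
probabilities — is implemented as `score_ensemble_fit_predict()` and kept
as a baseline; fusing features lets downstream models exploit
complementary views jointly rather than averaging opinions after the fact.

*Stacking.* Ten heterogeneous base classifiers
(`rps_model_names()`: two kNN variants, four forest variants, three
gradient-boosting variants, one neural network) are fitted on the fused
block. Their predictions are appended to the fused features to form the
composite $z(x) = (xR_1, \dots, xR_m, \hat p_1, \dots, \hat p_N)$, and a
four-hidden-layer MLP $g(\cdot)$ (128–64–32–16 units, ReLU, dropout 0.2)
maps $z(x)$ to class probabilities; the final label is $\hat y =
\arg\max_c g(z(x))_c$. The MLP is trained with softmax cross-entropy, Adam
at learning rate $10^{-4}$, batch size 64, and class-weighted random
sampling: each example is drawn with probability inversely proportional to
its class frequency, one epoch being $n$ draws with replacement, which
keeps minority subtypes represented in every batch.

*Leakage control.* Which predictions may the meta-learner be trained on?
If base models are refit on all rows and then asked about those same rows,
the meta-features encode the training labels and the stack collapses into
memorization. `oof_base_predictions()` therefore builds meta-training
inputs out-of-fold: an inner stratified 5-fold split, each sample's
prediction coming from models that never saw it. The test suite pins this
down with a deliberately pathological "memorizing" base learner whose
out-of-fold predictions must collapse to the fallback class while its
refit-on-all predictions reproduce the labels exactly. At inference time
base predictions come from models refit on the full training set.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 400 | dimensions per projection; preservation rises steeply to ~400 and then flattens |
| `m` | 20 | independent projections; fused width is `m*k` |
| `meta_mode` | `"hard_labels"` | base models contribute 0/1 labels (binary) or one-hot blocks; `"probabilities"` gives `N*C` richer columns |
| `inner_folds` | 5 | out-of-fold split for meta-training inputs |
| `epochs`, `batch_size`, `learning_rate`, `dropout` | 1000, 64, 1e-4, 0.2 | MLP training budget and regularization |
| `seed` | 1 | one global seed, fanned out deterministically to projection, fold, base-model and meta-learner streams |

Both meta-feature modes are legitimate designs; hard labels are the
default and probabilities are one switch away. Binary hard labels are
encoded as a single 0/1 integer column per model; multiclass labels are
one-hot encoded, keeping the composite numeric and order-free.

The composite appends base predictions to the *fused projection features*,
not to the raw d-dimensional transcriptome: the meta-learner sees the same
representation the base models saw, and the model archive stays
independent of d at prediction time (projections are regenerated from
their seeds).

## The base-model panel

The registry names the ten panel slots by the conventional abbreviations
(KNN-D, KNN-U, RF-G, RF-E, ET-G, ET-E, LGBM, CB, XGB, NN). Engines, and
two honest caveats:

* `KNN-D` / `KNN-U`: an in-package kNN with distance-weighted or uniform
  votes returning full per-class probability rows.
* `RF-G`: `ranger` with Gini splits. `ET-G`: `ranger` extremely-randomized
  trees.
* `RF-E` / `ET-E`: entropy-criterion forests built in-package as bagged
  `rpart` trees (`split = "information"`) with per-tree feature
  subsampling — no installed R forest exposes an entropy split rule. The
  `ET-E` variant drops the bootstrap (full sample per tree), though true
  random-threshold splitting is not available in `rpart`, so it is an
  entropy forest without resampling rather than a literal extra-trees.
* `LGBM`: `xgboost` with histogram, leaf-wise (`lossguide`) growth — the
  LightGBM-style algorithm as implemented inside xgboost. `CB`: a third,
  depth-wise, more heavily regularized boosting configuration occupying
  the CatBoost slot (ordered boosting has no R implementation here).
  `XGB`: depth-wise xgboost defaults.
* `NN`: the package's own MLP engine with one smaller hidden block
  (64–32), the same engine that powers the meta-learner.

Hyperparameters are library defaults pinned in the registry and recorded
in each spec; all seeds derive from the global one. Custom learners join
the panel via `rps_model_spec()`.

## Evaluation machinery

`compute_metrics()` reports accuracy, F1 (positive-class by default,
macro by flag), MCC (confusion-matrix closed form; any zero marginal
gives 0), and AUC as the Mann–Whitney probability with ties counted 1/2 —
all cross-checked in the tests against brute-force counting and an
all-pairs AUC oracle. `repeated_stratified_cv()` draws an independent
stratified partition per repeat (per-fold class proportions within one
sample of the global ones) and keeps every training-side random draw —
projections included — inside the training fold. `paired_comparison()`
runs a two-sided Wilcoxon signed-rank test on per-fold differences between
two runs that share partitions; the p-value is exact by sign-flip
enumeration up to 14 non-zero pairs (correct under tied ranks, which CV
metrics produce constantly), with a tie-corrected normal approximation
beyond and the convention p = 1 when all differences vanish. A paired
t-test is available via `method = "t"`. No multiplicity correction is
applied.

## What the synthetic generator emulates — and what it does not

Real subtype cohorts are not shareable here, so `synth_generate()`
produces data with the structure the method actually relies on:

* log2(TPM+1)-scale values, per-gene baselines from a gamma(2, 2)
  distribution (range ≈ 0–15);
* co-expression through shared latent factors: genes belong to blocks,
  each sample draws one N(0,1) factor per block, loadings are
  `block_strength * U(0.5, 1.5)`. The default strength 1.0 puts roughly
  half of per-gene variance into shared programs, so sample-to-sample
  geometry is dominated by a few directions — the regime of bulk tumour
  cohorts (subtype, purity, proliferation programs) in which random
  projections preserve distances well;
* class signal as a ±delta/2 shift in a random subset of signal genes
  (random sign per gene), a 0.45 minority fraction, clipping at zero.

`make_benchmark_suite()` fixes four regimes: `strong_signal` (n=300,
d=2000, 100 signal genes, delta=2 — nearly separable; a plain
nearest-centroid oracle reaches ≥0.9 five-fold accuracy, which is the
floor any competent pipeline must clear), `mid_signal` (delta=0.8),
`null` (delta=0) and `high_dim_small_n` (n=120, d=10000).

Not emulated: batch effects, library-size artifacts, count-level
(negative-binomial) noise, realistic gene-length distributions, outlier
samples. Passing tests on this generator shows the pipeline's mechanics
are sound and calibrated — not that any particular accuracy will transfer
to a given clinical cohort.

One calibration subtlety: with co-expressed blocks, per-gene two-sample
t statistics under delta=0 are *marginally* standard normal but strongly
dependent (a whole block shares the realized between-group factor
imbalance), so an iid Kolmogorov–Smirnov bound does not apply to them.
The distributional check is therefore run with `block_strength = 0`,
and the full null configuration is instead validated where it matters:
the whole pipeline's cross-validated AUC stays within [0.40, 0.60] —
the architecture invents no signal.

## Numerical choices and degenerate inputs

* TPM rows sum to 10^6 within 1e-6 relative tolerance; all-zero samples
  stay all-zero with a warning rather than producing NaN.
* Log transform is log2(x+1); base and pseudocount are arguments, since
  upstream pipelines differ.
* Pairwise distances are paired in (i<j) row-major order in both
  representations, so the two distance vectors align exactly; a
  zero-variance distance vector (all points coincident) yields a defined
  correlation of 0 with a warning.
* `k >= d` warns but proceeds (projection is then pointless but legal).
* Meta-learner inputs are z-scored with training statistics stored in the
  model (constant columns get scale 1); fused features have spreads ~10
  while label columns are 0/1, and Adam at 1e-4 trains poorly across that
  scale mismatch. The composite container itself keeps raw values.
* MLP weights use He initialization; dropout is inverted (inference needs
  no rescaling); softmax is row-max stabilized; ties in argmax resolve to
  the first class deterministically.
* Everything flows from one integer seed via a fixed affine fan-out, and
  training restores the caller's RNG state.

## Problem sizes used by the tests and the acceptance script

The reference operating point (k=400, m=20, 10×5-fold CV, 1000 epochs) is
the package default, but the shipped experiments run at desk scale, chosen
so the full suite completes on a single CPU while leaving every method
parameter (architecture, optimizer, sampling scheme, split rules) at its
reference value: strong-signal and mid-signal experiments use k=100 with
m=5 or m=10, inner 3-fold stacking, 300 meta-epochs, slimmer forest and
boosting budgets (150/30 trees, 60 rounds), and 5-fold or paired 5×2-fold
CV; the null calibration uses k=50, m=2 over three generator seeds. The
fusion-vs-ensemble comparison uses 5 paired repeats of stratified 2-fold
CV — the comparison stays a paired cross-validation while keeping the
heavier pipeline tractable.

## Known limitations

* Binary subtype problems are the tuned path; multiclass is supported
  throughout (one-hot meta-features, macro-F1, multiclass MCC) but AUC is
  binary-only and the operating point was never optimized for C > 2.
* The MLP engine is plain R matrix arithmetic: fine at composite widths of
  a few thousand and n in the hundreds, not meant for much larger n.
* Probabilities are not calibrated; the score-ensemble baseline uses one
  configurable learner per projection rather than a full per-projection
  stack.
* The entropy-criterion and boosting panel slots are algorithmic stand-ins
  as described above; conclusions about "LightGBM vs CatBoost" per se
  should not be read off this panel.
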