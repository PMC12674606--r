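# rpstack

Subtype classification of high-dimensional expression profiles by
**random-projection feature fusion + stacked generalization**.

Bulk RNA-seq cohorts are small-n/large-d: a few hundred samples, thousands
of genes. `rpstack` compresses the transcriptome with *m* independent
Gaussian random projections $R_1, \dots, R_m$ ($r_{ij} \sim \mathcal{N}(0,
1/k)$, so each $Y = XR$ approximately preserves pairwise Euclidean
distances per the Johnson–Lindenstrauss lemma), concatenates the projected
blocks into one fused feature matrix, fits a heterogeneous panel of ten
base classifiers (kNN, random forests, extremely randomized trees,
gradient boosting, a neural network), and trains a four-layer MLP
meta-learner $g(\cdot)$ on the composite

$$z(x) = \big(xR_1, \dots, xR_m,\; \hat p_1, \dots, \hat p_N\big), \qquad
\hat y = \arg\max_{c} \; g(z(x))_c,$$

where $\hat p_i$ are the base-model predictions, built **out-of-fold**
during training so the meta-learner never sees leaked labels. The package
also ships the evaluation machinery around the classifier: a
distance-preservation diagnostic for any dimensionality reduction, a
score-ensemble baseline (one model per projection, probabilities
averaged), repeated stratified cross-validation with accuracy / F1 / MCC /
AUC, paired signed-rank comparisons, and a seeded synthetic-data generator
with co-expressed gene blocks for fully reproducible experiments.

Intended users: computational biologists benchmarking subtype classifiers
on expression matrices (TSV in, TSV out), and method developers who want a
leakage-safe stacking scaffold with a pluggable base-model registry.

## Worked example

```r
library(rpstack)

## a synthetic two-subtype cohort: 300 samples x 2000 genes, 100 signal
## genes shifted by 2 log2-units between classes, co-expressed gene blocks
sim <- synth_generate(make_benchmark_suite(seed = 1)$strong_signal)
sim$X
#> expr_matrix: 300 samples x 2000 genes, stage = log
table(sim$y)
#> classA classB
#>    165    135

## desk-scale configuration: k = 100 dims per projection, m = 5 projections
cfg <- rps_config(k = 100, m = 5, inner_folds = 3, epochs = 300, seed = 1,
                  num_trees = 150, entropy_trees = 30, nrounds = 60,
                  nn_epochs = 100)

cv <- repeated_stratified_cv(sim$X, sim$y, rps_trainer(cfg),
                             repeats = 1, folds = 5, seed = 7)
print(cv)
#> stratified cross-validation: 1 repeat(s) x 5 fold(s)
#>   accuracy mean 0.9933  sd 0.0091
#>   f1       mean 0.9926  sd 0.0101
#>   mcc      mean 0.9868  sd 0.0181
#>   auc      mean 1.0000  sd 0.0000
```

Mean five-fold accuracy 0.993: the stack recovers the planted subtype
structure almost perfectly, and (as the acceptance checks assert) is never
more than 0.02 below the best individual base model, while the null
configuration of the same pipeline stays at chance (AUC ≈ 0.5) — the
architecture invents no signal.

Fitting and predicting directly:

```r
fit <- rps_fit(sim$X, sim$y, cfg)
print(fit)
#> Random-projection stacking classifier
#>   trained on 300 samples x 2000 genes
#>   projections: m = 5 blocks of k = 100 (fused width 500)
#>   base models: KNN-D, KNN-U, RF-G, RF-E, ET-G, ET-E, LGBM, CB, XGB, NN
#>   meta-learner: MLP 128-64-32-16, meta-features = hard_labels
#>   classes: classA, classB (positive: classB)
pred <- predict(fit, sim$X)
head(pred$prob, 2)
rps_save(fit, "model.rds")   # archive: config, RP seeds, base + meta models
```

How faithfully does one projection preserve the geometry?

```r
dc <- distance_preservation(sim$X, rp_project(sim$X, rp_matrix(2000, 400, 1)))
print(dc)
#> distance preservation over 44850 pairs: Pearson r = 0.9523
plot(dc)  # the distance-fitting curve
```

A command-line interface wrapping the same functions (simulate / fit /
predict / cv / compare / distcheck, YAML config, run manifests) is
installed at `system.file("cli", "rpstack", package = "rpstack")`.

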