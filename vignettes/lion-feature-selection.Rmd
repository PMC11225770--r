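---
title: "Lion optimization wrapper feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lion optimization wrapper feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lionsel)
```

This vignette documents the methods implemented by `lionsel`, the modelling
choices behind them, and the numerical conventions the package commits to.
The target application is two-class crop-pest image classification: images
are filtered and optionally augmented, mapped to fixed-length feature
vectors, reduced by a feature selector, and scored by a bank of classifiers
under stratified evaluation protocols.

## The Lion Optimization Algorithm

`loa_optimize()` is a from-scratch implementation of the Lion Optimization
Algorithm (LOA), a population metaheuristic that mimics the social structure
of lions. A population of `population_size` candidate solutions ("lions") is
split at initialization into a nomad share (`nomad_ratio`, default 0.2) and
residents partitioned over `num_prides` prides (default 5); each pride holds
`female_ratio` females (default 0.8, reversed for nomads). Every lion keeps
its personal best position ("territory marking"). One iteration applies, per
pride:

* **Hunting.** A fraction of the pride's females (`hunter_fraction`) encircles
  a dummy prey placed at the hunters' centroid. Hunters are split into a
  center group and two wings: center hunters move uniformly between their
  position and the prey, wing hunters move beyond the reflected prey
  position. When a hunter improves, the prey flees by the relative
  improvement `PI = (f_old - f_new) / max(|f_old|, eps)` clamped to [0, 1],
  scaled by a uniform draw.
* **Moving toward safe place.** Each remaining female selects a territory
  point by tournament over the pride's personal bests. The tournament size
  is `max(2, ceiling(K/2))`, where `K` counts pride members whose personal
  best improved last iteration. The move is
  `new = old + 2 D u1 R1 + u2 tan(theta) D R2`
  with `D` the distance to the selected point, `R1` the unit vector toward
  it, `R2` a random unit vector orthogonal to `R1`,
  `u1 ~ U(0,1)`, `u2 ~ U(-1,1)` and `theta ~ U(-pi/2, pi/2)`.
* **Roaming.** Each resident male visits `roaming_fraction` of the pride's
  territory points; toward each it steps `x ~ U(0, 2d)` (`d` = distance to
  the point) along a direction perturbed by `theta ~ U(-pi/6, pi/6)`.
* **Mating.** A `mating_fraction` share of females mates with one resident
  male. With `beta ~ N(0.5, 0.1)`, the two offspring are
  `beta * F + (1 - beta) * M` and `(1 - beta) * F + beta * M`; each gene
  mutates to a uniform draw over its bounds with probability
  `mutation_rate`. Offspring genders are balanced one female, one male.

Globally, nomad females mate with nomad males the same way; nomad males
optionally roam the whole search space (`nomad_walk`); **defense** evicts the
weakest resident males beyond the pride's male quota and lets stronger
nomad males (attacking with probability 0.5) displace weaker residents;
**migration** moves each pride's surplus females plus
`round(immigration_fraction * quota)` randomly chosen females to the nomad
pool, then refills vacancies with the fittest nomad females; **equilibrium**
removes exactly the number of worst nomads needed to restore
`population_size`, taking genders above their nomad cap first.

These defaults — `population_size = 500`, `nomad_ratio = 0.2`,
`num_prides = 5`, `female_ratio = 0.8`, `roaming_fraction = 0.2`,
`mating_fraction = 0.3`, `mutation_rate = 0.2`,
`immigration_fraction = 0.4` — are the published operating point of the
method. They suit expensive, low-dimensional continuous problems; the
wrapper selector below deliberately uses a smaller budget.

Invariants the implementation guarantees (and the test suite asserts):

* the census equals `population_size` after every full iteration;
* the best-so-far fitness trace is monotonically non-increasing;
* pride gender quotas are never exceeded after defense/migration;
* identical configuration and seed reproduce the trace bit for bit. Ties
  are always broken by lion id, and all randomness flows from the single
  `seed` in `loa_config()`.

```{r loa-demo, eval = FALSE}
cfg <- loa_config(nvar = 5, population_size = 50, num_prides = 4,
                  max_iterations = 200, patience = 0,
                  lower_bounds = rep(-5, 5), upper_bounds = rep(5, 5),
                  seed = 1)
res <- loa_optimize(function(x) sum(x^2), cfg)
res$best_fitness
```

## Wrapper feature selection

`loa_select()` runs the optimizer over the continuous cube `[0, 1]^d`; a
position decodes to a feature mask by thresholding at 0.5 (an all-zero
decode falls back to the largest coordinate, so the mask is never empty).
The fitness of a mask is the repeated stratified 5-fold cross-validated
error of a classifier restricted to the masked features, plus an optional
sparsity penalty `lambda * selected / d` (`lambda = 0` by default, so
parsimony is an emergent property rather than an imposed one).

Two design choices matter here:

* **The wrapped classifier defaults to Manhattan-distance kNN.** A
  max-margin or maximum-likelihood separator (e.g. logistic regression) can
  reach exactly zero CV error on near-separable tables through many
  different masks — including masks full of noise features — which flattens
  the fitness landscape and leaves the optimizer nothing to rank. Distance
  votes degrade smoothly as noise features dilute the metric, so kNN keeps
  the landscape informative and the selector recovers planted informative
  features reliably.
* **Fitness averages over three independent fold assignments** (derived
  seeds). Scoring against one fixed partition lets the search overfit that
  partition: the winning mask looks perfect under the internal folds and
  mediocre under any other. Averaging costs 3x per evaluation and removes
  most of this winner's curse. Fold assignments are fixed per call, and
  fitness values are memoized per decoded mask, so the optimizer never pays
  twice for the same mask.

The default search budget (`population_size = 30`, 3 prides, 40 iterations,
patience 15) is the package's own choice for tables of tens to a few
hundred features; pass an explicit `loa_config()` to change it.

Classical reducers are provided for comparison and for chaining:
`pca_reduce()` (eigendecomposition of the `1/n` population covariance),
`lda_reduce()` (generalized Fisher directions of `Sw^{-1} Sb`, with a ridge
of `1e-6 * tr(Sw)/d` for numerical rank safety) and `rfe_select()`
(recursive feature elimination, one feature per round, importance from
squared standardized logistic coefficients, squared linear-SVM weights, or
random-forest importance). The pipeline accepts chained selectors such as
`"pca+loa"` — classical stage first, wrapper on its output.

## Classifiers, metrics and protocols

Seven classifiers sit behind one `fit_predict()` contract: linear-kernel
SVM, logistic regression, decision tree, Manhattan kNN, random forest,
gradient-boosted trees and Gaussian naive Bayes. Standard learners are
delegated to their established implementations (`e1071`, `rpart`,
`randomForest`, `xgboost`); the Manhattan-metric kNN is implemented in the
package because no installed dependency provides that metric.

Metrics are reported on the 0-100 scale, with label 1 ("with pest") as the
positive class: `A = (TP+TN)/N * 100`, `P = TP/(TP+FP) * 100`,
`R = TP/(TP+FN) * 100`, `F1 = 2PR/(P+R)`. Zero denominators yield 0 with a
warning so report grids never abort. Splits are always stratified: an 80/20
holdout and k-fold assignments whose per-class counts differ by at most one
across folds. All split helpers save and restore the caller's RNG state.

## Images, filtering, augmentation and features

Images are `[0, 255]` matrices (grayscale) or `H x W x 3` arrays. Filters
(median, Gaussian with kernel `G(x) = exp(-x^2/(2 sigma^2))/(2 pi sigma^2)`
renormalized to sum 1, average) use reflective borders and clip back to
`[0, 255]`; the median-filter pass schedule uses odd sizes `a = 2A - 1`.
Augmentation produces seven variants per image: horizontal flip, vertical
flip, 15-degree rotation, shear, a 20% contrast increase, reflection and a
brightness shift; flips are exact pixel permutations, resampling is
bilinear with zero fill.

Feature extraction is pluggable via `backbone_spec()`. The `"mock"` backbone
is a deterministic, weight-free extractor: resize to 224 x 224 x 3, scale to
`[0, 1]`, then concatenate a translation-invariant block (33 per-channel
intensity quantiles, interleaved probability-major so any prefix spans the
whole intensity distribution) and a spatial block (mean and sd of each cell
of an 8 x 8 patch grid per channel), truncated to `output_dim` (default 256,
at most 483). An earlier design projected the pooled statistics through a
fixed dense random matrix and was rejected: when object positions vary
across images, randomly signed mixtures convert a consistent one-sided
intensity shift into class variance, destroying separability — the quantile
block restores the translation invariance a convolution-plus-pooling
backbone would provide. The mock stands in for pretrained CNN
penultimate-layer features (VGG16/19 at 4096 dimensions, ResNet50,
InceptionV3, Xception at 2048), whose names are accepted but which require
an optional deep-learning toolchain the package does not bundle; requesting
them raises an actionable error.

## Synthetic generators and calibration

`generate_feature_table()` draws a two-class Gaussian table: class 0 is
`N(0, sd)` everywhere, class 1 shifts the first `n_informative` features by
`separation * sd`. The informative index set is returned, which makes
selector *recovery* a measurable quantity. With the default operating point
(200 samples per class, 50 features, 10 informative, separation 2) the
all-features problem is easy but the informative subset is identifiable only
through the data. `generate_toy_images()` builds textured backgrounds with
(for the pest class) one to three dark elliptical blobs, so pest images are
linearly separable from backgrounds via pooled intensity statistics — a toy
with known structure, not a simulation of field imagery.

Calibration checks in the test suite: at `separation = 0` holdout accuracy
stays at chance level across replicate seeds, at large separation it
approaches 100, and large-sample moments match the generative model.

## Numerical conventions

* All operators clip positions into the configured bounds.
* Distances below `1e-12` are treated as zero (no move, no division).
* `theta` ranges: `U(-pi/2, pi/2)` for safe-place (the tangent's heavy tails
  supply occasional long jumps), `U(-pi/6, pi/6)` for roaming.
* Ties (tournaments, evictions, culls, refills) break by lion id, making
  every operator a deterministic function of (state, RNG stream).
* Seeded helpers (`holdout_split`, `stratified_folds`, the data generators)
  save and restore the global RNG, so library calls never perturb
  user-level reproducibility; mock feature extraction uses no randomness at
  all.
* Report provenance includes an MD5 hash of the configuration and the run
  seed; timestamps are informational and excluded from determinism
  guarantees.

## Limitations

* The optimizer targets box-bounded continuous problems; the binary mask
  space is reached only through the threshold decoding.
* The mock backbone is not a CNN: its features are sufficient for the toy
  generators and for exercising the selection machinery, not for real
  imagery.
* Wrapper fitness is an internal CV error; reported holdout metrics are
  computed on data the selector never saw, but a nested outer protocol is
  the user's responsibility when comparing selectors.
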