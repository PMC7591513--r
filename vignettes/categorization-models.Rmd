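---
title: "Prototype and exemplar models over high-dimensional embeddings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype and exemplar models over high-dimensional embeddings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protex)
```

## The modeling problem

Given a real-valued embedding $y \in \mathbb{R}^{N_d}$ for each stimulus and,
for each stimulus, counts of how often human raters assigned it to each of
$N_c$ categories, we ask which similarity-based categorization strategy best
predicts the full distribution of human choices — not just the modal label.
The package treats the embedding source as given (pixels, HOG descriptors,
CNN activations, or synthetic Gaussian clusters all enter the same way) and
models only the mapping from embeddings to choice distributions.

All models share the Luce–Shepard choice rule: the probability of choosing
category $i$ is

$$p(i \mid y) = \frac{S(y, C_i)^{\gamma}}{\sum_j S(y, C_j)^{\gamma}},$$

where $\gamma \ge 0$ is a freely estimated response-scaling exponent
($\gamma \to 0$ gives random responding, $\gamma \to \infty$ deterministic
choice), and $S$ is an exponentially decaying function of squared distance.
Distances are squared diagonal-Mahalanobis forms
$\sum_k c_k (y_k - z_k)^2$, so each variant amounts to a choice of
reference points and diagonal inverse covariance:

| variant | reference | metric | free parameters |
|---|---|---|---|
| classic prototype | category mean | identity | $\gamma$ (1) |
| linear prototype | category mean | shared $c$ | $N_d + 1$ |
| quadratic prototype | category mean | per-category $c_i$ | $N_c N_d + 1$ |
| exemplar (uniform) | all members | $\beta \cdot \mathbf{1}/N_d$ | $\gamma, \beta$ (2) |
| exemplar (attention) | all members | $\beta w$, $w$ on the simplex | $N_d + 2$ |

Exemplar similarity is the *sum* of member similarities,
$S(y, C) = \sum_{x \in C} \exp\{-\beta \sum_k w_k (x_k - y_k)^2\}$ — a
soft-nearest-neighbors rule whose boundary complexity grows with the stored
set. Prototypes are always the empirical means of the ground-truth category
members, never free parameters. The shape exponents are fixed at
$q = r = 2$ (integral stimulus dimensions).

Two modeling choices deserve emphasis. First, the "classic" model uses the
*squared* Euclidean distance — the identity-metric special case of the
quadratic family — so all five variants are nested in a single Mahalanobis
framework. Second, the exemplar set for a category is the full set of
ground-truth members of the supplied feature table, including the query
stimulus itself when it is a member; an `exclude_self` flag is available
but off by default, because the dataset-scale likelihood the package is
designed for compares each stimulus against every stored member.

## Numerical treatment

Similarities underflow catastrophically in high dimensions
($\exp\{-d\}$ with $d$ in the hundreds), so all similarity arithmetic is
carried in log space: per-category log similarities feed a log-sum-exp
normalization of $\gamma \log S_i$. The exemplar sum is itself a
log-sum-exp over members. The identity between the direct
similarity-power form and the log-space form is asserted to $10^{-10}$ in
the test suite, as are the family reductions (linear with constant $c$
collapses to classic with $\gamma$ absorbing the scale; a one-exemplar-per-
category model placed at the prototypes collapses to classic).

Constrained parameters are optimized in unconstrained coordinates:
$\log \gamma$, $\log \beta$, $\log c$, and softmax logits for the attention
weights, so positivity and the sum-to-one constraint hold by construction.
Fold-averaged parameters are averaged in these coordinates and
re-transformed, which keeps the constraints exactly satisfied (attention
weights are effectively combined by a normalized geometric mean).

## Fitting procedure

`fit_model()` partitions *stimuli* (not individual judgments) into
`n_folds = 5` cross-validation folds; batching and fold membership operate
per image, mirroring how the behavioral data are organized. Each fold's
training stimuli are visited in mini-batches (default 256 stimuli) and the
negative log likelihood is minimized with Adam. After every epoch the
held-out negative log likelihood per judgment is averaged across folds;
training stops when this trace has not improved for `patience = 10` epochs
(granularity one epoch), and the epoch minimizing the trace is selected.
The returned parameters are the unconstrained-space average of the five
fold parameters at that epoch. `grid_search()` repeats this over a small
learning-rate × decay grid (defaults $\{10^{-3}, 10^{-2}, 10^{-1}\} \times
\{0, 10^{-4}\}$) and keeps the cell with the lowest cross-validated
likelihood; cells that diverge to non-finite loss are discarded rather
than selected.

### Identifiability and what recovery tests check

Because the inverse-variance vectors are unconstrained in scale, any
common factor of $c$ can migrate into $\gamma$: linear and quadratic
prototype likelihoods depend only on the product $\gamma c$. Recovery
checks for these variants therefore assert (a) the rank ordering of the
recovered dimension weights against the truth and (b) the identifiable
scale product $\gamma \cdot \overline{c}$, rather than $\gamma$ alone.
For the exemplar variants $\gamma$ and $\beta$ are separately identifiable
(the log-sum-exp is nonlinear in $\beta$), but only weakly so when
responses are saturated: if nearly every stimulus is classified
unanimously, the likelihood is almost flat along $\gamma\beta \approx
\text{const}$. The recovery studies therefore generate data at moderate
separability (mean inter-prototype distance 2.5 with unit within-category
spread, mean guess entropy well inside the observable range), where the
response distributions are informative about both parameters. This is a
property of experimental design, not of the fitting code: a recovery study
run at saturation would be uninformative about $\gamma$ for any estimator.

Recovery studies use 1000 stimuli (100 per category), 8 embedding
dimensions and 50 raters per stimulus; at that size each variant's
recoverable parameters come back within a few percent.

## Evaluation metrics

* **Negative log likelihood** over all stimuli, computed from the
  fold-averaged parameters, and **AIC** $= 2k - 2\hat{L}$ with $k$ the
  free-parameter count in the table above. The identity
  $\mathrm{AIC} = 2k + 2\,\mathrm{NLL}$ is asserted on every report.
* **Entropy stratification.** Guess entropy is computed in natural log:
  with ten categories and guesses rarely spread beyond four, the
  operational range 0–1.37 nats ($\ln 4 \approx 1.39$) is consistent with
  the conventional bin edges 0.64 and 1.0, which a base-2 or base-10
  convention would not be. Binning uses *unsmoothed* proportions: plus-one
  smoothing (which the package also implements, for entropy reporting)
  cannot produce an entropy of exactly 0 at ~50 raters, while the lowest
  bin's floor is 0. Stimuli exactly on an edge fall in the lower bin.
* **Floored Spearman correlation.** Model probabilities strictly below
  0.04 — the resolution of ~50 raters (two guesses in fifty) — are set to
  zero before rank-correlating with the human proportions; this stops
  vanishing model probabilities over never-chosen categories from
  injecting ordering noise. Ties receive average ranks (flooring creates
  many zeros). A probability of exactly 0.04 is kept. If both vectors are
  constant the correlation is 1 when their ranks agree and undefined
  otherwise; undefined cases are excluded from bin averages.
* **Second-best accuracy.** The model's second-ranked category is compared
  with the humans' second-most-common choice. A human tie at second place
  counts as correct if the model matches any tied label; stimuli with
  fewer than two chosen categories leave the denominator.
* **Noise ceiling.** Per stimulus, raw judgments are split into random
  halves, the halves' proportion vectors are Spearman-correlated, the
  Spearman–Brown correction $2r/(1+r)$ is applied, and the result is
  averaged over 100 splits. This estimates how well a model could possibly
  predict one half of the raters from the other.

## The dimensionality simulation

The simulation asks when a zero-parameter nearest-prototype classifier and
a one-parameter exemplar classifier (only $\beta$ estimated; all other
parameters 1, i.e. unweighted squared Euclidean distances) differ in test
accuracy, as category complexity, dimensionality and training-set size
vary. Categories are built from Gaussian components with standard-normal
means. Covariances are identity for the *linear* regime and scaled Wishart
draws otherwise: $\Sigma = W/d$ with $W \sim \mathrm{Wishart}(I, d)$, so
$\mathbb{E}[\Sigma] = I$ and the degrees of freedom $d$ act purely as a
conditioning knob — $d = N_d + 20$ (simple/medium/complex) yields
well-conditioned covariances, $d = N_d$ (ill-conditioned regime) extreme
anisotropy. We deliberately normalize so the expected covariance is the
identity: a covariance whose magnitude grew with $d$ would confound
conditioning with overall scale. The *medium* regime groups the closest
pair of four component means into category 1; *complex* and
*ill-conditioned* pair the four components at random; mixtures weight
their components evenly. In the *linear* regime the two means are pushed
apart along their difference direction to distance 8, far enough that the
Bayes accuracy for unit-variance Gaussians is essentially 1 — making
"linearly separable" unambiguous.

Each grid cell averages a fresh set of replicate category pairs; each
replicate draws its own training set (per-category size swept) and 100
test stimuli per category. The exemplar's $\beta$ is selected from 13
log-spaced values $2^{-6} \ldots 2^{6}$ by 5-fold cross-validated training
accuracy, ties going to the smaller (smoother) $\beta$; prototype
decision ties break toward the lower category index (a measure-zero
event). The packaged acceptance run sweeps regimes {linear, complex} ×
dimensions {2, 32, 256} × training sizes {16, 512} with 30 replicates per
cell — enough to resolve the qualitative pattern (exemplar advantage for
complex low-dimensional categories with many samples; convergence of the
two strategies in high dimensions; both at ceiling for linearly separable
categories at any dimensionality) while keeping a desktop-scale runtime.
The full-scale design with 300 replicates per cell is available by
changing one configuration field.

## The synthetic-data generator

`synthesis_config()` + `generate_dataset()` emulate the statistical shape
of a large soft-label categorization dataset: cluster-structured
embeddings (isotropic Gaussian categories with controllable separation
and spread, optionally with designated category pairs pulled together to
plant confusions) and guess counts drawn i.i.d. from a known rater model's
choice probabilities (~50 raters per stimulus). Category means are
rescaled after drawing so the realized mean inter-prototype distance
equals the configured separation exactly, which removes draw-to-draw
variability in the difficulty of the generated problem.

The default separation of 5 (with unit spread, 8 dimensions, a classic
prototype rater at $\gamma = 0.5$) was calibrated once against the
qualitative profile of crowd-sourced image-categorization data: roughly
85% of stimuli in the low-entropy bin, about 40% with perfect consensus,
and a right-skewed entropy tail — alongside structured confusions when
pairs are planted. Features of real data the generator deliberately does
*not* emulate: rater-level effects (all draws are i.i.d. given the
stimulus; the models fitted here have no rater parameters), perceptual
noise correlated across stimuli, non-Gaussian category shapes in the
embedding, and any actual image content. Passing recovery and closure
tests on these data therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not that real human data
follow those assumptions.

## Degenerate inputs and edge rules

Empty categories error (naming the category) in prototype computation and
exemplar grouping. Counts must be non-negative integers with at least one
judgment per stimulus; misaligned stimulus ids between feature and guess
tables error rather than silently reorder. `gamma = 0` is valid (uniform
responding); `beta` must be strictly positive. Noise-ceiling estimation
requires at least four raw judgments per stimulus. Non-finite training
loss aborts the fit with the offending batch reported; in a grid search
such cells are recorded as diverged and never selected.

## Problem sizes used in the shipped checks

Unit and property tests run on datasets of tens to hundreds of stimuli.
The recovery studies use 1000 stimuli × 50 raters per variant; the
simulation acceptance grid uses 30 replicates per cell with 200 test
stimuli each. These sizes are the package's own defaults for a
desk-scale, fully reproducible verification run; all of them are plain
configuration fields that scale up unchanged.

## Known limitations

* Only diagonal inverse covariances are supported; full matrices would
  need far more behavioral data plus regularization, and are out of scope.
* The optimizer is plain mini-batch Adam; second-order methods and
  regularization beyond early stopping are not provided.
* Baseline models consume an external probability matrix; the package
  does not extract features or train classifiers.
* Exemplar fitting precomputes per-dimension pairwise squared-difference
  matrices, so memory grows as $N_d \times N^2$ for attention-weighted
  fits; at the shipped sizes this is tens of megabytes, but very large
  stimulus sets would need chunking.
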