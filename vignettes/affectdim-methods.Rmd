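---
title: "Methods: testing whether classifier outputs reduce to core affect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing whether classifier outputs reduce to core affect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectdim)
```

## The question and the data model

A facial-physiology classifier assigns each video stimulus a probability
vector over five emotion categories (amusement, disgust, fear, neutral,
sexual desire); the probabilities are nonnegative and sum to 1, so each
stimulus is a point on the 4-simplex. Alongside this, each stimulus has
stimulus-level affect norms — mean valence and arousal on a 1–9 Likert
scale with 5 anchoring neutral, aggregated over a rater panel — and the
fraction of participants endorsing each discrete emotion label
(multi-select plus a "none of the above" option, so endorsement rows need
not sum to 1).

The *core affect* view predicts that the classifier's output is a
function of two latent dimensions: any five-way structure in it should
survive projection onto two dimensions, and valence + arousal should
predict it about as well as anything. The *discrete* view predicts
five-way structure that no two-dimensional representation preserves.
`affectdim` operationalizes this contrast three ways: cluster fit before
and after dimensionality reduction, predictor-set comparison by pooled
cross-validated R², and a reliability analysis that rules out "the affect
norms were just noisy" as an explanation.

## Cluster evaluation

The five classifier outputs are z-scored column-wise (mean 0, sample sd 1
with the n−1 denominator; a constant column is an error rather than a
silent division by zero), then clustered agglomeratively with the
complete-linkage rule under Euclidean distance and cut at *k* clusters.
Agreement with the validated categories is normalized mutual information
with natural logarithms,

$$\mathrm{NMI} = \frac{2\,I(T;C)}{H(T) + H(C)},$$

the arithmetic-mean normalization — chosen as the default because it is
symmetric and the most common convention; `min`, `max` and `geometric`
normalizations are selectable in `nmi()`. NMI is base-invariant under any
matched normalization, so the log base is a pure implementation detail.
Conventions for degenerate input: any table with a zero-entropy marginal
(everything in one cluster) scores 0, and tiny negative mutual
information from floating-point rounding is clamped to 0.

`nmi_curve()` cuts one tree over a k range (default 2–10) rather than
re-clustering, so the curve is deterministic and cheap. Cluster-to-
category naming (`majority_cluster_labels()`) takes the modal category
per cluster, breaking ties toward the earliest category in canonical
(alphabetical) order and flagging them.

**The permutation test.** `nmi_permutation_test()` compares how well two
representations of the *same* stimuli fit the categories at a common k.
Both clusterings are computed once and held fixed; the statistic is
NMI_A − NMI_B; the null is built by jointly permuting the category labels
across stimuli and recomputing both NMIs per draw; the one-sided p-value
is (1 + #{permuted ≥ observed}) / (B + 1), so p can never be 0 and equals
1/(B+1) when the observed difference beats every draw. Permuting labels
with clusterings fixed conditions on the observed geometry and tests
exactly the reported contrast — "does representation A's partition align
with the categories better than B's" — rather than re-estimating
clusterings under the null, which would mix clustering variability into
the question. The default B = 10,000 keeps the p-value granularity well
below conventional thresholds; B ≥ 99 is enforced.

## Dimensionality reduction

`pca_fit()` is a column-centered covariance eigendecomposition. In the
standard pipeline it runs on already z-scored features, which makes
covariance and correlation PCA coincide — one fewer arbitrary choice.
Component signs are fixed by making each component's largest-magnitude
loading positive. Because simplex rows lose one dimension after
centering, at most four of the five components carry variance.
Re-clustering "in the two-dimensional space" uses the raw leading-two
scores without rescaling them: the scores are already centered, and
rescaling would reweight the components relative to the variance
structure PCA just estimated. t-SNE (`tsne_embed()`, exact O(n²),
perplexity 10, seeded) is provided for figures only and feeds no
quantitative result.

## Model comparison by pooled cross-validated R²

Each model predicts a five-column outcome — the classifier probability
vector, or the five label endorsements — from one predictor set:
`core_affect` (valence, arousal), `discrete` (the five endorsement
fractions; the optional none-of-the-above column is stored but never
enters predictor sets), or `combined` (all seven). One regression is fit
per outcome column; fit is pooled over columns,

$$R^2 = 1 - \frac{\sum_t \mathrm{SSR}_t}{\sum_t \mathrm{SST}_t},$$

computed on out-of-fold predictions. The SST baseline is the observed
mean of each target over the rows being scored: the grand mean for the
headline pooled value, the test-fold mean for per-fold values (both are
reported — the alternative conventions differ and neither is derivable
from the other). Predicted probability columns are deliberately not
renormalized onto the simplex; each target is fit independently, and a
log-ratio-transform alternative is documented as out of scope.

Folds are stratified by category with a global balancing rule
(per-stratum remainders go to the currently smallest folds), so with 130
stimuli in 5 balanced categories and 10 folds every fold has exactly 13
items with 2–3 per category. One fold assignment is shared by every model
in a comparison, making per-fold R² values paired; pairs of models are
summarized by the mean per-fold difference and an exact fold-paired
sign-flip test (all 2^K sign patterns enumerated for K ≤ 14 folds).
Cross-validation alone is used throughout — no additional single holdout —
as the cleaner reading of a k-fold design.

The linear family uses least squares with predictors standardized by
training-fold statistics; an exactly singular design falls back to ridge
with penalty 1e-8 and a logged message. The kernel family is
ε-insensitive support vector regression (via `e1071`) with radial,
linear, polynomial, or sigmoid kernels. Random-search tuning draws cost
from log-uniform [1e-2, 1e3], kernel width γ from log-uniform [1e-3, 10],
ε from log-uniform [1e-3, 1], and polynomial degree from {2, 3, 4};
each draw is scored by pooled R² under an inner 5-fold split of each
outer training fold only, averaged over outer folds, and the single best
draw is returned. The nested design is deliberately conservative: tuning
never sees the reporting folds, so tuned test R² is not optimistically
biased, at the cost of not matching workflows that tune on the reporting
folds. Default 50 draws.

## Reliability

`split_half_reliability()` reads "randomly divide the panel and correlate
the halves' per-video means" literally: disjoint equal halves drawn
without replacement per run (an odd rater is dropped at random for that
run), Pearson correlation across videos per dimension (Spearman behind a
flag), 10 runs by default, and the per-run correlations averaged. Under
the generator's noise model the expectation has the closed form
τ² / (τ² + 2σ²/m) for stimulus-mean sd τ, rater noise sd σ, and panel
size m — the package's Monte-Carlo check against this form at
τ = σ = 1, m = 100 (expected 0.9804) is what licenses interpreting the
statistic as a reliability.

## The synthetic generator

The generator emulates the study shape: 26 stimuli per category (130
total), a 110-rater panel, category mean valences matching reported norms
(neutral 5.21, amusement 6.57, fear 3.73, disgust 2.82, sexual desire
5.51). No arousal norms are published, so arousal defaults (neutral low
at 2.8, the emotional categories 5.8–7.2) are free parameters chosen once
to separate neutral from the rest. Stimulus-level affect jitter and
rater noise share one sd, σ_e = 0.8 Likert points, a typical single-rater
spread for affect scales.

*Discrete regime.* Probability vectors are Dirichlet draws around
category centroids with own-class mass 0.6 and 0.1 elsewhere
(concentration κ = 30 by default; the five centroids span four simplex
dimensions, so no plane holds them). Endorsements track the centroid
profile, scaled by a fidelity parameter (0.9) plus clipped Gaussian noise
(sd 0.05).

*Core-affect regime.* Noise-free probabilities are an affine map of
centered (valence, arousal) onto the simplex, with the map's class
directions pointing at the category affect means and its gain set to the
largest value keeping every probability ≥ 0.02 over the whole [1, 9]²
square — so rows sum to 1 exactly and the centered probability matrix has
rank ≤ 2 *by construction*, making the regime's dimensionality claim true
rather than approximate. Noise perturbs the log-probabilities with
Gaussian sd 0.5 and renormalizes through softmax, which reduces exactly
to the identity at zero noise. Endorsements come from the same two
latents through a fixed monotone logistic link. Dirichlet noise for the
discrete regime versus logit-Gaussian for core affect keeps each regime's
dimensionality structure exact.

Out-of-range ratings are clipped to [1, 9] rather than resampled —
simple and monotone. A root seed spawns independent per-stage substreams
(`derive_seed()`), so adding a stage never perturbs earlier draws and
identical (config, seed) pairs are bit-reproducible.

**What the generator does not emulate.** Real classifier outputs have
fold-to-fold dependence from leave-one-out training, raters disagree
systematically (not i.i.d. Gaussian), category sizes and endorsement
profiles are not exactly balanced or symmetric, and real probability
vectors concentrate near simplex faces in stimulus-specific ways. Passing
the regime-recovery checks therefore shows the *pipeline* distinguishes
the two generative structures when they hold exactly — it does not show
which structure real data follow, and the package makes no claim to
reproduce statistics computable only from the original study data.

## Problem sizes and test design

The test-suite and acceptance-script study conditions are: 130 stimuli
per replicate, 50 replicates for each linear-family regime-recovery
check (10 for the kernel family), 500 null replicates at B = 199 for the
permutation-calibration study on 60 items, 1,000 random tables/vectors
for the NMI and R² oracle comparisons, 200 instances at n ≤ 7 for the
linkage oracle, and 20 simulated 100-rater panels for the reliability
closed form. These sizes put Monte-Carlo error comfortably inside each
check's tolerance while keeping the whole suite fast to run routinely.

## Known limitations

- The pooled-R² SST convention and the hyperparameter-tuning protocol of
  published analyses in this design are typically unstated; where a
  convention had to be fixed, the choice is documented above and both
  variants are surfaced where feasible. Numerical agreement with a
  specific published table cannot be expected without its data.
- "Overall accuracy" is the unweighted macro mean of per-category rates;
  with unbalanced category sizes a weighted mean would differ.
- Compositional outcomes are fit per-column without a simplex-aware
  transform; predicted vectors need not lie on the simplex.
- Complete linkage with tied merge distances follows `stats::hclust`'s
  dendrogram construction; ties have probability zero for continuous
  features but can occur in constructed examples.
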