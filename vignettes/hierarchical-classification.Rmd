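---
title: "Hierarchical top-down classification and taxon prediction"
author: "HiClassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical top-down classification and taxon prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiClassify)
```

## The model

Biomolecular classes are frequently organized in a taxonomy: bacteria run
from Gram stain down through class, order, family and genus to species;
cancer samples split into morphological types and molecular subtypes. A
*flat* classifier over all terminal classes ignores this structure, which
hurts in two ways: discrimination degrades as the number of classes grows,
and a sample from a class absent from the training database can only ever
be wrong. HiClassify instead trains one *local* discriminant model per
internal node of the taxonomy and classifies *top-down*: a sample enters at
the root, is assigned to the child with the highest probability, and
descends recursively. Because each decision is local, a sample from an
unknown terminal class can still be routed correctly at upper levels —
often all that is needed to act (e.g. choosing an antibiotic regimen by
genus rather than species).

Each node model is a dimensionality-reduction/discriminant step followed by
a probabilistic layer:

1. one of four linear methods, chosen *per node* by nested cross-validation:
   - **PLS (SIMPLS)** — components maximize covariance between the data and
     class membership (between-class variance, ignoring within-class
     variance), computed by direct deflation;
   - **MMC-LDA** — projection onto the top eigenvectors of $S_b - S_w$
     (between- minus within-class scatter), which maximizes the margin
     criterion $w^\top(S_b - S_w)w$ without inverting $S_w$, so it tolerates
     tiny classes;
   - **PCA-LDA (Fisherfaces)** — PCA to $\min(n - c,\, d)$ dimensions, then
     Fisher LDA ($S_b w = \lambda S_w w$) in that subspace, which sidesteps
     the singular-$S_w$ problem when features outnumber samples;
   - **linear SVM** — one-vs-all maximum-margin hyperplanes; only the
     explicit normals and offsets are kept, so the model serializes like the
     projection methods.
2. a one-vs-all logistic regression layer on the reducer scores (a single
   symmetric model when a node has exactly two children), normalized to a
   probability distribution over the children. The sample takes the argmax
   child.

Two rules govern the descent. The **non-classification threshold**
$\delta$: when the gap between the two largest child probabilities is below
$\delta$, the sample halts as *non-classified* at that level rather than
guessing. The **single-offspring rule**: a parent with exactly one
downstream node would accept everything, so its single child is instead
discriminated against the offspring of the parent's sibling nodes, and a
sample whose winning class is not the single child halts as non-classified.

## Method selection and evaluation

`crossValidate()` splits the data into stratified outer folds. Within each
outer training portion only, every internal node runs all four methods on
identical stratified inner folds; the method with the highest mean inner
accuracy wins, and the per-node record of winners (the *method map*) is
then applied to the outer test fold. Outer test samples never touch method
selection or node fitting, which a leakage test asserts. The whole
procedure is repeated with re-randomized folds and reported as per-level
mean ± sd accuracies plus per-level confusion matrices carrying an explicit
`non_classified` column. A sample is counted correct at a level only if its
path passes through the true ancestor there, so per-level accuracy is
non-increasing with depth by construction.

Ties in method selection are broken by the fixed priority
PLS > MMC-LDA > PCA-LDA > SVM. Breaking ties by measured wall-clock time
would make runs irreproducible; the fixed order encodes the same intent
(prefer the cheapest method) deterministically. The PLS component count is
tuned on the same inner folds over the grid {1, 2, 3, 4, 6, 8, 10, 12, 15}
capped at $\min(15, n-1, d)$, with ties going to the smaller count; LDA-type
methods always use $c - 1$ components. Effective fold counts shrink
automatically to the smallest class size (with a warning) instead of
prompting the user interactively. Fold assignment is a pure function of the
seed, the repetition index and the sample order, so identical seeds
reproduce the method map and the confusion report bitwise.

Unpenalized logistic maximum likelihood diverges under perfect separation,
which is routine at well-separated nodes; the iteration is capped and the
(finite, deterministic) coefficients kept, falling back to a tiny ridge
(`1e-8`) only for collinear designs. Probabilities from the one-vs-all
models are normalized by their sum; argmax ties resolve by child order in
the tree.

## Predicting unknown classes

`leaveOneClassOut()` removes a terminal class entirely, prunes ancestors
left childless, re-derives the method map and retrains on the remaining
subset, then routes the held-out samples top-down with the
$\delta$-threshold active. The sensible evaluation point is
`highestPredictionLevel()`: the deepest ancestor whose existence does not
depend on the held-out leaf (an ancestor left childless is pruned away, so
evaluation moves up automatically for an only child). Accuracy is the
fraction of held-out samples whose trajectory passes through the true
ancestor at that level, averaged over repetitions.

The numeric value of $\delta$ is a genuinely open choice; the rule itself
is what matters. The default is 0.05 — small enough not to halt confident
descents, large enough to catch coin-flip decisions — and it is exposed in
`predictionConfig()`. Raising $\delta$ can only shorten a trajectory, never
deepen it, and the test suite asserts this monotonicity.

## Preprocessing chains

The spectral chain (`preprocessSpectra()`) reproduces a profile-mode
mass-spectrometry workflow: import at fixed resolution (default 0.001 Da
over 150–2000 m/z, half-open bins, intensities summed per bin); adaptive
noise thresholding per spectrum by maximizing between-class variance of the
histogram of nonzero log-intensities (Otsu's criterion, 256 bins — the
standard parameter-free "histogram-based optimum threshold"); retention of
the top five replicates per sample by post-threshold total ion current
(ties keep the earlier replicate); peak detection by Savitzky–Golay
filtering (order 3, window 11 bins) with apexes at positive-to-negative
zero crossings of the smoothed first derivative; alignment of apex lists
across spectra by Gaussian kernel density estimation (bandwidth 0.003 Da)
on the pooled apex positions, taking within each density mode the m/z with
the highest peak count as the common feature and assigning each spectrum's
peaks to the nearest feature within 3 bandwidths; replicate averaging per
sample; median-fold-change normalization; and a `log(1 + x)` variance
stabilization motivated by the intensity-dependent technical variance of
spectral data. The phrase "third-order derivative Savitzky–Golay peak
picking" admits several readings; this package fits order-3 polynomials and
detects apexes on the first derivative, with both the window and order
configurable.

Median-fold-change normalization divides each sample by the median of its
nonzero ratios to the feature-wise median spectrum, so every sample's
median fold change to that reference is exactly 1 afterwards. The reference
is computed once from the input; zeros are excluded from ratios as a
division guard.

The expression-table chain (`filterSamples()`, `normalizeLog2()`) applies,
in order: removal of normal-tissue samples and of dubiously annotated genes
(a user-supplied pattern, by default `?`-prefixed symbols — no hard-coded
gene list); retention of one seeded-random sample per patient; and removal
of subtypes below 15 samples. Ordering the size filter after
deduplication means subtype sizes are counted at the patient level. The
operation is idempotent. Normalization is the shared median-fold-change
followed by `log2(1 + x)`.

## What the synthetic generators emulate

`genHierarchicalGaussians()` draws class means recursively — children
scatter around their parent mean at a per-level separation expressed in
units of the within-class standard deviation — and samples isotropic
Gaussians around leaf means. It emulates the *hierarchical* structure of
real data (classes nested in higher taxa, adjustable signal strength per
level) but not its messiness: no heavy tails, no correlated features, no
batch effects (a heteroscedastic option scales noise with signal to mimic
spectral variance). Passing tests on this generator therefore demonstrates
that the machinery is correct and calibrated, not that any particular real
dataset will reach a particular accuracy.

`genSyntheticSpectra()` plants known peak positions per class and renders
replicate profile spectra with m/z jitter, per-spectrum multiplicative
scale and additive half-normal baseline noise, so pipeline recovery of
positions and dilution factors can be checked against ground truth.

One geometric caveat discovered with these generators and worth stating
plainly: when the per-level separations are *equal* (e.g. 6σ at every
level), a held-out terminal class is as far from its own parent's remaining
leaf as the parents are from each other, and upper-level routing of the
unknown class becomes genuinely ambiguous — the near-zero-Bayes-error
premise of unknown-class prediction holds only when upper-level separations
dominate the within-parent spread, as they do in real taxonomic data
(Gram types differ far more than congeneric species do). The leave-one-out
machinery is exercised under both regimes in the tests; under the
equal-separation regime some leaves route below the 95% mark, and this is a
property of the geometry, not of the estimator.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to finish in minutes while
keeping every estimate stable: hierarchies of branching [2, 3, 2] (12
leaves, 360 samples, 50 features) for classification and unknown-class
prediction, 20 generator seeds for the chance-level calibration, and
two-class ten-peak spectra (30 replicate spectra, 2000 bins at 0.001 Da)
for the pipeline. Projection sign is fixed by making each column's
largest-magnitude element positive, so results are reproducible across
linear-algebra backends. Scatter matrices use biased (divide-by-n) scaling
throughout; only relative scaling reaches the eigenvectors. Rank-deficient
inputs truncate PLS components with a warning; constant matrices are
rejected as zero-variance.

## Limitations

- The four node methods are linear by design (scalability and transparent
  loadings); kernel methods and regularized LDA variants are out of scope.
- Logistic layers are fitted on training scores, not on held-out
  calibration folds, so probabilities near the decision boundary are
  optimistic; the probability-difference rule uses gaps, which are less
  affected.
- Accuracy is reported both counting non-classified samples as errors and
  excluding them; the two coincide when $\delta = 0$ and no
  single-offspring node fires.
- Hierarchical error propagates: a mistake at one level forecloses all
  levels below, which is visible in the monotone per-level accuracies.
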