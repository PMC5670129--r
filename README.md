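# HiClassify

Hierarchical top-down classification and taxon prediction for biomolecular
feature matrices.

## The problem

Bacterial isolates, cancer samples and many other biomedical specimens carry
classes that live in a taxonomy — Gram stain → class → order → family →
genus → species, or cancer type → molecular subtype. Conventional "flat"
classifiers train one model over all terminal classes, so accuracy erodes as
classes multiply and, worse, a sample from a class missing from the database
can only ever be misassigned. For clinical use the upper-level identity is
often actionable on its own (a genus is frequently enough to pick an
antibiotic), which flat classification cannot deliver.

HiClassify trains one discriminant model per internal node of the class
taxonomy and classifies top-down. At each node the method is chosen by
nested stratified cross-validation among four linear reducers —
SIMPLS partial least squares, maximum-margin-criterion LDA (top
eigenvectors of $S_b - S_w$), Fisherfaces PCA-LDA (PCA to $\min(n-c, d)$
dimensions, then $S_b w = \lambda S_w w$), and a one-vs-all linear SVM —
followed by a one-vs-all logistic layer giving child probabilities. A
sample descends by argmax; when its top-two child probabilities differ by
less than a threshold $\delta$ it halts as *non-classified*, and a parent
with a single downstream node discriminates that child against the
offspring of its sibling nodes. Held-out ("unknown") terminal classes are
evaluated by leave-one-class-out: retrain without the class, route its
samples top-down, and score them at the deepest ancestor that survives the
removal.

The package also ships the two preprocessing chains that feed such models —
profile mass spectra (fixed-resolution binning, Otsu histogram denoising,
top-TIC replicate selection, Savitzky–Golay derivative peak picking,
kernel-density peak matching to a common m/z vector, median-fold-change
normalization, log transform) and annotated expression tables
(normal-sample/gene filters, per-patient deduplication, minimum subtype
size, median-fold-change + log2) — plus synthetic generators with known
ground truth for validation.

## Worked example

```r
library(HiClassify)

# synthetic two-level hierarchy: 2 x 3 leaves, 6-sigma separation
g <- genHierarchicalGaussians(branching = c(2, 3), samplesPerLeaf = 15,
                              nFeatures = 20, separation = 6, seed = 3)
show(g$tree)
#> HierarchyTree: 8 nodes, 6 leaves, depth 2
#>   nodes per level: L1=2, L2=6

rep <- crossValidate(g$tree, g$X, g$labels, cvConfig(reps = 2, seed = 5))
show(rep)
#> ConfusionReport: 2 levels, 2 repetitions
#>   level 1: 100.0 +/- 0.0 %
#>   level 2: 100.0 +/- 0.0 %

mm <- deriveMethodMap(g$tree, g$X, g$labels, cvConfig(seed = 5))
mm@map
#>     node method k singleOffspring meanAccuracy
#> 1 <root>    PLS 1           FALSE            1
#> 2   n1_1    PLS 2           FALSE            1
#> 3   n1_2    PLS 2           FALSE            1

model <- trainHCModel(g$tree, g$X, g$labels, mm, cvConfig(seed = 5))
paths <- predictTopdown(model, g$X[1:3, ], predictionConfig(delta = 0.05))
pathTable(paths)
#>   sample level1 p1_level1 p2_level1    level2 p1_level2    p2_level2 status
#> 1  s0001   n1_1         1         0 n1_1;n2_1         1 1.934757e-11   leaf
#> 2  s0002   n1_1         1         0 n1_1;n2_1         1 2.300774e-12   leaf
#> 3  s0003   n1_1         1         0 n1_1;n2_1         1 4.836107e-12   leaf
#> ...
```

The per-level accuracies are the percent of outer-test samples whose
top-down path passes through their true ancestor at that level
(non-classified counts as incorrect); the method map records which reducer
won the nested CV at each node and, for PLS, the tuned component count.
`leaveOneClassOut(g$tree, g$X, g$labels, leaf, ...)` reports how reliably a
removed terminal class is still routed to its true ancestors.

A thin command-line interface over the same functions (subcommands `synth`,
`preprocess-ms`, `preprocess-table`, `crossval`, `train`, `predict`,
`loco`) lives at `inst/cli/hiclassify.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hiclassify.R",package="HiClassify"))')" \
    synth --branching 2,3 --out demo
```

## Documentation

The methods vignette (`vignettes/hierarchical-classification.Rmd`) explains
the model, the per-node method selection, the non-classification and
single-offspring rules, every tunable parameter with its default and
rationale, what the synthetic generators do and do not emulate, and known
limitations.
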