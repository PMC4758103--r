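---
title: "Methods: feature-based quality control of single-cell RNA-seq"
author: "cellqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based quality control of single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellqc)
```

## The problem

Single-cell RNA-seq capture is imperfect: chambers or droplets may hold a
broken cell, no cell at all, or several cells at once, and some cells that
look intact under the microscope are already damaged inside ("deceptive"
cells). All of these produce distorted transcriptomes and must be removed
before downstream analysis. Threshold-based filters catch only part of this
landscape, and visual inspection does not scale. `cellqc` instead derives a
curated set of per-cell features from the expression matrix and the read
accounting, and uses them in three complementary ways: statistical
characterization of the damage signature, unsupervised outlier screening,
and a supervised SVM ensemble classifier.

## Normalization

Each cell is normalized independently: every gene's count is divided by the
cell's total count over non-spike-in genes, giving read proportions that sum
to 1 per cell. ERCC spike-in rows are carried through with the same
denominator, so a cell that lost endogenous RNA shows spike-in proportions
above their nominal share. We deliberately avoid cross-sample normalization
(e.g. size factors): a cell to be classified must not depend on which other
cells are in the batch, or training- and prediction-time representations
would diverge. TPM input is accepted and passed through the same per-cell
proportion transform; because subsets of genes (or the spike-in rows) may be
present or absent, dividing by the observed non-ERCC total is the only
choice that keeps the proportion contract identical for both units, and the
provenance is recorded on the object.

## Features

**Biological features** are gene-set read proportions: the summed normalized
values of the member genes of each set, one feature per set, overlaps
ignored. The shipped roles are the GO-derived categories (cytoplasm,
membrane, mitochondrion, metabolism, extracellular region, ribosome,
programmed cell death) plus housekeeping genes, the ~37 mitochondrially
*encoded* genes, and the larger (~10^3) set of mitochondrially *localized*
proteins. The mechanism that makes these informative: when the membrane
ruptures, cytoplasmic RNA leaks out while RNA inside mitochondria is
retained, so broken cells show a depressed cytoplasm proportion and elevated
mtDNA and spike-in proportions. Gene-set membership is matched by exact
string identity; users supply memberships in the namespace of their count
matrix.

**Technical features** come from the per-cell read accounting and the shape
of the expression profile: proportions of mapped, multi-mapped and unaligned
reads (relative to total reads), of non-exonic and duplicated reads
(relative to mapped reads — each ratio conditions on the universe it
describes), the ERCC-to-exonic read ratio, the total read count, the number
of detected genes, the transcriptome variance (variance across genes of
`log10(proportion + 1e-6)`; the offset stabilizes the zeros), the Spearman
correlation between the cell's profile and the across-cell mean profile
(rank-based so it is insensitive to the heavy-tailed scale of expression),
the number of detected genes in the dataset-level highly-expressed,
highly-variable set (mean above the across-gene median and DM > 0), and
five expression-bin counts. The bins are fixed CPM decades — (0,1], (1,10],
(10,100], (100,1000], >1000 — chosen to be deterministic and transferable
across datasets rather than dataset-adaptive; their counts sum to the
number of detected genes by construction. Zero denominators (a cell with no
mapped or no exonic reads) yield an imputed 0 and a warning rather than an
error, so degenerate cells remain classifiable.

## Distance-to-median noise

DM quantifies expression noise independently of expression level: for each
gene, the squared coefficient of variation is computed across cells, genes
are ordered by log10 mean, and DM is the deviation of log10 CV² from a
centered rolling median along that ordering (window 50 genes by default,
truncated at the edges). The rolling window makes the median local in
expression, removing the mean–CV² trend; by construction the DM median is
near zero. Genes with zero mean or zero CV² have no defined DM and are
excluded. The window default of 50 balances trend resolution against
stability of the median; it is exposed as a parameter everywhere DM is
used.

## Statistical characterization

For each gene set, the two quality classes are compared with a two-sided
*paired* t-test, pairing by gene: once on the class-mean normalized
expression and once on DM computed within each class separately. Pairing by
gene removes the dominant gene-to-gene variation from the comparison. A set
whose paired differences are all exactly zero (identical classes) is
reported as t = 0, p = 1; constant non-zero differences are degenerate and
reported NA with a warning. P-values are adjusted across sets
(Benjamini–Hochberg by default, Bonferroni selectable), and the signed
−log10 p values (sign of the t statistic times −log10 p) are the standard
display coordinates. Enrichment of annotated cells among detected outliers
is tested with Fisher's exact test (one-sided "greater" by default);
degenerate 2×2 tables return p = 1 with a warning.

## Accuracy metrics

LOW quality is the positive class. Sensitivity = TP/(TP+FN), specificity =
TN/(TN+FP), accuracy = (TP+TN)/N, and

$$F_\beta = \frac{(1+\beta^2)\,TP}{(1+\beta^2)\,TP + \beta^2 FN + FP}.$$

With the typical 80/20 class imbalance, total accuracy is misleading (an
all-HIGH classifier scores 0.8), so F_β with β = 2 — which weights recovery
of low-quality cells more heavily — is the default selection criterion; β is
configurable. Matthews correlation is also reported, with the standard
convention of 0 when a confusion-table marginal is zero.

## Cell-type-independent feature selection

When cells of several types or protocols are pooled, the first two
principal components of the (centered, unit-variance scaled) feature table
separate the cell types; features with extreme loadings on these components
are cell-type specific. The filter removes every feature whose PC1 or PC2
loading lies at or below the 25% or at or above the 75% empirical quantile
(type-7, ties removed inclusively — conservative toward type independence)
of that component's loadings, applied per component with the removals
unioned, and then removes features tied to the experimental setting (total
reads and detected genes by default). Component signs are fixed by making
each component's largest-magnitude loading positive, so the decomposition
is reproducible. Note that trimming both tails of two components removes
around half of the features by construction — the rule identifies the
*most* type-specific features rather than guaranteeing survival of all
type-independent ones. On data from a single cell type, the filter is
intentionally not applied; the canonical seven-feature common set
(`commonFeatureNames()`) is carried as metadata on the feature table.

## Unsupervised outlier detection

The feature table is scaled, projected onto its leading principal
components (2 by default), and a robust location/scatter is fitted with the
minimum covariance determinant. Cells whose squared robust Mahalanobis
distance exceeds the χ² quantile at level 0.975 (df = number of components)
are flagged. MCD's subset search is randomized, so the seed is a required,
recorded input and reports are reproducible. A singular robust scatter
falls back to its diagonal with a warning. This detector is defined on the
package's own terms as a deterministic, documented procedure; its
calibration (false-flag rate near 1 − level on clean data) and its
sensitivity to planted damaged cells are verified in the test suite. Its
known failure mode is shared by all outlier methods: if low-quality cells
are the majority, they form the dense cluster and are not "outliers" — which
is why the supervised classifier exists.

## Supervised classification

A radial-kernel SVM with class weights is tuned over a grid of (gamma,
cost, LOW-class weight) by stratified 10-fold cross-validation maximizing
mean F₂; ties resolve toward smaller cost, then smaller gamma (the smoother
model). The default grid spans gamma 2⁻¹⁰..2² and cost 2⁻⁴..2¹² in
four-fold steps with LOW weights {1, 2, 4, 8}; the weight grid exists
because on imbalanced data an unweighted SVM can collapse to the all-HIGH
solution. Accuracy is estimated by nested cross-validation — an outer
10-fold loop for measurement, an inner 10-fold loop for selection — so the
reported sensitivity/specificity are not optimistically biased by the
tuning. Scaling parameters are refit inside each training fold.

The final model is an ensemble: hyperparameter selection is repeated 50
times under reshuffled folds (one derived seed per member), one SVM is fit
on the full training set per selected combination, and prediction is by
majority vote with the LOW-vote fraction reported. An exact tie is called
LOW: in quality control the cheaper error is discarding a questionable
cell. We use reshuffled stratified CV repeats as the sole source of member
diversity (no bootstrap resampling of the training cells); the
member-to-member variation in selected hyperparameters is what the vote
averages over. Models serialize to a single archive with a schema version
tag; loading a truncated or foreign file fails loudly.

## UMI count transform

UMI protocols yield absolute transcript counts while the features and any
pretrained classifier are defined on read counts. The bridge is a cubic
polynomial between log10 gene-mean transcripts and log10 gene-mean reads,
with a pseudo count of 0.1 added to both sides before the log. The model is
linear in its coefficients, so ordinary least squares is exact — no
iterative optimizer is needed. The fitted gene-level curve is applied
entry-wise to the matrix (the simplest reading consistent with a gene-mean
fit, recorded here as an assumption), negative back-transformed values are
clipped to 0, and monotone fitted curves preserve count ordering.

## The synthetic generator

`simulateDataset()` emulates the structure the method assumes, at desk
scale: 2000 genes, 50 spike-in rows, and by default 200 cells in the 80/20
high/low mix (160 high-quality, 24 broken, 8 empty wells, 8 multiples)
reported for annotated training sets; published datasets carry roughly
10–40% low-quality cells, and 20% sits in that range. Expression follows a
log-normal gene program with per-cell on/off masks (70% of genes active),
sampled as negative-binomial counts at log-normal library sizes (mean
50,000 endogenous reads). Each well receives the same expected absolute
amount of spike-in (5% of the mean library). Damage mechanisms: broken
cells retain 15% of non-mtDNA transcripts with a further two-fold relative
mtDNA enrichment, a 0.2 drop in mapping rate and a 0.15 rise in the
non-exonic fraction; empty wells scale endogenous content so spike-ins make
up 90% of expected reads; multiples double the library and take the union
of two gene masks. Alignment statistics are derived from the simulated
counts so the read-accounting identities hold by construction. These
defaults were chosen once as the study conditions for all tests.

What the generator does *not* emulate: chemistry-specific artifacts (UMI
collisions, index hopping), gene length/GC effects, batch structure, or
doublets of distinct cell types. Passing tests therefore demonstrate that
the implementation recovers the damage signatures it models — near-perfect
nested-CV accuracy on this separable fixture is expected and is a
correctness check, not a forecast of accuracy on real data, where reported
sensitivities are materially lower.

## Numerical choices and edge cases

* Cells with zero endogenous counts normalize to all-zero and are flagged,
  not dropped.
* Proportion features are exactly invariant to scaling a cell's counts and
  read-accounting integers by a common factor.
* PCA sign fixing, ordered hyperparameter grids, explicit seeds for every
  stochastic step (fold shuffles, MCD, simulation), and serialization with
  a version tag make every pipeline run byte-reproducible.
* Test problem sizes (200-cell fixtures, 500-gene DM calibrations, the
  reduced 8-point SVM grid) were chosen as the smallest sizes at which the
  statistical properties under test are stable.

## Known limitations

* A classifier trained on one species or a very distinct cell type does not
  transfer: cell-type-specific biological features (notably the cytoplasm
  proportion) dominate. Retraining on a partially annotated subset of the
  new data is the supported route.
* Datasets rich in multiples are hard for the common-feature-only model;
  multiples mimic large healthy cells in those features.
* Gene-set membership is exact-match; no identifier mapping is attempted.
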