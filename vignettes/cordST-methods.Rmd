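---
title: "cordST: models, parameters and design choices"
author: "cordST authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cordST: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cordST analyses Visium-style spatial transcriptomics of mouse spinal cord
in experimental autoimmune encephalomyelitis (EAE), together with lesion
morphometry and serum neurofilament light chain (sNfL) biomarker data.
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The analysis pipeline

`run_pipeline()` chains the stages:

1. **Simulation** (optional): synthetic capture areas, lesion tables,
   biomarkers with planted ground truth.
2. **Preprocessing**: log-normalization, variable-feature selection, PCA,
   batch centering, cellular detection rate (CDR).
3. **Clustering**: shared-nearest-neighbor (SNN) graph with
   `k = ln(n spots)`, Louvain at resolution 0.5, then AUC-guided cluster
   merging.
4. **Region labeling**: cluster-level anatomical annotation and the
   marker-based split of white matter (WM) spots into lesion ("WML") and
   normal-appearing ("NAWM") subsets.
5. **Differential expression**: per-gene two-part hurdle tests of early
   vs late disease with the CDR covariate and Bonferroni correction, then
   concordance and spatial-pattern classification across the two subsets.
6. **Term modules**: hypergeometric enrichment against the expressed-gene
   background, Jaccard term networks, gene-to-module assignment.
7. **Morphometry**: relative lesion sizes, anatomical and CSF-contact
   classification, per-category burdens, and burden/sNfL correlation
   heat maps.

## Preprocessing

Counts are normalized as `ln(1 + count / libsize * 1e4)`. Variable
features are ranked by the ratio of a gene's variance to the value
predicted by a loess fit of log variance on log mean (span 0.5, degree
2); the default keeps up to 2000 genes (an ecosystem default — the
selection count is a config knob since no single value is canonical).
Scaling is per-gene z-scoring with denominator `n - 1` and clipping at
±10; the clip guards against negative-binomial outliers dominating a PC.
The embedding is the top 10 principal components by exact SVD, with each
component's sign fixed so its largest-magnitude loading is positive.

**Batch handling.** Slide-to-slide offsets are removed by
`batch_center()`: per principal component, each slide's centroid is
subtracted and the global centroid restored. This removes constant
per-slide displacement — the dominant slide artefact in the embedding —
and is idempotent. It is deliberately a simple linear stage, not an
iterative soft-clustering correction; externally corrected embeddings can
be passed to the clustering step instead when stronger mixing is needed.

**CDR.** The cellular detection rate is the fraction of genes detected
(count > 0) per spot. It proxies capture depth and enters the hurdle
model as a nuisance covariate.

## Clustering and the AUC merge rule

The SNN graph uses `k = max(2, round(ln(n)))` neighbors (neighbor sets
include the spot itself), Jaccard edge weights, and prunes edges below
1/15. Louvain community detection runs at resolution 0.5 under a recorded
seed. The rounding convention (half away from zero) and the
Louvain-family optimizer are fixed choices; alternatives change k by at
most 1 and labels immaterially on well-separated domains.

Cluster centroids in PC space are then joined by average-linkage
hierarchical clustering (Euclidean metric; linkage is configurable), and
the tree is traversed bottom-up. At each node, every PC is scored as a
univariate classifier of the two branches: the separation is
`|(AUC - 0.5) * 2|`, computed over all member spots with ties counted 0.5
(the Mann-Whitney convention). The node merges iff **no** PC separates
the branches with a score **over** 0.8 — a score of exactly 0.8 merges.
Consequences of this boundary semantics: at threshold 1.0 every node
merges and any clustering collapses to one cluster, and the final cluster
count is non-increasing in the threshold.

Two traversal choices were open. First, parents are evaluated on the
pooled spots of their (possibly merged) children. Second, a node is
eligible to merge only when each branch is itself a single merged
cluster — if a subtree refused to merge, its parent cannot silently
swallow it; the separation scores are still recorded for every node.
This keeps merging a pure coarsening of the input partition. Merges do
not cascade: the dendrogram is not rebuilt after merging. The AUC uses
the same (batch-centered) embedding as the clustering.

## Lesion labeling and DGE subsets

A spot is a lesion if at least 2 of the T-cell markers (defaults `Cd3e`,
`Cd4`, `Cd8a` — the murine single-gene stand-ins for the CD3/CD8
complexes) have raw count > 0. Detection semantics are deliberate: the
rule is invariant to any positivity-preserving transform, so
normalization choices cannot change lesion membership. The WML subset is
the lesion-flagged WM spots, NAWM the rest of the WM; lesion flags on
grey-matter spots are computed but ignored. Because co-detection of two
markers by chance is possible (its probability follows from the NB model
at the marker baselines), the WML subset has a known, quantifiable
false-positive admixture at default settings.

## The hurdle model

For each gene in a subset, the two-part model is

* discrete: logistic regression of detection on condition and CDR;
* continuous: Gaussian linear model of log-normalized expression on the
  same covariates, over detected spots only, with the likelihood
  evaluated at the MLE variance so the likelihood-ratio test (LRT) is
  well defined.

The LRT against the no-condition model sums the two components' 2Δlog-
likelihoods and uses one chi-square degree of freedom per available
component (2 when both are present). The continuous component is dropped
(df 1) when any condition group has fewer than 2 detected spots. Genes
detected in fewer than 5 subset spots are skipped and reported, keeping
fits identifiable. Complete separation in the logistic part falls back to
a lightly ridge-penalized fit (λ = 1e-3) and flags the gene. Bonferroni
correction uses the number of genes actually tested in the subset;
significance is adjusted p < 0.05.

Log2 fold changes are differences of all-spot group means of the
log-normalized values (zeros included), divided by ln 2; a detected-only
variant is available as a config option. Positive values mean higher in
early disease — this sign convention is fixed once and echoed in all
outputs. No fold-change shrinkage is applied.

**Concordance classes.** Genes tested in both subsets are partitioned:
significant (Bonferroni) in both; significant in one and *regulated*
(raw p < 0.05, concordant sign) in the other; regulated in both without
significance; or not regulated. "Regulated" is a knob (`reg_p`) because
the boundary between "regulated but not significant" and noise is not
canonically defined. **Spatial patterns.** Among genes with raw p < 0.05
in both subsets and Bonferroni p < 0.05 in at least one, a gene is
*centrifugal* if its fold change is higher in WML than NAWM and
*centripetal* if lower.

A recoverability caveat worth stating precisely: the singly-significant
classes are delimited by the window between raw and Bonferroni
significance of a chi-square statistic. The probability that a gene's
statistic lands in that window is at most ≈ 0.65 for any effect size
(the window is about two noncentral-chi-square standard deviations
wide), so per-gene recovery of these boundary classes is intrinsically
capped well below 1 — a property of the class definitions, not of any
implementation. Class tallies over many genes are stable; per-gene
labels near the boundary are not.

## Enrichment and modules

Enrichment is the one-sided hypergeometric test of query/term overlap
against the background of all expressed genes, with Benjamini-Hochberg
multiplicity control at 0.05. Term networks connect enriched terms whose
*contributing* gene sets (query ∩ term) have Jaccard similarity ≥ 0.15
(inclusive boundary); contributing rather than full annotation sets match
the plotting convention of enrichment-map-style figures and are a config
switch. The curated module map (term → module, each term in exactly one
module) is an input table; genes join every module containing an
enriched term they contribute to. A small synthetic GMT and module map
ship under `inst/extdata/` (files are labelled synthetic; they are
generated by `make_term_annotation()`, not curated biology).

## Morphometry and biomarker statistics

Relative lesion size is `lesion area / (total section area - grey matter
area) * 100`. A lesion is classified *without* CSF contact only when five
consecutive observed sections all lack contact; any contact anywhere
makes it *with contact*; a lesion observed in fewer than five sections
with no contact cannot satisfy the rule and defaults to *with contact*
carrying an indeterminate flag (the rule defines only the negative call).
Burdens are summed relative sizes per level × position × CSF-contact
cell, plus marginals. Correlations are Pearson, or Spearman implemented
as Pearson on average ranks, both with two-sided t-based p-values; all
tests are two-sided at the exploratory 5% level. Group comparisons gate
on per-group Shapiro-Wilk normality at 0.05 between Student's t and
Mann-Whitney U, and report which branch ran. Heat-map cells are
uncorrected (exploratory) by default; zero-variance cells are flagged
undefined rather than imputed.

## The synthetic cord generator

The generator is first-class, tested code; it plants the ground truth all
recovery claims are measured against.

* **Geometry**: square spot grid (pitch 100 µm; square rather than
  hexagonal because every downstream stage is geometry-agnostic), outer
  WM ellipse 2000 × 1400 µm, grey matter as two mirrored ellipses, about
  880 in-tissue spots per section (the true per-section spot count of
  spinal cord sections is not published; 800–1500 is the design range),
  at most ~5000 spots per capture area. Lesions are discs (radius 280
  µm) fully inside the WM; CSF contact means the disc touches the pial
  boundary; zones (anterolateral/dorsal) follow the placement angle.
* **Counts**: negative binomial per gene (mean/size parameterization)
  with log-normal library-size factors, planted log2 effects for
  anatomical programs (50 genes each for GM and WM at +2.5), a lesion
  program (40 genes at +2, T-cell markers at +4 over baseline 0.25), and
  early-vs-late condition effects planted separately for the WML (±1.5)
  and NAWM (±1.2) subsets, with 15 genes regulated in both, 15 in NAWM
  only and 5 in WML only; genes without planted effects have log2FC
  exactly 0. Per-slide batch offsets are N(0, 0.25) log2 units.
* **Library-size spread**: within a capture area the default is
  log-normal sd 0.15. The generator's role is to emulate the statistical
  structure the downstream stages assume — anatomy dominating nuisance
  axes. A much larger spread manufactures a detection-depth principal
  component along which contiguous chunks of one anatomical domain are
  trivially AUC-separable, so no merge rule of this family could pool
  them; depth effects on *testing* are exercised instead through the
  geometry-free two-group simulator (`simulate_two_group_counts`), whose
  CDR-confound experiments use sd 0.3 and condition-dependent means.
* **Cohorts**: 8 animals per condition for morphometry and biomarkers,
  spatial slides for 2 healthy / 3 early / 3 late animals (healthy cords
  carry no lesions). Lesion rates are highest in the lumbar
  anterolateral WM and 80% of lesions contact the CSF. Late-stage sNfL
  is a linear function of the anterolateral-lumbar CSF-contacting burden
  with noise calibrated to a planted correlation of 0.8 (`r_late`;
  setting the noise to 0 makes the map exactly monotone); early-stage
  sNfL comes from a diffuse-damage term independent of lesion burden
  (planted correlation 0) and is higher on average than late, matching
  the relapse-then-decline biology. ROI immunostaining stand-ins draw
  around the reported group means (early WML/NAWM 37.4/70.7, late
  66.8/31.7 for SMI32), so lesion/NAWM ratios land near 0.5 (early) and
  2.2 (late).

**What the generator does not emulate**: hexagonal spot packing, spatial
autocorrelation of expression within a domain beyond the domain label
itself, sequencing-level artifacts (UMIs, reads), histology images,
cell-type mixtures within spots, and mean-variance trends beyond the NB
family. Passing recovery tests therefore demonstrates correctness of the
pipeline's logic under its stated statistical assumptions, not
performance on real tissue.

## Problem sizes and determinism

The default study configuration analyses 8 capture areas (~7000 spots,
400 genes) and runs in well under a minute; calibration and power
experiments use 2000 genes × 300 spots and 500 genes × 400 spots.  These
sizes were chosen so that planted effects are recoverable with the power
the design intends while the whole analysis remains desk-scale.  All
randomness flows from a single master seed through per-stage hashed
substreams (`stage_seed`), so identical configurations and seeds
reproduce byte-identical results and adding draws to one stage does not
perturb another.

## Known limitations

* `batch_center` removes only location shifts per slide; rotational or
  variance batch distortions pass through (by design — see above).
* The hurdle LRT relies on chi-square asymptotics; for genes detected in
  only a handful of spots the discrete component is conservative.
* Lesion labeling ignores spatial contiguity; isolated marker-positive
  NAWM spots are labelled lesions at the analytically expected
  co-detection rate.
* The merge rule cannot pool clusters split along a genuinely continuous
  gradient (depth, smooth anatomical axes): adjacent chunks of a
  gradient are always separable along the cut axis. This is a property
  of the published criterion itself.
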