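# cordST

Spatial transcriptomics and lesion morphometry of murine spinal cord
neuroinflammation.

In experimental autoimmune encephalomyelitis (EAE) — the mouse model of
multiple sclerosis — axonal damage releases neurofilament light chain
into blood (sNfL), but *where* that damage sits changes with disease
stage: early disease shows diffuse injury across normal-appearing white
matter (NAWM), while late disease concentrates damage in focal white
matter lesions (WML), and sNfL then tracks the burden of anterolateral
lumbar lesions touching the CSF. cordST implements the full analysis
that establishes this picture, for Visium-style spot-count data plus
histology-derived lesion tables, and ships a synthetic spinal-cord
generator with planted ground truth so every stage is testable end to
end.

The pipeline's core methods:

* **Spot clustering with AUC-guided merging.** SNN graph
  (k = ln n, Jaccard weights, prune < 1/15), Louvain at resolution 0.5,
  then hierarchical clustering of cluster centroids in 10-PC space; a
  dendrogram node is merged iff no principal component classifies its
  branches with |(AUC − 0.5) · 2| > 0.8.
* **Lesion labeling.** A WM spot is "WML" iff ≥ 2 of {Cd3e, Cd4, Cd8a}
  have raw count > 0; remaining WM is "NAWM".
* **Hurdle differential expression.** Per gene, logistic detection +
  Gaussian expression components with the cellular detection rate (CDR)
  as covariate, combined by a chi-square LRT (df = available
  components); Bonferroni-adjusted p < 0.05. Genes are then classified
  by cross-subset concordance (significant in both / NAWM-only /
  WML-only / regulated / not) and spatial pattern (centrifugal:
  FC_WML > FC_NAWM; centripetal: the reverse).
* **Term modules.** Hypergeometric enrichment against the expressed-gene
  background (BH 0.05), Jaccard networks over contributing gene sets
  (edges ≥ 0.15), unique term→module maps, gene→module assignment.
* **Lesion morphometry.** Relative lesion size =
  lesion / (total − grey) × 100 %, the five-consecutive-section
  CSF-contact rule, per-category burdens, and Spearman/Pearson
  burden–sNfL correlation heat maps.

## Worked example

```r
library(cordST)
rep <- run_pipeline(pipeline_config(seed = 1))
rep$n_clusters_pre_merge   # 6
rep$n_clusters_post_merge  # 3
rep$n_deg_wml              # 35
rep$n_deg_nawm             # 97
rep$class_counts
#>          sig_both     sig_nawm_only      sig_wml_only regulated_not_sig
#>                34                27                 0                16
#>     not_regulated
#>               323
hm <- rep$morphometry$heatmap$late
hm[hm$category == "lumbar_anterolateral_with_contact", c("r", "p")]
#>           r           p
#> 3 0.8982197 0.002438797
```

Reading: the 7016 synthetic spots cluster into 6 communities that the
AUC merge collapses onto the three planted anatomical domains (grey
matter, white matter, lesions). Hurdle testing finds more early-vs-late
regulation in NAWM (97 genes) than in lesions (35), and in the late
cohort sNfL correlates strongly (Spearman r ≈ 0.9 at n = 8) with the
anterolateral-lumbar CSF-contacting lesion burden — the planted
stage-dependent coupling — while the same cell in the early cohort shows
no association.

Individual stages are exported (`lognormalize`, `select_variable_genes`,
`pca_embedding`, `batch_center`, `build_snn_graph`, `cluster_graph`,
`merge_clusters`, `label_lesion_spots`, `dge_subset`,
`concordance_classes`, `spatial_pattern`, `enrich`,
`build_term_network`, `relative_lesion_size`, `classify_csf_contact`,
`snfl_heatmap`, ...), as are the 10x-triplet reader/writer
(`read_matrix`, `write_spot_dataset`) and the generator
(`generate_cord_geometry`, `simulate_counts`, `simulate_cohort`,
`simulate_two_group_counts`). See the methods vignette
(`vignettes/cordST-methods.Rmd`) for models, parameter rationale and
limitations.

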