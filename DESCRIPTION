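Package: cordST
Title: Spatial Transcriptomics and Lesion Morphometry of Murine Spinal Cord
    Neuroinflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Visium-style spatial transcriptomics of
    mouse spinal cord in experimental autoimmune encephalomyelitis (EAE),
    together with lesion morphometry and serum neurofilament light chain
    (sNfL) association analysis.  Provides a synthetic spinal-cord data
    generator with planted ground truth (negative-binomial spot counts,
    white/grey-matter domains, T-cell-marker-enriched lesions, slide batch
    effects, stage-dependent lesion/sNfL coupling); log-normalization,
    variable-feature selection, PCA and batch centering; shared-nearest-
    neighbor graph clustering with an AUC-guided dendrogram cluster-merging
    step; marker-based lesion spot labeling into "WML" and "NAWM" subsets;
    two-part hurdle differential expression with a cellular detection rate
    covariate and Bonferroni correction; fold-change concordance and
    spatial-pattern classification; hypergeometric term enrichment with
    Jaccard term networks and gene-to-module assignment; and lesion size,
    anatomical classification, CSF-contact and biomarker correlation
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
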