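#' Pipeline configuration
#'
#' Bundles all stage parameters with their defaults: log-normalization
#' scale factor 1e4, up to 2000 variable features, 10 PCs, clip 10,
#' Louvain resolution 0.5, AUC merge threshold 0.8, T-cell lesion markers
#' with a 2-of-3 rule, Bonferroni at 0.05 with a 5-detected-spot filter,
#' BH enrichment at 0.05 with Jaccard network threshold 0.15, and
#' Spearman burden/sNfL correlations.
#'
#' @param seed master seed; all stage seeds derive from it via
#'   [stage_seed()].
#' @param cohort a [cohort_config()] for the synthetic study.
#' @param scale_factor,n_hvg,n_pcs,clip preprocessing parameters.
#' @param resolution,merge_threshold,linkage clustering parameters.
#' @param markers,min_positive lesion labeling rule.
#' @param dge_alpha,min_detect,fc_method,reg_p differential expression
#'   parameters.
#' @param enrich_alpha,min_jaccard enrichment / network parameters.
#' @param heatmap_method correlation method for the burden/sNfL heat map.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, cohort = cohort_config(),
                            scale_factor = 1e4, n_hvg = 2000L,
                            n_pcs = 10L, clip = 10,
                            resolution = 0.5, merge_threshold = 0.8,
                            linkage = "average",
                            markers = c("Cd3e", "Cd4", "Cd8a"),
                            min_positive = 2L,
                            dge_alpha = 0.05, min_detect = 5L,
                            fc_method = "all", reg_p = 0.05,
                            enrich_alpha = 0.05, min_jaccard = 0.15,
                            heatmap_method = "spearman") {
  stopifnot(merge_threshold >= 0, merge_threshold <= 1,
            dge_alpha > 0, dge_alpha < 1, n_pcs >= 2)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 scale_factor = scale_factor, n_hvg = as.integer(n_hvg),
                 n_pcs = as.integer(n_pcs), clip = clip,
                 resolution = resolution,
                 merge_threshold = merge_threshold, linkage = linkage,
                 markers = markers, min_positive = as.integer(min_positive),
                 dge_alpha = dge_alpha, min_detect = as.integer(min_detect),
                 fc_method = fc_method, reg_p = reg_p,
                 enrich_alpha = enrich_alpha, min_jaccard = min_jaccard,
                 heatmap_method = heatmap_method),
            class = "pipeline_config")
}

#' Combine several capture areas into one analysis matrix
#'
#' Binds the count matrices of a list of `spot_dataset`s (same gene set)
#' and stacks geometry, per-spot condition and slide (batch) labels.
#'
#' @param datasets list of `spot_dataset`s.
#' @return list `counts`, `geometry`, `condition`, `batch`.
#' @export
combine_spot_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  counts <- do.call(cbind, lapply(datasets, `[[`, "counts"))
  geometry <- do.call(rbind, lapply(datasets, `[[`, "geometry"))
  condition <- unlist(lapply(datasets, function(d)
    rep(d$condition, ncol(d$counts))), use.names = FALSE)
  batch <- unlist(lapply(datasets, function(d)
    rep(d$slide_id, ncol(d$counts))), use.names = FALSE)
  list(counts = counts, geometry = geometry,
       condition = factor(condition), batch = factor(batch))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-cord analysis pipeline
#'
#' Simulate (optional) -> preprocess -> cluster -> merge -> annotate ->
#' lesion labeling -> hurdle DGE in the WML and NAWM subsets ->
#' concordance / spatial pattern -> term enrichment, network and modules
#' -> lesion morphometry and biomarker correlations.  Every stage failure
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally a pre-simulated [simulate_cohort()] result
#'   (skips the simulate stage).
#' @param outdir optional directory for TSV outputs.
#' @return a report list with per-stage results and summary counts.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- cohort %||% run_stage("simulate",
    simulate_cohort(config$cohort, seed = stage_seed(seed, "simulate")))
  if (length(cohort$spatial) == 0)
    stop("pipeline stage 'simulate' failed: no spatial datasets")
  combined <- run_stage("combine", combine_spot_datasets(cohort$spatial))
  pre <- run_stage("preprocess", {
    norm <- lognormalize(combined$counts,
                         scale_factor = config$scale_factor)
    kept <- colnames(norm)
    keep_idx <- match(kept, colnames(combined$counts))
    hvg <- select_variable_genes(norm, n = min(config$n_hvg, nrow(norm)))
    scaled <- scale_center(norm, hvg, clip = config$clip)
    emb <- pca_embedding(scaled, n_components = config$n_pcs)
    emb <- batch_center(emb, combined$batch[keep_idx])
    cdr <- cellular_detection_rate(combined$counts[, keep_idx,
                                                   drop = FALSE])
    list(norm = norm, hvg = hvg, embedding = emb, cdr = cdr,
         keep_idx = keep_idx)
  })
  condition <- combined$condition[pre$keep_idx]
  geometry <- combined$geometry[pre$keep_idx, , drop = FALSE]
  counts <- combined$counts[, pre$keep_idx, drop = FALSE]
  clust <- run_stage("cluster",
    cluster_spots(pre$embedding, resolution = config$resolution,
                  merge_threshold = config$merge_threshold,
                  seed = stage_seed(seed, "cluster"),
                  linkage = config$linkage))
  labels <- clust$labels
  regions <- run_stage("label", {
    ann_map <- majority_annotation(labels, geometry$region_true)
    comp <- annotate_compartments(labels, ann_map)
    lesion <- label_lesion_spots(counts, markers = config$markers,
                                 min_positive = config$min_positive)
    subsets <- make_dge_subsets(comp, lesion)
    list(map = ann_map, compartments = comp, lesion = lesion,
         subsets = subsets)
  })
  eae <- condition %in% c("early", "late")
  dge <- run_stage("dge", {
    present <- unique(as.character(condition[eae]))
    if (length(present) < 2)
      stop("differential expression needs spots from both the early and ",
           "late conditions; present: ",
           if (length(present)) paste(present, collapse = ", ") else
             "healthy only")
    run_one <- function(spots, tag) {
      spots <- intersect(spots, colnames(counts)[eae])
      if (length(spots) < 2 * config$min_detect) return(NULL)
      dge_subset(counts, pre$norm, condition, cdr = pre$cdr$cdr,
                 spots = spots, subset_name = tag,
                 min_detect = config$min_detect,
                 alpha = config$dge_alpha, fc_method = config$fc_method)
    }
    list(wml = run_one(regions$subsets$wml, "WML"),
         nawm = run_one(regions$subsets$nawm, "NAWM"))
  })
  conc <- pattern <- NULL
  if (!is.null(dge$wml) && !is.null(dge$nawm)) {
    conc <- run_stage("concordance",
      concordance_classes(dge$wml, dge$nawm, reg_p = config$reg_p,
                          alpha = config$dge_alpha))
    pattern <- run_stage("pattern", spatial_pattern(dge$wml, dge$nawm))
  }
  modules <- run_stage("enrich", {
    ann <- make_term_annotation(cohort$gene_model,
                                seed = stage_seed(seed, "terms"))
    background <- rownames(counts)[Matrix::rowSums(counts) > 0]
    sig <- unique(c(dge$wml$gene[dge$wml$significant],
                    dge$nawm$gene[dge$nawm$significant]))
    if (length(sig) == 0) return(NULL)
    er <- enrich(intersect(sig, background), background,
                 ann$annotations, alpha = config$enrich_alpha)
    network <- build_term_network(er, min_jaccard = config$min_jaccard)
    gm <- assign_genes_to_modules(er, ann$module_map)
    summary <- if (!is.null(dge$wml) && !is.null(dge$nawm))
      module_fc_summary(gm, dge$wml, dge$nawm,
                        min_jaccard = config$min_jaccard)
    list(annotation = ann, enrichment = er, network = network,
         gene_modules = gm, fc_summary = summary)
  })
  morpho <- run_stage("morpho", {
    if (is.null(cohort$lesions)) return(NULL)
    burdens <- category_burden(cohort$lesions,
                               animals = cohort$animals$animal_id)
    heatmap <- snfl_heatmap(burdens, cohort$animals,
                            method = config$heatmap_method)
    ratios <- if (!is.null(cohort$roi))
      compartment_ratio(cohort$roi, "smi32_count")
    eae_a <- cohort$animals[cohort$animals$condition != "healthy", ]
    snfl_cnfl <- if (nrow(eae_a) >= 3)
      correlation(eae_a$snfl, eae_a$cnfl, method = "pearson")
    list(burdens = burdens, heatmap = heatmap, ratios = ratios,
         snfl_cnfl = snfl_cnfl)
  })
  report <- list(
    seed = seed, config = config,
    n_spots = ncol(counts),
    n_clusters_pre_merge = clust$n_before,
    n_clusters_post_merge = clust$n_after,
    n_wml_spots = length(regions$subsets$wml),
    n_nawm_spots = length(regions$subsets$nawm),
    n_deg_wml = if (!is.null(dge$wml)) sum(dge$wml$significant) else NA,
    n_deg_nawm = if (!is.null(dge$nawm)) sum(dge$nawm$significant) else NA,
    class_counts = if (!is.null(conc)) table(conc$class),
    pattern_counts = if (!is.null(pattern)) table(pattern$pattern),
    cohort = cohort, combined = combined, preprocess = pre,
    condition = condition, geometry = geometry, counts = counts,
    clustering = clust, regions = regions, dge = dge,
    concordance = conc, pattern = pattern, modules = modules,
    morphometry = morpho)
  if (!is.null(outdir)) write_pipeline_outputs(report, outdir)
  report
}

#' Write the pipeline's tabular outputs
#'
#' @param report a [run_pipeline()] report.
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(report, outdir) {
  dir.create(file.path(outdir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  tab <- function(x, name) if (!is.null(x))
    write.table(x, file.path(outdir, "tables", paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  labels <- data.frame(barcode = names(report$clustering$labels),
                       cluster_pre_merge =
                         as.vector(report$clustering$labels_pre_merge),
                       cluster_post_merge =
                         as.vector(report$clustering$labels))
  tab(labels, "cluster_labels")
  tab(report$clustering$decisions, "merge_decisions")
  tab(report$dge$wml, "dge_wml")
  tab(report$dge$nawm, "dge_nawm")
  tab(report$concordance, "concordance")
  tab(report$pattern, "spatial_pattern")
  if (!is.null(report$modules)) {
    tab(report$modules$enrichment, "enrichment")
    tab(report$modules$network$edges, "term_network_edges")
  }
  if (!is.null(report$morphometry)) {
    b <- report$morphometry$burdens
    tab(data.frame(animal_id = rownames(b), b, check.names = FALSE),
        "category_burden")
    tab(report$morphometry$heatmap$early, "snfl_heatmap_early")
    tab(report$morphometry$heatmap$late, "snfl_heatmap_late")
    tab(report$morphometry$ratios, "smi32_ratios")
  }
  invisible(outdir)
}
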