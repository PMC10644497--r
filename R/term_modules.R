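#' Hypergeometric term enrichment against an expressed-gene background
#'
#' One-sided hypergeometric (Fisher) upper-tail test per term of the
#' overlap between the query gene list and the term's gene set, both
#' intersected with the background of all expressed genes; multiplicity is
#' controlled by Benjamini-Hochberg.
#'
#' @param query_genes character vector (must be a subset of the
#'   background).
#' @param background_genes the expressed-gene universe.
#' @param annotations named list, term id -> gene set (or a GMT list from
#'   [read_gmt()]).
#' @param alpha BH-adjusted significance level flagging enriched terms.
#' @return data.frame per term: `term_id`, `k` (query in term), `K` (term
#'   size in background), `n` (query size), `N` (background size), `p`,
#'   `p_adj`, `enriched`, `contributing_genes` (comma-joined k genes),
#'   ordered by p.
#' @export
enrich <- function(query_genes, background_genes, annotations,
                   alpha = 0.05) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  if (length(query_genes) == 0) stop("empty query gene list")
  if (length(background_genes) == 0) stop("empty background gene list")
  if (!all(query_genes %in% background_genes))
    stop("query genes outside the background: ",
         paste(utils::head(setdiff(query_genes, background_genes), 5),
               collapse = ", "))
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- lapply(names(annotations), function(t) {
    term_genes <- intersect(annotations[[t]], background_genes)
    K <- length(term_genes)
    hits <- intersect(query_genes, term_genes)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N, p = p,
               contributing_genes = paste(sort(hits), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj < alpha
  out[order(out$p, out$term_id), ]
}

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets have similarity 0.
#'
#' @param a,b vectors treated as sets.
#' @return similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Build the Jaccard similarity network over enriched terms
#'
#' Nodes are the enriched terms; an edge joins two terms whose
#' contributing (query-overlap) gene sets have Jaccard similarity of at
#' least `min_jaccard` (inclusive, default 0.15).
#'
#' @param enrichment an [enrich()] table (only `enriched` rows are used
#'   unless `enriched_only = FALSE`).
#' @param min_jaccard minimum edge weight kept.
#' @param enriched_only restrict nodes to enriched terms.
#' @return list with `nodes` (term ids) and `edges` data.frame
#'   (`term_a`, `term_b`, `jaccard`).
#' @export
build_term_network <- function(enrichment, min_jaccard = 0.15,
                               enriched_only = TRUE) {
  rows <- if (enriched_only)
    enrichment[enrichment$enriched, , drop = FALSE] else enrichment
  sets <- strsplit(rows$contributing_genes, ",", fixed = TRUE)
  names(sets) <- rows$term_id
  edges <- list()
  ids <- rows$term_id
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        jc <- jaccard(sets[[i]], sets[[j]])
        if (jc >= min_jaccard)
          edges[[length(edges) + 1L]] <-
            data.frame(term_a = ids[i], term_b = ids[j], jaccard = jc)
      }
    }
  }
  list(nodes = ids,
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(term_a = character(), term_b = character(),
                    jaccard = numeric()))
}

#' Assign genes to functional modules via their enriched terms
#'
#' A gene belongs to a module iff it contributes to at least one enriched
#' term assigned to that module; genes may belong to several modules, and
#' genes contributing only to non-enriched terms stay unassigned.
#'
#' @param enrichment an [enrich()] table.
#' @param module_map data.frame (`module`, `term_id`): the curated unique
#'   term -> module assignment.
#' @return named list, gene -> character vector of modules.
#' @export
assign_genes_to_modules <- function(enrichment, module_map) {
  stopifnot(all(c("module", "term_id") %in% names(module_map)))
  if (anyDuplicated(module_map$term_id))
    stop("module map assigns a term to more than one module")
  rows <- enrichment[enrichment$enriched, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    mod <- module_map$module[match(rows$term_id[i], module_map$term_id)]
    if (is.na(mod)) next
    for (g in strsplit(rows$contributing_genes[i], ",", fixed = TRUE)[[1]])
      if (nzchar(g)) out[[g]] <- union(out[[g]], mod)
  }
  lapply(out, sort)
}

#' Per-module fold-change distributions and module overlaps
#'
#' For each module, collects the log2 fold changes of its member genes in
#' both white-matter subsets (the violin/arc-diagram quantities), and the
#' pairwise Jaccard overlap of module gene sets at the arc threshold.
#'
#' @param gene_modules output of [assign_genes_to_modules()].
#' @param table_wml,table_nawm [dge_subset()] tables.
#' @param min_jaccard arc threshold on module overlap (default 0.15).
#' @return list: `fc` data.frame (`module`, `gene`, `log2fc_wml`,
#'   `log2fc_nawm`), `overlap` data.frame of module pairs with Jaccard at
#'   or above the threshold.
#' @export
module_fc_summary <- function(gene_modules, table_wml, table_nawm,
                              min_jaccard = 0.15) {
  rows <- list()
  for (g in names(gene_modules)) {
    fw <- table_wml$log2fc[match(g, table_wml$gene)]
    fn <- table_nawm$log2fc[match(g, table_nawm$gene)]
    for (mod in gene_modules[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, gene = g, log2fc_wml = fw, log2fc_nawm = fn)
  }
  fc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), gene = character(),
               log2fc_wml = numeric(), log2fc_nawm = numeric())
  mods <- sort(unique(fc$module))
  sets <- lapply(mods, function(m) fc$gene[fc$module == m])
  names(sets) <- mods
  ov <- list()
  if (length(mods) >= 2) {
    for (i in seq_len(length(mods) - 1L))
      for (j in (i + 1L):length(mods)) {
        jc <- jaccard(sets[[i]], sets[[j]])
        if (jc >= min_jaccard)
          ov[[length(ov) + 1L]] <- data.frame(
            module_a = mods[i], module_b = mods[j], jaccard = jc)
      }
  }
  list(fc = fc,
       overlap = if (length(ov)) do.call(rbind, ov) else
         data.frame(module_a = character(), module_b = character(),
                    jaccard = numeric()))
}
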