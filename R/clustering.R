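#' Neighborhood size for graph clustering
#'
#' The k of the kNN/SNN graph is set to `ln(number of spots)` (the
#' spaceranger convention), rounded half away from zero with a floor of 2.
#'
#' @param n_spots number of spots.
#' @return integer k.
#' @export
choose_k <- function(n_spots) {
  stopifnot(n_spots >= 2)
  max(2L, as.integer(round_half_up(log(n_spots))))
}

#' Build a shared-nearest-neighbor graph in PC space
#'
#' k-nearest neighbors by Euclidean distance in the embedding (neighbor
#' sets of size `k` including the spot itself); edge weight is the Jaccard
#' overlap of the two neighbor sets; edges with weight below `prune`
#' (default 1/15) are removed.
#'
#' @param embedding an `embedding` or a spots x PCs score matrix.
#' @param k neighborhood size (see [choose_k()]).
#' @param prune minimum Jaccard weight kept.
#' @return an undirected weighted [igraph::graph] with one vertex per spot.
#' @export
build_snn_graph <- function(embedding, k, prune = 1 / 15) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(scores)
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (",
                   n, ")")
  sn <- rowSums(scores^2)
  nn <- matrix(0L, n, k)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sn[idx], sn, `+`) - 2 * tcrossprod(scores[idx, , drop = FALSE],
                                                   scores)
    d2[cbind(seq_along(idx), idx)] <- -Inf   # guarantee self-inclusion
    nn[idx, ] <- t(apply(d2, 1L, function(row) order(row)[seq_len(k)]))
  }
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- shared@x / (2 * k - shared@x)
  diag(jac) <- 0
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(scores) %||% as.character(seq_len(n))
  g
}

#' Louvain community detection on the SNN graph
#'
#' Modularity-based community detection with a resolution parameter;
#' deterministic for a fixed seed.  Isolated vertices form singleton
#' communities.
#'
#' @param graph weighted graph from [build_snn_graph()].
#' @param resolution modularity resolution (default 0.5).
#' @param seed integer seed.
#' @return named integer vector of cluster labels, contiguous from 1.
#' @export
cluster_graph <- function(graph, resolution = 0.5, seed = 1L) {
  membership <- with_seed(seed, {
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    igraph::membership(cl)
  })
  labels <- as.integer(factor(membership))
  names(labels) <- igraph::V(graph)$name
  labels
}

#' Hierarchical dendrogram over cluster centroids
#'
#' Agglomerates the per-cluster mean PC scores with (by default) average
#' linkage on Euclidean distance.
#'
#' @param embedding an `embedding` or score matrix.
#' @param labels cluster label per spot.
#' @param linkage an [stats::hclust()] method.
#' @return a `centroid_tree`: list with the `hclust` object, `cluster_ids`
#'   (leaf order of ids) and the centroid matrix.
#' @export
centroid_dendrogram <- function(embedding, labels, linkage = "average") {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  stopifnot(nrow(scores) == length(labels))
  ids <- sort(unique(labels))
  if (length(ids) < 2) stop("need at least 2 clusters for a dendrogram")
  centroids <- rowsum(scores, group = labels) /
    as.vector(table(factor(labels, levels = ids)))
  rownames(centroids) <- as.character(ids)
  hc <- hclust(dist(centroids), method = linkage)
  structure(list(hclust = hc, cluster_ids = ids, centroids = centroids),
            class = "centroid_tree")
}

#' ROC AUC of one score as a classifier of two branches
#'
#' The probability that a right-branch score exceeds a left-branch score,
#' ties counted 0.5 (the Mann-Whitney convention); equivalently the scaled
#' rank-sum statistic.
#'
#' @param scores_left,scores_right numeric scores of the two branches.
#' @return AUC in `[0, 1]`.
#' @export
branch_auc <- function(scores_left, scores_right) {
  n1 <- length(scores_left); n2 <- length(scores_right)
  if (n1 == 0L || n2 == 0L) stop("branch_auc: empty branch")
  r <- rank(c(scores_left, scores_right))
  (sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' AUC separation score |(AUC - 0.5) * 2|
#'
#' @inheritParams branch_auc
#' @return separation in `[0, 1]`; 0 = indistinguishable, 1 = perfectly
#'   separated.
#' @export
auc_separation <- function(scores_left, scores_right)
  abs((branch_auc(scores_left, scores_right) - 0.5) * 2)

#' Merge clusters whose dendrogram branches no PC can classify
#'
#' Bottom-up single pass over the centroid dendrogram: at each internal
#' node the separation score `|(AUC - 0.5) * 2|` of every principal
#' component, computed over all member spots of the two branches (pooling
#' already-merged children), is evaluated; the node's clusters are merged
#' iff no PC separates the branches with a score over `threshold` (a score
#' of exactly `threshold` merges) and both branches are themselves single
#' merged clusters.  Merging only coarsens the partition; labels are
#' relabeled contiguously from 1 (largest cluster first).
#'
#' @param tree a [centroid_dendrogram()].
#' @param embedding an `embedding` or score matrix (same spots as
#'   `labels`).
#' @param labels cluster label per spot the tree was built on.
#' @param threshold separation threshold in `[0, 1]` (default 0.8).
#' @return list with `labels` (merged, contiguous), `decisions` (one row
#'   per dendrogram node: per-PC separations, max, eligibility, merged),
#'   `n_before`, `n_after`.
#' @export
merge_clusters <- function(tree, embedding, labels, threshold = 0.8) {
  stopifnot(inherits(tree, "centroid_tree"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  stopifnot(nrow(scores) == length(labels))
  hc <- tree$hclust
  ids <- tree$cluster_ids
  n_nodes <- nrow(hc$merge)
  node_leaves <- vector("list", n_nodes)
  group <- seq_along(ids)               # union-find over leaf clusters
  names(group) <- as.character(ids)
  get_leaves <- function(ref)
    if (ref < 0) ids[-ref] else node_leaves[[ref]]
  decisions <- vector("list", n_nodes)
  n_pc <- ncol(scores)
  for (node in seq_len(n_nodes)) {
    left <- get_leaves(hc$merge[node, 1])
    right <- get_leaves(hc$merge[node, 2])
    node_leaves[[node]] <- c(left, right)
    li <- labels %in% left
    ri <- labels %in% right
    s <- vapply(seq_len(n_pc), function(pc)
      auc_separation(scores[li, pc], scores[ri, pc]), numeric(1))
    eligible <- length(unique(group[as.character(left)])) == 1L &&
      length(unique(group[as.character(right)])) == 1L
    merged <- eligible && max(s) <= threshold
    if (merged) {
      gids <- group[as.character(c(left, right))]
      group[group %in% gids] <- min(gids)
    }
    decisions[[node]] <- data.frame(
      node = node, t(setNames(s, paste0("s_", seq_len(n_pc)))),
      max_separation = max(s), eligible = eligible, merged = merged,
      height = hc$height[node])
  }
  decisions <- do.call(rbind, decisions)
  merged_of_spot <- group[as.character(labels)]
  sizes <- sort(table(merged_of_spot), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  new_labels <- as.integer(relabel[as.character(merged_of_spot)])
  names(new_labels) <- names(labels)
  list(labels = new_labels, decisions = decisions,
       n_before = length(ids), n_after = length(sizes))
}

#' Cluster spots: SNN graph + Louvain + AUC-guided merging
#'
#' Convenience wrapper running [choose_k()], [build_snn_graph()],
#' [cluster_graph()], [centroid_dendrogram()] and [merge_clusters()].
#'
#' @param embedding an `embedding` (typically batch-centered).
#' @param resolution Louvain resolution (default 0.5).
#' @param merge_threshold AUC separation threshold (default 0.8).
#' @param seed integer seed.
#' @param k neighborhood size; default `choose_k(n)`.
#' @param linkage dendrogram linkage.
#' @return list with `labels_pre_merge`, `labels` (post-merge),
#'   `decisions`, `k`, `n_before`, `n_after`.
#' @export
cluster_spots <- function(embedding, resolution = 0.5,
                          merge_threshold = 0.8, seed = 1L, k = NULL,
                          linkage = "average") {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  k <- k %||% choose_k(nrow(scores))
  g <- build_snn_graph(scores, k)
  pre <- cluster_graph(g, resolution = resolution,
                       seed = stage_seed(seed, "louvain"))
  if (length(unique(pre)) < 2) {
    return(list(labels_pre_merge = pre, labels = pre, decisions = NULL,
                k = k, n_before = 1L, n_after = 1L))
  }
  tree <- centroid_dendrogram(scores, pre, linkage = linkage)
  m <- merge_clusters(tree, scores, pre, threshold = merge_threshold)
  list(labels_pre_merge = pre, labels = m$labels, decisions = m$decisions,
       k = k, n_before = m$n_before, n_after = m$n_after)
}
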