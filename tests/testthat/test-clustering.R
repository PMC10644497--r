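test_that("k follows ln(n) with round-half-away-from-zero and floor 2", {
  expect_equal(choose_k(1000), 7)    # ln(1000) = 6.9078
  expect_equal(choose_k(5000), 9)    # ln(5000) = 8.5172
  expect_equal(choose_k(8), 2)       # floor guard
  expect_equal(choose_k(2), 2)
})

test_that("SNN graph matches a brute-force kNN/Jaccard enumeration", {
  set.seed(7)
  pts <- matrix(runif(24) * 10, 12, 2)
  k <- 4
  g <- build_snn_graph(pts, k, prune = 0)
  # oracle: neighbor sets of size k including self, exhaustive pairs
  d <- as.matrix(dist(pts))
  sets <- lapply(1:12, function(i) order(d[i, ])[1:k])
  adj <- matrix(0, 12, 12)
  for (i in 1:11) for (j in (i + 1):12) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    adj[i, j] <- inter / (2 * k - inter)
  }
  got <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(got[upper.tri(got)], adj[upper.tri(adj)], tolerance = 1e-12)
})

test_that("identical points share a full neighbor set; far pairs none", {
  pts <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 0), c(0, 9))
  g <- build_snn_graph(pts, k = 4, prune = 0)
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(w[1, 2], 1)           # identical neighbor sets
  # two tight, mutually distant pairs with k = 2: disjoint neighbor sets
  far <- rbind(c(0, 0), c(0, 1), c(100, 100), c(100, 101))
  g2 <- build_snn_graph(far, k = 2, prune = 0)
  w2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(w2[1, 3], 0)
  expect_equal(w2[2, 4], 0)
  expect_error(build_snn_graph(far, k = 4), "smaller than the number")
})

test_that("Louvain separates distant blobs and is seed-deterministic", {
  blobs <- make_two_clusters(n = 50, shift = 10, seed = 11)
  g <- build_snn_graph(blobs$scores, k = 5)
  lab1 <- cluster_graph(g, resolution = 0.5, seed = 3)
  lab2 <- cluster_graph(g, resolution = 0.5, seed = 3)
  expect_identical(lab1, lab2)
  expect_equal(length(unique(lab1)), 2)
  expect_equal(mclust::adjustedRandIndex(lab1, blobs$labels), 1)
  # fully connected uniform graph at vanishing resolution: one community
  full <- igraph::make_full_graph(20)
  igraph::E(full)$weight <- 1
  expect_equal(length(unique(cluster_graph(full, resolution = 0.01,
                                           seed = 1))), 1)
})

test_that("centroid dendrogram joins the nearest collinear centroids", {
  scores <- matrix(c(rep(0, 5), rep(1, 5), rep(10, 5)), ncol = 1)
  labels <- rep(1:3, each = 5)
  tree <- centroid_dendrogram(scores, labels)
  expect_setequal(tree$cluster_ids, 1:3)
  first <- tree$hclust$merge[1, ]
  expect_setequal(-first, c(1, 2))   # clusters at 0 and 1 join first
  two <- centroid_dendrogram(scores[labels != 3, , drop = FALSE],
                             labels[labels != 3])
  expect_equal(nrow(two$hclust$merge), 1)  # 2 clusters -> single node
})

test_that("branch AUC counts concordant and tied pairs", {
  expect_equal(branch_auc(c(1, 2), c(3, 4)), 1)
  expect_equal(auc_separation(c(1, 2), c(3, 4)), 1)
  expect_equal(branch_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc_separation(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(branch_auc(c(1, 3), c(2, 4)), 3 / 4)
  expect_equal(auc_separation(c(1, 3), c(2, 4)), 0.5)
  expect_error(branch_auc(numeric(0), 1), "empty branch")
})

test_that("branch AUC is antisymmetric and matches pair enumeration", {
  set.seed(13)
  for (i in 1:30) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    l <- sample(0:6, n1, replace = TRUE)
    r <- sample(0:6, n2, replace = TRUE)
    expect_equal(branch_auc(l, r), 1 - branch_auc(r, l))
    expect_equal(2 * n1 * n2 * branch_auc(l, r), auc_oracle_2u(l, r))
    expect_equal(auc_separation(l, r), auc_separation(r, l))
  }
})

test_that("clusters merge iff no PC separates their branches", {
  same <- make_two_clusters(n = 40, shift = 0, seed = 21)
  tree <- centroid_dendrogram(same$scores, same$labels)
  m <- merge_clusters(tree, same$scores, same$labels)
  expect_equal(m$n_after, 1)
  expect_true(all(m$decisions$merged))

  split <- make_two_clusters(n = 40, shift = 8, seed = 22)
  tree2 <- centroid_dendrogram(split$scores, split$labels)
  m2 <- merge_clusters(tree2, split$scores, split$labels)
  expect_equal(m2$n_after, 2)
  expect_gt(m2$decisions$s_1[1], 0.8)
  # threshold 1.0 collapses everything (separation never exceeds 1)
  m3 <- merge_clusters(tree2, split$scores, split$labels, threshold = 1)
  expect_equal(m3$n_after, 1)
  expect_error(merge_clusters(tree2, split$scores, split$labels,
                              threshold = 1.5), "\\[0, 1\\]")
})

test_that("merging only coarsens the partition, monotonely in threshold", {
  set.seed(31)
  scores <- rbind(matrix(rnorm(60 * 10), 60, 10),
                  matrix(rnorm(60 * 10, mean = 2), 60, 10),
                  matrix(rnorm(60 * 10, mean = 8), 60, 10))
  labels <- rep(1:6, each = 30)
  tree <- centroid_dendrogram(scores, labels)
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    merge_clusters(tree, scores, labels, threshold = th)$n_after,
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  m <- merge_clusters(tree, scores, labels, threshold = 0.8)
  # every merged cluster is a union of original clusters
  tab <- table(labels, m$labels)
  expect_true(all(rowSums(tab > 0) == 1))
})
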