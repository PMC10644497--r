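test_that("lognormalize applies ln(1 + count/libsize * scale)", {
  counts <- Matrix::Matrix(matrix(c(100, 9900,   # spot s1, libsize 10000
                                    0,   50), 2, 2),  # spot s2
                           sparse = TRUE)
  rownames(counts) <- c("g1", "g2"); colnames(counts) <- c("s1", "s2")
  norm <- lognormalize(counts, scale_factor = 1e4)
  expect_equal(norm["g1", "s1"], log(101))        # libsize 10000
  expect_equal(norm["g1", "s2"], 0)               # zero stays zero
  # doubling a spot's counts leaves its normalized profile unchanged
  doubled <- counts; doubled[, 1] <- counts[, 1] * 2
  expect_equal(as.matrix(lognormalize(doubled)[, 1]),
               as.matrix(norm[, 1]))
  # monotone in count for fixed libsize
  v <- log1p(c(1, 5, 20) / 100 * 1e4)
  expect_true(all(diff(v) > 0))
})

test_that("lognormalize rejects empty input and drops all-zero spots", {
  z <- Matrix::Matrix(0, 3, 2, sparse = TRUE)
  expect_error(lognormalize(z), "all-zero")
  m <- Matrix::Matrix(matrix(c(1, 2, 0, 0), 2, 2), sparse = TRUE)
  colnames(m) <- c("keep", "drop")
  expect_message(norm <- lognormalize(m), "dropping 1")
  expect_equal(colnames(norm), "keep")
  expect_equal(attr(norm, "dropped"), "drop")
})

test_that("variable-gene ranking puts planted high-variance genes first", {
  set.seed(1)
  n_spots <- 200
  # flat genes spanning a range of means, one bimodal gene, one constant
  means <- seq(0.3, 3, length.out = 48)
  flat <- t(vapply(means, function(m)
    log1p(rpois(n_spots, exp(m))), numeric(n_spots)))
  bimodal <- ifelse(runif(n_spots) < 0.5, 0, 4) + rnorm(n_spots, 0, 0.1)
  norm <- rbind(bimodal, flat, 1.5)
  rownames(norm) <- c("planted", paste0("flat", 1:48), "constant")
  ranked <- select_variable_genes(norm, n = nrow(norm))
  expect_equal(ranked[1], "planted")
  expect_equal(ranked[length(ranked)], "constant")
  tab <- attr(ranked, "ranking")
  expect_equal(tab$standardized_variance[tab$gene == "constant"], 0)
  # n = n_genes returns every gene
  expect_setequal(ranked, rownames(norm))
  expect_error(select_variable_genes(norm[1:5, ], n = 2), "at least 10")
})

test_that("scale_center z-scores with denominator n - 1 and clips", {
  m <- matrix(c(1, 3,
                4, 4,
                0, 100), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sc <- scale_center(m, clip = 10)
  expect_equal(sc["a", ], c(s1 = -1 / sqrt(2), s2 = 1 / sqrt(2)))
  expect_equal(unname(sc["b", ]), c(0, 0))       # constant gene
  expect_true(all(abs(rowMeans(sc)) < 1e-10))
  sc1 <- scale_center(m, clip = 0.5)
  expect_true(all(abs(sc1) <= 0.5))
})

test_that("PCA matches a dense eigendecomposition and fixes signs", {
  set.seed(2)
  x <- matrix(rnorm(30 * 20), 20, 30)              # genes x spots
  sc <- scale_center(x)
  emb <- pca_embedding(sc, n_components = 10)
  ev <- eigen(stats::cov(t(sc)), symmetric = TRUE)$values
  got <- emb$variance_explained[1:3] * sum(ev)
  expect_equal(got, ev[1:3], tolerance = 1e-8)
  # score columns are centered; loadings unit-norm; sign convention
  expect_true(all(abs(colMeans(emb$scores)) < 1e-8))
  expect_equal(unname(sqrt(colSums(emb$loadings^2))), rep(1, 10))
  for (j in 1:10) {
    l <- emb$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("collinear data load entirely on PC1", {
  t_param <- seq(-1, 1, length.out = 40)
  x <- rbind(2 * t_param, -1 * t_param, 0.5 * t_param)  # genes x spots
  emb <- pca_embedding(x, n_components = 2)
  expect_equal(emb$variance_explained[1], 1, tolerance = 1e-12)
})

test_that("batch centering removes offsets, keeps the global centroid", {
  set.seed(3)
  scores <- matrix(rnorm(200 * 5), 200, 5)
  batch <- rep(c("a", "b"), each = 100)
  scores[batch == "b", 1] <- scores[batch == "b", 1] + 4
  fixed <- batch_center(scores, batch)
  expect_lt(abs(cor(fixed[, 1], as.numeric(batch == "b"))), 0.05)
  expect_equal(colMeans(fixed), colMeans(scores), tolerance = 1e-10)
  # idempotent, and identity for a single batch
  expect_equal(batch_center(fixed, batch), fixed, tolerance = 1e-12)
  one <- batch_center(scores, rep("a", 200))
  expect_equal(one, scores, tolerance = 1e-12)
})

test_that("cellular detection rate counts detected genes per spot", {
  m <- Matrix::Matrix(matrix(c(1, 0, 0, 2, 5, 0,
                               0, 0, 1, 1, 1, 1,
                               0, 0, 0, 0, 1, 3,
                               0, 0, 0, 0, 1, 2,
                               0, 0, 0, 0, 1, 9), 5, 6, byrow = TRUE),
                      sparse = TRUE)
  colnames(m) <- paste0("s", 1:6)
  cdr <- cellular_detection_rate(m)
  expect_equal(cdr$cdr[1], 1 / 5)
  expect_equal(cdr$cdr[6], 4 / 5)
  expect_equal(cdr$cdr[5], 1)                # all genes detected
  expect_equal(sum(cdr$cdr_centered), 0, tolerance = 1e-12)
  # invariant to scaling counts by a positive integer
  expect_equal(cellular_detection_rate(m * 3)$cdr, cdr$cdr)
})
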