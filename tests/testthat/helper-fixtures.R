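# shared fixtures, built in code

# two 10-D Gaussian clusters; `shift` displaces the second along dim 1
make_two_clusters <- function(n = 40, shift = 0, seed = 1, d = 10) {
  set.seed(seed)
  scores <- rbind(matrix(rnorm(n * d), n, d),
                  cbind(matrix(rnorm(n, mean = shift), n, 1),
                        matrix(rnorm(n * (d - 1)), n, d - 1)))
  labels <- rep(1:2, each = n)
  list(scores = scores, labels = labels)
}

# exhaustive pair-counting AUC oracle: returns 2 * n1 * n2 * AUC as an
# exact integer (concordant pairs count 2, ties count 1)
auc_oracle_2u <- function(left, right) {
  total <- 0L
  for (l in left) for (r in right)
    total <- total + if (r > l) 2L else if (r == l) 1L else 0L
  total
}

# brute-force hypergeometric upper tail P(X >= k)
hyper_oracle <- function(k, K, n, N) {
  js <- max(k, 0):min(K, n)
  if (length(js) == 0 || k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# small deterministic count matrix with named genes
toy_counts <- function() {
  m <- matrix(c(5, 0, 2, 1,
                0, 3, 0, 2,
                1, 1, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("Cd3e", "Cd4", "Cd8a"),
                              paste0("spot", 1:4)))
  Matrix::Matrix(m, sparse = TRUE)
}

# minimal dge_subset-style table for classification tests
fake_dge <- function(gene, log2fc, p, p_bonf, subset = "X") {
  data.frame(gene = gene, subset = subset, log2fc = log2fc, p = p,
             p_bonf = p_bonf, significant = p_bonf < 0.05)
}
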