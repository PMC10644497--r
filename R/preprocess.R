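#' Log-normalize spot counts
#'
#' Each count is divided by its spot's library size, multiplied by
#' `scale_factor`, and transformed `ln(1 + x)`; zeros map to zeros, and a
#' spot's normalized profile is invariant to scaling its counts.  All-zero
#' spots are dropped (with a message reporting how many).
#'
#' @param counts non-negative integer matrix or sparse Matrix,
#'   genes x spots.
#' @param scale_factor library-size scale factor.
#' @return sparse normalized matrix; dropped barcodes in
#'   `attr(, "dropped")`.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  counts <- to_sparse(counts)
  if (any(counts@x < 0)) stop("counts must be non-negative")
  libsize <- Matrix::colSums(counts)
  if (all(libsize == 0)) stop("all-zero count matrix: nothing to normalize")
  dropped <- colnames(counts)[libsize == 0]
  if (length(dropped)) {
    message("dropping ", length(dropped), " all-zero spot(s)")
    counts <- counts[, libsize > 0, drop = FALSE]
    libsize <- libsize[libsize > 0]
  }
  norm <- counts
  per_col <- rep.int(libsize, diff(norm@p))
  norm@x <- log1p(norm@x / per_col * scale_factor)
  attr(norm, "dropped") <- dropped
  norm
}

#' Rank genes by standardized variance
#'
#' Genes are ranked by the ratio of their observed variance (of the
#' log-normalized values) to the variance predicted by a loess trend of
#' log variance on log mean — a mean-variance-trend-corrected variable
#' feature selection.  Constant genes score 0 and rank last.
#'
#' @param normalized log-normalized matrix (genes x spots).
#' @param n number of variable genes to return.
#' @param span loess span of the mean-variance trend.
#' @return character vector of `n` gene names, most variable first; the
#'   full ranking table in `attr(, "ranking")`.
#' @export
select_variable_genes <- function(normalized, n = 2000, span = 0.5) {
  n_genes <- nrow(normalized)
  if (n_genes < 10) stop("need at least 10 genes to fit the ",
                         "mean-variance trend")
  if (n > n_genes) stop("n (", n, ") exceeds the number of genes")
  mu <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  v <- (ex2 - mu^2) * ncol(normalized) / (ncol(normalized) - 1)
  v <- pmax(v, 0)
  ok <- mu > 0 & v > 0
  std_var <- numeric(n_genes)
  if (sum(ok) >= 10) {
    fit <- loess(log(v[ok]) ~ log(mu[ok]), span = span, degree = 2)
    expected <- exp(predict(fit))
    std_var[ok] <- v[ok] / expected
  } else {
    std_var[ok] <- v[ok]
  }
  ord <- order(std_var, decreasing = TRUE)
  ranking <- data.frame(gene = rownames(normalized)[ord],
                        mean = mu[ord], variance = v[ord],
                        standardized_variance = std_var[ord])
  out <- ranking$gene[seq_len(n)]
  attr(out, "ranking") <- ranking
  out
}

#' Z-score genes across spots
#'
#' Per-gene centering and scaling to unit variance (denominator n - 1);
#' genes with zero variance become all-zero rows; values are clipped to
#' `[-clip, clip]`.
#'
#' @param normalized log-normalized matrix (genes x spots).
#' @param genes genes to keep (default all).
#' @param clip absolute clip value.
#' @return dense scaled matrix, genes x spots.
#' @export
scale_center <- function(normalized, genes = NULL, clip = 10) {
  m <- if (is.null(genes)) as.matrix(normalized) else
    as.matrix(normalized[genes, , drop = FALSE])
  mu <- rowMeans(m)
  s <- sqrt(pmax(rowSums(m^2) - ncol(m) * mu^2, 0) / (ncol(m) - 1))
  m <- (m - mu) / ifelse(s > 0, s, 1)
  m[s == 0, ] <- 0
  m[m > clip] <- clip
  m[m < -clip] <- -clip
  m
}

#' Principal component embedding of scaled expression
#'
#' Computes the top principal components of the spots-by-genes scaled
#' matrix via singular value decomposition.  The sign of each component is
#' fixed so that its largest-magnitude gene loading is positive; loadings
#' columns have unit norm and components are ordered by non-increasing
#' variance explained.
#'
#' @param scaled genes x spots scaled matrix (from [scale_center()]).
#' @param n_components number of components (default 10).
#' @return an `embedding` list: `scores` (spots x PCs), `loadings`
#'   (genes x PCs, unit columns), `variance_explained`.
#' @export
pca_embedding <- function(scaled, n_components = 10) {
  x <- t(scaled)                       # spots x genes, columns centered
  n_components <- min(n_components, dim(x) - c(1L, 0L))
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)],
                                n_components), 2L, flip, `*`)
  loadings <- sweep(sv$v, 2L, flip, `*`)
  dimnames(scores) <- list(rownames(x),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(x), colnames(scores))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = sv$d[seq_len(n_components)]^2 /
                   sum(sv$d^2)),
            class = "embedding")
}

#' Center out per-batch offsets in PC space
#'
#' Subtracts each batch's centroid and restores the global centroid, per
#' principal component.  This is a simplified batch-mixing stage: it
#' removes constant per-slide offsets in the embedding (the dominant
#' Visium batch artefact) and is idempotent; externally corrected
#' embeddings can be supplied to downstream steps instead.
#'
#' @param embedding an `embedding` (or bare score matrix).
#' @param batch factor-like batch (slide) id per spot.
#' @return same type as the input with corrected scores.
#' @export
batch_center <- function(embedding, batch) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    embedding
  stopifnot(nrow(scores) == length(batch))
  batch <- as.factor(batch)
  global <- colMeans(scores)
  centroids <- apply(scores, 2L, function(col) tapply(col, batch, mean))
  centroids <- matrix(centroids, nlevels(batch), ncol(scores))
  corrected <- scores - centroids[as.integer(batch), , drop = FALSE] +
    rep(global, each = nrow(scores))
  dimnames(corrected) <- dimnames(scores)
  if (inherits(embedding, "embedding")) {
    embedding$scores <- corrected
    embedding
  } else corrected
}

#' Cellular detection rate per spot
#'
#' The fraction of genes detected (count > 0) in each spot, the nuisance
#' covariate of the hurdle model.
#'
#' @param counts genes x spots count matrix.
#' @return data.frame with `barcode`, `cdr` in `[0, 1]` and the cohort-
#'   mean-centered `cdr_centered`.
#' @export
cellular_detection_rate <- function(counts) {
  cdr <- Matrix::colSums(counts > 0) / nrow(counts)
  data.frame(barcode = colnames(counts) %||%
               sprintf("spot%04d", seq_along(cdr)),
             cdr = as.numeric(cdr),
             cdr_centered = as.numeric(cdr - mean(cdr)))
}
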