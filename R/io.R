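#' Write a spot dataset as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer), `features.tsv`
#' (gene_id, gene_symbol), `barcodes.tsv`, a `positions.csv` spot table
#' (barcode, in_tissue, array_row, array_col, x_um, y_um) and the ground
#' truth as `truth.tsv`.
#'
#' @param dataset a `spot_dataset` from [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spot_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- dataset$counts
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  g <- dataset$gene_model$genes
  write.table(data.frame(gene_id = g$gene_id, gene_symbol = g$symbol),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  geo <- dataset$geometry
  pos <- data.frame(barcode = geo$barcode,
                    in_tissue = as.integer(geo$in_tissue),
                    array_row = geo$array_row, array_col = geo$array_col,
                    x_um = geo$x_um, y_um = geo$y_um)
  write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE,
            quote = FALSE)
  truth <- geo[, c("barcode", "section_index", "region_true", "zone_true",
                   "lesion_id_true", "level_true")]
  truth$condition <- dataset$condition
  truth$slide_id <- dataset$slide_id
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style triplet directory into a spot dataset
#'
#' Parses `matrix.mtx` + `features.tsv` + `barcodes.tsv` + `positions.csv`
#' (and `truth.tsv` when present), validating dimension agreement and
#' barcode uniqueness.
#'
#' @param dir directory written by [write_spot_dataset()] or following the
#'   same convention.
#' @return a `spot_dataset`-like list with `counts`, `features`,
#'   `geometry` and, if available, ground-truth columns merged into
#'   `geometry`.
#' @export
read_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  header <- readLines(mtx, n = 1L)
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", header))
    stop("malformed MatrixMarket header in ", mtx, ": ", header)
  m <- to_sparse(Matrix::readMM(mtx))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      col.names = c("gene_id", "gene_symbol"),
                      stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes in barcodes.tsv: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  if (nrow(m) != nrow(feats))
    stop("dimension mismatch: matrix has ", nrow(m), " rows but ",
         nrow(feats), " features")
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: matrix has ", ncol(m), " columns but ",
         length(barcodes), " barcodes")
  dimnames(m) <- list(feats$gene_symbol, barcodes)
  geometry <- NULL
  pos_path <- file.path(dir, "positions.csv")
  if (file.exists(pos_path)) {
    geometry <- read.csv(pos_path, stringsAsFactors = FALSE)
    if (!all(colnames(m) %in% geometry$barcode))
      stop("positions.csv does not cover all matrix barcodes")
    geometry <- geometry[match(colnames(m), geometry$barcode), ,
                         drop = FALSE]
    rownames(geometry) <- NULL
  }
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path) && !is.null(geometry)) {
    truth <- read.delim(truth_path, stringsAsFactors = FALSE)
    geometry <- cbind(geometry,
                      truth[match(geometry$barcode, truth$barcode),
                            setdiff(names(truth), "barcode"), drop = FALSE])
    rownames(geometry) <- NULL
  }
  structure(list(counts = m, features = feats, geometry = geometry),
            class = "spot_dataset")
}

#' Read a GMT-format term annotation file
#'
#' Each line: term_id, description, then tab-separated gene identifiers.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[[`, "", 1L)
  attr(out, "description") <- vapply(parts, `[[`, "", 2L)
  out
}

#' Write a term annotation as GMT
#'
#' @param annotations named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional descriptions (defaults to the term ids).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(annotations)
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(annotations), descriptions, annotations)
  writeLines(unname(lines), path)
  invisible(path)
}
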