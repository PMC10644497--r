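#' Annotate clusters with anatomical compartments
#'
#' Assigns each spot the compartment (WM / GM / excluded) of its cluster,
#' from an explicit cluster -> compartment map (mirroring manual H&E-based
#' annotation) or, on synthetic data, from [majority_annotation()].
#'
#' @param labels cluster label per spot (named by barcode).
#' @param annotation_map data.frame with columns `cluster` and
#'   `compartment` (values in WM, GM, excluded).
#' @return data.frame `spot_id`, `cluster`, `compartment`.
#' @export
annotate_compartments <- function(labels, annotation_map) {
  if (is.null(annotation_map) || nrow(annotation_map) == 0)
    stop("empty annotation map: every cluster needs a compartment")
  stopifnot(all(c("cluster", "compartment") %in% names(annotation_map)))
  bad <- setdiff(annotation_map$compartment, c("WM", "GM", "excluded"))
  if (length(bad)) stop("unknown compartment(s): ",
                        paste(bad, collapse = ", "))
  missing <- setdiff(unique(labels), annotation_map$cluster)
  if (length(missing))
    stop("unannotated cluster(s): ", paste(sort(missing), collapse = ", "))
  comp <- annotation_map$compartment[match(labels, annotation_map$cluster)]
  data.frame(spot_id = names(labels) %||%
               sprintf("spot%04d", seq_along(labels)),
             cluster = as.vector(labels), compartment = comp)
}

#' Majority-vote cluster annotation from ground truth
#'
#' Builds a cluster -> compartment map by majority vote of the true
#' per-spot regions (the synthetic stand-in for the manual H&E
#' cross-referencing step).  Background-majority clusters map to
#' `excluded`.
#'
#' @param labels cluster label per spot.
#' @param region_true per-spot true region (WM / GM / background).
#' @return annotation map data.frame (`cluster`, `compartment`).
#' @export
majority_annotation <- function(labels, region_true) {
  stopifnot(length(labels) == length(region_true))
  tab <- table(labels, region_true)
  winner <- colnames(tab)[apply(tab, 1L, which.max)]
  winner[winner == "background"] <- "excluded"
  data.frame(cluster = as.integer(rownames(tab)), compartment = winner)
}

#' Label lesion spots by T-cell marker co-detection
#'
#' A spot is a lesion if it shows any expression (raw count > 0) of at
#' least `min_positive` of the marker genes (default the T-cell markers
#' Cd3e, Cd4, Cd8a — the murine stand-ins for CD3/CD4/CD8).
#'
#' @param counts genes x spots raw count matrix.
#' @param markers marker gene names (rows of `counts`).
#' @param min_positive minimum number of detected markers.
#' @return named logical vector per spot.
#' @export
label_lesion_spots <- function(counts,
                               markers = c("Cd3e", "Cd4", "Cd8a"),
                               min_positive = 2L) {
  missing <- setdiff(markers, rownames(counts))
  if (length(missing))
    stop("marker gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  hits <- Matrix::colSums(counts[markers, , drop = FALSE] > 0)
  out <- as.vector(hits) >= min_positive
  names(out) <- colnames(counts)
  out
}

#' Split white-matter spots into the WML and NAWM subsets
#'
#' White-matter spots labeled lesions form the "WML" subset; the remaining
#' white-matter spots form the "NAWM" subset.  The two sets are disjoint
#' and cover exactly the WM spots; lesion flags outside the white matter
#' are ignored.
#'
#' @param compartments data.frame from [annotate_compartments()].
#' @param lesion named logical from [label_lesion_spots()] (matched by
#'   `spot_id`).
#' @return list with character vectors `wml` and `nawm` of spot ids and a
#'   per-spot `subset` factor (WML / NAWM / none).
#' @export
make_dge_subsets <- function(compartments, lesion) {
  les <- lesion[match(compartments$spot_id, names(lesion))]
  wm <- compartments$compartment == "WM"
  wml <- compartments$spot_id[wm & les %in% TRUE]
  nawm <- compartments$spot_id[wm & !(les %in% TRUE)]
  if (length(wml) == 0 && any(wm))
    warning("no lesion spots in the white matter; WML subset is empty ",
            "and WML DGE will be skipped")
  subset <- rep("none", nrow(compartments))
  subset[compartments$spot_id %in% wml] <- "WML"
  subset[compartments$spot_id %in% nawm] <- "NAWM"
  list(wml = wml, nawm = nawm,
       subset = factor(subset, levels = c("WML", "NAWM", "none")))
}
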