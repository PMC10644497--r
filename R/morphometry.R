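#' Relative lesion size per section
#'
#' `lesion_area / (total_section_area - grey_matter_area) * 100` — the
#' lesion's share of the section's white matter, in percent.
#'
#' @param lesion_area,total_area,grey_area areas in the same units
#'   (vectorized).
#' @return percent.
#' @export
relative_lesion_size <- function(lesion_area, total_area, grey_area) {
  if (any(lesion_area < 0)) stop("negative lesion area")
  if (any(grey_area >= total_area))
    stop("grey matter area must be smaller than the total section area")
  if (any(lesion_area > total_area - grey_area))
    stop("lesion area exceeds the white matter area")
  lesion_area / (total_area - grey_area) * 100
}

#' Classify a lesion's CSF contact from its section track
#'
#' A lesion is `without_contact` only when five consecutive observed
#' sections all lack contact and no section shows contact; any contact in
#' any section gives `with_contact`.  A lesion observed in fewer than five
#' sections without any contact cannot satisfy the rule and defaults to
#' `with_contact` with an `indeterminate` flag.
#'
#' @param contact_track logical per-section contact flags, ordered by
#'   section index (or a comma-joined 0/1 string).
#' @return list `class` ("with_contact"/"without_contact") and
#'   `indeterminate`.
#' @export
classify_csf_contact <- function(contact_track) {
  if (is.character(contact_track))
    contact_track <- as.logical(as.integer(
      strsplit(contact_track, ",", fixed = TRUE)[[1]]))
  contact_track <- as.logical(contact_track)
  if (length(contact_track) == 0 || anyNA(contact_track))
    stop("contact track must be non-empty logical values")
  if (any(contact_track))
    return(list(class = "with_contact", indeterminate = FALSE))
  runs <- rle(!contact_track)
  if (any(runs$lengths[runs$values] >= 5))
    list(class = "without_contact", indeterminate = FALSE)
  else
    list(class = "with_contact", indeterminate = TRUE)
}

#' Per-animal lesion burden by anatomical category
#'
#' Sums relative lesion sizes per combination of level (cervical /
#' thoracic / lumbar), position (anterolateral / dorsal) and CSF contact,
#' plus the level x position, level, and position marginals; absent
#' categories are 0.
#'
#' @param lesions lesion table with columns `animal_id`, `level`,
#'   `position`, `csf_contact`, `relative_size_pct`.
#' @param animals optional animal ids defining the rows (animals without
#'   lesions get all-zero burdens).
#' @return matrix animals x categories of summed relative sizes (percent).
#' @export
category_burden <- function(lesions, animals = NULL) {
  levels3 <- c("cervical", "thoracic", "lumbar")
  pos2 <- c("anterolateral", "dorsal")
  animals <- animals %||% sort(unique(lesions$animal_id))
  cats <- c(
    as.vector(outer(as.vector(outer(levels3, pos2, paste, sep = "_")),
                    c("with_contact", "without_contact"), paste,
                    sep = "_")),
    as.vector(outer(levels3, pos2, paste, sep = "_")),
    levels3, pos2, "total")
  burden <- matrix(0, length(animals), length(cats),
                   dimnames = list(animals, cats))
  if (is.null(lesions) || nrow(lesions) == 0) return(burden)
  contact_tag <- ifelse(lesions$csf_contact, "with_contact",
                        "without_contact")
  keys <- list(paste(lesions$level, lesions$position, contact_tag,
                     sep = "_"),
               paste(lesions$level, lesions$position, sep = "_"),
               lesions$level, lesions$position,
               rep("total", nrow(lesions)))
  for (key in keys) {
    agg <- tapply(lesions$relative_size_pct,
                  list(lesions$animal_id, key), sum)
    hit_a <- intersect(rownames(agg), animals)
    hit_c <- intersect(colnames(agg), cats)
    vals <- agg[hit_a, hit_c, drop = FALSE]
    vals[is.na(vals)] <- 0
    burden[hit_a, hit_c] <- burden[hit_a, hit_c] + vals
  }
  burden
}

#' Pearson or Spearman correlation with a t-based two-sided p-value
#'
#' Pearson is the standard product-moment correlation; Spearman is the
#' Pearson correlation of the average-ranked values, with the same
#' t-distribution p-value machinery.
#'
#' @param x,y numeric vectors without missing pairs, length at least 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list `r`, `p`, `n`, `method`.
#' @export
correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, method = method))
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n, method = method)
}

#' Correlation heat map of sNfL against per-category lesion burdens
#'
#' For each cohort (condition) and anatomical burden category, the
#' correlation between per-animal sNfL and the summed relative lesion
#' size in that category.  Zero-variance categories are flagged
#' undefined (NA).
#'
#' @param burdens animals x categories matrix from [category_burden()].
#' @param animals data.frame with `animal_id`, `condition`, `snfl`.
#' @param method correlation method (default `"spearman"`).
#' @param conditions cohorts analysed (default early and late).
#' @return list of per-cohort data.frames (`category`, `r`, `p`, `n`,
#'   `undefined`).
#' @export
snfl_heatmap <- function(burdens, animals, method = "spearman",
                         conditions = c("early", "late")) {
  out <- list()
  for (cond in conditions) {
    ids <- animals$animal_id[animals$condition == cond]
    ids <- intersect(ids, rownames(burdens))
    snfl <- animals$snfl[match(ids, animals$animal_id)]
    rows <- lapply(colnames(burdens), function(cat) {
      b <- burdens[ids, cat]
      if (sd(b) == 0 || sd(snfl) == 0)
        return(data.frame(category = cat, r = NA_real_, p = NA_real_,
                          n = length(ids), undefined = TRUE))
      ct <- correlation(b, snfl, method = method)
      data.frame(category = cat, r = ct$r, p = ct$p, n = ct$n,
                 undefined = FALSE)
    })
    out[[cond]] <- do.call(rbind, rows)
  }
  out
}

#' Per-animal lesion/NAWM ratio of an ROI measure
#'
#' Mean of the WML regions of interest divided by the mean of the NAWM
#' ROIs, per animal; undefined (NA, flagged) when the NAWM mean is 0.
#'
#' @param roi data.frame with `animal_id`, `compartment` (WML/NAWM),
#'   `measure`, `value`.
#' @param measure which measure to ratio (e.g. `"smi32_count"`).
#' @return data.frame `animal_id`, `condition` (if present), `wml_mean`,
#'   `nawm_mean`, `ratio`, `undefined`.
#' @export
compartment_ratio <- function(roi, measure) {
  sub <- roi[roi$measure == measure, , drop = FALSE]
  if (nrow(sub) == 0) stop("no ROI rows for measure ", measure)
  ids <- unique(sub$animal_id)
  rows <- lapply(ids, function(a) {
    s <- sub[sub$animal_id == a, ]
    wm <- mean(s$value[s$compartment == "WML"])
    nw <- mean(s$value[s$compartment == "NAWM"])
    data.frame(animal_id = a,
               condition = if ("condition" %in% names(s))
                 s$condition[1] else NA_character_,
               wml_mean = wm, nawm_mean = nw,
               ratio = if (nw > 0) wm / nw else NA_real_,
               undefined = !(nw > 0))
  })
  do.call(rbind, rows)
}

#' Compare a measurement between two cohorts
#'
#' Normality is assessed per group (Shapiro-Wilk at 0.05); when both
#' groups pass, a two-sided Student's t-test is used, otherwise a
#' two-sided Mann-Whitney U test.  The chosen branch is reported.
#'
#' @param x numeric values.
#' @param group two-level factor.
#' @return list `p`, `test` ("t" or "wilcoxon"), group means.
#' @export
compare_groups <- function(x, group) {
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2)
  xs <- split(x, group)
  normal <- vapply(xs, function(v)
    length(v) >= 3 && length(unique(v)) > 1 &&
      shapiro.test(v)$p.value >= 0.05, logical(1))
  if (all(normal)) {
    list(p = t.test(xs[[1]], xs[[2]])$p.value, test = "t",
         means = vapply(xs, mean, numeric(1)))
  } else {
    list(p = suppressWarnings(wilcox.test(xs[[1]], xs[[2]])$p.value),
         test = "wilcoxon", means = vapply(xs, mean, numeric(1)))
  }
}
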