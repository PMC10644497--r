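#' Configuration for the synthetic spinal-cord geometry
#'
#' Describes one Visium-like capture area holding coronal spinal-cord
#' sections on a square spot grid.  Grey matter (GM) is modelled as two
#' mirrored ellipses (the "butterfly"), white matter (WM) as the enclosing
#' ellipse minus the GM, and lesions as discs placed fully inside the WM
#' ring.  A lesion is CSF-contacting when its disc touches the outer WM
#' (pial) boundary.
#'
#' @param n_sections number of sections per capture area.
#' @param pitch_um spot grid pitch in microns.
#' @param outer_semiaxes semi-axes (a, b) of the outer WM boundary, microns.
#' @param gm_offset_um lateral offset of the two GM ellipse centres.
#' @param gm_semiaxes semi-axes of each GM ellipse, microns.
#' @param n_lesions_per_section lesions planted per section.
#' @param lesion_radius_um lesion disc radius, microns.
#' @param p_dorsal probability a lesion is placed in the dorsal zone
#'   (otherwise anterolateral).
#' @param p_csf_contact probability a lesion is placed touching the pial
#'   boundary (CSF contact).
#' @param max_spots_per_area maximum in-tissue spots per capture area
#'   (Visium capture areas hold roughly 5000 spots).
#' @param levels rostro-caudal levels cycled over sections.
#' @return a `cord_sim_config` list.
#' @export
cord_sim_config <- function(n_sections = 1L,
                            pitch_um = 100,
                            outer_semiaxes = c(2000, 1400),
                            gm_offset_um = 620,
                            gm_semiaxes = c(520, 460),
                            n_lesions_per_section = 2L,
                            lesion_radius_um = 280,
                            p_dorsal = 0.25,
                            p_csf_contact = 0.8,
                            max_spots_per_area = 5000L,
                            levels = c("cervical", "thoracic", "lumbar")) {
  cfg <- list(n_sections = as.integer(n_sections), pitch_um = pitch_um,
              outer_semiaxes = outer_semiaxes, gm_offset_um = gm_offset_um,
              gm_semiaxes = gm_semiaxes,
              n_lesions_per_section = as.integer(n_lesions_per_section),
              lesion_radius_um = lesion_radius_um, p_dorsal = p_dorsal,
              p_csf_contact = p_csf_contact,
              max_spots_per_area = as.integer(max_spots_per_area),
              levels = levels)
  ring_width <- outer_semiaxes[1] - (gm_offset_um + gm_semiaxes[1])
  if (cfg$n_lesions_per_section > 0 && lesion_radius_um > 0.45 * ring_width)
    stop("lesion radius ", lesion_radius_um,
         " um exceeds the WM ring width (", round(ring_width),
         " um); reduce lesion_radius_um or widen the WM ring")
  class(cfg) <- "cord_sim_config"
  cfg
}

ellipse_s <- function(x, y, a, b) sqrt((x / a)^2 + (y / b)^2)

# radial distance from an interior point to the outer ellipse boundary,
# measured along the ray from the origin
radial_gap <- function(x, y, a, b) {
  s <- ellipse_s(x, y, a, b)
  sqrt(x^2 + y^2) * (1 / s - 1)
}

in_gm <- function(x, y, cfg) {
  g <- cfg$gm_semiaxes
  ellipse_s(x - cfg$gm_offset_um, y, g[1], g[2]) <= 1 |
    ellipse_s(x + cfg$gm_offset_um, y, g[1], g[2]) <= 1
}

#' Generate the spot-level geometry of a synthetic spinal-cord capture area
#'
#' Lays a square spot grid over `n_sections` coronal sections, assigns each
#' spot a true compartment (WM / GM / background), and plants lesion discs
#' inside the white matter with an anatomical zone (anterolateral or
#' dorsal) and a CSF-contact flag (disc touches the pial boundary).
#' Deterministic for a fixed `(config, seed)` pair.
#'
#' @param config a [cord_sim_config()].
#' @param seed integer seed.
#' @return a data.frame of grid spots with columns `spot_id`,
#'   `section_index`, `array_row`, `array_col`, `x_um`, `y_um`,
#'   `in_tissue`, `region_true`, `zone_true`, `lesion_id_true`,
#'   `level_true`; the planted lesion table is attached as
#'   `attr(, "lesions")`.
#' @export
generate_cord_geometry <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cord_sim_config"))
  with_seed(seed, {
    a <- config$outer_semiaxes[1]; b <- config$outer_semiaxes[2]
    p <- config$pitch_um
    xs <- seq(-a, a, by = p); ys <- seq(-b, b, by = p)
    grid <- expand.grid(array_col = seq_along(xs), array_row = seq_along(ys))
    sections <- vector("list", config$n_sections)
    lesion_rows <- list()
    row_block <- length(ys) + 2L
    for (sec in seq_len(config$n_sections)) {
      g <- grid
      g$section_index <- sec
      g$x_um <- xs[g$array_col]
      g$y_um <- ys[g$array_row]
      g$array_row <- g$array_row + (sec - 1L) * row_block
      g$in_tissue <- ellipse_s(g$x_um, g$y_um, a, b) <= 1
      g$region_true <- ifelse(!g$in_tissue, "background",
                              ifelse(in_gm(g$x_um, g$y_um, config),
                                     "GM", "WM"))
      g$zone_true <- "none"
      g$lesion_id_true <- NA_character_
      g$level_true <- config$levels[(sec - 1L) %% length(config$levels) + 1L]
      r <- config$lesion_radius_um
      n_les <- config$n_lesions_per_section
      if (n_les > 0) {
        for (j in seq_len(n_les)) {
          placed <- FALSE
          for (try in 1:200) {
            dorsal <- runif(1) < config$p_dorsal
            theta <- if (dorsal) runif(1, 50, 130) * pi / 180 else {
              # anterolateral: lateral and ventral arc
              runif(1, 150, 390) %% 360 * pi / 180
            }
            bx <- a * cos(theta); by <- b * sin(theta)
            contact <- runif(1) < config$p_csf_contact
            shrink <- if (contact) 1 - r / sqrt(bx^2 + by^2) else
              1 - 2 * r / sqrt(bx^2 + by^2)
            cx <- bx * shrink; cy <- by * shrink
            gsem <- config$gm_semiaxes
            clear <- min(ellipse_s(cx - config$gm_offset_um, cy,
                                   gsem[1], gsem[2]),
                         ellipse_s(cx + config$gm_offset_um, cy,
                                   gsem[1], gsem[2]))
            if (clear >= 1 + r / min(gsem)) { placed <- TRUE; break }
          }
          if (!placed)
            stop("could not place a lesion of radius ", r,
                 " um inside the WM ring; the radius exceeds the usable ",
                 "ring width for this geometry")
          id <- sprintf("sec%02d_les%d", sec, j)
          member <- g$in_tissue & g$region_true == "WM" &
            (g$x_um - cx)^2 + (g$y_um - cy)^2 <= r^2 &
            is.na(g$lesion_id_true)
          zone <- if (dorsal) "dorsal" else "anterolateral"
          g$lesion_id_true[member] <- id
          g$zone_true[member] <- zone
          lesion_rows[[length(lesion_rows) + 1L]] <- data.frame(
            lesion_id = id, section_index = sec, zone = zone,
            x_um = cx, y_um = cy, radius_um = r,
            csf_contact_true = radial_gap(cx, cy, a, b) <= r * 1.05,
            level_true = g$level_true[1], n_spots = sum(member))
        }
      }
      sections[[sec]] <- g
    }
    geom <- do.call(rbind, sections)
    geom$spot_id <- sprintf("s%02d_r%03d_c%03d", geom$section_index,
                            geom$array_row, geom$array_col)
    n_in <- sum(geom$in_tissue)
    if (n_in > config$max_spots_per_area)
      stop("configuration yields ", n_in, " in-tissue spots, more than the ",
           config$max_spots_per_area, " a capture area can hold")
    geom <- geom[, c("spot_id", "section_index", "array_row", "array_col",
                     "x_um", "y_um", "in_tissue", "region_true", "zone_true",
                     "lesion_id_true", "level_true")]
    rownames(geom) <- NULL
    attr(geom, "lesions") <-
      if (length(lesion_rows)) do.call(rbind, lesion_rows) else
        data.frame(lesion_id = character(), section_index = integer(),
                   zone = character(), x_um = numeric(), y_um = numeric(),
                   radius_um = numeric(), csf_contact_true = logical(),
                   level_true = character(), n_spots = integer())
    geom
  })
}

#' Construct the gene-level generative model
#'
#' Genes receive a negative-binomial baseline mean and dispersion, and
#' planted log2 effects: T-cell marker genes (default Cd3e, Cd4, Cd8a)
#' folded up in lesion spots, grey/white-matter program genes defining the
#' anatomical domains, a lesion expression program, and condition effects
#' (early vs late, positive = higher in early) planted separately for the
#' lesion ("WML") and surrounding white matter ("NAWM") subsets.  Genes
#' with no planted condition effect have log2 fold change exactly 0.
#' Condition-regulated genes carry a true functional module label used to
#' build the synthetic term annotation.
#'
#' @param n_genes total number of genes.
#' @param seed integer seed.
#' @param markers lesion marker gene symbols.
#' @param marker_baseline NB baseline mean of the markers.
#' @param marker_lesion_log2fc lesion fold-up of the markers (log2).
#' @param n_region_genes genes per anatomical (GM and WM) program.
#' @param region_log2fc log2 fold-up of program genes in their domain.
#' @param n_lesion_program genes up-regulated in lesion spots.
#' @param lesion_program_log2fc their log2 fold-up.
#' @param n_de_both,n_de_nawm_only,n_de_wml_only numbers of planted
#'   condition-regulated genes per concordance group.
#' @param de_wml_log2fc,de_nawm_log2fc effect sizes (log2, early vs late)
#'   in the two subsets for genes regulated there; genes regulated in only
#'   one subset get `weak_log2fc` in the other (same sign).
#' @param weak_log2fc sub-threshold effect used in the non-significant
#'   subset of singly-regulated genes.
#' @param baseline_meanlog,baseline_sdlog log-normal NB baseline means.
#' @param size_shape,size_rate gamma parameters of the NB size (dispersion).
#' @param batch_sd SD of per-slide log2 batch offsets drawn at simulation.
#' @return a `gene_model` list with a per-gene data.frame `genes` and the
#'   simulation parameters.
#' @export
make_gene_model <- function(n_genes = 400L, seed = 1L,
                            markers = c("Cd3e", "Cd4", "Cd8a"),
                            marker_baseline = 0.25,
                            marker_lesion_log2fc = 4,
                            n_region_genes = 50L, region_log2fc = 2.5,
                            n_lesion_program = 40L,
                            lesion_program_log2fc = 2,
                            n_de_both = 15L, n_de_nawm_only = 15L,
                            n_de_wml_only = 5L,
                            de_wml_log2fc = 1.5, de_nawm_log2fc = 1.2,
                            weak_log2fc = 0.45,
                            baseline_meanlog = log(0.5), baseline_sdlog = 1,
                            size_shape = 3, size_rate = 1.5,
                            batch_sd = 0.25) {
  n_genes <- as.integer(n_genes)
  need <- length(markers) + 2L * n_region_genes + n_lesion_program +
    n_de_both + n_de_nawm_only + n_de_wml_only
  if (n_genes < need + 20L)
    stop("n_genes too small for the planted structure (need at least ",
         need + 20L, ")")
  with_seed(seed, {
    symbol <- c(markers, sprintf("Gene%04d", seq_len(n_genes - length(markers))))
    baseline <- pmin(pmax(rlnorm(n_genes, baseline_meanlog, baseline_sdlog),
                          0.02), 30)
    size <- pmax(rgamma(n_genes, size_shape, size_rate), 0.3)
    baseline[seq_along(markers)] <- marker_baseline
    size[seq_along(markers)] <- 2
    g <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                    symbol = symbol, baseline_mean = baseline, size = size,
                    gm_log2fc = 0, wm_log2fc = 0, lesion_log2fc = 0,
                    de_wml_log2fc = 0, de_nawm_log2fc = 0,
                    module_true = NA_character_,
                    stringsAsFactors = FALSE)
    g$lesion_log2fc[seq_along(markers)] <- marker_lesion_log2fc
    i <- length(markers)
    idx <- function(n) { out <- i + seq_len(n); i <<- i + n; out }
    gm_idx <- idx(n_region_genes); g$gm_log2fc[gm_idx] <- region_log2fc
    wm_idx <- idx(n_region_genes); g$wm_log2fc[wm_idx] <- region_log2fc
    les_idx <- idx(n_lesion_program)
    g$lesion_log2fc[les_idx] <- lesion_program_log2fc
    sgn <- function(n) rep_len(c(1, -1), n)
    both <- idx(n_de_both)
    g$de_wml_log2fc[both] <- sgn(n_de_both) * de_wml_log2fc
    g$de_nawm_log2fc[both] <- sgn(n_de_both) * de_nawm_log2fc
    nawm <- idx(n_de_nawm_only)
    g$de_nawm_log2fc[nawm] <- sgn(n_de_nawm_only) * de_nawm_log2fc
    g$de_wml_log2fc[nawm] <- sgn(n_de_nawm_only) * weak_log2fc
    wml <- idx(n_de_wml_only)
    g$de_wml_log2fc[wml] <- sgn(n_de_wml_only) * de_wml_log2fc
    g$de_nawm_log2fc[wml] <- sgn(n_de_wml_only) * weak_log2fc
    de <- c(both, nawm, wml)
    up_early <- de[g$de_nawm_log2fc[de] > 0 | g$de_wml_log2fc[de] > 0]
    g$module_true[de] <- "gliogenesis"
    g$module_true[up_early] <- "cytochemokine_response"
    structure(list(genes = g, markers = markers, batch_sd = batch_sd,
                   planted = list(both = g$symbol[both],
                                  nawm_only = g$symbol[nawm],
                                  wml_only = g$symbol[wml])),
              class = "gene_model")
  })
}

#' Simulate spot counts for one capture area
#'
#' Counts are drawn from a negative binomial with mean
#' `baseline * 2^(sum of applicable log2 effects) * libsize_factor` and the
#' gene's size (dispersion) parameter.  Applicable effects: anatomical
#' program (GM/WM), lesion program and marker fold-up in lesion spots, the
#' planted condition effect (early condition only; in lesion spots the WML
#' effect, in other WM spots the NAWM effect), and a per-slide batch
#' offset.
#'
#' @param geometry output of [generate_cord_geometry()].
#' @param gene_model a [make_gene_model()] object.
#' @param condition one of `"healthy"`, `"early"`, `"late"`.
#' @param slide_id slide/batch identifier (prefixes barcodes).
#' @param seed integer seed.
#' @param libsize_meanlog,libsize_sdlog log-normal spot library-size
#'   factors.
#' @param libsize_factors optional explicit per-spot factors (overrides the
#'   log-normal draw); a factor of 0 yields an all-zero spot.
#' @param batch_log2fc optional per-gene log2 batch offset; by default
#'   drawn `N(0, batch_sd)` from the slide's seed.
#' @return a `spot_dataset`: list with sparse integer `counts`
#'   (genes x spots), the in-tissue `geometry` (with `barcode`),
#'   `slide_id`, `condition`, `libsize_factors` and the `gene_model`.
#' @export
simulate_counts <- function(geometry, gene_model,
                            condition = c("healthy", "early", "late"),
                            slide_id = "slide1", seed = 1L,
                            libsize_meanlog = 0, libsize_sdlog = 0.15,
                            libsize_factors = NULL, batch_log2fc = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(gene_model, "gene_model"))
  g <- gene_model$genes
  tissue <- geometry[geometry$in_tissue, , drop = FALSE]
  n_spots <- nrow(tissue); n_genes <- nrow(g)
  with_seed(seed, {
    if (is.null(libsize_factors))
      libsize_factors <- rlnorm(n_spots, libsize_meanlog, libsize_sdlog)
    stopifnot(length(libsize_factors) == n_spots, all(libsize_factors >= 0))
    if (is.null(batch_log2fc))
      batch_log2fc <- rnorm(n_genes, 0, gene_model$batch_sd)
    gm_ind <- tissue$region_true == "GM"
    wm_ind <- tissue$region_true == "WM"
    les_ind <- wm_ind & !is.na(tissue$lesion_id_true)
    nawm_ind <- wm_ind & !les_ind
    cond_on <- as.numeric(condition == "early")
    log2mu <- matrix(log2(g$baseline_mean) + batch_log2fc,
                     n_genes, n_spots) +
      outer(g$gm_log2fc, as.numeric(gm_ind)) +
      outer(g$wm_log2fc, as.numeric(wm_ind)) +
      outer(g$lesion_log2fc, as.numeric(les_ind)) +
      cond_on * outer(g$de_wml_log2fc, as.numeric(les_ind)) +
      cond_on * outer(g$de_nawm_log2fc, as.numeric(nawm_ind))
    mu <- 2^log2mu * rep(libsize_factors, each = n_genes)
    counts <- matrix(rnbinom(n_genes * n_spots, mu = as.vector(mu),
                             size = rep(g$size, times = n_spots)),
                     n_genes, n_spots)
    barcodes <- paste0(slide_id, ":", tissue$spot_id)
    dimnames(counts) <- list(g$symbol, barcodes)
    tissue$barcode <- barcodes
    structure(list(counts = to_sparse(counts),
                   geometry = tissue, slide_id = slide_id,
                   condition = condition,
                   libsize_factors = libsize_factors,
                   gene_model = gene_model),
              class = "spot_dataset")
  })
}

#' Simulate a plain two-group count experiment
#'
#' A geometry-free negative-binomial simulator for calibration and power
#' experiments: two conditions (early/late), optional planted per-gene log2
#' fold changes (positive = higher in early), and optionally different
#' library-size distributions per condition, which confounds the detection
#' rate with condition.
#'
#' @param n_genes,n_per_group problem size.
#' @param seed integer seed.
#' @param log2fc per-gene planted effect (recycled; 0 = null).
#' @param libsize_meanlog length-2 meanlog of the library-size factors for
#'   (early, late); unequal values plant a CDR/condition confound.
#' @param libsize_sdlog log-normal sd of library-size factors.
#' @param baseline_meanlog,baseline_sdlog,size_shape,size_rate NB gene
#'   parameters.
#' @param baseline_mean optional explicit per-gene baseline means
#'   (recycled); overrides the log-normal draw where not `NA`.
#' @return list with sparse `counts` (genes x spots), `condition` factor,
#'   `libsize_factors` and the planted `log2fc`.
#' @export
simulate_two_group_counts <- function(n_genes = 500L, n_per_group = 200L,
                                      seed = 1L, log2fc = 0,
                                      libsize_meanlog = c(0, 0),
                                      libsize_sdlog = 0.3,
                                      baseline_meanlog = log(0.8),
                                      baseline_sdlog = 0.7,
                                      size_shape = 3, size_rate = 1.5,
                                      baseline_mean = NULL) {
  with_seed(seed, {
    n_spots <- 2L * n_per_group
    condition <- factor(rep(c("early", "late"), each = n_per_group),
                        levels = c("early", "late"))
    baseline <- pmin(pmax(rlnorm(n_genes, baseline_meanlog, baseline_sdlog),
                          0.1), 30)
    if (!is.null(baseline_mean)) {
      override <- rep_len(baseline_mean, n_genes)
      baseline[!is.na(override)] <- override[!is.na(override)]
    }
    size <- pmax(rgamma(n_genes, size_shape, size_rate), 0.5)
    log2fc <- rep_len(log2fc, n_genes)
    lib <- rlnorm(n_spots, libsize_meanlog[as.integer(condition)],
                  libsize_sdlog)
    mu <- outer(baseline, lib) *
      2^outer(log2fc, as.numeric(condition == "early"))
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = rep(size, times = n_spots)),
                     n_genes, n_spots,
                     dimnames = list(sprintf("Gene%04d", seq_len(n_genes)),
                                     sprintf("spot%04d", seq_len(n_spots))))
    list(counts = to_sparse(counts),
         condition = condition, libsize_factors = lib, log2fc = log2fc,
         baseline_mean = baseline, size = size)
  })
}

#' Build a synthetic term annotation from the planted gene modules
#'
#' Creates biological-process-style terms: for each planted module a few
#' terms drawing most of their genes from that module's regulated genes,
#' plus unrelated noise terms of random genes.  Returns the term -> gene
#' annotation, the term -> module map, and the per-module truth.
#'
#' @param gene_model a [make_gene_model()] object.
#' @param n_terms_per_module terms generated per planted module.
#' @param noise_terms number of random unrelated terms.
#' @param noise_term_size genes per noise term.
#' @param seed integer seed.
#' @return list with `annotations` (named list term -> gene symbols),
#'   `module_map` (data.frame module, term_id) and `term_names`.
#' @export
make_term_annotation <- function(gene_model, n_terms_per_module = 3L,
                                 noise_terms = 20L, noise_term_size = 25L,
                                 seed = 1L) {
  g <- gene_model$genes
  with_seed(seed, {
    ann <- list(); map <- list()
    for (mod in unique(na.omit(g$module_true))) {
      members <- g$symbol[!is.na(g$module_true) & g$module_true == mod]
      for (t in seq_len(n_terms_per_module)) {
        id <- sprintf("T:%s_%02d", mod, t)
        core <- sample(members, max(3L, round(0.7 * length(members))))
        pad <- sample(setdiff(g$symbol, core), 5L)
        ann[[id]] <- sort(unique(c(core, pad)))
        map[[length(map) + 1L]] <- data.frame(module = mod, term_id = id)
      }
    }
    for (t in seq_len(noise_terms)) {
      id <- sprintf("T:noise_%02d", t)
      ann[[id]] <- sort(sample(g$symbol, noise_term_size))
    }
    list(annotations = ann, module_map = do.call(rbind, map),
         term_names = names(ann))
  })
}

#' Configuration for a synthetic EAE cohort
#'
#' Defaults mirror the study design: 8 animals per condition for
#' morphometry and biomarkers, spatial transcriptomics on 2 healthy and 3
#' early / 3 late slides, 12 histological sections per animal, lesions
#' concentrated in the lumbar anterolateral white matter and mostly in
#' contact with the CSF/pia.  In the late cohort serum NfL is generated as
#' a linear function of the anterolateral-lumbar CSF-contacting lesion
#' burden with noise calibrated to a planted correlation `r_late`; in the
#' early cohort sNfL derives from a diffuse-damage term independent of
#' lesion burden (planted correlation 0).
#'
#' @param n_animals named vector: animals per condition.
#' @param n_spatial named vector: how many animals per condition also get a
#'   simulated capture area.
#' @param sim a [cord_sim_config()] for the spatial slides.
#' @param gene_model a [make_gene_model()] object (built lazily if NULL).
#' @param n_hist_sections histology sections scored per animal.
#' @param lesion_rate Poisson lesion rate per section, per position
#'   (anterolateral/dorsal) and level (cervical/thoracic/lumbar).
#' @param p_csf_contact probability a histology lesion contacts the CSF.
#' @param rel_size_meanlog,rel_size_sdlog log-normal per-lesion relative
#'   size (percent of section white matter).
#' @param section_total_area_um2,section_grey_area_um2 section areas.
#' @param severity_sdlog animal-level severity (log-normal sd); drives
#'   lesion rates and sizes, hence the inter-category burden correlation.
#' @param r_late planted late-stage Spearman correlation between sNfL and
#'   the anterolateral-lumbar CSF-contact burden.
#' @param snfl_noise_sd overrides the calibrated sNfL noise sd (0 gives an
#'   exactly monotone burden -> sNfL map).
#' @param roi_means per-condition mean ROI measurements for the SMI32 and
#'   Iba1 stand-ins, `list(measure = c(early_wml, early_nawm, late_wml,
#'   late_nawm))`; defaults reproduce the reported group means.
#' @param n_roi ROIs per animal and compartment.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_animals = c(healthy = 8L, early = 8L, late = 8L),
                          n_spatial = c(healthy = 2L, early = 3L, late = 3L),
                          sim = cord_sim_config(),
                          gene_model = NULL,
                          n_hist_sections = 12L,
                          lesion_rate = list(
                            anterolateral = c(cervical = 0.15,
                                              thoracic = 0.3, lumbar = 0.9),
                            dorsal = c(cervical = 0.05, thoracic = 0.1,
                                       lumbar = 0.3)),
                          p_csf_contact = 0.8,
                          rel_size_meanlog = log(4), rel_size_sdlog = 0.5,
                          section_total_area_um2 = 8.8e6,
                          section_grey_area_um2 = 1.6e6,
                          severity_sdlog = 0.6,
                          r_late = 0.8, snfl_noise_sd = NULL,
                          roi_means = list(
                            smi32_count = c(37.4, 70.7, 66.8, 31.7),
                            iba1_intensity = c(40, 45, 80, 27)),
                          n_roi = 6L) {
  structure(list(n_animals = n_animals, n_spatial = n_spatial, sim = sim,
                 gene_model = gene_model,
                 n_hist_sections = as.integer(n_hist_sections),
                 lesion_rate = lesion_rate, p_csf_contact = p_csf_contact,
                 rel_size_meanlog = rel_size_meanlog,
                 rel_size_sdlog = rel_size_sdlog,
                 section_total_area_um2 = section_total_area_um2,
                 section_grey_area_um2 = section_grey_area_um2,
                 severity_sdlog = severity_sdlog, r_late = r_late,
                 snfl_noise_sd = snfl_noise_sd, roi_means = roi_means,
                 n_roi = as.integer(n_roi)),
            class = "cohort_config")
}

simulate_animal_lesions <- function(animal_id, condition, severity, cfg) {
  levels3 <- c("cervical", "thoracic", "lumbar")
  rows <- list()
  wm_area <- cfg$section_total_area_um2 - cfg$section_grey_area_um2
  for (sec in seq_len(cfg$n_hist_sections)) {
    level <- levels3[ceiling(sec / (cfg$n_hist_sections / 3))]
    for (pos in c("anterolateral", "dorsal")) {
      lam <- cfg$lesion_rate[[pos]][[level]] * severity
      n <- rpois(1, lam)
      for (j in seq_len(n)) {
        rel <- rlnorm(1, cfg$rel_size_meanlog + 0.3 * log(severity),
                      cfg$rel_size_sdlog)
        rel <- min(rel, 60)
        contact <- runif(1) < cfg$p_csf_contact
        track <- if (contact) {
          tr <- runif(5) < 0.6; tr[3] <- TRUE; tr
        } else rep(FALSE, 5)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animal_id, condition = condition,
          section_index = sec, level = level, position = pos,
          lesion_id = sprintf("%s_s%02d_%s_%d", animal_id, sec, pos, j),
          lesion_area_um2 = rel / 100 * wm_area,
          section_total_area_um2 = cfg$section_total_area_um2,
          section_grey_area_um2 = cfg$section_grey_area_um2,
          relative_size_pct = rel,
          csf_contact = contact,
          contact_track = paste(as.integer(track), collapse = ","))
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Simulate a full synthetic EAE cohort
#'
#' Generates per-animal lesion tables, biomarkers (sNfL, cNfL, EAE score),
#' ROI immunostaining stand-ins, and Visium-like spatial datasets for the
#' designated spatial animals (healthy slides carry no lesions).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with data.frames `animals`, `lesions`, `roi`, a list
#'   `spatial` of `spot_dataset` objects, the `gene_model` and `config`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  gene_model <- config$gene_model %||%
    make_gene_model(seed = stage_seed(seed, "gene_model"))
  with_seed(stage_seed(seed, "cohort"), {
    conditions <- rep(names(config$n_animals), config$n_animals)
    n_total <- length(conditions)
    n_eae <- config$n_animals[c("early", "late")]
    if (any(n_eae > 0 & n_eae < 3))
      warning("fewer than 3 animals in an EAE condition; ",
              "correlation recovery will be unreliable")
    animal_id <- sprintf("%s%02d", substr(conditions, 1, 1),
                         unlist(lapply(config$n_animals, seq_len)))
    severity <- ifelse(conditions == "healthy", 0,
                       rlnorm(n_total, 0, config$severity_sdlog))
    lesions <- list()
    for (i in seq_len(n_total)) {
      if (conditions[i] == "healthy") next
      lesions[[length(lesions) + 1L]] <-
        simulate_animal_lesions(animal_id[i], conditions[i], severity[i],
                                config)
    }
    lesions <- if (length(lesions)) do.call(rbind, lesions) else NULL
    burden_alc <- vapply(animal_id, function(a) {
      if (is.null(lesions)) return(0)
      sub <- lesions[lesions$animal_id == a &
                       lesions$level == "lumbar" &
                       lesions$position == "anterolateral" &
                       lesions$csf_contact, , drop = FALSE]
      sum(sub$relative_size_pct)
    }, numeric(1))
    snfl <- numeric(n_total)
    h <- conditions == "healthy"; e <- conditions == "early"
    l <- conditions == "late"
    snfl[h] <- rlnorm(sum(h), log(60), 0.3)
    # early: diffuse NAWM damage independent of focal lesion burden
    snfl[e] <- rlnorm(sum(e), log(4000), 0.45)
    signal <- 120 * burden_alc[l]
    noise_sd <- config$snfl_noise_sd %||%
      (if (length(signal) >= 2 && sd(signal) > 0 && config$r_late > 0)
        sd(signal) * sqrt(1 / config$r_late^2 - 1) else 0)
    snfl[l] <- pmax(800 + signal + rnorm(sum(l), 0, noise_sd), 20)
    cnfl <- snfl * 8 * rlnorm(n_total, 0, 0.35)
    score <- ifelse(h, 0, pmin(4, pmax(1, round(1.5 + log(severity + 1e-9) /
                                                  config$severity_sdlog))))
    animals <- data.frame(animal_id = animal_id, condition = conditions,
                          severity = severity, snfl = snfl, cnfl = cnfl,
                          eae_score = score,
                          burden_anterolateral_lumbar_contact = burden_alc)
    roi <- list()
    for (i in which(!h)) {
      col <- if (conditions[i] == "early") 1:2 else 3:4
      shift <- rnorm(1, 0, 4)
      for (m in names(config$roi_means)) {
        mu <- config$roi_means[[m]][col]
        for (cmp in c("WML", "NAWM")) {
          v <- pmax(rnorm(config$n_roi,
                          mu[if (cmp == "WML") 1 else 2] + shift, 7), 0.5)
          roi[[length(roi) + 1L]] <- data.frame(
            animal_id = animal_id[i], condition = conditions[i],
            compartment = cmp, measure = m, roi_index = seq_along(v),
            value = v)
        }
      }
    }
    roi <- do.call(rbind, roi)
    spatial <- list()
    for (cond in names(config$n_spatial)) {
      ids <- animal_id[conditions == cond][seq_len(config$n_spatial[[cond]])]
      for (a in ids) {
        sim_cfg <- config$sim
        if (cond == "healthy") sim_cfg$n_lesions_per_section <- 0L
        slide <- paste0("slide_", a)
        geom <- generate_cord_geometry(sim_cfg,
                                       stage_seed(seed, paste0("geom_", a)))
        spatial[[slide]] <- simulate_counts(
          geom, gene_model, condition = cond, slide_id = slide,
          seed = stage_seed(seed, paste0("counts_", a)))
      }
    }
    list(animals = animals, lesions = lesions, roi = roi, spatial = spatial,
         gene_model = gene_model, config = config)
  })
}
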