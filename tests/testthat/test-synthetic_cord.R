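test_that("geometry is deterministic and honors the no-lesion case", {
  cfg0 <- cord_sim_config(n_lesions_per_section = 0)
  g0 <- generate_cord_geometry(cfg0, seed = 3)
  expect_true(all(is.na(g0$lesion_id_true)))
  expect_equal(nrow(attr(g0, "lesions")), 0)

  cfg <- cord_sim_config()
  g1 <- generate_cord_geometry(cfg, seed = 5)
  g2 <- generate_cord_geometry(cfg, seed = 5)
  expect_identical(g1, g2)
  g3 <- generate_cord_geometry(cfg, seed = 6)
  expect_false(identical(attr(g1, "lesions"), attr(g3, "lesions")))
})

test_that("planted lesions are WM discs, enumerable across sections", {
  cfg <- cord_sim_config(n_sections = 12, pitch_um = 150,
                         n_lesions_per_section = 2)
  geom <- generate_cord_geometry(cfg, seed = 2)
  lesions <- attr(geom, "lesions")
  expect_equal(nrow(lesions), 24)
  member <- !is.na(geom$lesion_id_true)
  expect_true(all(geom$region_true[member] == "WM"))
  expect_setequal(unique(geom$lesion_id_true[member]), lesions$lesion_id)
  # grid indices unique within a section
  key <- paste(geom$section_index, geom$array_row, geom$array_col)
  expect_false(anyDuplicated(key) > 0)
  expect_lte(sum(geom$in_tissue), cfg$max_spots_per_area)
})

test_that("an oversized lesion radius is rejected with a clear message", {
  expect_error(cord_sim_config(lesion_radius_um = 800),
               "exceeds the WM ring width")
})

test_that("NB counts match the analytic mean in the Poisson limit", {
  sim <- simulate_two_group_counts(
    n_genes = 20, n_per_group = 5000, seed = 7, log2fc = 0,
    libsize_sdlog = 0, size_shape = 3000, size_rate = 1)
  mu <- sim$baseline_mean          # libsize factors are exactly 1
  emp <- Matrix::rowMeans(sim$counts)
  se <- sqrt((mu + mu^2 / sim$size) / ncol(sim$counts))
  expect_lte(sum(abs(emp - mu) > 3 * se), 1)
})

test_that("marker genes are detected more often in lesion spots", {
  cfg <- cord_sim_config(pitch_um = 70)
  geom <- generate_cord_geometry(cfg, seed = 4)
  gm <- make_gene_model(seed = 1)
  ds <- simulate_counts(geom, gm, condition = "late", seed = 9)
  les <- !is.na(ds$geometry$lesion_id_true)
  nawm <- ds$geometry$region_true == "WM" & !les
  expect_gt(sum(les), 30)
  for (mk in gm$markers) {
    det <- as.vector(ds$counts[mk, ] > 0)
    expect_gt(mean(det[les]), mean(det[nawm]))
  }
})

test_that("a zero library-size factor yields an all-zero spot", {
  cfg <- cord_sim_config(pitch_um = 300, n_lesions_per_section = 0)
  geom <- generate_cord_geometry(cfg, seed = 1)
  gm <- make_gene_model(seed = 1)
  n <- sum(geom$in_tissue)
  lf <- rep(1, n); lf[3] <- 0
  ds <- simulate_counts(geom, gm, condition = "healthy", seed = 2,
                        libsize_factors = lf)
  expect_equal(sum(ds$counts[, 3]), 0)
  expect_gt(sum(ds$counts[, 1]), 0)
  # counts are non-negative integers
  expect_true(all(ds$counts@x >= 0))
  expect_true(all(ds$counts@x == round(ds$counts@x)))
})

test_that("count simulation is reproducible for a fixed seed", {
  cfg <- cord_sim_config(pitch_um = 250)
  geom <- generate_cord_geometry(cfg, seed = 2)
  gm <- make_gene_model(seed = 3)
  d1 <- simulate_counts(geom, gm, condition = "early", seed = 11)
  d2 <- simulate_counts(geom, gm, condition = "early", seed = 11)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
})

test_that("late-cohort sNfL couples to anterolateral lumbar lesion burden", {
  cfg <- cohort_config(n_animals = c(healthy = 0, early = 0, late = 50),
                       n_spatial = c(healthy = 0, early = 0, late = 0))
  co <- simulate_cohort(cfg, seed = 21)
  late <- co$animals[co$animals$condition == "late", ]
  r <- correlation(late$burden_anterolateral_lumbar_contact, late$snfl,
                   method = "spearman")$r
  expect_gte(r, 0.6)
  expect_lte(r, 0.95)
})

test_that("zero sNfL noise makes the burden -> sNfL map exactly monotone", {
  cfg <- cohort_config(n_animals = c(healthy = 0, early = 0, late = 20),
                       n_spatial = c(healthy = 0, early = 0, late = 0),
                       snfl_noise_sd = 0)
  co <- simulate_cohort(cfg, seed = 31)
  late <- co$animals[co$animals$condition == "late", ]
  r <- correlation(late$burden_anterolateral_lumbar_contact, late$snfl,
                   method = "spearman")$r
  expect_equal(r, 1)
})

test_that("early-cohort sNfL is uncoupled from lesion burden", {
  cfg <- cohort_config(n_animals = c(healthy = 0, early = 50, late = 0),
                       n_spatial = c(healthy = 0, early = 0, late = 0))
  co <- simulate_cohort(cfg, seed = 41)
  early <- co$animals[co$animals$condition == "early", ]
  r <- correlation(early$burden_anterolateral_lumbar_contact, early$snfl,
                   method = "spearman")$r
  expect_lt(abs(r), 0.5)
})

test_that("tiny cohorts with correlation structure requested warn", {
  cfg <- cohort_config(n_animals = c(healthy = 0, early = 2, late = 2),
                       n_spatial = c(healthy = 0, early = 0, late = 0))
  expect_warning(simulate_cohort(cfg, seed = 1), "fewer than 3 animals")
})
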