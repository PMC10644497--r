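test_that("the continuous component recovers a planted expression shift", {
  set.seed(5)
  n <- 400
  condition <- factor(rep(c("early", "late"), each = n / 2),
                      levels = c("early", "late"))
  cdr <- runif(n, 0.2, 0.8)
  y <- rnorm(n, sd = 0.6) + 2 * (condition == "early") + 0.5 * cdr
  detected <- rep(TRUE, n)
  fit <- fit_hurdle(y, detected, condition, cdr)
  expect_equal(unname(fit$continuous_coefs["condition"]), 2,
               tolerance = 0.15)
  expect_true(fit$components[["continuous"]])
})

test_that("fully detected genes put all evidence in the continuous part", {
  set.seed(6)
  n <- 200
  condition <- factor(rep(c("early", "late"), each = n / 2),
                      levels = c("early", "late"))
  y <- rnorm(n) + 1.5 * (condition == "early")
  det <- rep(TRUE, n)
  full <- fit_hurdle(y, det, condition, cdr = NULL)
  red <- fit_hurdle(y, det, condition, cdr = NULL,
                    include_condition = FALSE)
  disc_contrib <- 2 * (full$loglik[["discrete"]] - red$loglik[["discrete"]])
  expect_lt(abs(disc_contrib), 0.05)
  lrt <- hurdle_lrt(full, red)
  expect_lt(lrt$p, 1e-6)
})

test_that("the continuous part is absent when a group lacks detections", {
  condition <- factor(rep(c("early", "late"), each = 10),
                      levels = c("early", "late"))
  det <- c(rep(TRUE, 10), TRUE, rep(FALSE, 9))   # 1 detected late spot
  y <- ifelse(det, rnorm(20, 2), 0)
  fit <- fit_hurdle(y, det, condition, cdr = NULL)
  expect_false(fit$components[["continuous"]])
  expect_null(fit$continuous_coefs)
})

test_that("hurdle LRT combines component likelihood differences", {
  mk <- function(ld, lc) structure(
    list(loglik = c(discrete = ld, continuous = lc),
         components = c(discrete = TRUE, continuous = TRUE)),
    class = "hurdle_fit")
  # equal likelihoods: chi2 0, p 1
  same <- hurdle_lrt(mk(-10, -20), mk(-10, -20))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # chi2 5.991 on 2 df sits at the 5% point
  lrt <- hurdle_lrt(mk(-10 + 1.5, -20 + 1.4955), mk(-10, -20))
  expect_equal(lrt$chi2, 5.991, tolerance = 1e-9)
  expect_equal(lrt$df, 2)
  expect_equal(lrt$p, 0.05, tolerance = 1e-3)
})

test_that("hurdle p-values are near-uniform under the null", {
  sim <- simulate_two_group_counts(n_genes = 200, n_per_group = 150,
                                   seed = 17, log2fc = 0)
  norm <- lognormalize(sim$counts)
  cdr <- cellular_detection_rate(sim$counts)$cdr
  tab <- dge_subset(sim$counts, norm, sim$condition, cdr = cdr)
  expect_gt(stats::ks.test(tab$p, "punif")$p.value, 0.01)
  expect_lt(mean(tab$p < 0.05), 0.12)
})

test_that("log2 fold change uses all-spot means over ln 2", {
  g <- factor(rep(c("early", "late"), each = 4))
  expect_equal(log2_fold_change(rep(1, 8), g), 0)
  y <- c(rep(2 * log(2), 4), rep(0, 4))
  expect_equal(log2_fold_change(y, g), 2)
  # swapping the group labels negates the value
  expect_equal(log2_fold_change(y, factor(rep(c("late", "early"),
                                              each = 4))), -2)
  # detected-only variant ignores zeros
  det <- c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 4))
  y2 <- c(4, 4, 0, 0, 1, 1, 1, 1) * log(2)
  expect_equal(log2_fold_change(y2, g, method = "detected",
                                detected = det), 3)
  expect_equal(log2_fold_change(y2, g), 1)
})

test_that("Bonferroni adjustment and detection filter shape the table", {
  sim <- simulate_two_group_counts(n_genes = 40, n_per_group = 60,
                                   seed = 23, log2fc = 0)
  counts <- sim$counts
  counts[5, ] <- 0; counts[5, 1] <- 1     # 1 detected spot: skipped
  norm <- lognormalize(counts)
  tab <- dge_subset(counts, norm, sim$condition, min_detect = 5)
  skipped <- attr(tab, "skipped")
  expect_true(rownames(counts)[5] %in% skipped)
  expect_equal(nrow(tab) + length(skipped), nrow(counts))
  m <- attr(tab, "m")
  expect_equal(tab$p_bonf, pmin(1, m * tab$p))
  # p = 0.01 with m = 10 gives p_bonf = 0.1
  expect_equal(min(1, 10 * 0.01), 0.1)
  expect_error(dge_subset(counts, norm,
                          factor(rep("early", ncol(counts)))),
               "both conditions")
})

test_that("concordance classes follow the two-subset significance rules", {
  wml <- fake_dge(gene = c("a", "b", "c", "d", "e"),
                  log2fc = c(2, 1.1, -0.8, 0.9, 0.1),
                  p = c(1e-6, 0.03, 0.2, 0.04, 0.9),
                  p_bonf = c(1e-3, 0.3, 1, 0.4, 1), subset = "WML")
  nawm <- fake_dge(gene = c("a", "b", "c", "d", "e"),
                   log2fc = c(1.5, 1.0, -0.7, 1.2, -0.2),
                   p = c(1e-7, 1e-5, 0.5, 0.01, 0.8),
                   p_bonf = c(1e-4, 0.01, 1, 0.08, 1), subset = "NAWM")
  cls <- concordance_classes(wml, nawm)
  got <- setNames(as.character(cls$class), cls$gene)
  expect_equal(got[["a"]], "sig_both")
  expect_equal(got[["b"]], "sig_nawm_only")
  expect_equal(got[["c"]], "not_regulated")  # regulated nowhere near p
  expect_equal(got[["d"]], "regulated_not_sig")
  expect_equal(got[["e"]], "not_regulated")
  # stable under permutation of gene order
  cls2 <- concordance_classes(wml[5:1, ], nawm[c(3, 1, 5, 2, 4), ])
  expect_equal(setNames(as.character(cls2$class), cls2$gene)[names(got)],
               got)
})

test_that("spatial patterns compare fold changes among eligible genes", {
  wml <- fake_dge(gene = c("up", "down", "ineligible", "tie"),
                  log2fc = c(2, 0.5, 3, 1),
                  p = c(0.01, 0.01, 0.2, 0.01),
                  p_bonf = c(0.01, 0.04, 1, 0.01))
  nawm <- fake_dge(gene = c("up", "down", "ineligible", "tie"),
                   log2fc = c(1, 1.2, 2.5, 1),
                   p = c(0.01, 0.02, 0.001, 0.01),
                   p_bonf = c(0.3, 0.3, 0.01, 0.01))
  pat <- spatial_pattern(wml, nawm)
  got <- setNames(as.character(pat$pattern), pat$gene)
  expect_equal(got[["up"]], "centrifugal")
  expect_equal(got[["down"]], "centripetal")
  expect_equal(got[["ineligible"]], "none")
  expect_equal(got[["tie"]], "none")
  expect_false(pat$eligible[pat$gene == "ineligible"])
})
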