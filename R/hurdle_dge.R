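# Gaussian log-likelihood at the MLE variance, from a residual sum of
# squares; keeps the hurdle LRT well-defined for the continuous part.
gauss_loglik <- function(rss, n) {
  if (n == 0) return(NA_real_)
  rss <- max(rss, 1e-12)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# logistic fit via IRLS with an optional ridge penalty on the non-
# intercept terms; the penalized path is the fallback under complete
# separation.  Returns coefficients and the (unpenalized) log-likelihood.
logistic_fit <- function(X, y, lambda = 0) {
  if (lambda == 0) {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    sep <- !fit$converged || max(abs(fit$coefficients), na.rm = TRUE) > 15
    return(list(coef = fit$coefficients, loglik = -fit$deviance / 2,
                separated = sep))
  }
  p <- ncol(X)
  pen <- rep(lambda, p)
  beta <- rep(0, p)
  for (i in 1:100) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(pen + 1e-8, p)
    g <- crossprod(X, y - mu) - pen * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  ll <- sum(y * eta - log1p(exp(eta)))
  list(coef = setNames(drop(beta), colnames(X)), loglik = ll,
       separated = TRUE)
}

#' Fit the two-part hurdle model for one gene
#'
#' Discrete part: maximum-likelihood logistic regression of detection
#' (count > 0) on condition and the cellular detection rate (CDR).
#' Continuous part: least-squares regression of the log-normalized
#' expression on the same covariates over the detected spots, with a
#' Gaussian likelihood at the MLE variance.  The continuous part is absent
#' (0 df) when a condition group has fewer than 2 detected spots.  Under
#' complete separation the discrete part falls back to a ridge-penalized
#' fit and the gene is flagged.
#'
#' @param y_norm log-normalized expression per spot.
#' @param detected logical detection indicator per spot.
#' @param condition two-level factor.
#' @param cdr cellular detection rate per spot (dropped with a message if
#'   it makes the design rank-deficient); `NULL` omits the covariate.
#' @param include_condition set `FALSE` for the null (reduced) model.
#' @return a `hurdle_fit`: coefficient vectors, per-component
#'   log-likelihoods, component availability, detection counts, flags.
#' @export
fit_hurdle <- function(y_norm, detected, condition, cdr = NULL,
                       include_condition = TRUE) {
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2)
    stop("condition must have exactly 2 levels present")
  detected <- as.numeric(detected)
  cond01 <- as.numeric(condition == levels(condition)[1])
  X <- cbind(intercept = rep(1, length(detected)),
             if (include_condition) cbind(condition = cond01),
             if (!is.null(cdr)) cbind(cdr = cdr))
  if (qr(X)$rank < ncol(X) && !is.null(cdr)) {
    message("CDR covariate collinear with the design; dropping it")
    X <- X[, colnames(X) != "cdr", drop = FALSE]
  }
  disc <- logistic_fit(X, detected)
  if (disc$separated) disc <- logistic_fit(X, detected, lambda = 1e-3)
  det_idx <- detected > 0
  n_det_by_group <- tapply(detected, condition, sum)
  cont <- NULL
  cont_ok <- all(n_det_by_group >= 2) && sum(det_idx) > ncol(X)
  if (cont_ok) {
    Xd <- X[det_idx, , drop = FALSE]
    fit <- lm.fit(Xd, y_norm[det_idx])
    rss <- sum(fit$residuals^2)
    cont <- list(coef = fit$coefficients,
                 loglik = gauss_loglik(rss, sum(det_idx)))
  }
  structure(list(discrete_coefs = disc$coef,
                 continuous_coefs = if (cont_ok) cont$coef,
                 loglik = c(discrete = disc$loglik,
                            continuous = if (cont_ok) cont$loglik else
                              NA_real_),
                 components = c(discrete = TRUE, continuous = cont_ok),
                 n_detected = sum(det_idx),
                 n_detected_by_group = as.vector(n_det_by_group),
                 separated = disc$separated,
                 include_condition = include_condition),
            class = "hurdle_fit")
}

#' Hurdle likelihood-ratio test
#'
#' Combines the discrete and continuous components: the test statistic is
#' twice the summed log-likelihood difference over the components
#' available in both fits, referred to a chi-square with one degree of
#' freedom per available component (2 when both are present, 1 when the
#' continuous part is missing).
#'
#' @param fit_full,fit_reduced `hurdle_fit`s with and without the
#'   condition term.
#' @return list `chi2`, `df`, `p`.
#' @export
hurdle_lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "hurdle_fit"),
            inherits(fit_reduced, "hurdle_fit"))
  avail <- fit_full$components & fit_reduced$components
  chi2 <- 0
  for (comp in names(avail)[avail])
    chi2 <- chi2 + max(0, 2 * (fit_full$loglik[[comp]] -
                                 fit_reduced$loglik[[comp]]))
  df <- max(1L, sum(avail))
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Log2 fold change of log-normalized expression
#'
#' Difference of group means of the natural-log-normalized values,
#' converted to log2 by `1/ln 2`.  By default means are over all subset
#' spots with zeros included; `method = "detected"` restricts to detected
#' spots.
#'
#' @param y_norm log-normalized expression.
#' @param groups two-level factor.
#' @param early,late the group labels contrasted (positive = higher in
#'   `early`).
#' @param method `"all"` (zeros included) or `"detected"`.
#' @param detected logical detection vector (required for
#'   `method = "detected"`).
#' @return log2 fold change.
#' @export
log2_fold_change <- function(y_norm, groups, early = "early",
                             late = "late", method = c("all", "detected"),
                             detected = NULL) {
  method <- match.arg(method)
  groups <- as.character(groups)
  if (method == "detected") {
    stopifnot(!is.null(detected))
    keep <- as.logical(detected)
    y_norm <- y_norm[keep]; groups <- groups[keep]
  }
  m_early <- mean(y_norm[groups == early])
  m_late <- mean(y_norm[groups == late])
  (m_early - m_late) / log(2)
}

#' Hurdle differential expression over one spot subset
#'
#' Per-gene two-part hurdle test of early vs late condition with the CDR
#' covariate, Bonferroni correction over the genes actually tested in the
#' subset, and all-spot log2 fold changes.  Genes detected in fewer than
#' `min_detect` subset spots are skipped and reported separately.
#'
#' @param counts raw counts, genes x spots.
#' @param normalized log-normalized matrix with the same dimensions.
#' @param condition factor per spot with levels containing `"early"` and
#'   `"late"`.
#' @param cdr per-spot cellular detection rate; computed from `counts`
#'   (full gene set) when `NULL`; `use_cdr = FALSE` omits the covariate.
#' @param spots optional barcodes selecting the subset (default all
#'   columns).
#' @param subset_name tag recorded in the output (e.g. "WML").
#' @param min_detect minimum detected spots for a gene to be tested.
#' @param use_cdr include the CDR covariate.
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @param fc_method fold-change convention, see [log2_fold_change()].
#' @return data.frame (one row per tested gene): `gene`, `subset`,
#'   `log2fc`, `chi2`, `df`, `p`, `p_bonf`, `significant`, `n_early`,
#'   `n_late`, `n_detected`, `flagged`; skipped genes in
#'   `attr(, "skipped")`.
#' @export
dge_subset <- function(counts, normalized, condition, cdr = NULL,
                       spots = NULL, subset_name = "subset",
                       min_detect = 5L, use_cdr = TRUE, alpha = 0.05,
                       fc_method = "all") {
  if (is.null(cdr) && use_cdr)
    cdr <- cellular_detection_rate(counts)$cdr
  if (!is.null(spots)) {
    idx <- match(spots, colnames(counts))
    if (anyNA(idx)) stop("unknown spot id(s) in `spots`")
    counts <- counts[, idx, drop = FALSE]
    normalized <- normalized[, idx, drop = FALSE]
    condition <- condition[idx]
    if (use_cdr) cdr <- cdr[idx]
  }
  condition <- droplevels(factor(condition))
  if (!all(c("early", "late") %in% levels(condition)))
    stop("both conditions (early, late) must be present in the subset; ",
         "found: ", paste(levels(condition), collapse = ", "))
  condition <- factor(as.character(condition), levels = c("early", "late"))
  cdr_use <- if (use_cdr) cdr else NULL
  genes <- rownames(counts)
  det_counts <- Matrix::rowSums(counts > 0)
  test_idx <- which(det_counts >= min_detect)
  skipped <- genes[det_counts < min_detect]
  rows <- vector("list", length(test_idx))
  # row access dominates the per-gene loop; densify when affordable
  if (prod(dim(counts)) <= 5e7) {
    dense_counts <- as.matrix(counts)
    normalized <- as.matrix(normalized)
  } else dense_counts <- counts
  for (j in seq_along(test_idx)) {
    g <- test_idx[j]
    y <- as.vector(normalized[g, ])
    det <- as.vector(dense_counts[g, ] > 0)
    full <- fit_hurdle(y, det, condition, cdr_use)
    red <- fit_hurdle(y, det, condition, cdr_use,
                      include_condition = FALSE)
    lrt <- hurdle_lrt(full, red)
    rows[[j]] <- data.frame(
      gene = genes[g], subset = subset_name,
      log2fc = log2_fold_change(y, condition, method = fc_method,
                                detected = det),
      chi2 = lrt$chi2, df = lrt$df, p = lrt$p,
      n_early = sum(condition == "early"),
      n_late = sum(condition == "late"),
      n_detected = full$n_detected, flagged = full$separated)
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_bonf <- pmin(1, m * out$p)
  out$significant <- out$p_bonf < alpha
  attr(out, "skipped") <- skipped
  attr(out, "m") <- m
  out
}

#' Concordance classification of genes across the WML and NAWM subsets
#'
#' Partitions the genes tested in both subsets: significant in both
#' (Bonferroni), significant in one subset and regulated (raw p below
#' `reg_p`, same direction) in the other, regulated in both without
#' reaching significance, or not regulated.
#'
#' @param table_wml,table_nawm [dge_subset()] tables.
#' @param reg_p raw-p threshold defining "regulated".
#' @param alpha Bonferroni significance level.
#' @return data.frame `gene`, `class`, `direction_agreement`, plus the
#'   per-subset fold changes and p-values.
#' @export
concordance_classes <- function(table_wml, table_nawm, reg_p = 0.05,
                                alpha = 0.05) {
  genes <- intersect(table_wml$gene, table_nawm$gene)
  w <- table_wml[match(genes, table_wml$gene), ]
  n <- table_nawm[match(genes, table_nawm$gene), ]
  sig_w <- w$p_bonf < alpha
  sig_n <- n$p_bonf < alpha
  same_dir <- sign(w$log2fc) == sign(n$log2fc) & w$log2fc != 0
  cls <- rep("not_regulated", length(genes))
  cls[!sig_w & !sig_n & w$p < reg_p & n$p < reg_p & same_dir] <-
    "regulated_not_sig"
  cls[sig_n & !sig_w & w$p < reg_p & same_dir] <- "sig_nawm_only"
  cls[sig_w & !sig_n & n$p < reg_p & same_dir] <- "sig_wml_only"
  cls[sig_w & sig_n] <- "sig_both"
  data.frame(gene = genes,
             class = factor(cls, levels = c("sig_both", "sig_nawm_only",
                                            "sig_wml_only",
                                            "regulated_not_sig",
                                            "not_regulated")),
             direction_agreement = same_dir,
             log2fc_wml = w$log2fc, log2fc_nawm = n$log2fc,
             p_wml = w$p, p_nawm = n$p,
             p_bonf_wml = w$p_bonf, p_bonf_nawm = n$p_bonf)
}

#' Spatial fold-change pattern of DE genes
#'
#' Among eligible genes (raw p below 0.05 in both subsets and Bonferroni
#' p below 0.05 in at least one), a gene is `centrifugal` when its fold
#' change is higher in WML than in NAWM and `centripetal` when lower;
#' exact ties and ineligible genes are `none`.
#'
#' @param table_wml,table_nawm [dge_subset()] tables.
#' @param raw_p,alpha eligibility thresholds.
#' @return data.frame `gene`, `eligible`, `pattern`.
#' @export
spatial_pattern <- function(table_wml, table_nawm, raw_p = 0.05,
                            alpha = 0.05) {
  genes <- intersect(table_wml$gene, table_nawm$gene)
  w <- table_wml[match(genes, table_wml$gene), ]
  n <- table_nawm[match(genes, table_nawm$gene), ]
  eligible <- w$p < raw_p & n$p < raw_p &
    (w$p_bonf < alpha | n$p_bonf < alpha)
  pattern <- rep("none", length(genes))
  pattern[eligible & w$log2fc > n$log2fc] <- "centrifugal"
  pattern[eligible & w$log2fc < n$log2fc] <- "centripetal"
  data.frame(gene = genes, eligible = eligible,
             pattern = factor(pattern, levels = c("centrifugal",
                                                  "centripetal", "none")),
             log2fc_wml = w$log2fc, log2fc_nawm = n$log2fc)
}
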