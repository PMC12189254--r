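# Per-dose differential expression on negative-binomial counts: each
# positive-dose arm is contrasted against the shared dose-0 control with a
# Wald test on a log-link NB GLM at fixed gene-wise dispersion. The stage is
# deliberately simple and transparent: median-of-ratios normalization,
# method-of-moments dispersion shrunk toward a fitted mean-dispersion trend,
# no fold-change shrinkage and no independent filtering beyond the exclusion
# of all-zero genes.

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is
#' the median ratio of its counts to the gene-wise geometric mean; factors
#' are rescaled to geometric mean 1.
#'
#' @param counts count matrix.
#' @return named positive numeric vector, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- validate_counts(counts)
  use <- rowSums(counts == 0) == 0
  if (!any(use))
    stop("no gene has nonzero counts in every sample; ",
         "supply a pseudo-reference fallback or filter samples")
  lg <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- exp(apply(lg - geo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Gene-wise dispersion with trend shrinkage
#'
#' Method-of-moments estimates `alpha_g = max((var - mu)/mu^2, floor)` on
#' normalized counts are shrunk 50/50 toward a mean-dispersion trend
#' `alpha(mu) = a0/mu + a1` fitted by robust regression. When `groups` is
#' given (the dose arms), mean and variance are taken within each group and
#' the per-group moment estimates are pooled with degree-of-freedom weights,
#' so genuine between-dose expression changes do not masquerade as
#' biological dispersion. Genes with zero residual variance carry no
#' dispersion information and are set to the floor.
#'
#' @param counts count matrix.
#' @param size_factors per-sample size factors.
#' @param groups optional per-sample group labels (e.g. dose arms); default
#'   treats all samples as one group.
#' @param floor lower bound on alpha.
#' @return named numeric vector of dispersions; attributes `a0`, `a1` hold
#'   the fitted trend.
#' @export
estimate_dispersion <- function(counts, size_factors, groups = NULL,
                                floor = 1e-8) {
  if (ncol(counts) < 2) stop("dispersion estimation needs >= 2 samples")
  norm <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(norm)
  if (is.null(groups)) groups <- rep(1, ncol(counts))
  groups <- as.character(groups)
  raw_num <- raw_den <- rep(0, nrow(counts))
  v <- rep(0, nrow(counts))
  for (g in unique(groups)) {
    cols <- groups == g
    if (sum(cols) < 2) next
    sub <- norm[, cols, drop = FALSE]
    mu_a <- rowMeans(sub)
    var_a <- apply(sub, 1, stats::var)
    v <- v + (sum(cols) - 1) * var_a
    use <- mu_a > 0
    w <- sum(cols) - 1
    raw_num[use] <- raw_num[use] +
      w * (var_a[use] - mu_a[use]) / mu_a[use]^2
    raw_den[use] <- raw_den[use] + w
  }
  if (all(raw_den == 0)) stop("need at least one group with >= 2 samples")
  raw <- pmax(ifelse(raw_den > 0, raw_num / pmax(raw_den, 1), floor), floor)
  raw[!is.finite(raw)] <- floor

  # The gene-wise moment estimate is right-skewed (roughly alpha * chi^2_d/d
  # at d residual df), so a robust fit tracks its median, qchisq(0.5, d)/d
  # below the mean; the fitted trend is rescaled by the reciprocal to
  # recenter it.
  d_typ <- max(stats::median(raw_den), 1)
  skew_corr <- d_typ / stats::qchisq(0.5, d_typ)
  ok <- mu > 1 & v > 0
  if (sum(ok) >= 10) {
    fit <- tryCatch(
      MASS::rlm(raw[ok] ~ I(1 / mu[ok]), maxit = 50),
      error = function(e) stats::lm(raw[ok] ~ I(1 / mu[ok])))
    a1 <- max(unname(stats::coef(fit)[1]) * skew_corr, 1e-6)
    a0 <- max(unname(stats::coef(fit)[2]) * skew_corr, 0)
  } else {
    a1 <- max(stats::median(raw) * skew_corr, 1e-6); a0 <- 0
  }
  trend <- a0 / mu + a1
  alpha <- pmax(0.5 * raw + 0.5 * trend, floor)
  alpha[v == 0] <- floor
  structure(stats::setNames(alpha, rownames(counts)), a0 = a0, a1 = a1)
}

# Vectorized per-arm Newton fit of the NB log-link group mean.
# Solves, per gene, sum_j (y_j - s_j q) / (1 + alpha s_j q) = 0 for
# eta = log q (the GLM score equation at fixed dispersion); returns eta and
# the Fisher information I(eta) = sum_j mu_j / (1 + alpha mu_j).
# Arms whose total count is zero sit at the boundary of the parameter space;
# q is floored at 0.5 / sum(s_j) (a half-count continuity correction) so the
# contrast remains finite.
fit_arm <- function(y, s, alpha, tol = 1e-10, max_iter = 50) {
  tot <- rowSums(y)
  zero <- tot == 0
  eta <- log(pmax(tot, 0.5) / sum(s))
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% s                      # G x n
    denom <- 1 + alpha * mu
    U <- rowSums((y - mu) / denom)
    I <- rowSums(mu / denom)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    step[zero] <- 0                           # boundary genes stay at floor
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% s
  I <- rowSums(mu / (1 + alpha * mu))
  list(eta = eta, info = I)
}

#' Wald test of one dose arm against the control
#'
#' Per gene, a negative-binomial log-link GLM (intercept + arm indicator)
#' is fit at fixed dispersion; the log2 fold change is the arm coefficient
#' divided by ln 2 and the two-sided Wald p-value compares coefficient/SE to
#' the standard normal. Genes with zero counts in every sample of both arms
#' are excluded from testing and flagged.
#'
#' @param counts count matrix.
#' @param design validated design table.
#' @param contrast_dose the positive dose to contrast against dose 0.
#' @param size_factors optional; computed from the full matrix if missing.
#' @param dispersions optional; estimated if missing.
#' @param strict_below if TRUE the significance flag uses padj < alpha
#'   rather than padj <= alpha.
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame: gene_id, dose, log2FC, lfcSE, stat, pvalue, padj,
#'   baseMean, status, significant.
#' @export
wald_test <- function(counts, design, contrast_dose,
                      size_factors = NULL, dispersions = NULL,
                      alpha = 0.05, strict_below = FALSE) {
  design <- validate_design(design, counts)
  if (!contrast_dose %in% design$dose)
    stop("contrast dose ", contrast_dose, " absent from design")
  ctrl <- design$sample_id[design$dose == 0]
  trt <- design$sample_id[design$dose == contrast_dose]
  if (length(ctrl) < 2 || length(trt) < 2)
    stop("both arms need at least 2 replicates")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(
      counts, size_factors,
      groups = design$dose[match(colnames(counts), design$sample_id)])

  yc <- counts[, ctrl, drop = FALSE]
  yt <- counts[, trt, drop = FALSE]
  sc <- size_factors[ctrl]
  st <- size_factors[trt]
  a <- as.numeric(dispersions[rownames(counts)])

  all_zero <- rowSums(yc) == 0 & rowSums(yt) == 0
  fc <- fit_arm(yc, sc, a)
  ft <- fit_arm(yt, st, a)
  beta <- ft$eta - fc$eta
  se <- sqrt(1 / pmax(ft$info, 1e-12) + 1 / pmax(fc$info, 1e-12))
  stat <- beta / se
  p <- 2 * stats::pnorm(-abs(stat))
  p[all_zero] <- NA_real_
  padj <- bh_adjust(p)
  norm <- sweep(counts[, c(ctrl, trt), drop = FALSE], 2,
                size_factors[c(ctrl, trt)], "/")
  res <- data.frame(
    gene_id = rownames(counts),
    dose = contrast_dose,
    log2FC = ifelse(all_zero, NA_real_, beta / log(2)),
    lfcSE = ifelse(all_zero, NA_real_, se / log(2)),
    stat = ifelse(all_zero, NA_real_, stat),
    pvalue = p,
    padj = padj,
    baseMean = rowMeans(norm),
    status = ifelse(all_zero, "all_zero_excluded", "tested"),
    stringsAsFactors = FALSE)
  res$significant <- !is.na(res$padj) &
    (if (strict_below) res$padj < alpha else res$padj <= alpha)
  rownames(res) <- NULL
  res
}

#' Run per-dose differential expression for every positive dose
#'
#' Size factors and dispersions are estimated once on the full matrix and
#' shared across contrasts.
#'
#' @inheritParams wald_test
#' @return named list of [wald_test()] data.frames, one per positive dose,
#'   names the dose values in increasing order.
#' @export
run_dea <- function(counts, design, alpha = 0.05, strict_below = FALSE) {
  design <- validate_design(design, counts)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(
    counts, sf, groups = design$dose[match(colnames(counts), design$sample_id)])
  doses <- sort(unique(design$dose[design$dose > 0]))
  out <- lapply(doses, function(d)
    wald_test(counts, design, d, sf, disp, alpha, strict_below))
  stats::setNames(out, doses)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (monotone, capped at 1) applied
#' over the non-missing entries; missing values are passed through. Values
#' outside \[0, 1\] are an error.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Volcano-table export
#'
#' Tabulates (log2FC, -log10 padj) for plotting, with the conventional
#' +/- 0.25 log2FC guide lines recorded as metadata.
#'
#' @param de a [wald_test()] result.
#' @param lfc_guides guide-line positions on the lFC axis.
#' @return data.frame gene_id, log2FC, neg_log10_padj, significant;
#'   attribute `lfc_guides`.
#' @export
volcano_table <- function(de, lfc_guides = c(-0.25, 0.25)) {
  tab <- data.frame(gene_id = de$gene_id, log2FC = de$log2FC,
                    neg_log10_padj = -log10(de$padj),
                    significant = de$significant,
                    stringsAsFactors = FALSE)
  attr(tab, "lfc_guides") <- lfc_guides
  tab
}
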