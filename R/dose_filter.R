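# Dose-consistency filtering of differentially expressed genes.
#
# Genes are kept only when their dysregulation is coherent across the dose
# grid, judged by three criteria:
#   (1) persistence — once a gene first reaches significance at some dose,
#       it must stay significant at every higher dose;
#   (2) expression behavior — a single sign change in the fold-change
#       trajectory is tolerated (high doses can trigger feedback that
#       reverses a response), implemented as the explicit non-exclusion of
#       <=1 sign alternation inside criterion 3;
#   (3) dose-effect relationship — over the persistence window the
#       fold-change trajectory must be monotone within a tolerance, or close
#       to linear in log2(dose); trajectories alternating sign repeatedly
#       are excluded.

#' Assemble per-gene dose series from per-dose DE results
#'
#' Combines the per-contrast test tables into one ordered record per gene of
#' (dose, log2FC, padj, significance). Doses are sorted increasingly
#' regardless of input order. Genes excluded as all-zero in every contrast
#' are dropped; a contrast in which a gene was all-zero contributes a
#' non-significant entry with zero fold change.
#'
#' @param de_list named list of [wald_test()] tables; names are dose values.
#' @return object of class `dose_series`: list with `gene_ids`, `doses`, and
#'   gene-by-dose matrices `lfc`, `padj`, `sig`.
#' @export
build_dose_series <- function(de_list) {
  doses <- suppressWarnings(as.numeric(names(de_list)))
  if (anyNA(doses)) stop("de_list must be named by numeric dose")
  ord <- order(doses)
  de_list <- de_list[ord]
  doses <- doses[ord]
  genes <- de_list[[1]]$gene_id
  for (d in de_list)
    if (!setequal(d$gene_id, genes))
      stop("all contrasts must share the same gene universe")

  k <- length(doses)
  lfc <- matrix(0, length(genes), k, dimnames = list(genes, doses))
  padj <- matrix(NA_real_, length(genes), k, dimnames = list(genes, doses))
  sig <- matrix(FALSE, length(genes), k, dimnames = list(genes, doses))
  excluded <- matrix(FALSE, length(genes), k)
  for (i in seq_len(k)) {
    d <- de_list[[i]]
    m <- match(genes, d$gene_id)
    lfc[, i] <- ifelse(is.na(d$log2FC[m]), 0, d$log2FC[m])
    padj[, i] <- d$padj[m]
    sig[, i] <- d$significant[m] %in% TRUE
    excluded[, i] <- d$status[m] == "all_zero_excluded"
  }
  keep <- rowSums(excluded) < k
  structure(list(gene_ids = genes[keep], doses = doses,
                 lfc = lfc[keep, , drop = FALSE],
                 padj = padj[keep, , drop = FALSE],
                 sig = sig[keep, , drop = FALSE]),
            class = "dose_series")
}

#' Persistence criterion
#'
#' A gene passes when it is significant at its first significant dose and at
#' every higher dose. A gene significant nowhere fails (first significant
#' dose undefined, returned as NA).
#'
#' @param sig logical significance flags ordered by increasing dose.
#' @param doses the dose grid.
#' @return list(pass, first_significant_dose).
#' @export
criterion_persistence <- function(sig, doses) {
  if (length(sig) == 0) stop("empty series")
  if (!any(sig)) return(list(pass = FALSE, first_significant_dose = NA_real_))
  i0 <- which(sig)[1]
  list(pass = all(sig[i0:length(sig)]), first_significant_dose = doses[i0])
}

# Sign alternation count of a fold-change sequence; zeros inherit the
# previous sign so a trajectory touching zero is not counted as reversing.
count_sign_alternations <- function(lfc) {
  s <- sign(lfc)
  for (i in seq_along(s))
    if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Trend criterion over the persistence window
#'
#' Evaluated on the signed log2 fold changes at doses from the first
#' significant dose upward. Passes when the trajectory has at most one sign
#' alternation AND is either monotone (non-decreasing or non-increasing,
#' successive steps allowed to violate monotonicity by at most `tau`) or
#' approximately linear in log2(dose) (least-squares R^2 >= `r2_min`).
#' A window of length 1 passes trivially with trend class "none".
#'
#' @param lfc log2 fold changes over the window (increasing dose order).
#' @param doses corresponding doses.
#' @param tau monotonicity tolerance on successive steps (default 0.1).
#' @param r2_min linearity threshold on R^2 of lfc ~ log2(dose) (default 0.5).
#' @return list(pass, trend_class, sign_alternations).
#' @export
criterion_trend <- function(lfc, doses, tau = 0.1, r2_min = 0.5) {
  k <- length(lfc)
  if (k == 0) stop("empty window")
  if (k == 1)
    return(list(pass = TRUE, trend_class = "none", sign_alternations = 0L))
  alt <- count_sign_alternations(lfc)
  dl <- diff(lfc)
  mono_up <- all(dl >= -tau)
  mono_down <- all(dl <= tau)
  lin <- FALSE
  if (!(mono_up || mono_down)) {
    x <- log2(doses)
    ss_tot <- sum((lfc - mean(lfc))^2)
    if (ss_tot == 0) {
      lin <- TRUE
    } else {
      fit <- stats::lm.fit(cbind(1, x), lfc)
      r2 <- 1 - sum(fit$residuals^2) / ss_tot
      lin <- r2 >= r2_min
    }
  }
  pass <- alt <= 1 && (mono_up || mono_down || lin)
  trend_class <- if (!pass) "none"
    else if (mono_up && mono_down) "linear"   # flat within tolerance
    else if (mono_up) "increasing"
    else if (mono_down) "decreasing"
    else "linear"
  list(pass = pass, trend_class = trend_class,
       sign_alternations = as.integer(alt))
}

#' Apply the three dose-consistency criteria to every gene
#'
#' Produces the retained gene list and a full audit table. Criterion 2 is a
#' documented pass-through: it never excludes on its own, and its feedback
#' allowance is realized as the tolerance of one sign alternation inside the
#' trend criterion. Genes whose persistence window has length 1 (significant
#' only at the top dose) pass vacuously and are flagged `single_dose_window`
#' so users can exclude them.
#'
#' @param series a `dose_series` from [build_dose_series()].
#' @param tau monotonicity tolerance.
#' @param r2_min linearity threshold.
#' @return list with `retained` (character vector) and `verdicts`
#'   (data.frame: gene_id, retained, first_significant_dose,
#'   criterion1_pass, criterion3_pass, trend_class, sign_alternations,
#'   single_dose_window).
#' @export
filter_degs <- function(series, tau = 0.1, r2_min = 0.5) {
  stopifnot(inherits(series, "dose_series"))
  G <- length(series$gene_ids)
  verdicts <- data.frame(
    gene_id = series$gene_ids,
    retained = logical(G),
    first_significant_dose = NA_real_,
    criterion1_pass = logical(G),
    criterion3_pass = logical(G),
    trend_class = rep("none", G),
    sign_alternations = integer(G),
    single_dose_window = logical(G),
    stringsAsFactors = FALSE)
  for (g in seq_len(G)) {
    sig <- series$sig[g, ]
    c1 <- criterion_persistence(sig, series$doses)
    verdicts$criterion1_pass[g] <- c1$pass
    verdicts$first_significant_dose[g] <- c1$first_significant_dose
    if (is.na(c1$first_significant_dose)) next
    win <- series$doses >= c1$first_significant_dose
    c3 <- criterion_trend(series$lfc[g, win], series$doses[win],
                          tau = tau, r2_min = r2_min)
    verdicts$criterion3_pass[g] <- c3$pass
    verdicts$trend_class[g] <- c3$trend_class
    verdicts$sign_alternations[g] <- c3$sign_alternations
    verdicts$single_dose_window[g] <- sum(win) == 1
    verdicts$retained[g] <- c1$pass && c3$pass
  }
  list(retained = verdicts$gene_id[verdicts$retained], verdicts = verdicts)
}
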