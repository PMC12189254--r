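# Over-representation analysis: hypergeometric upper-tail test of the
# overlap between the retained gene list and each gene set, BH correction
# across sets, a deliberately stringent genome-wide significance threshold
# (5e-8) on the adjusted values, and the cross-product odds ratio of the
# 2x2 overlap table.

# Validate 2x2 overlap margins: a successes among n drawn from a universe of
# N containing K marked genes.
check_margins <- function(a, K, n, N) {
  if (K > N || n > N) stop("inconsistent margins: K and n must not exceed N")
  if (a < 0 || a > min(K, n)) stop("inconsistent margins: need 0 <= a <= min(K, n)")
  if (n - a > N - K) stop("inconsistent margins: too few unmarked genes")
  invisible(TRUE)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= a)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `a` marked genes when drawing `n` from a universe of
#' `N` genes of which `K` are marked. Computed through the log-space-stable
#' distribution function, so extreme tails do not underflow.
#'
#' @param a observed overlap.
#' @param K gene-set size.
#' @param n drawn-list size.
#' @param N universe size.
#' @return tail probability in \[0, 1\].
#' @export
hypergeom_tail <- function(a, K, n, N) {
  check_margins(a, K, n, N)
  if (a == 0) return(1)
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Cross-product odds ratio of the 2x2 overlap table
#'
#' `OR = (a*d)/(b*c)` with `b = n - a`, `c = K - a`, `d = N - n - c`. When
#' any of b, c, d is zero the Haldane-Anscombe correction adds 0.5 to all
#' four cells; the returned value then carries attribute `haldane = TRUE`.
#'
#' @inheritParams hypergeom_tail
#' @return odds ratio (>= 0), attribute `haldane` marking correction.
#' @export
odds_ratio <- function(a, K, n, N) {
  check_margins(a, K, n, N)
  b <- n - a
  cc <- K - a
  d <- N - n - cc
  if (d < 0) stop("inconsistent margins: negative complement cell")
  haldane <- any(c(b, cc, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  structure((a * d) / (b * cc), haldane = haldane)
}

#' Over-representation analysis of a gene list against a collection
#'
#' Each set is intersected with the universe before testing, and set sizes
#' are reported post-intersection. The significance flag compares the
#' BH-adjusted p-value to `alpha_strict` (default 5e-8, a genome-wide
#' association cut-off chosen to keep only the most robust pathways when the
#' input list is large). Sets with zero overlap are reported with p = 1.
#'
#' @param genes retained gene list (character). Genes outside the universe
#'   are dropped with a warning.
#' @param collection a `gene_set_collection`.
#' @param universe either a character vector of measured genes or a single
#'   number giving the universe size N (default 20000). With a numeric
#'   universe, set members are assumed measured.
#' @param alpha_strict FDR threshold for the significance flag.
#' @param uppercase case-fold identifiers before matching?
#' @return data.frame sorted by p: term, overlap, set_size, list_size,
#'   universe_size, pvalue, fdr, odds_ratio, haldane, significant,
#'   gene_ratio.
#' @export
run_ora <- function(genes, collection, universe = 20000,
                    alpha_strict = 5e-8, uppercase = FALSE) {
  if (length(genes) == 0) stop("empty retained gene list")
  genes <- unique(normalize_gene_ids(genes, uppercase))
  sets <- lapply(collection$sets, normalize_gene_ids, uppercase = uppercase)
  if (is.character(universe)) {
    uni <- unique(normalize_gene_ids(universe, uppercase))
    drop <- setdiff(genes, uni)
    if (length(drop) > 0) {
      warning(length(drop), " retained gene(s) outside the universe dropped")
      genes <- intersect(genes, uni)
    }
    sets <- lapply(sets, intersect, y = uni)
    N <- length(uni)
  } else {
    N <- as.integer(universe)
  }
  sets <- sets[vapply(sets, length, 1L) > 0]
  n <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    a <- length(intersect(genes, sets[[nm]]))
    p <- hypergeom_tail(a, K, n, N)
    or <- odds_ratio(a, K, n, N)
    data.frame(term = nm, overlap = a, set_size = K, list_size = n,
               universe_size = N, pvalue = p, odds_ratio = as.numeric(or),
               haldane = isTRUE(attr(or, "haldane")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out$significant <- out$fdr <= alpha_strict
  out$gene_ratio <- out$overlap / out$set_size
  out <- out[order(out$pvalue, -out$overlap), ]
  rownames(out) <- NULL
  out[, c("term", "overlap", "set_size", "list_size", "universe_size",
          "pvalue", "fdr", "odds_ratio", "haldane", "significant",
          "gene_ratio")]
}

#' Bubble-plot table export
#'
#' The encoding used for enrichment bubble charts: one row per set with the
#' gene ratio (overlap / set size) for bubble size and -log10 FDR for
#' position.
#'
#' @param ora a [run_ora()] table.
#' @export
ora_bubble_table <- function(ora) {
  data.frame(term = ora$term, gene_ratio = ora$gene_ratio,
             neg_log10_fdr = -log10(ora$fdr), stringsAsFactors = FALSE)
}
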