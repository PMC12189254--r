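# In-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10L, 20L, 30L, 60L), nrow = 2, byrow = TRUE,
              dimnames = list(c("GeneA", "GeneB"), c("s1", "s2")))
  m
}

write_tsv_counts <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# A two-gene, five-dose series fixture encoding the canonical worked
# example: gene "keep" significant at 20/50/100, gene "drop" significant at
# 10/50/100 but not 20. Both carry a clean increasing fold-change trend so
# only the persistence criterion separates them.
worked_example_series <- function() {
  doses <- c(5, 10, 20, 50, 100)
  lfc <- rbind(keep = c(0.1, 0.2, 0.5, 0.8, 1.1),
               drop = c(0.1, 0.4, 0.2, 0.8, 1.1))
  sig <- rbind(keep = c(FALSE, FALSE, TRUE, TRUE, TRUE),
               drop = c(FALSE, TRUE, FALSE, TRUE, TRUE))
  padj <- ifelse(sig, 0.01, 0.5)
  colnames(lfc) <- colnames(sig) <- colnames(padj) <- doses
  structure(list(gene_ids = rownames(lfc), doses = doses,
                 lfc = lfc, padj = padj, sig = sig),
            class = "dose_series")
}

# Build a dose_series directly from matrices (rows = genes).
make_series <- function(lfc, sig, doses = c(5, 10, 20, 50, 100)) {
  lfc <- rbind(lfc); sig <- rbind(sig)
  if (is.null(rownames(lfc)))
    rownames(lfc) <- rownames(sig) <- paste0("g", seq_len(nrow(lfc)))
  structure(list(gene_ids = rownames(lfc), doses = doses, lfc = lfc,
                 padj = ifelse(sig, 0.01, 0.5), sig = sig),
            class = "dose_series")
}

# Small chain topology g1 -> g2 with a chosen relation.
chain_topology <- function(relation = "activation") {
  pathway_topology("chain", c("g1", "g2"),
                   data.frame(source = "g1", relation = relation,
                              target = "g2", stringsAsFactors = FALSE))
}

# Random DAG topology over n genes with spectral radius < 1 (forward edges
# only, so B is strictly triangular under the generation order).
random_dag_topology <- function(n = 8, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  genes <- paste0("n", seq_len(n))
  src <- character(0); rel <- character(0); tgt <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      src <- c(src, genes[i])
      rel <- c(rel, sample(c("activation", "inhibition"), 1))
      tgt <- c(tgt, genes[j])
    }
  }
  pathway_topology(paste0("dag", seed), genes,
                   data.frame(source = src, relation = rel, target = tgt,
                              stringsAsFactors = FALSE))
}

# Independent brute-force oracles ------------------------------------------

# Hypergeometric upper tail by direct pmf summation (choose(), no phyper).
brute_hyper_tail <- function(a, K, n, N) {
  xs <- a:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Truncated Neumann-series solution of PF = dE + B PF.
neumann_pf <- function(B, dE, K = 200) {
  pf <- dE
  term <- dE
  for (k in seq_len(K)) {
    term <- B %*% term
    pf <- pf + term
  }
  as.numeric(pf)
}

# Direct-definition persistence check: all doses after the first
# significant one must be significant.
brute_persistence <- function(sig) {
  if (!any(sig)) return(FALSE)
  i0 <- which(sig)[1]
  all(sig[i0:length(sig)])
}
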