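# Topology-based pathway perturbation analysis, run per dose and traversed
# over a pathway hierarchy.
#
# For a pathway with signed edge matrix B (edge weights divided by the
# source gene's number of contributing outgoing edges), the per-gene
# perturbation factor PF solves PF = dE + B %*% PF, where dE is the observed
# log2 fold change of differentially expressed member genes (0 elsewhere).
# The net accumulation Acc = PF - dE sums to the pathway score tA. Evidence
# is combined from an over-representation p-value (pNDE, hypergeometric) and
# a bootstrap perturbation p-value (pPERT) into pG = c - c*ln(c) with
# c = pNDE * pPERT, then family-wise corrected (Bonferroni) across the
# pathways tested at each dose. Because non-curated topologies make the
# perturbation's direction unreliable, ranked outputs report |tA|; signed tA
# is kept in the raw table.

#' Default edge-weight map for relation types
#'
#' Activation/expression edges propagate +1, inhibition/repression -1;
#' binding and unknown relations carry no signal and do not count toward a
#' gene's outgoing-edge normalization.
#'
#' @return named numeric vector over relation types with values in
#'   \{-1, 0, +1\}.
#' @export
default_weight_map <- function() {
  c(activation = 1, expression = 1, inhibition = -1, repression = -1,
    binding = 0, unknown = 0)
}

#' Build the normalized signed adjacency matrix of a pathway
#'
#' `B[i, j] = beta_ij / Nds(j)`: the weight of edge j -> i divided by the
#' number of outgoing edges of j with nonzero weight. Zero-weight edges do
#' not contribute and do not count toward Nds; a gene whose outgoing edges
#' are all zero-weight contributes an all-zero column. A pathway without
#' topology yields the zero matrix.
#'
#' @param topology a `pathway_topology`.
#' @param weight_map named relation-type weights in \{-1, 0, +1\}.
#' @return square numeric matrix over `topology$nodes`.
#' @export
build_beta <- function(topology, weight_map = default_weight_map()) {
  stopifnot(inherits(topology, "pathway_topology"))
  nodes <- topology$nodes
  B <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- topology$edges
  if (nrow(e) == 0) return(B)
  missing_rel <- setdiff(unique(e$relation), names(weight_map))
  if (length(missing_rel) > 0)
    stop("relation type(s) absent from weight map: ",
         paste(missing_rel, collapse = ", "))
  w <- unname(weight_map[e$relation])
  contributing <- w != 0
  nds <- table(factor(e$source[contributing], levels = nodes))
  for (i in which(contributing)) {
    B[e$target[i], e$source[i]] <-
      B[e$target[i], e$source[i]] + w[i] / as.numeric(nds[[e$source[i]]])
  }
  B
}

#' Propagate perturbation through a pathway
#'
#' Solves `(I - B) PF = dE` by a linear solve (never explicit inversion),
#' returning the perturbation factors, net accumulations `Acc = PF - dE` and
#' the total pathway perturbation `tA = sum(Acc)`. Systems with reciprocal
#' condition number below `rcond_min` are declared singular.
#'
#' @param beta matrix from [build_beta()].
#' @param deltaE named numeric vector over pathway genes: signed log2 fold
#'   changes for DE genes, 0 elsewhere. Missing names are treated as 0.
#' @param rcond_min singularity guard on the reciprocal condition number.
#' @return list(PF, Acc, tA, status, residual).
#' @export
compute_perturbation <- function(beta, deltaE, rcond_min = 1e-12) {
  nodes <- rownames(beta)
  dE <- stats::setNames(rep(0, length(nodes)), nodes)
  common <- intersect(names(deltaE), nodes)
  dE[common] <- deltaE[common]
  A <- diag(length(nodes)) - beta
  if (length(nodes) > 0 && rcond(A) < rcond_min)
    return(list(PF = NULL, Acc = NULL, tA = NA_real_,
                status = "singular", residual = NA_real_))
  PF <- as.numeric(solve(A, dE))
  names(PF) <- nodes
  resid <- max(abs(A %*% PF - dE))
  Acc <- PF - dE
  list(PF = PF, Acc = Acc, tA = sum(Acc), status = "ok", residual = resid)
}

#' Over-representation p-value of a pathway's DE genes
#'
#' Hypergeometric upper tail shared with the enrichment stage: the chance of
#' seeing at least `n_de` DE genes in a pathway of `pathway_size` when
#' `n_de_total` of `n_universe` measured genes are differentially expressed.
#'
#' @param n_de DE genes in the pathway.
#' @param pathway_size pathway gene count (measured genes only).
#' @param n_de_total total DE genes.
#' @param n_universe measured-gene universe size.
#' @export
p_nde <- function(n_de, pathway_size, n_de_total, n_universe) {
  hypergeom_tail(n_de, pathway_size, n_de_total, n_universe)
}

#' Bootstrap perturbation p-value
#'
#' The observed nonzero fold changes are reassigned to `n_de` genes drawn
#' uniformly from the pathway in each bootstrap replicate; the two-sided,
#' median-centered, add-one estimate compares the observed tA to the null
#' distribution. A pathway with no DE genes (or no propagating topology)
#' returns 1.
#'
#' @param beta matrix from [build_beta()].
#' @param deltaE named observed fold changes (nonzero on DE genes).
#' @param tA observed total accumulation.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for this pathway/dose sub-stream.
#' @return p-value in (0, 1].
#' @export
p_pert <- function(beta, deltaE, tA, n_boot = 2000, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  nodes <- rownames(beta)
  vals <- deltaE[names(deltaE) %in% nodes]
  vals <- vals[vals != 0]
  nde <- length(vals)
  if (nde == 0 || is.na(tA)) return(1)
  A <- diag(length(nodes)) - beta
  set.seed(seed)
  E <- matrix(0, length(nodes), n_boot)
  for (b in seq_len(n_boot))
    E[sample.int(length(nodes), nde), b] <- vals[sample.int(nde)]
  PF <- solve(A, E)
  tA_null <- colSums(PF - E)
  med <- stats::median(tA_null)
  (1 + sum(abs(tA_null - med) >= abs(tA - med))) / (n_boot + 1)
}

#' Combine enrichment and perturbation evidence
#'
#' `pG = c - c*ln(c)` with `c = pNDE * pPERT` (the product method for two
#' independent uniform p-values); tends to 0 as c tends to 0 and equals 1
#' when both inputs are 1.
#'
#' @param pnde,ppert component p-values.
#' @export
combine_pg <- function(pnde, ppert) {
  cc <- pnde * ppert
  ifelse(cc == 0, 0, cc - cc * log(cc))
}

#' Perturbation analysis of one pathway at one dose
#'
#' Pathway nodes absent from the measured universe are dropped before
#' building the propagation matrix. Pathways without topology are reported
#' with status `no_topology` and no scores.
#'
#' @param topology a `pathway_topology`.
#' @param deltaE named signed log2 fold changes of the DE genes at this dose.
#' @param de_genes character vector of DE genes at this dose.
#' @param universe_genes measured genes (the count-matrix gene ids).
#' @param n_boot,seed bootstrap controls.
#' @param weight_map relation-type weights.
#' @return one-row data.frame (term, size, n_de, tA, abs_tA, pNDE, pPERT,
#'   pG, status).
#' @export
spia_pathway <- function(topology, deltaE, de_genes, universe_genes,
                         n_boot = 2000, seed = 1L,
                         weight_map = default_weight_map()) {
  nodes <- intersect(topology$nodes, universe_genes)
  n_in <- length(intersect(de_genes, nodes))
  base <- data.frame(term = topology$term, size = length(nodes), n_de = n_in,
                     tA = NA_real_, abs_tA = NA_real_, pNDE = NA_real_,
                     pPERT = NA_real_, pG = NA_real_,
                     status = "no_topology", stringsAsFactors = FALSE)
  if (!topology$has_topology || length(nodes) == 0) return(base)
  topo <- topology
  keep <- topo$edges$source %in% nodes & topo$edges$target %in% nodes
  topo <- pathway_topology(topo$term, nodes, topo$edges[keep, , drop = FALSE])
  beta <- build_beta(topo, weight_map)
  pert <- compute_perturbation(beta, deltaE)
  if (pert$status == "singular") {
    base$status <- "singular"
    return(base)
  }
  pnde <- p_nde(n_in, length(nodes),
                length(intersect(de_genes, universe_genes)),
                length(universe_genes))
  ppert <- p_pert(beta, deltaE, pert$tA, n_boot = n_boot, seed = seed)
  data.frame(term = topology$term, size = length(nodes), n_de = n_in,
             tA = pert$tA, abs_tA = abs(pert$tA), pNDE = pnde,
             pPERT = ppert, pG = combine_pg(pnde, ppert),
             status = "ok", stringsAsFactors = FALSE)
}

#' Traverse a pathway hierarchy with per-dose perturbation analysis
#'
#' For every node under each requested root and every dose, runs the full
#' perturbation computation on that node's topology with that dose's DE fold
#' changes, then applies a Bonferroni family-wise correction per dose across
#' the nodes that produced a score. The profile table is the node-by-dose
#' matrix of |tA| behind perturbation-tree plots, annotated per node and
#' dose with whether the pathway's DE genes were significantly enriched
#' (pNDE <= 0.05).
#'
#' @param hierarchy validated parent-child edge table.
#' @param topologies named list of `pathway_topology` objects.
#' @param dose_inputs named list (by dose) of lists with elements `deltaE`
#'   (named signed lFCs of DE genes) and `de_genes`.
#' @param roots root terms to traverse.
#' @param universe_genes measured gene universe.
#' @param n_boot bootstrap replicates.
#' @param seed global seed; each (pathway, dose) pair derives a sub-stream.
#' @param weight_map relation-type weights.
#' @return list with `results` (long data.frame incl. pG_fwer, enriched) and
#'   `profile` (data.frame term x dose of |tA|, NA where no topology).
#' @export
traverse_hierarchy <- function(hierarchy, topologies, dose_inputs, roots,
                               universe_genes, n_boot = 2000, seed = 1L,
                               weight_map = default_weight_map()) {
  all_terms <- unique(c(hierarchy$parent, hierarchy$child))
  missing_roots <- setdiff(roots, all_terms)
  if (length(missing_roots) > 0)
    stop("root(s) absent from hierarchy: ",
         paste(missing_roots, collapse = ", "))
  nodes <- unique(unlist(lapply(roots, hierarchy_descendants,
                                hierarchy = hierarchy)))
  nodes <- intersect(nodes, names(topologies))
  doses <- as.numeric(names(dose_inputs))
  ord <- order(doses)
  dose_inputs <- dose_inputs[ord]
  doses <- doses[ord]

  res <- list()
  for (di in seq_along(doses)) {
    d <- doses[di]
    inp <- dose_inputs[[di]]
    rows <- lapply(nodes, function(nm)
      spia_pathway(topologies[[nm]], inp$deltaE, inp$de_genes,
                   universe_genes, n_boot = n_boot,
                   seed = substream_seed(seed, paste(nm, d)),
                   weight_map = weight_map))
    tab <- do.call(rbind, rows)
    tab$dose <- d
    m <- sum(tab$status == "ok")
    tab$pG_fwer <- ifelse(tab$status == "ok", pmin(1, m * tab$pG), NA_real_)
    tab$enriched <- !is.na(tab$pNDE) & tab$pNDE <= 0.05
    res[[di]] <- tab
  }
  results <- do.call(rbind, res)
  results <- results[, c("term", "dose", "size", "n_de", "tA", "abs_tA",
                         "pNDE", "pPERT", "pG", "pG_fwer", "enriched",
                         "status")]
  profile <- data.frame(term = nodes, stringsAsFactors = FALSE)
  for (d in doses)
    profile[[paste0("dose_", d)]] <-
      results$abs_tA[results$dose == d][match(nodes,
                                              results$term[results$dose == d])]
  list(results = results, profile = profile)
}
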