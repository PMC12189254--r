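test_that("beta matrix: single edge, out-degree normalization, zero weights", {
  B <- build_beta(chain_topology("activation"))
  expect_equal(B["g2", "g1"], 1)
  expect_equal(sum(B != 0), 1)

  fan <- pathway_topology("fan", c("A", "B", "C"),
    data.frame(source = c("A", "A"), relation = "activation",
               target = c("B", "C")))
  Bf <- build_beta(fan)
  expect_equal(Bf["B", "A"], 0.5)
  expect_equal(Bf["C", "A"], 0.5)

  bind <- pathway_topology("bind", c("A", "B"),
    data.frame(source = "A", relation = "binding", target = "B"))
  expect_true(all(build_beta(bind) == 0))

  # a zero-weight edge does not count toward the source's out-degree
  mixed <- pathway_topology("mix", c("A", "B", "C"),
    data.frame(source = c("A", "A"), relation = c("activation", "binding"),
               target = c("B", "C")))
  expect_equal(build_beta(mixed)["B", "A"], 1)

  bad <- pathway_topology("bad", c("A", "B"),
    data.frame(source = "A", relation = "phosphorylation", target = "B"))
  expect_error(build_beta(bad), "phosphorylation")
})

test_that("perturbation propagation: edgeless, activation and inhibition chains", {
  B0 <- build_beta(pathway_topology("bare", c("x", "y")))
  r0 <- compute_perturbation(B0, c(x = 1.2, y = -0.3))
  expect_equal(unname(r0$PF), c(1.2, -0.3))
  expect_equal(unname(r0$Acc), c(0, 0))
  expect_equal(r0$tA, 0)

  r <- compute_perturbation(build_beta(chain_topology("activation")),
                            c(g1 = 1, g2 = 0))
  expect_equal(unname(r$PF), c(1, 1))
  expect_equal(r$tA, 1)
  expect_lt(r$residual, 1e-10)

  ri <- compute_perturbation(build_beta(chain_topology("inhibition")),
                             c(g1 = 1, g2 = 0))
  expect_equal(ri$tA, -1)
})

test_that("propagation matches the truncated Neumann-series oracle", {
  for (s in 1:30) {
    topo <- random_dag_topology(n = sample(4:12, 1), seed = s)
    B <- build_beta(topo)
    set.seed(s + 1000)
    dE <- setNames(rnorm(length(topo$nodes)) *
                     rbinom(length(topo$nodes), 1, 0.5), topo$nodes)
    r <- compute_perturbation(B, dE)
    expect_equal(unname(r$PF), neumann_pf(B, dE[topo$nodes]),
                 tolerance = 1e-8)
  }
})

test_that("tA is invariant to gene index permutation", {
  topo <- random_dag_topology(n = 9, seed = 4)
  B <- build_beta(topo)
  set.seed(5)
  dE <- setNames(rnorm(9), topo$nodes)
  r1 <- compute_perturbation(B, dE)
  perm <- sample(topo$nodes)
  r2 <- compute_perturbation(B[perm, perm], dE[perm])
  expect_equal(r1$tA, r2$tA, tolerance = 1e-12)
})

test_that("singular feedback systems are flagged, not solved", {
  loop <- pathway_topology("loop", c("A", "B"),
    data.frame(source = c("A", "B"), relation = "activation",
               target = c("B", "A")))
  r <- compute_perturbation(build_beta(loop), c(A = 1, B = 0))
  expect_identical(r$status, "singular")
  expect_true(is.na(r$tA))
})

test_that("pG combination: closed form and bounds", {
  expect_equal(combine_pg(1, 1), 1)
  cc <- 0.01
  expect_equal(combine_pg(0.1, 0.1), cc - cc * log(cc), tolerance = 1e-12)
  expect_equal(round(combine_pg(0.1, 0.1), 4), 0.0561)
  expect_equal(combine_pg(0, 0.5), 0)
  for (c1 in c(0.001, 0.05, 0.3, 0.9))
    expect_gte(combine_pg(c1, 1), c1)
})

test_that("bootstrap p-value: trivial cases and exact reproducibility", {
  B <- build_beta(chain_topology("activation"))
  expect_equal(p_pert(B, c(g1 = 0, g2 = 0), 0, n_boot = 200, seed = 1), 1)

  B0 <- build_beta(pathway_topology("bare", c("g1", "g2")))
  expect_equal(p_pert(B0, c(g1 = 2), 0, n_boot = 200, seed = 1), 1)

  p1 <- p_pert(B, c(g1 = 1.5), 1.5, n_boot = 500, seed = 9)
  p2 <- p_pert(B, c(g1 = 1.5), 1.5, n_boot = 500, seed = 9)
  expect_identical(p1, p2)
  expect_error(p_pert(B, c(g1 = 1), 1, n_boot = 50), ">= 100")
})

test_that("bootstrap null is roughly uniform on a symmetric pathway", {
  topo <- random_dag_topology(n = 10, p_edge = 0.3, seed = 77)
  B <- build_beta(topo)
  set.seed(78)
  ps <- vapply(1:40, function(i) {
    dE <- setNames(rep(0, 10), topo$nodes)
    dE[sample(10, 3)] <- rnorm(3)
    r <- compute_perturbation(B, dE)
    p_pert(B, dE[dE != 0], r$tA, n_boot = 300, seed = 100 + i)
  }, numeric(1))
  # super-uniform or uniform: mean should not be far below 0.5
  expect_gt(mean(ps), 0.3)
  expect_lte(max(ps), 1)
})

test_that("single-pathway analysis drops unmeasured genes and flags topology", {
  topo <- pathway_topology("t", c("g1", "g2", "gX"),
    data.frame(source = c("g1", "g2"), relation = "activation",
               target = c("g2", "gX")))
  universe <- c(paste0("g", 1:50))
  row <- spia_pathway(topo, c(g1 = 1), "g1", universe, n_boot = 200, seed = 1)
  expect_identical(row$status, "ok")
  expect_equal(row$size, 2L)   # gX is not measured
  expect_equal(row$tA, 1)      # g1 -> g2 chain survives

  bare <- pathway_topology("bare", c("g1", "g2"))
  rowb <- spia_pathway(bare, c(g1 = 1), "g1", universe)
  expect_identical(rowb$status, "no_topology")
  expect_true(is.na(rowb$tA))
})

test_that("hierarchy traversal: flags, Bonferroni, dose-order invariance", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 23))
  gs <- simulate_genesets(sim$truth, n_sets = 8, seed = 23,
                          n_topologyless = 1)
  de <- run_dea(sim$counts, sim$design)
  dose_inputs <- lapply(de, function(d) {
    sig <- d$significant
    list(deltaE = setNames(d$log2FC[sig], d$gene_id[sig]),
         de_genes = d$gene_id[sig])
  })
  roots <- attr(gs$hierarchy, "roots")
  out <- traverse_hierarchy(gs$hierarchy, gs$topologies, dose_inputs,
                            roots, rownames(sim$counts),
                            n_boot = 200, seed = 23)
  res <- out$results
  topo_less <- names(gs$topologies)[!vapply(gs$topologies, `[[`, TRUE,
                                            "has_topology")]
  expect_true(all(res$status[res$term %in% topo_less] == "no_topology"))
  expect_true(all(is.na(res$tA[res$status == "no_topology"])))
  ok <- res$status == "ok"
  for (d in unique(res$dose)) {
    sel <- ok & res$dose == d
    m <- sum(sel)
    expect_equal(res$pG_fwer[sel], pmin(1, m * res$pG[sel]))
  }
  expect_true(all(res$pG_fwer[ok] >= res$pG[ok]))

  out2 <- traverse_hierarchy(gs$hierarchy, gs$topologies, rev(dose_inputs),
                             roots, rownames(sim$counts),
                             n_boot = 200, seed = 23)
  expect_identical(out$results, out2$results)
  expect_identical(out$profile, out2$profile)

  expect_error(traverse_hierarchy(gs$hierarchy, gs$topologies, dose_inputs,
                                  "NOPE", rownames(sim$counts)),
               "NOPE")
})
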