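test_that("size factors: symmetry, hand-computed ratios, scaling", {
  m <- matrix(c(5L, 9L, 5L, 9L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  sf <- estimate_size_factors(tiny_counts())
  # rows (10,20),(30,60): geomeans sqrt(200), sqrt(1800); median ratios
  # (1/sqrt 2, sqrt 2) after rescaling to geometric mean 1
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)

  m3 <- cbind(tiny_counts(), s3 = 3L * tiny_counts()[, 2])
  sf3 <- estimate_size_factors(m3)
  expect_equal(unname(sf3["s3"] / sf3["s2"]), 3)

  z <- matrix(c(0L, 1L, 1L, 0L), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(estimate_size_factors(z), "pseudo-reference")
})

test_that("dispersion: Poisson near floor, constant at floor, NB recovered", {
  set.seed(1)
  G <- 300; n <- 100
  pois <- matrix(rpois(G * n, 50), G,
                 dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  sf <- rep(1, n)
  a_pois <- estimate_dispersion(pois, sf)
  expect_lt(median(a_pois), 0.02)

  cm <- matrix(7L, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  a_const <- estimate_dispersion(cm, rep(1, 6))
  expect_true(all(a_const == 1e-8))

  nb <- matrix(rnbinom(G * 200, size = 1 / 0.2, mu = 100), G,
               dimnames = list(paste0("g", 1:G), paste0("s", 1:200)))
  a_nb <- estimate_dispersion(nb, rep(1, 200))
  expect_gt(median(a_nb), 0.1)
  expect_lt(median(a_nb), 0.4)

  expect_error(estimate_dispersion(pois[, 1, drop = FALSE], 1), "2 samples")
})

test_that("group-aware dispersion ignores between-arm signal", {
  set.seed(2)
  G <- 200
  y0 <- matrix(rpois(G * 3, 50), G)
  y1 <- matrix(rpois(G * 3, 200), G)  # strong arm effect, Poisson noise
  m <- cbind(y0, y1)
  dimnames(m) <- list(paste0("g", 1:G), paste0("s", 1:6))
  grp <- rep(c(0, 5), each = 3)
  pooled <- estimate_dispersion(m, rep(1, 6))
  within <- estimate_dispersion(m, rep(1, 6), groups = grp)
  expect_gt(median(pooled), 10 * median(within))
})

test_that("wald test: null identity, all-zero exclusion, sign convention", {
  G <- 40
  set.seed(3)
  base <- matrix(rpois(G * 3, 60), G)
  m <- cbind(base, base)  # identical arms
  dimnames(m) <- list(paste0("g", 1:G),
                      c(paste0("c", 1:3), paste0("t", 1:3)))
  m["g1", ] <- 0L
  d <- data.frame(sample_id = colnames(m), dose = rep(c(0, 5), each = 3),
                  replicate = rep(1:3, 2))
  res <- wald_test(m, d, 5)
  tested <- res[res$status == "tested", ]
  expect_true(all(abs(tested$log2FC) < 1e-8))
  expect_true(all(abs(tested$pvalue - 1) < 1e-8))
  expect_identical(res$status[res$gene_id == "g1"], "all_zero_excluded")
  expect_true(is.na(res$pvalue[res$gene_id == "g1"]))

  # sign of lFC equals sign of mean difference
  set.seed(4)
  m2 <- cbind(matrix(rpois(G * 3, 40), G), matrix(rpois(G * 3, 90), G))
  dimnames(m2) <- dimnames(m)
  res2 <- wald_test(m2, d, 5)
  norm <- sweep(m2, 2, estimate_size_factors(m2), "/")
  dirs <- sign(rowMeans(norm[, 4:6]) - rowMeans(norm[, 1:3]))
  expect_true(all(sign(res2$log2FC) == dirs | dirs == 0))
})

test_that("wald estimates agree with a fixed-dispersion GLM oracle", {
  set.seed(7)
  G <- 15
  sf <- exp(runif(6, -0.2, 0.2)); sf <- sf / exp(mean(log(sf)))
  mu <- runif(G, 30, 300)
  alpha <- runif(G, 0.01, 0.2)
  y <- t(sapply(seq_len(G), function(g)
    rnbinom(6, size = 1 / alpha[g],
            mu = sf * mu[g] * c(1, 1, 1, 2, 2, 2))))
  dimnames(y) <- list(paste0("g", 1:G), paste0("s", 1:6))
  d <- data.frame(sample_id = colnames(y), dose = rep(c(0, 10), each = 3),
                  replicate = rep(1:3, 2))
  res <- wald_test(y, d, 10, size_factors = setNames(sf, colnames(y)),
                   dispersions = setNames(alpha, rownames(y)))
  arm <- factor(rep(c("c", "t"), each = 3))
  for (g in seq_len(G)) {
    fit <- suppressWarnings(stats::glm(
      y[g, ] ~ arm + offset(log(sf)),
      family = MASS::negative.binomial(theta = 1 / alpha[g])))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(res$log2FC[g], co["armt", "Estimate"] / log(2),
                 tolerance = 1e-4)
    expect_equal(res$lfcSE[g], co["armt", "Std. Error"] / log(2),
                 tolerance = 1e-3)
  }
})

test_that("wald test recovers a planted fold change", {
  set.seed(8)
  G <- 100
  mu <- rlnorm(G, 5, 0.5)
  alpha <- rep(0.02, G)
  y0 <- t(sapply(1:G, function(g) rnbinom(5, 1 / alpha[g], mu = mu[g])))
  y1 <- t(sapply(1:G, function(g)
    rnbinom(5, 1 / alpha[g], mu = mu[g] * 2^1.5)))
  m <- cbind(y0, y1)
  dimnames(m) <- list(paste0("g", 1:G), paste0("s", 1:10))
  d <- data.frame(sample_id = colnames(m), dose = rep(c(0, 5), each = 5),
                  replicate = rep(1:5, 2))
  res <- wald_test(m, d, 5, size_factors = setNames(rep(1, 10), colnames(m)),
                   dispersions = setNames(alpha, rownames(m)))
  expect_lt(abs(mean(res$log2FC) - 1.5), 0.15)
})

test_that("BH adjustment: hand example, m = 1, dominance, range check", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.7), 0.7)
  set.seed(9)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_adjust(c(0.04, NA, 0.5)), c(0.08, NA, 0.5))
})

test_that("results are invariant to gene row order", {
  sim <- simulate_counts(sim_config(n_genes = 60, seed = 12))
  res1 <- wald_test(sim$counts, sim$design, 100)
  perm <- sample(nrow(sim$counts))
  res2 <- wald_test(sim$counts[perm, ], sim$design, 100)
  m <- match(res1$gene_id, res2$gene_id)
  expect_equal(res1$log2FC, res2$log2FC[m], tolerance = 1e-10)
  expect_equal(res1$pvalue, res2$pvalue[m], tolerance = 1e-10)
})

test_that("volcano export carries the 0.25 lFC guides", {
  sim <- simulate_counts(sim_config(n_genes = 40, seed = 13))
  res <- wald_test(sim$counts, sim$design, 100)
  v <- volcano_table(res)
  expect_identical(attr(v, "lfc_guides"), c(-0.25, 0.25))
  expect_identical(nrow(v), nrow(res))
})
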