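test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_landscape(n_localities = 5, n_per_locality = 3,
                           n_loci = 50, seed = 9)
  s2 <- simulate_landscape(n_localities = 5, n_per_locality = 3,
                           n_loci = 50, seed = 9)
  expect_identical(s1$genotypes$geno, s2$genotypes$geno)
  expect_identical(s1$env, s2$env)
  expect_identical(s1$localities, s2$localities)
  l1 <- simulate_linked_genotypes(ld_sim_truth(seed = 4))
  l2 <- simulate_linked_genotypes(ld_sim_truth(seed = 4))
  expect_identical(l1$genotypes$geno, l2$genotypes$geno)
  l3 <- simulate_linked_genotypes(ld_sim_truth(seed = 5))
  expect_false(identical(l1$genotypes$geno, l3$genotypes$geno))
})

test_that("landscape output is well formed and in range", {
  sim <- simulate_landscape(n_localities = 6, n_per_locality = c(3, 5),
                            n_loci = 80, seed = 2)
  g <- sim$genotypes$geno
  expect_true(all(g %in% 0:2))
  expect_setequal(sim$localities$sample, sim$genotypes$samples)
  # environment standardized per variable across localities
  for (v in unique(sim$env$variable)) {
    vals <- sim$env$value[sim$env$variable == v]
    expect_equal(mean(vals), 0, tolerance = 1e-12)
    expect_equal(sd(vals), 1, tolerance = 1e-12)
  }
  expect_true(all(sim$truth$ancestral_freq > 0 &
                    sim$truth$ancestral_freq < 1))
  # causal ids appear in the environment table
  expect_true(all(sim$truth$causal %in% sim$env$variable))
})

test_that("landscape argument validation", {
  expect_error(simulate_landscape(n_localities = 2), ">= 3")
  expect_error(
    simulate_landscape(n_localities = 5,
                       ibe = list(sigma2 = 1, phi = 1, causal = "nope")),
    "causal")
  expect_error(simulate_environment(0), ">= 2")
  vars <- default_env_variables()
  vars$name[2] <- vars$name[1]
  expect_error(simulate_environment(5, vars), "duplicate")
})

test_that("zero structure parameters give an unstructured population", {
  sim <- simulate_landscape(n_localities = 8, n_per_locality = 6,
                            n_loci = 600,
                            ibd = list(sigma2 = 0, phi = 500),
                            ibe = list(sigma2 = 0, phi = 1,
                                       causal = character(0)),
                            seed = 31)
  expect_true(all(sim$truth$locality_freq[1, ] ==
                    t(sim$truth$locality_freq)[, 1]))
  groups <- sim$localities$locality
  fst <- wc_fst(sim$genotypes, groups)
  # bootstrap loci for a standard error of the null F_ST
  set.seed(1)
  boot <- replicate(200, {
    idx <- sample(ncol(sim$genotypes$geno), replace = TRUE)
    wc_fst(subset_genotypes(sim$genotypes, loci = idx), groups)
  })
  expect_lt(abs(fst), 3 * sd(boot))
})

test_that("strong IBD produces Mantel-detectable distance correlation", {
  hits <- 0L
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    sim <- simulate_landscape(n_localities = 10, n_per_locality = 4,
                              n_loci = 300,
                              ibd = list(sigma2 = 2, phi = 800),
                              ibe = list(sigma2 = 0, phi = 1,
                                         causal = character(0)),
                              seed = 100 + s)
    gd <- gower_distance(genotype_covariance(sim$genotypes))
    geo <- geo_distance_matrix(sim$localities$lat, sim$localities$lon)
    mt <- mantel_test(gd, geo, n_perm = 99, seed = s)
    if (mt$p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep) - 1)  # >= 18/20
})

test_that("noise environment variables are spatially unstructured, spatial ones not", {
  noise_hits <- 0L
  spatial_hits <- 0L
  n_rep <- 30
  vars <- data.frame(name = c("sp", "noi"), category = c("Water", "Water"),
                     scale = c(500, NA))
  for (s in seq_len(n_rep)) {
    env <- simulate_environment(25, vars, seed = 500 + s)
    coords <- attr(env, "coords")
    dmat <- geo_distance_matrix(coords$lat, coords$lon)
    ww <- env$value[env$variable == "noi"]
    sp <- env$value[env$variable == "sp"]
    # permutation test of the Moran-like statistic for the noise variable
    obs <- oracle_moran(ww, dmat)
    perm <- replicate(99, oracle_moran(sample(ww), dmat))
    if ((1 + sum(perm >= obs)) / 100 > 0.05) noise_hits <- noise_hits + 1L
    if (oracle_moran(sp, dmat) > 0) spatial_hits <- spatial_hits + 1L
  }
  expect_gte(noise_hits, ceiling(0.9 * n_rep) - 1)    # >= 26/30
  expect_gte(spatial_hits, ceiling(0.9 * n_rep) - 1)  # >= 26/30
})

test_that("two founders with no switching give complete LD", {
  truth <- ld_sim_truth(n_founders = 2, switch_prob = 1e-12,
                        snp_density = 2e-3, chrom_length = 20000,
                        n_diploids = 12, seed = 6)
  ld <- simulate_linked_genotypes(truth)
  pr <- pairwise_r2(ld$genotypes)
  expect_gt(nrow(pr), 0)
  expect_true(all(abs(pr$r2 - 1) < 1e-12))
})

test_that("near-certain switching collapses LD to the unlinked baseline", {
  truth <- ld_sim_truth(n_founders = 30, switch_prob = 0.9,
                        snp_density = 5e-3, chrom_length = 10000,
                        n_diploids = 40, seed = 8)
  ld <- simulate_linked_genotypes(truth)
  g <- ld$genotypes
  adj <- pairwise_r2(g)
  adj <- adj[adj$dist <= 50, ]
  # permuted-locus baseline: shuffle each locus across samples independently
  set.seed(1)
  gp <- apply(g$geno, 2, sample)
  rownames(gp) <- g$samples
  gperm <- genotype_matrix(gp, g$loci$chrom, g$loci$pos)
  base <- pairwise_r2(gperm)
  expect_lt(abs(mean(adj$r2) - mean(base$r2)), 0.02)
})

test_that("simulator rejects parameter sets yielding too few SNPs", {
  expect_error(
    simulate_linked_genotypes(ld_sim_truth(snp_density = 1e-5,
                                           chrom_length = 10000)),
    "< 2 SNPs")
})

test_that("hill_weir_synthetic_pairs matches the closed form when noiseless", {
  n <- 40
  d <- c(1, 10, 100, 1000)
  pr <- hill_weir_synthetic_pairs(1e-3, n, d, noise_sd = 0)
  expect_equal(pr$r2, hill_weir_expectation(1e-3 * d, n))
  # near-zero and asymptotic limits of the expectation itself
  expect_equal(hill_weir_expectation(0, n), (10 / 22) * (1 + 36 / (22 * n)))
  expect_equal(hill_weir_expectation(1e9, n), 1 / n, tolerance = 1e-6)
  # noise is truncated to [0, 1]
  pr2 <- hill_weir_synthetic_pairs(1e-3, n, rep(d, 50), noise_sd = 0.5,
                                   seed = 3)
  expect_true(all(pr2$r2 >= 0 & pr2$r2 <= 1))
})
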