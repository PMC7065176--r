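gm <- function(mat, pos = NULL) {
  genotype_matrix(mat, rep("chr1", ncol(mat)),
                  pos %||% seq_len(ncol(mat)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("expected heterozygosity closed forms and brute-force oracle", {
  # monomorphic locus contributes 0
  expect_equal(expected_heterozygosity(gm(rbind(c(0, 0), c(0, 2)))),
               mean(c(0, (4 / 3) * 0.5)))
  # N = 2, p = q = 0.5, single locus -> (4/3) * 0.5
  expect_equal(expected_heterozygosity(gm(cbind(c(0, 2)))), 2 / 3)
  # random matrix vs per-locus formula evaluated independently
  set.seed(5)
  mat <- matrix(sample(c(0:2, NA), 120, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 6, 20)
  mat[, 1] <- NA  # all-missing locus must be excluded
  x <- gm(mat)
  he_by_hand <- c()
  for (l in seq_len(ncol(x$geno))) {
    v <- x$geno[!is.na(x$geno[, l]), l]
    if (length(v) == 0) next
    p <- sum(v) / (2 * length(v))
    he_by_hand <- c(he_by_hand,
                    (2 * length(v) / (2 * length(v) - 1)) *
                      (1 - p^2 - (1 - p)^2))
  }
  expect_equal(expected_heterozygosity(x), mean(he_by_hand))
  expect_error(expected_heterozygosity(gm(cbind(c(NA, NA)))), "non-missing")
})

test_that("nucleotide diversity convention and invariances", {
  # two homozygous samples differing at 1 of 10 sites: corrected convention
  x <- gm(cbind(c(0, 2)))
  expect_equal(nucleotide_diversity(x, 10), 2 * 0.25 * (4 / 3) / 10)
  # identical samples -> 0
  expect_equal(nucleotide_diversity(gm(rbind(c(0, 2), c(0, 2))), 5), 0)
  # sample-order invariance
  set.seed(7)
  mat <- matrix(rbinom(60, 2, 0.4), 6, 10)
  x1 <- gm(mat)
  x2 <- gm(mat[sample(6), ])
  expect_equal(nucleotide_diversity(x1, 20), nucleotide_diversity(x2, 20))
  expect_error(nucleotide_diversity(x1, 5), "total_sites")
})

test_that("the corrected pi convention matches mean pairwise hap differences", {
  # Brute-force oracle, exact for homozygous diploids (each contributes two
  # identical haplotypes): pi per site is the fraction of *distinct*
  # haplotype pairs that differ, which is what the (2N/(2N-1)) correction
  # of 2pq computes.
  mat <- rbind(c(0, 2, 2), c(2, 2, 0), c(0, 0, 2))  # 3 homozygous diploids
  x <- gm(mat)
  haps <- mat[rep(1:3, each = 2), ] / 2
  n_hap <- nrow(haps)
  per_locus <- apply(haps, 2, function(h) {
    diff_pairs <- 0
    for (i in 1:(n_hap - 1)) for (j in (i + 1):n_hap) {
      diff_pairs <- diff_pairs + (h[i] != h[j])
    }
    diff_pairs / choose(n_hap, 2)
  })
  total_sites <- 3
  expect_equal(nucleotide_diversity(x, total_sites),
               sum(per_locus) / total_sites)
})

test_that("WC84 F_ST: complete differentiation, null, and oracle agreement", {
  # two groups fixed for alternate alleles -> 1
  mat <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  expect_equal(wc_fst(gm(mat), rep(c("a", "b"), each = 4)), 1)
  # printed toy vs straight-from-the-formulas oracle
  set.seed(11)
  toy <- matrix(rbinom(100, 2, runif(10, 0.2, 0.8)), 10, 10, byrow = TRUE)
  toy[2, 3] <- NA
  labels <- rep(c("d1", "d2"), each = 5)
  expect_equal(wc_fst(gm(toy), labels), oracle_wc84(toy, labels))
  # panmictic population split randomly: mean estimate within 3 SE of 0
  set.seed(13)
  ests <- replicate(60, {
    m <- matrix(rbinom(40 * 30, 2, rep(runif(30, 0.2, 0.8), each = 40)),
                40, 30)
    wc_fst(gm(m), sample(rep(c("x", "y"), each = 20)))
  })
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
  expect_error(wc_fst(gm(mat), rep("a", 8)), ">= 2 groups")
})

test_that("genotype covariance matches hand evaluation and is invariant", {
  # 3 samples x 2 loci hand example
  mat <- rbind(c(0, 1), c(1, 2), c(2, 1))
  x <- gm(mat)
  p <- colMeans(mat) / 2
  cmat_hand <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    cmat_hand[i, j] <- mean((mat[i, ] - 2 * p) * (mat[j, ] - 2 * p) /
                              (2 * p * (1 - p)))
  }
  expect_equal(unname(genotype_covariance(x)), cmat_hand)
  # identical samples: C_ii = C_jj = C_ij
  xx <- gm(rbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0)))
  cc <- genotype_covariance(xx)
  expect_equal(cc[1, 1], cc[1, 2])
  expect_equal(cc[1, 1], cc[2, 2])
  # locus-order permutation invariance
  set.seed(3)
  m2 <- matrix(rbinom(80, 2, 0.5), 8, 10)
  expect_equal(unname(genotype_covariance(gm(m2))),
               unname(genotype_covariance(gm(m2[, sample(10)]))),
               tolerance = 1e-12)
  expect_error(genotype_covariance(gm(matrix(c(0, 0, 2, 2), 2, 2))),
               "excluded")
})

test_that("Gower transform: closed forms and eigen-embedding oracle", {
  expect_equal(unname(gower_distance(diag(2))),
               matrix(c(0, 2, 2, 0), 2), ignore_attr = TRUE)
  expect_equal(gower_distance(matrix(c(2, 1, 1, 2), 2))[1, 2], 2)
  # PSD 5x5: D equals squared Euclidean distances of the eigen-embedding
  set.seed(9)
  a <- matrix(rnorm(25), 5)
  cmat <- crossprod(a)
  d <- gower_distance(cmat)
  e <- eigen(cmat, symmetric = TRUE)
  emb <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  d_oracle <- as.matrix(dist(emb))^2
  expect_equal(unname(d), unname(d_oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(gower_distance(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  # sqrt flag
  expect_equal(gower_distance(diag(2), sqrt_dist = TRUE)[1, 2], sqrt(2))
})

test_that("PCA of covariance: rank-1, fractions, dense-solver agreement", {
  v <- c(1, 2, 3)
  r1 <- cov_pca(outer(v, v))
  expect_equal(r1$var_fraction[1], 1)
  set.seed(4)
  a <- matrix(rnorm(36), 6)
  cmat <- crossprod(a)
  p <- cov_pca(cmat)
  expect_equal(sum(p$var_fraction), 1)
  sv <- svd(cmat)
  expect_equal(p$values, sv$d)
  expect_equal(abs(diag(crossprod(p$axes, sv$u))), rep(1, 6),
               tolerance = 1e-8)
})

test_that("Mantel statistic and p-value behave as defined", {
  set.seed(21)
  xy <- matrix(runif(20), 10)
  d1 <- as.matrix(dist(xy))
  # identical matrices: r = 1, minimal p
  mt <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100)
  # r equals plain Pearson on the vectorized lower triangles
  d2 <- as.matrix(dist(matrix(runif(20), 10)))
  mt2 <- mantel_test(d1, d2, n_perm = 99, seed = 2)
  expect_equal(mt2$r, cor(d1[lower.tri(d1)], d2[lower.tri(d2)]))
  expect_error(mantel_test(d1, matrix(0, 10, 10), n_perm = 99), "constant")
  expect_error(mantel_test(d1, d2, n_perm = 50), ">= 99")
})

test_that("haversine distance closed forms", {
  expect_equal(geo_distance(10, 20, 10, 20), 0)
  expect_equal(geo_distance(0, 0, 1, 0), 6371.0088 * pi / 180,
               tolerance = 1e-10)
  expect_equal(geo_distance(-30, 150, -35, 145),
               geo_distance(-35, 145, -30, 150))
  dm <- geo_distance_matrix(c(-30, -35), c(150, 145))
  expect_equal(dm[1, 2], geo_distance(-30, 150, -35, 145))
  expect_equal(diag(dm), c(0, 0))
})
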