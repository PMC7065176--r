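#' Great-circle distance between points (haversine)
#'
#' Vectorized haversine distance on a spherical Earth of radius 6371.0088 km
#' (IUGG mean radius), the convention used by common `earth.dist`-style
#' helpers.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in kilometres.
#' @export
geo_distance <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * r * asin(sqrt(a))
}

#' Pairwise great-circle distance matrix
#'
#' @param lat,lon Coordinate vectors (decimal degrees); names, if any, label
#'   the result.
#' @return Symmetric matrix of distances in km with zero diagonal.
#' @export
geo_distance_matrix <- function(lat, lon) {
  n <- length(lat)
  stopifnot(length(lon) == n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- geo_distance(lat[i], lon[i], lat, lon)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(names(lat), names(lat))
  d
}

# Pooled alternate-allele frequency per locus from dosages (NA-aware).
.allele_freq <- function(g) colMeans(g, na.rm = TRUE) / 2

#' Nei's sample-size corrected gene diversity (expected heterozygosity)
#'
#' Averages, over usable loci, the corrected per-locus gene diversity
#' (2N/(2N-1)) * (1 - p^2 - q^2), where N is the number of diploids with
#' non-missing data at the locus and p, q the two allele frequencies.
#'
#' @param x A [genotype_matrix()], typically restricted to one locality.
#' @return Scalar H_e in \[0, 1\].
#' @export
expected_heterozygosity <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$geno
  N <- colSums(!is.na(g))
  use <- N >= 1
  if (!any(use)) stop("no loci with any non-missing data")
  if (nrow(g) < 2) stop("need at least 2 diploid samples")
  p <- .allele_freq(g)[use]
  N <- N[use]
  he <- (2 * N / (2 * N - 1)) * (1 - p^2 - (1 - p)^2)
  mean(he)
}

#' Nucleotide diversity from variant genotypes
#'
#' Per-site expected pairwise difference: each variant locus contributes
#' 2*p*q * (2N/(2N-1)) (the small-sample corrected heterozygosity), summed and
#' divided by `total_sites`, the total number of genomic sites the variants
#' were ascertained from. Monomorphic sites contribute zero, so `total_sites`
#' may exceed the number of variant loci; using `total_sites = n_loci(x)`
#' gives a per-variant-site quantity.
#'
#' @param x A [genotype_matrix()].
#' @param total_sites Total callable sites (>= number of variant loci).
#' @return Scalar per-site diversity.
#' @export
nucleotide_diversity <- function(x, total_sites) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$geno
  if (total_sites < ncol(g)) {
    stop("total_sites (", total_sites, ") < number of variant loci (",
         ncol(g), ")")
  }
  N <- colSums(!is.na(g))
  p <- .allele_freq(g)
  ok <- N >= 1
  contrib <- 2 * p[ok] * (1 - p[ok]) * (2 * N[ok] / (2 * N[ok] - 1))
  sum(contrib) / total_sites
}

#' Weir & Cockerham (1984) multi-locus F_ST
#'
#' Global theta-hat from the a (between-population), b (between individuals
#' within populations) and c (within individuals) variance components,
#' aggregated as ratio of sums over loci: sum(a) / sum(a + b + c). Loci where
#' fewer than two populations have at least one genotyped diploid, or where
#' all components are undefined, are skipped.
#'
#' @param x A [genotype_matrix()].
#' @param groups Factor or character vector of group labels, one per sample
#'   (in `x$samples` order).
#' @return Scalar F_ST estimate (can be slightly negative in unstructured
#'   data, as is standard for this estimator).
#' @export
wc_fst <- function(x, groups) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$geno
  groups <- as.character(groups)
  if (length(groups) != nrow(g)) stop("one group label per sample required")
  glev <- unique(groups)
  if (length(glev) < 2) stop("need >= 2 groups")
  big <- vapply(glev, function(k) sum(groups == k) >= 2, logical(1))
  if (sum(big) < 2) stop("need >= 2 groups with >= 2 diploids")
  num <- 0
  den <- 0
  n_used <- 0L
  for (l in seq_len(ncol(g))) {
    gl <- g[, l]
    comp <- .wc_components(gl, groups)
    if (is.null(comp)) next
    num <- num + comp[["a"]]
    den <- den + comp[["a"]] + comp[["b"]] + comp[["c"]]
    n_used <- n_used + 1L
  }
  if (n_used == 0L || den == 0) stop("no informative loci for F_ST")
  num / den
}

# Per-locus WC84 variance components for a biallelic locus from dosages.
# Returns NULL when the locus is uninformative (monomorphic overall or
# fewer than two populations with data).
.wc_components <- function(gl, groups) {
  keep <- !is.na(gl)
  gl <- gl[keep]
  grp <- groups[keep]
  tab <- table(grp)
  tab <- tab[tab >= 1]
  r <- length(tab)
  if (r < 2) return(NULL)
  pops <- names(tab)
  ni <- as.numeric(tab)
  pi <- vapply(pops, function(k) mean(gl[grp == k]) / 2, numeric(1))
  hi <- vapply(pops, function(k) mean(gl[grp == k] == 1), numeric(1))
  nbar <- mean(ni)
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(NULL)
  pbar <- sum(ni * pi) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(NULL)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Frequency-standardized genotype covariance (GRM)
#'
#' The genomic relationship matrix C with entries
#' C_ij = (1/L'_ij) * sum_l (g_il - 2p_l)(g_jl - 2p_l) / (2 p_l (1 - p_l)),
#' where p_l is the pooled alternate-allele frequency and the sum runs over
#' loci where both samples are genotyped (pairwise-complete, with per-pair
#' locus counts L'_ij). Monomorphic loci (p = 0 or 1) are excluded.
#'
#' @param x A [genotype_matrix()] with >= 2 samples.
#' @param standardize Divide each locus by 2p(1-p) (default). `FALSE` gives
#'   the raw centred covariance.
#' @return Symmetric covariance matrix with sample ids as dimnames.
#' @export
genotype_covariance <- function(x, standardize = TRUE) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$geno
  if (nrow(g) < 2) stop("need >= 2 samples")
  p <- .allele_freq(g)
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("all loci excluded (monomorphic or all-missing)")
  g <- g[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(g, 2, 2 * p, "-")
  if (standardize) z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(z)
  z[!obs] <- 0
  counts <- tcrossprod(obs * 1)
  if (any(counts == 0)) {
    stop("some sample pairs share no genotyped loci")
  }
  cmat <- tcrossprod(z) / counts
  dimnames(cmat) <- list(x$samples, x$samples)
  (cmat + t(cmat)) / 2
}

#' Gower transformation of a covariance matrix to distances
#'
#' D_ij = C_ii + C_jj - 2 C_ij, the squared-Euclidean distances realized by
#' any embedding with covariance C. Numerically negative entries (possible
#' with pairwise-complete missing-data covariances) are clipped to zero; the
#' number clipped is recorded in `attr(, "n_clipped")`.
#'
#' @param cmat Symmetric covariance matrix.
#' @param sqrt_dist Return plain Euclidean distances (`sqrt(D)`) instead of
#'   the squared-Euclidean values the formula yields. Default `FALSE`, i.e.
#'   the literal formula.
#' @param tol Symmetry tolerance.
#' @return Symmetric non-negative distance matrix, zero diagonal.
#' @export
gower_distance <- function(cmat, sqrt_dist = FALSE, tol = 1e-8) {
  cmat <- as.matrix(cmat)
  if (nrow(cmat) != ncol(cmat) ||
      max(abs(cmat - t(cmat))) > tol * max(1, max(abs(cmat)))) {
    stop("covariance matrix must be square and symmetric")
  }
  dg <- diag(cmat)
  d <- outer(dg, dg, "+") - 2 * cmat
  n_clipped <- sum(d < 0 & row(d) != col(d))
  if (n_clipped > 0) {
    warning(n_clipped, " negative Gower distances clipped to 0")
  }
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  if (sqrt_dist) d <- sqrt(d)
  attr(d, "n_clipped") <- n_clipped
  d
}

#' PCA of a sample covariance matrix
#'
#' Eigendecomposition with variance fractions computed over the positive
#' eigenvalues: fraction_i = lambda_i / sum_j max(lambda_j, 0).
#'
#' @param cmat Symmetric covariance matrix.
#' @return List with `values` (eigenvalues, descending), `axes` (orthonormal
#'   eigenvectors in columns) and `var_fraction`.
#' @export
cov_pca <- function(cmat) {
  cmat <- as.matrix(cmat)
  if (max(abs(cmat - t(cmat))) > 1e-8 * max(1, max(abs(cmat)))) {
    stop("covariance matrix must be symmetric")
  }
  e <- eigen((cmat + t(cmat)) / 2, symmetric = TRUE)
  pos <- sum(pmax(e$values, 0))
  list(values = e$values, axes = e$vectors,
       var_fraction = if (pos > 0) e$values / pos else rep(NA_real_,
                                                           length(e$values)))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strictly-lower-triangle entries, with a
#' permutation p-value obtained by jointly permuting rows and columns of the
#' second matrix: p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1).
#'
#' @param d1,d2 Square symmetric matrices with matching dimension/order.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @return List with `r` (statistic) and `p` (one-sided p-value).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (any(dim(d2) != n) || ncol(d1) != n) stop("matrix orders must match")
  if (n_perm < 99) stop("n_perm must be >= 99")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (sd(v1) == 0 || sd(d2[lt]) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  r_obs <- cor(v1, d2[lt])
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_p <- cor(v1, d2[idx, idx][lt])
    if (r_p >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (n_perm + 1))
}
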