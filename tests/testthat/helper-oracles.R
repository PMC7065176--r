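# Independent oracles used across test files.  These deliberately take the
# slow, literal route so they stay independent of the package's vectorized
# implementations.

# Weir & Cockerham (1984) theta-hat, transcribed component by component from
# the published estimator for one biallelic locus.  `pop_dosages` is a list
# of dosage vectors (one per population, NAs allowed).  Returns c(a, b, c)
# or NULL when the locus is uninformative.
oracle_wc84_locus <- function(pop_dosages) {
  pop_dosages <- lapply(pop_dosages, function(v) v[!is.na(v)])
  pop_dosages <- pop_dosages[vapply(pop_dosages, length, 1L) >= 1]
  r <- length(pop_dosages)
  if (r < 2) return(NULL)
  n_i <- vapply(pop_dosages, length, numeric(1))
  p_i <- vapply(pop_dosages, function(v) sum(v) / (2 * length(v)), numeric(1))
  h_i <- vapply(pop_dosages, function(v) mean(v == 1), numeric(1))
  n_bar <- sum(n_i) / r
  if (n_bar <= 1) return(NULL)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  if (p_bar <= 0 || p_bar >= 1) return(NULL)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) * (s2 - (1 / (n_bar - 1)) *
                          (p_bar * (1 - p_bar) -
                             ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
                                  ((r - 1) / r) * s2 -
                                  ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# Multi-locus ratio-of-sums theta from a dosage matrix + labels.
oracle_wc84 <- function(geno, groups) {
  num <- 0
  den <- 0
  for (l in seq_len(ncol(geno))) {
    pops <- split(geno[, l], groups)
    comp <- oracle_wc84_locus(pops)
    if (is.null(comp)) next
    num <- num + comp[["a"]]
    den <- den + sum(comp)
  }
  num / den
}

# Sort-based quantile oracle (type-7 interpolation, written out long-hand).
oracle_quantile <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Inverse-distance-weighted spatial autocorrelation (Moran-like statistic).
oracle_moran <- function(values, dmat) {
  z <- values - mean(values)
  w <- 1 / (dmat + 1)
  diag(w) <- 0
  n <- length(z)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}

# M-spline densities corresponding to the 3-knot order-2 I-spline basis;
# used to check the basis by numerical integration.
oracle_mspline_density <- function(x, q, k) {
  if (k == 1) {
    ifelse(x >= q[1] & x <= q[2], 2 * (q[2] - x) / (q[2] - q[1])^2, 0)
  } else if (k == 2) {
    ifelse(x >= q[1] & x <= q[2],
           2 * (x - q[1]) / ((q[3] - q[1]) * (q[2] - q[1])),
           ifelse(x <= q[3], 2 * (q[3] - x) / ((q[3] - q[1]) * (q[3] - q[2])),
                  0))
  } else {
    ifelse(x >= q[2] & x <= q[3], 2 * (x - q[2]) / (q[3] - q[2])^2, 0)
  }
}

# GDM binomial deviance, written independently of the package internals.
oracle_gdm_deviance <- function(d, mu) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  s <- 0
  for (i in seq_along(d)) {
    t1 <- if (d[i] > 0) d[i] * log(d[i] / mu[i]) else 0
    t2 <- if (d[i] < 1) (1 - d[i]) * log((1 - d[i]) / (1 - mu[i])) else 0
    s <- s + t1 + t2
  }
  2 * s
}
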