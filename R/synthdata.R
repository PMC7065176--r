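#' Default environmental variable layout
#'
#' Six locality-level variables in the three categories used for landscape
#' models of woodland trees (Water, Energy, Soil): one spatially
#' autocorrelated variable per category plus one pure-noise decoy per
#' category. Spatial scales are exponential-covariance ranges in km.
#'
#' @return data.frame with columns `name`, `category`, `scale` (km; `NA`
#'   marks an i.i.d. noise decoy).
#' @export
default_env_variables <- function() {
  data.frame(
    name = c("precip_annual", "moisture_noise",
             "temp_mean", "solar_noise",
             "soil_phosphorus", "soil_noise"),
    category = rep(c("Water", "Energy", "Soil"), each = 2),
    scale = c(400, NA, 600, NA, 300, NA),
    stringsAsFactors = FALSE
  )
}

# Draw zero-mean Gaussian vectors with covariance `sigma` (jittered).
# Returns an n x k matrix of k independent draws.
.mvn_draws <- function(sigma, k, what = "covariance") {
  n <- nrow(sigma)
  ch <- tryCatch(chol(sigma + diag(1e-8, n)),
                 error = function(e) NULL)
  if (is.null(ch)) {
    stop("non-positive-definite ", what,
         " matrix (after 1e-8 jitter); check scale/magnitude parameters")
  }
  t(ch) %*% matrix(rnorm(n * k), n, k)
}

#' Simulate spatially structured environmental variables
#'
#' Spatial variables are draws from a zero-mean Gaussian field over the
#' localities with exponential covariance exp(-d/scale) in great-circle
#' distance; noise decoys are i.i.d. standard normal. Every variable is
#' standardized to mean 0, sample variance 1 across localities.
#'
#' @param n_localities Number of localities (>= 2, for standardization).
#' @param variables data.frame with columns `name`, `category`, `scale`
#'   (km, `NA` = noise), as in [default_env_variables()].
#' @param seed Integer seed.
#' @param coords Optional data.frame with `locality`, `lat`, `lon`; when
#'   omitted, localities are placed uniformly in the default box (see
#'   [simulate_landscape()]).
#' @return Long-format environment table: `locality`, `variable`, `category`,
#'   `value`, with the coordinates attached as `attr(, "coords")`.
#' @export
simulate_environment <- function(n_localities,
                                 variables = default_env_variables(),
                                 seed = 1, coords = NULL) {
  if (n_localities < 2) stop("need >= 2 localities")
  variables <- as.data.frame(variables)
  if (nrow(variables) < 1) stop("need at least one variable")
  if (anyDuplicated(variables$name)) {
    stop("duplicate variable names: ",
         paste(unique(variables$name[duplicated(variables$name)]),
               collapse = ", "))
  }
  if (any(!nzchar(variables$category))) stop("categories must be non-empty")
  set.seed(seed)
  if (is.null(coords)) {
    coords <- .default_locality_coords(n_localities)
  }
  stopifnot(nrow(coords) == n_localities)
  dgeo <- geo_distance_matrix(coords$lat, coords$lon)
  out <- vector("list", nrow(variables))
  for (v in seq_len(nrow(variables))) {
    sc <- variables$scale[v]
    if (is.na(sc)) {
      val <- rnorm(n_localities)
    } else {
      val <- drop(.mvn_draws(exp(-dgeo / sc), 1, "environmental field"))
    }
    val <- (val - mean(val)) / sd(val)
    out[[v]] <- data.frame(locality = coords$locality,
                           variable = variables$name[v],
                           category = variables$category[v],
                           value = val, stringsAsFactors = FALSE)
  }
  env <- do.call(rbind, out)
  rownames(env) <- NULL
  attr(env, "coords") <- coords
  env
}

# Uniform locality placement in a north-south elongated box over
# south-eastern Australia (lon 146-153 E, lat 26-38 S), mimicking a
# latitudinal sampling gradient.
.default_locality_coords <- function(n_localities,
                                     lat_range = c(-38, -26),
                                     lon_range = c(146, 153)) {
  data.frame(
    locality = sprintf("L%02d", seq_len(n_localities)),
    lat = runif(n_localities, lat_range[1], lat_range[2]),
    lon = runif(n_localities, lon_range[1], lon_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate a landscape of spatially structured genotypes
#'
#' Localities are placed uniformly in a lat/lon box. Per-locus locality
#' allele frequencies are the ancestral frequency perturbed on the logit
#' scale by a zero-mean multivariate normal draw with covariance
#' `sigma2_geo * exp(-d_geo/phi_geo) + sigma2_env * exp(-d_env/phi_env)`,
#' where `d_geo` is great-circle distance (km) and `d_env` Euclidean
#' distance over the standardized causal environmental variables. Individual
#' dosages are binomial(2, locality frequency) draws. This directly
#' parameterizes the strength of isolation by distance (IBD) and by
#' environment (IBE) without coalescent machinery.
#'
#' @param n_localities Number of localities (>= 3); default 39 as in a
#'   typical latitudinal sampling design.
#' @param n_per_locality Diploids per locality: a single count, or a
#'   `c(min, max)` range sampled per locality (default `c(3, 15)`).
#' @param n_loci Number of biallelic loci.
#' @param ibd List `list(sigma2, phi)`: magnitude and geographic range (km)
#'   of the IBD covariance component.
#' @param ibe List `list(sigma2, phi, causal)`: magnitude, environmental
#'   range and causal variable names of the IBE component.
#' @param variables Environmental variable layout (see
#'   [default_env_variables()]).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `landscape_sim`: `genotypes`
#'   ([genotype_matrix()]), `localities` (sample, locality, lat, lon),
#'   `env` (long-format table) and `truth` (all generator parameters,
#'   locality frequencies and coordinates).
#' @export
simulate_landscape <- function(n_localities = 39,
                               n_per_locality = c(3, 15),
                               n_loci = 1000,
                               ibd = list(sigma2 = 1, phi = 500),
                               ibe = list(sigma2 = 0, phi = 1,
                                          causal = character(0)),
                               variables = default_env_variables(),
                               seed = 1) {
  if (n_localities < 3) stop("need >= 3 localities")
  if (n_loci < 1) stop("need at least one locus")
  stopifnot(ibd$sigma2 >= 0, ibe$sigma2 >= 0)
  causal <- ibe$causal %||% character(0)
  if (!all(causal %in% variables$name)) {
    stop("causal variable(s) not in environment layout: ",
         paste(setdiff(causal, variables$name), collapse = ", "))
  }
  env <- simulate_environment(n_localities, variables,
                              seed = derive_seed(seed, 11L))
  coords <- attr(env, "coords")
  set.seed(derive_seed(seed, 23L))

  dgeo <- geo_distance_matrix(coords$lat, coords$lon)
  sigma <- matrix(0, n_localities, n_localities)
  if (ibd$sigma2 > 0) {
    sigma <- sigma + ibd$sigma2 * exp(-dgeo / ibd$phi)
  }
  if (ibe$sigma2 > 0 && length(causal) > 0) {
    emat <- .env_wide(env)[, causal, drop = FALSE]
    denv <- as.matrix(stats::dist(emat))
    sigma <- sigma + ibe$sigma2 * exp(-denv / ibe$phi)
  }

  p0 <- runif(n_loci, 0.1, 0.9)
  if (all(sigma == 0)) {
    freqs <- matrix(p0, n_localities, n_loci, byrow = TRUE)
  } else {
    z <- .mvn_draws(sigma, n_loci, "locality")
    freqs <- plogis(sweep(z, 2, qlogis(p0), "+"))
  }

  if (length(n_per_locality) == 2) {
    npl <- sample(seq(n_per_locality[1], n_per_locality[2]),
                  n_localities, replace = TRUE)
  } else {
    npl <- rep(n_per_locality[1], n_localities)
  }
  n_total <- sum(npl)
  loc_of <- rep(seq_len(n_localities), npl)
  geno <- matrix(rbinom(n_total * n_loci, 2,
                        rep(freqs[loc_of, ], 1)),
                 n_total, n_loci)
  sample_ids <- sprintf("%s_s%02d", coords$locality[loc_of],
                        unlist(lapply(npl, seq_len)))
  rownames(geno) <- sample_ids
  gm <- genotype_matrix(geno, chrom = rep("chr1", n_loci),
                        pos = seq_len(n_loci) * 10000L)
  localities <- data.frame(sample = sample_ids,
                           locality = coords$locality[loc_of],
                           lat = coords$lat[loc_of],
                           lon = coords$lon[loc_of],
                           stringsAsFactors = FALSE)
  truth <- list(coords = coords, ancestral_freq = p0,
                locality_freq = freqs,
                sigma2_geo = ibd$sigma2, phi_geo = ibd$phi,
                sigma2_env = ibe$sigma2, phi_env = ibe$phi,
                causal = causal, seed = seed)
  env2 <- env
  attr(env2, "coords") <- NULL
  structure(list(genotypes = gm, localities = localities, env = env2,
                 truth = truth),
            class = "landscape_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Long environment table -> locality x variable matrix.
.env_wide <- function(env) {
  vars <- unique(env$variable)
  locs <- unique(env$locality)
  m <- matrix(NA_real_, length(locs), length(vars),
              dimnames = list(locs, vars))
  m[cbind(match(env$locality, locs), match(env$variable, vars))] <- env$value
  m
}

#' Parameters of the founder-mosaic linked-genotype simulator
#'
#' @param n_founders Number of founder haplotypes (>= 2).
#' @param switch_prob Per-base probability of switching founder (in (0, 1)).
#' @param snp_density SNPs per bp.
#' @param chrom_length Chromosome length in bp.
#' @param n_diploids Number of diploid samples (>= 2).
#' @param seed Integer seed.
#' @return List of class `ld_sim_truth`.
#' @export
ld_sim_truth <- function(n_founders = 20, switch_prob = 1e-3,
                         snp_density = 5e-3, chrom_length = 30000,
                         n_diploids = 25, seed = 1) {
  stopifnot(n_founders >= 2, n_diploids >= 2,
            switch_prob > 0, switch_prob < 1,
            snp_density > 0, chrom_length >= 2)
  structure(list(n_founders = n_founders, switch_prob = switch_prob,
                 snp_density = snp_density, chrom_length = chrom_length,
                 n_diploids = n_diploids, seed = seed),
            class = "ld_sim_truth")
}

#' Simulate linked genotypes under a founder-mosaic model
#'
#' Founder haplotypes carry independent alleles at each SNP; each sampled
#' haplotype is a mosaic of founders with a per-base switch probability, and
#' diploids pair two haplotypes. Lower switch probability yields longer
#' stretches copied from a single founder and hence longer-range linkage
#' disequilibrium.
#'
#' @param truth An [ld_sim_truth()] object.
#' @return List with `genotypes` (a [genotype_matrix()] with bp positions on
#'   one chromosome) and `truth`.
#' @export
simulate_linked_genotypes <- function(truth) {
  stopifnot(inherits(truth, "ld_sim_truth"))
  set.seed(truth$seed)
  n_snps <- round(truth$snp_density * truth$chrom_length)
  if (n_snps < 2) {
    stop("snp_density * chrom_length yields < 2 SNPs")
  }
  pos <- sort(sample.int(truth$chrom_length, n_snps))
  pfound <- runif(n_snps, 0.1, 0.9)
  founders <- matrix(rbinom(truth$n_founders * n_snps, 1,
                            rep(pfound, each = truth$n_founders)),
                     truth$n_founders, n_snps)
  gaps <- diff(pos)
  p_switch <- 1 - (1 - truth$switch_prob)^gaps
  n_hap <- 2L * truth$n_diploids
  haps <- matrix(0L, n_hap, n_snps)
  for (h in seq_len(n_hap)) {
    sw <- runif(n_snps - 1) < p_switch
    seg <- cumsum(c(1L, sw))
    fid <- sample.int(truth$n_founders, max(seg), replace = TRUE)[seg]
    haps[h, ] <- founders[cbind(fid, seq_len(n_snps))]
  }
  geno <- haps[seq(1, n_hap, 2), , drop = FALSE] +
    haps[seq(2, n_hap, 2), , drop = FALSE]
  rownames(geno) <- sprintf("D%03d", seq_len(truth$n_diploids))
  gm <- genotype_matrix(geno, chrom = rep("chr1", n_snps), pos = pos)
  list(genotypes = gm, truth = truth)
}

#' Synthetic (distance, r-squared) pairs from the Hill-Weir expectation
#'
#' Evaluates the Hill-Weir expected r-squared at C = rho * distance for
#' chromosome count n, adds Gaussian noise and truncates to \[0, 1\].
#' With `noise_sd = 0` the curve values are exact, giving a round-trip
#' oracle for [fit_hill_weir()].
#'
#' @param rho Per-bp recombination-scale rate (> 0).
#' @param n Chromosome count (>= 4).
#' @param distances Positive bp distances.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Optional seed (used only when `noise_sd > 0`).
#' @return data.frame with columns `dist` and `r2`.
#' @export
hill_weir_synthetic_pairs <- function(rho, n, distances, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(rho > 0, n >= 4, all(distances > 0))
  r2 <- hill_weir_expectation(rho * distances, n)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    r2 <- pmin(pmax(r2 + rnorm(length(r2), 0, noise_sd), 0), 1)
  }
  data.frame(dist = distances, r2 = r2)
}
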