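#' Run configuration for the pipeline
#'
#' A validated configuration list. Inputs are either file paths (`vcf`,
#' `locality_csv`, `env_csv`) or simulation parameters (`sim`, a list of
#' arguments for [simulate_landscape()]). Every stochastic stage derives
#' its stream from `seed`.
#'
#' @param vcf,locality_csv,env_csv Input file paths (all three, or none).
#' @param sim Optional list of [simulate_landscape()] arguments (used when
#'   file inputs are absent).
#' @param min_maf,max_missing Genotype filters for VCF input.
#' @param min_geo_km Site-pair distance filter (default 10 km).
#' @param threshold_pct Forward-selection gain threshold (default 1).
#' @param n_perm Permutation replicates (default 100).
#' @param jackknife_reps,cv_reps Replicate counts (defaults 100 and 20).
#' @param total_sites Denominator for nucleotide diversity (default: number
#'   of variant loci).
#' @param seed Master seed (default 1).
#' @return List of class `run_config`.
#' @export
run_config <- function(vcf = NULL, locality_csv = NULL, env_csv = NULL,
                       sim = NULL, min_maf = 0, max_missing = 1,
                       min_geo_km = 10, threshold_pct = 1, n_perm = 100,
                       jackknife_reps = 100, cv_reps = 20,
                       total_sites = NULL, seed = 1) {
  files <- c(!is.null(vcf), !is.null(locality_csv))
  if (any(files) && !all(files)) {
    stop("vcf and locality_csv must be given together")
  }
  if (!any(files) && is.null(sim)) sim <- list()
  structure(list(vcf = vcf, locality_csv = locality_csv, env_csv = env_csv,
                 sim = sim, min_maf = min_maf, max_missing = max_missing,
                 min_geo_km = min_geo_km, threshold_pct = threshold_pct,
                 n_perm = n_perm, jackknife_reps = jackknife_reps,
                 cv_reps = cv_reps, total_sites = total_sites,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose fields mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

# Load or simulate the (genotypes, localities, env) bundle.
.load_inputs <- function(config) {
  if (!is.null(config$vcf)) {
    geno <- read_vcf(config$vcf, config$min_maf, config$max_missing)
    localities <- read_locality_csv(config$locality_csv)
    env <- if (!is.null(config$env_csv)) read_env_csv(config$env_csv) else
      NULL
  } else {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- do.call(simulate_landscape, sim_args)
    geno <- sim$genotypes
    localities <- sim$localities
    env <- sim$env
  }
  validate_join(geno, localities, env)
}

# Genetic distances via GRM + Gower, pair table via the distance filter.
.pairs_from_bundle <- function(bundle, config) {
  cmat <- genotype_covariance(bundle$genotypes)
  gdist <- gower_distance(cmat)
  build_pair_table(gdist, bundle$localities, bundle$env,
                   min_geo_km = config$min_geo_km)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Serialize stage outputs and a manifest echoing the config.
.write_report <- function(report, config, out_dir, files) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(files)) {
    .write_tsv(files[[nm]], file.path(out_dir, nm))
  }
  manifest <- list(config = unclass(config),
                   outputs = names(files),
                   counts = report$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' Geography-only (isolation by distance) GDM analysis
#'
#' Composes genotype loading/simulation, the GRM and Gower genetic
#' distances, the site-pair table, the geography-only GDM fit and the
#' locality jackknife of the geographic spline.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for TSV/JSON artifacts and a
#'   `manifest.json`.
#' @return List of class `ibd_report`: `model`, `deviance_explained`,
#'   `jackknife` (spline envelope), `counts` (pairs retained/filtered),
#'   `spline` (geographic spline curve).
#' @export
run_ibd_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  bundle <- .load_inputs(config)
  pairs <- .pairs_from_bundle(bundle, config)
  model <- fit_gdm(pairs)
  jk <- jackknife_splines(pairs, character(0),
                          n_reps = config$jackknife_reps,
                          seed = derive_seed(config$seed, 101L))
  n_all <- choose(length(bundle$genotypes$samples), 2)
  report <- list(model = model,
                 deviance_explained = deviance_explained(model),
                 jackknife = jk,
                 spline = gdm_spline_curve(model, "geo"),
                 counts = list(n_samples = length(bundle$genotypes$samples),
                               n_loci = ncol(bundle$genotypes$geno),
                               n_pairs = nrow(pairs),
                               n_pairs_filtered = n_all - nrow(pairs),
                               jackknife_skipped = jk$n_skipped))
  class(report) <- "ibd_report"
  if (!is.null(out_dir)) {
    .write_report(report, config, out_dir,
                  list("geo_spline.tsv" = report$spline,
                       "pairs.tsv" = as.data.frame(pairs)))
  }
  report
}

#' Full isolation-by-distance-and-environment GDM analysis
#'
#' Extends [run_ibd_analysis()] with category-wise forward selection,
#' backward selection, locality cross-validation and the locality-wise
#' permutation significance test, reporting the deviance-explained gain of
#' environment over geography alone.
#'
#' @inheritParams run_ibd_analysis
#' @return List of class `ibe_report`: `model` (final GDM),
#'   `geo_deviance_explained`, `deviance_explained`, `de_gain`,
#'   `forward` and `backward` selection traces, `selected` (final
#'   variables), `cv` (cross-validation result), `significance_p`,
#'   `jackknife`, `counts`.
#' @export
run_ibe_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  bundle <- .load_inputs(config)
  if (is.null(bundle$env)) stop("environment table required for IBE analysis")
  pairs <- .pairs_from_bundle(bundle, config)
  geo_model <- fit_gdm(pairs)
  fwd <- forward_select(pairs, threshold_pct = config$threshold_pct)
  selected <- fwd$selected
  bwd <- NULL
  if (length(selected) > 1) {
    bwd <- backward_select(pairs, selected,
                           seed = derive_seed(config$seed, 103L))
    selected <- bwd$final
  }
  model <- fit_gdm(pairs, selected)
  cv <- cross_validate(pairs, selected, n_reps = config$cv_reps,
                       seed = derive_seed(config$seed, 107L))
  sig <- if (length(selected)) {
    model_significance(pairs, selected, n_perm = config$n_perm,
                       seed = derive_seed(config$seed, 109L))
  } else NULL
  jk <- jackknife_splines(pairs, selected, n_reps = config$jackknife_reps,
                          seed = derive_seed(config$seed, 113L))
  report <- list(model = model,
                 geo_deviance_explained = deviance_explained(geo_model),
                 deviance_explained = deviance_explained(model),
                 de_gain = deviance_explained(model) -
                   deviance_explained(geo_model),
                 forward = fwd, backward = bwd, selected = selected,
                 cv = cv,
                 significance_p = if (!is.null(sig)) sig$p else NA_real_,
                 jackknife = jk,
                 counts = list(n_pairs = nrow(pairs),
                               n_candidates = length(fwd$selected),
                               n_selected = length(selected),
                               jackknife_skipped = jk$n_skipped))
  class(report) <- "ibe_report"
  if (!is.null(out_dir)) {
    files <- list("forward_trace.tsv" = fwd$trace,
                  "pairs.tsv" = as.data.frame(pairs))
    if (!is.null(bwd)) files[["backward_trace.tsv"]] <- bwd$trace
    .write_report(report, config, out_dir, files)
    model_json <- list(intercept = model$intercept,
                       coefficients = as.list(model$coefficients),
                       knots = lapply(model$bases, `[[`, "knots"),
                       gd_scale = model$gd_scale,
                       deviance = model$deviance,
                       null_deviance = model$null_deviance,
                       deviance_explained = model$deviance_explained)
    jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Per-locality diversity report
#'
#' Expected heterozygosity and nucleotide diversity per locality plus a
#' global between-locality Weir-Cockerham F_ST. Localities with fewer than
#' 2 samples are flagged (`flag = "lt2_samples"`, H_e = NA), not dropped.
#'
#' @inheritParams run_ibd_analysis
#' @return List of class `diversity_report`: `table` (locality, n, he, pi,
#'   flag), `global_fst`, `counts`.
#' @export
run_diversity_report <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  bundle <- .load_inputs(config)
  geno <- bundle$genotypes
  loc <- bundle$localities
  total_sites <- config$total_sites %||% ncol(geno$geno)
  locs <- unique(loc$locality)
  rows <- lapply(locs, function(lc) {
    ids <- loc$sample[loc$locality == lc]
    sub <- subset_genotypes(geno, samples = ids)
    n <- length(ids)
    he <- if (n >= 2) expected_heterozygosity(sub) else NA_real_
    pi <- if (n >= 1) nucleotide_diversity(sub, total_sites) else NA_real_
    data.frame(locality = lc, n = n, he = he, pi = pi,
               flag = if (n < 2) "lt2_samples" else "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  groups <- loc$locality[match(geno$samples, loc$sample)]
  ok_groups <- names(which(table(groups) >= 2))
  fst <- if (length(ok_groups) >= 2) {
    keep <- groups %in% ok_groups
    wc_fst(subset_genotypes(geno, samples = which(keep)), groups[keep])
  } else NA_real_
  report <- list(table = tab, global_fst = fst,
                 counts = list(n_localities = length(locs),
                               n_flagged = sum(tab$flag != "")))
  class(report) <- "diversity_report"
  if (!is.null(out_dir)) {
    .write_report(report, config, out_dir, list("diversity.tsv" = tab))
  }
  report
}
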