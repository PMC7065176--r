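# Shared fixtures, all generated in code.

# Small landscape with moderate IBD and one causal Water variable.
fixture_landscape <- function(seed = 42, sigma2_env = 0.8,
                              n_localities = 15, n_loci = 400) {
  simulate_landscape(
    n_localities = n_localities, n_per_locality = 4, n_loci = n_loci,
    ibd = list(sigma2 = 1.5, phi = 500),
    ibe = list(sigma2 = sigma2_env, phi = 1, causal = "precip_annual"),
    seed = seed)
}

fixture_pairs <- function(sim) {
  gd <- gower_distance(genotype_covariance(sim$genotypes))
  build_pair_table(gd, sim$localities, sim$env)
}

# Hand-written toy VCF exercising the filter rules: one biallelic SNP,
# one triallelic record, one indel.
fixture_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sampleA", "sampleB"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tC\tT,G\t50\tPASS\t.\tGT\t0/1\t0/2",
    "chr1\t300\t.\tAT\tA\t50\tPASS\t.\tGT\t0/0\t0/1"
  ), path)
  path
}
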