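#' Read a VCF into a genotype dosage matrix
#'
#' Supports the plain-text VCF 4.2 dialect this pipeline writes and
#' consumes: the GT field is parsed to alternate-allele dosage regardless of
#' phasing separator; multi-allelic records and non-SNP records (indels,
#' block substitutions, symbolic alleles) are skipped; half-calls (e.g.
#' `./1`) are treated as missing. Loci failing the minor-allele-frequency or
#' missingness filters, or with no genotyped sample, are dropped.
#'
#' @param path Path to an uncompressed VCF file.
#' @param min_maf Minimum minor allele frequency to retain a locus
#'   (default 0: keep monomorphic loci).
#' @param max_missing Maximum fraction of missing genotypes per locus
#'   (default 1).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, min_maf = 0, max_missing = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("not a valid VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("VCF contains no records")
  recs <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(recs)
  if (any(nfield != length(cols))) {
    stop("malformed VCF record at data line ", which(nfield != length(cols))[1])
  }
  rec <- do.call(rbind, recs)
  fmt <- strsplit(rec[, 9], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) {
    bad <- which(is.na(gt_idx))[1]
    stop("record ", rec[bad, 1], ":", rec[bad, 2], " has no GT in FORMAT")
  }
  bases <- c("A", "C", "G", "T")
  snp <- rec[, 4] %in% bases & rec[, 5] %in% bases
  rec <- rec[snp, , drop = FALSE]
  gt_idx <- gt_idx[snp]
  if (nrow(rec) == 0) stop("no biallelic SNP records in VCF")
  gmat <- matrix(NA_integer_, length(samples), nrow(rec))
  for (l in seq_len(nrow(rec))) {
    calls <- rec[l, -(1:9)]
    gt <- vapply(strsplit(calls, ":", fixed = TRUE), `[`, character(1),
                 gt_idx[l])
    gmat[, l] <- .gt_to_dosage(gt)
  }
  pos <- as.integer(rec[, 2])
  keep <- .locus_filter(gmat, min_maf, max_missing)
  if (!any(keep)) stop("no loci pass the MAF/missingness filters")
  rownames(gmat) <- samples
  genotype_matrix(gmat[, keep, drop = FALSE],
                  chrom = rec[keep, 1], pos = pos[keep],
                  ref = rec[keep, 4], alt = rec[keep, 5])
}

# "0/1", "1|0" -> 1; "./.", ".", "./1" -> NA.
.gt_to_dosage <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
}

.locus_filter <- function(gmat, min_maf, max_missing) {
  miss <- colMeans(is.na(gmat))
  p <- colMeans(gmat, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  miss < 1 & miss <= max_missing & !is.na(maf) & maf >= min_maf
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits an uncompressed GT-only VCF with one contig header line per
#' chromosome, unphased `/` separators and `./.` for missing dosages.
#'
#' @param x A non-empty [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (ncol(x$geno) == 0 || nrow(x$geno) == 0) {
    stop("cannot write an empty genotype matrix")
  }
  loci <- x$loci
  chroms <- unique(loci$chrom)
  contig <- vapply(chroms, function(ch) {
    sprintf("##contig=<ID=%s,length=%d>", ch,
            max(loci$pos[loci$chrom == ch]) + 1L)
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=landgdm",
              contig,
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$samples), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(loci)), function(l) {
    g <- x$geno[, l]
    calls <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(loci$chrom[l], loci$pos[l], ".", loci$ref[l], loci$alt[l],
            ".", ".", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the locality table
#'
#' CSV with columns `sample`, `locality`, `lat`, `lon` (decimal degrees).
#'
#' @param path CSV path.
#' @return data.frame locality table.
#' @export
read_locality_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "locality", "lat", "lon")
  if (!all(need %in% names(tab))) {
    stop("locality CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(abs(tab$lat) > 90) || any(abs(tab$lon) > 180)) {
    stop("coordinates out of range")
  }
  tab[need]
}

#' @rdname read_locality_csv
#' @param tab Locality table.
#' @export
write_locality_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the long-format environment table
#'
#' CSV with columns `locality`, `variable`, `category`, `value`
#' (standardized).
#'
#' @param path CSV path.
#' @return data.frame environment table.
#' @export
read_env_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("locality", "variable", "category", "value")
  if (!all(need %in% names(tab))) {
    stop("environment CSV must have columns: ", paste(need, collapse = ", "))
  }
  tab[need]
}

#' @rdname read_env_csv
#' @param tab Environment table.
#' @export
write_env_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate cross-references between genotype, locality and environment data
#'
#' Checks that every genotype sample maps to exactly one locality row and
#' that every referenced locality has a complete set of environment values
#' (full locality-by-variable grid). All violations are collected and
#' reported in a single error.
#'
#' @param geno A [genotype_matrix()].
#' @param localities Locality table (`sample`, `locality`, `lat`, `lon`).
#' @param env Optional environment table (`locality`, `variable`,
#'   `category`, `value`).
#' @return Invisibly, a validated bundle `list(genotypes, localities, env)`.
#' @export
validate_join <- function(geno, localities, env = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  problems <- character(0)
  dup <- localities$sample[duplicated(localities$sample)]
  if (length(dup)) {
    problems <- c(problems, paste0("duplicated sample(s) in locality table: ",
                                   paste(unique(dup), collapse = ", ")))
  }
  orphan <- setdiff(geno$samples, localities$sample)
  if (length(orphan)) {
    problems <- c(problems, paste0("sample(s) without locality: ",
                                   paste(orphan, collapse = ", ")))
  }
  if (any(abs(localities$lat) > 90) || any(abs(localities$lon) > 180)) {
    problems <- c(problems, "locality coordinates out of range")
  }
  if (!is.null(env)) {
    locs <- unique(localities$locality[localities$sample %in% geno$samples])
    vars <- unique(env$variable)
    for (lc in locs) {
      have <- env$variable[env$locality == lc]
      missing_vars <- setdiff(vars, have)
      if (length(missing_vars)) {
        problems <- c(problems,
                      paste0("locality ", lc, " missing environment value(s): ",
                             paste(missing_vars, collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("join validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(list(genotypes = geno, localities = localities, env = env))
}
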