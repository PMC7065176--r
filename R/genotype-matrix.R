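#' Diploid genotype dosage matrix
#'
#' The central genotype container: a samples-by-loci matrix of biallelic
#' diploid dosages (count of the alternate allele, 0/1/2, `NA` for missing)
#' together with per-locus genomic coordinates. Loci are stored sorted by
#' (chromosome, position).
#'
#' @param geno Integer (or numeric) matrix, samples in rows, loci in columns.
#'   Row names are taken as sample identifiers. Entries must be 0, 1, 2 or
#'   `NA`.
#' @param chrom Character vector of chromosome names, one per locus.
#' @param pos Integer vector of 1-based positions, one per locus.
#' @param ref,alt Optional single-base reference/alternate alleles per locus;
#'   default `"A"`/`"T"` placeholders for simulated data.
#' @return An object of class `genotype_matrix`: a list with elements `geno`
#'   (integer matrix), `loci` (data.frame `chrom`, `pos`, `ref`, `alt`) and
#'   `samples` (character).
#' @export
genotype_matrix <- function(geno, chrom, pos, ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%03d", seq_len(nrow(geno)))
  }
  if (anyDuplicated(rownames(geno))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(geno)[duplicated(rownames(geno))]),
               collapse = ", "))
  }
  L <- ncol(geno)
  if (length(chrom) != L || length(pos) != L) {
    stop("chrom/pos length must equal number of loci (", L, ")")
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("T", L)
  loci <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                     ref = as.character(ref), alt = as.character(alt),
                     stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(loci) <- NULL
  if (nrow(loci) > 0) colnames(geno) <- paste0(loci$chrom, ":", loci$pos)
  structure(list(geno = geno, loci = loci, samples = rownames(geno)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%s missing)\n",
              nrow(x$geno), ncol(x$geno),
              sprintf("%.1f%%", 100 * mean(is.na(x$geno)))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x A [genotype_matrix()].
#' @param samples Sample ids or indices (default all).
#' @param loci Locus indices or logical vector (default all).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, samples = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$geno
  if (!is.null(samples)) g <- g[samples, , drop = FALSE]
  l <- x$loci
  if (!is.null(loci)) {
    g <- g[, loci, drop = FALSE]
    l <- l[loci, , drop = FALSE]
  }
  genotype_matrix(g, l$chrom, l$pos, l$ref, l$alt)
}

n_samples <- function(x) nrow(x$geno)
n_loci <- function(x) ncol(x$geno)
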