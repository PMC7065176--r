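#' Sliding genomic windows
#'
#' Overlapping windows of `window_bp` advancing by `window_bp - overlap_bp`.
#' Windows are 0-based half-open. The first window starts at 0; window
#' generation stops with the first window reaching the chromosome end, whose
#' end is truncated there, so every position is covered exactly as a sliding
#' scan would.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_bp Window length (default 30000).
#' @param overlap_bp Overlap between adjacent windows (default 10000).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, window_bp = 30000,
                         overlap_bp = 10000) {
  if (overlap_bp >= window_bp || overlap_bp < 0) {
    stop("require 0 <= overlap_bp < window_bp")
  }
  step <- window_bp - overlap_bp
  out <- lapply(seq_along(chrom_lengths), function(i) {
    len <- chrom_lengths[[i]]
    nm <- names(chrom_lengths)[i] %||% as.character(i)
    n_win <- max(1, ceiling((len - window_bp) / step) + 1)
    starts <- (seq_len(n_win) - 1) * step
    data.frame(chrom = nm, start = starts,
               end = pmin(starts + window_bp, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise composite r-squared within a set of SNPs
#'
#' Squared Pearson correlation of genotype-dosage vectors over
#' pairwise-complete samples (composite LD, appropriate for unphased data).
#' Pairs with fewer than `min_n` complete samples or zero variance at either
#' locus are skipped.
#'
#' @param x A [genotype_matrix()] (typically already windowed).
#' @param window Optional `list(chrom=, start=, end=)` (0-based half-open) to
#'   restrict loci.
#' @param min_n Minimum pairwise-complete samples (default 4).
#' @return data.frame with columns `dist` (bp) and `r2`; may have zero rows.
#' @export
pairwise_r2 <- function(x, window = NULL, min_n = 4) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$geno
  pos <- x$loci$pos
  if (!is.null(window)) {
    keep <- x$loci$chrom == window$chrom &
      pos - 1 >= window$start & pos - 1 < window$end
    g <- g[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  L <- ncol(g)
  if (L < 2) return(data.frame(dist = numeric(0), r2 = numeric(0)))
  suppressWarnings(cm <- cor(g, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(g))
  ut <- upper.tri(cm)
  r2 <- cm[ut]^2
  dist <- abs(outer(pos, pos, "-"))[ut]
  ok <- !is.na(r2) & nmat[ut] >= min_n
  data.frame(dist = dist[ok], r2 = r2[ok])
}

#' Hill-Weir expectation for r-squared under drift-recombination balance
#'
#' E\[r^2\] for population-scaled recombination parameter C and chromosome
#' sample size n:
#' ((10+C) / ((2+C)(11+C))) * (1 + ((3+C)(12+12C+C^2)) / (n (2+C)(11+C))).
#' At C = 0 this is (10/22)(1 + 36/(22 n)); as C grows it decays towards the
#' sampling floor 1/n.
#'
#' @param C Non-negative scaled recombination distance(s).
#' @param n Chromosome count (>= 2).
#' @return Expected r-squared value(s).
#' @export
hill_weir_expectation <- function(C, n) {
  stopifnot(all(C >= 0), n >= 2)
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir decay curve to (distance, r-squared) pairs
#'
#' Least-squares fit of the single rate parameter rho in
#' E\[r^2\](rho * dist, n). Positivity is enforced by optimizing log(rho),
#' with multi-start from rho in \{1e-5, 1e-3, 1e-1\} per bp and objective
#' tolerance 1e-10.
#'
#' @param pairs data.frame with `dist` and `r2` columns (from
#'   [pairwise_r2()] or [hill_weir_synthetic_pairs()]).
#' @param n Chromosome count used in the expectation.
#' @param min_pairs Minimum number of pairs required (default 50).
#' @return List of class `ld_fit`: `rho`, `n`, `n_pairs`, `objective`
#'   (residual sum of squares), `converged`.
#' @export
fit_hill_weir <- function(pairs, n, min_pairs = 50) {
  if (nrow(pairs) < min_pairs) {
    stop("need >= ", min_pairs, " pairs (got ", nrow(pairs), ")")
  }
  if (length(unique(pairs$dist)) < 2) {
    stop("pairs must span >= 2 distinct distances")
  }
  d <- pairs$dist
  r2 <- pairs$r2
  obj <- function(lr) {
    sum((r2 - hill_weir_expectation(exp(lr) * d, n))^2)
  }
  best <- NULL
  for (start in log(c(1e-5, 1e-3, 1e-1))) {
    fit <- tryCatch(
      nlminb(start, obj, control = list(rel.tol = 1e-12, abs.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(rho = NA_real_, n = n, n_pairs = nrow(pairs),
                          objective = NA_real_, converged = FALSE),
                     class = "ld_fit"))
  }
  # nlminb occasionally reports "false convergence" on flat objectives even
  # at the optimum; accept any finite minimizer from the multi-start.
  structure(list(rho = exp(best$par), n = n, n_pairs = nrow(pairs),
                 objective = best$objective,
                 converged = is.finite(best$objective) &&
                   is.finite(best$par)),
            class = "ld_fit")
}

#' Distance at which the fitted decay curve halves
#'
#' Smallest d with E\[r^2\](rho*d, n) = E\[r^2\](0, n) / 2, solved by
#' bracketing and bisection to within 0.5 bp. Undefined (NA) when the
#' asymptote 1/n exceeds half the zero-distance value, i.e. the curve never
#' halves.
#'
#' @param fit An `ld_fit` from [fit_hill_weir()].
#' @return Half-decay distance in bp, or `NA_real_` when undefined.
#' @export
half_decay_distance <- function(fit) {
  stopifnot(inherits(fit, "ld_fit"))
  if (!isTRUE(fit$converged) || is.na(fit$rho)) return(NA_real_)
  n <- fit$n
  target <- hill_weir_expectation(0, n) / 2
  if (1 / n >= target) return(NA_real_)
  f <- function(d) hill_weir_expectation(fit$rho * d, n) - target
  upper <- 1 / fit$rho
  while (f(upper) > 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = 0.25)$root
}

#' Summarize half-decay distances across windows
#'
#' @param fits List of `ld_fit` objects.
#' @return List with `median`, `iqr` (25/75% quantiles), `n_windows`,
#'   `n_failed` (non-converged fits) and `n_undefined` (converged but the
#'   curve never halves).
#' @export
summarize_ld <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  hd <- vapply(fits[conv], half_decay_distance, numeric(1))
  def <- !is.na(hd)
  if (!any(def)) stop("no windows with a defined half-decay distance")
  vals <- hd[def]
  list(median = median(vals),
       iqr = unname(quantile(vals, c(0.25, 0.75))),
       n_windows = length(fits),
       n_failed = sum(!conv),
       n_undefined = sum(!def))
}

#' Windowed LD-decay scan over a genotype matrix
#'
#' Composes [make_windows()], [pairwise_r2()] and [fit_hill_weir()] across
#' the genome: per window, pairwise r-squared is computed, the Hill-Weir
#' curve fitted and the half-decay distance extracted.
#'
#' @param x A [genotype_matrix()].
#' @param window_bp,overlap_bp Window geometry (defaults 30 kbp / 10 kbp).
#' @param min_pairs Windows with fewer SNP pairs are skipped (default 50).
#' @param n Chromosome count for the expectation; default `NULL` uses
#'   2 x (diploids with any data in the window).
#' @return data.frame, one row per window: `chrom`, `start`, `end`,
#'   `n_pairs`, `rho_hat`, `n`, `half_decay_bp`, `status` in
#'   \{"ok", "undefined", "failed", "skipped"\}; the list of fits is attached
#'   as `attr(, "fits")`.
#' @export
ld_decay_scan <- function(x, window_bp = 30000, overlap_bp = 10000,
                          min_pairs = 50, n = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  lens <- tapply(x$loci$pos, x$loci$chrom, max)
  wins <- make_windows(setNames(as.numeric(lens), names(lens)),
                       window_bp, overlap_bp)
  rows <- vector("list", nrow(wins))
  fits <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    win <- list(chrom = wins$chrom[w], start = wins$start[w],
                end = wins$end[w])
    inwin <- x$loci$chrom == win$chrom &
      x$loci$pos - 1 >= win$start & x$loci$pos - 1 < win$end
    pr <- pairwise_r2(x, window = win)
    row <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                      n_pairs = nrow(pr), rho_hat = NA_real_, n = NA_real_,
                      half_decay_bp = NA_real_, status = "skipped",
                      stringsAsFactors = FALSE)
    if (nrow(pr) >= min_pairs && length(unique(pr$dist)) >= 2) {
      nw <- if (is.null(n)) {
        2 * sum(rowSums(!is.na(x$geno[, inwin, drop = FALSE])) > 0)
      } else n
      fit <- fit_hill_weir(pr, n = nw, min_pairs = min_pairs)
      fits[[w]] <- fit
      if (isTRUE(fit$converged)) {
        hd <- half_decay_distance(fit)
        row$rho_hat <- fit$rho
        row$n <- nw
        row$half_decay_bp <- hd
        row$status <- if (is.na(hd)) "undefined" else "ok"
      } else {
        row$status <- "failed"
      }
    }
    rows[[w]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits[!vapply(fits, is.null, logical(1))]
  out
}
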