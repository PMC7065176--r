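#' Monotone I-spline basis for a GDM predictor
#'
#' Order-2 I-splines (integrated tent-function M-splines) on three knots
#' placed at the 0th, 50th and 100th percentiles of the supplied values.
#' Each basis function maps \[min, max\] into \[0, 1\], is 0 at the minimum,
#' 1 at the maximum and monotone non-decreasing, so any non-negative
#' combination is monotone.
#'
#' @param values Numeric values the predictor takes over site pairs.
#' @param name Predictor name.
#' @param n_knots Number of knots (currently 3).
#' @return List of class `ispline_basis` with `name` and `knots`.
#' @export
ispline_basis <- function(values, name = "x", n_knots = 3) {
  if (n_knots != 3) stop("only 3-knot bases are implemented")
  values <- values[is.finite(values)]
  q <- unname(quantile(values, c(0, 0.5, 1)))
  if (q[1] >= q[3]) {
    stop("degenerate predictor '", name, "': min equals max")
  }
  # A tied median collapses two knots; nudge it to the midrange so the
  # basis stays well defined.
  if (q[2] <= q[1] || q[2] >= q[3]) q[2] <- (q[1] + q[3]) / 2
  structure(list(name = name, knots = q, order = 2L),
            class = "ispline_basis")
}

#' Evaluate an I-spline basis
#'
#' Values outside the knot range are clamped to it before evaluation.
#'
#' @param basis An [ispline_basis()].
#' @param x Numeric vector.
#' @return Matrix with `length(x)` rows and one column per basis function
#'   (3), each in \[0, 1\].
#' @export
ispline_evaluate <- function(basis, x) {
  stopifnot(inherits(basis, "ispline_basis"))
  q <- basis$knots
  x <- pmin(pmax(x, q[1]), q[3])
  b1 <- ifelse(x <= q[1], 0,
               ifelse(x <= q[2], 1 - (q[2] - x)^2 / (q[2] - q[1])^2, 1))
  b2 <- ifelse(x <= q[1], 0,
               ifelse(x <= q[2], (x - q[1])^2 / ((q[3] - q[1]) * (q[2] - q[1])),
                      1 - (q[3] - x)^2 / ((q[3] - q[1]) * (q[3] - q[2]))))
  b3 <- ifelse(x <= q[2], 0, (x - q[2])^2 / (q[3] - q[2])^2)
  m <- cbind(b1, b2, b3)
  colnames(m) <- paste0(basis$name, "_s", 1:3)
  m
}

#' Build a GDM site-pair table
#'
#' One row per unordered sample pair whose great-circle distance exceeds
#' `min_geo_km` (the interlocation filter). Raw genetic distances are scaled
#' into \[0, 1) by dividing by `max * (1 + 1e-6)`; the scaling factor is
#' stored as an attribute. Environmental predictor values are looked up at
#' each endpoint's locality.
#'
#' @param gdist Square symmetric genetic-distance matrix with sample ids as
#'   dimnames (e.g. from [gower_distance()]).
#' @param localities Locality table (`sample`, `locality`, `lat`, `lon`).
#' @param env Optional long-format environment table; all of its variables
#'   become available as predictors (columns `x1_<var>`, `x2_<var>`).
#' @param min_geo_km Minimum pair distance in km (default 10).
#' @return data.frame of class `site_pair_table` with columns `s1`, `s2`,
#'   `loc1`, `loc2`, `observed`, `geo_km`, `weight` and endpoint predictor
#'   columns; attributes `gd_scale` (divisor applied) and `env_meta`
#'   (variable/category table).
#' @export
build_pair_table <- function(gdist, localities, env = NULL,
                             min_geo_km = 10) {
  gdist <- as.matrix(gdist)
  ids <- rownames(gdist)
  if (is.null(ids)) stop("genetic distance matrix needs sample dimnames")
  validate_join(genotype_stub(ids), localities, env)
  loc <- localities[match(ids, localities$sample), ]
  n <- length(ids)
  pr <- which(upper.tri(gdist), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  geo <- geo_distance(loc$lat[i], loc$lon[i], loc$lat[j], loc$lon[j])
  keep <- geo > min_geo_km
  if (!any(keep)) stop("all pairs filtered out by the ", min_geo_km,
                       " km distance filter")
  i <- i[keep]; j <- j[keep]; geo <- geo[keep]
  gd_raw <- gdist[cbind(i, j)]
  gd_scale <- max(gd_raw) * (1 + 1e-6)
  tab <- data.frame(s1 = ids[i], s2 = ids[j],
                    loc1 = loc$locality[i], loc2 = loc$locality[j],
                    observed = gd_raw / gd_scale,
                    geo_km = geo, weight = 1,
                    stringsAsFactors = FALSE)
  env_meta <- NULL
  if (!is.null(env)) {
    wide <- .env_wide(env)
    for (v in colnames(wide)) {
      tab[[paste0("x1_", v)]] <- wide[tab$loc1, v]
      tab[[paste0("x2_", v)]] <- wide[tab$loc2, v]
    }
    env_meta <- unique(env[, c("variable", "category")])
    rownames(env_meta) <- NULL
  }
  attr(tab, "gd_scale") <- gd_scale
  attr(tab, "env_meta") <- env_meta
  class(tab) <- c("site_pair_table", "data.frame")
  tab
}

# Minimal genotype_matrix stand-in so validate_join can check sample ids
# when only a distance matrix is in hand.
genotype_stub <- function(ids) {
  structure(list(geno = matrix(0L, length(ids), 0,
                               dimnames = list(ids, NULL)),
                 loci = data.frame(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0)),
                 samples = ids),
            class = "genotype_matrix")
}

# Design matrix for a pair table: geographic distance is splined on the
# pair's distance; each environmental predictor contributes
# |f_k(x1) - f_k(x2)| per basis function.  Returns list(X, bases).
.gdm_design <- function(pairs, predictors, include_geo, bases = NULL) {
  blocks <- list()
  new_bases <- list()
  if (include_geo) {
    b <- if (!is.null(bases)) bases[["geo"]] else
      ispline_basis(pairs$geo_km, "geo")
    new_bases[["geo"]] <- b
    blocks[["geo"]] <- ispline_evaluate(b, pairs$geo_km)
  }
  for (v in predictors) {
    c1 <- paste0("x1_", v); c2 <- paste0("x2_", v)
    if (!all(c(c1, c2) %in% names(pairs))) {
      stop("unknown predictor '", v, "' (no endpoint columns in pair table)")
    }
    vals <- c(pairs[[c1]], pairs[[c2]])
    b <- if (!is.null(bases)) bases[[v]] else
      tryCatch(ispline_basis(vals, v), error = function(e) NULL)
    if (is.null(b)) {
      warning("predictor '", v, "' is constant over pairs; excluded")
      next
    }
    new_bases[[v]] <- b
    blocks[[v]] <- abs(ispline_evaluate(b, pairs[[c1]]) -
                         ispline_evaluate(b, pairs[[c2]]))
  }
  X <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(0, nrow(pairs), 0)
  list(X = X, bases = new_bases)
}

# GDM binomial-style deviance of observed d given linear predictor eta.
.gdm_deviance <- function(d, mu, w) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(w * (t1 + t2))
}

#' Fit a generalized dissimilarity model
#'
#' Models scaled dissimilarities d in \[0, 1) through the negative
#' exponential link mu = 1 - exp(-eta), eta = alpha + sum_pk beta_pk *
#' (pair basis value), with alpha, beta >= 0, minimizing the binomial-style
#' deviance 2 * sum w \[d log(d/mu) + (1-d) log((1-d)/(1-mu))\] by
#' bound-constrained quasi-Newton optimization (analytic gradient,
#' multi-start from all-zeros and from the intercept-only optimum).
#' Deviance explained is 100 * (1 - D_model / D_null) with D_null from the
#' intercept-only fit.
#'
#' @param pairs A [build_pair_table()] result (>= 10 rows).
#' @param predictors Character vector of environmental predictor names
#'   (default none).
#' @param include_geo Include geographic distance as a splined predictor
#'   (default `TRUE`).
#' @return Object of class `gdm_model`: `intercept`, `coefficients` (named
#'   vector over basis functions), `bases`, `predictors`, `deviance`,
#'   `null_deviance`, `deviance_explained` (percent), `n_pairs`,
#'   `gd_scale`, `convergence`.
#' @export
fit_gdm <- function(pairs, predictors = character(0), include_geo = TRUE) {
  if (nrow(pairs) < 10) stop("need >= 10 site pairs")
  d <- pairs$observed
  w <- pairs$weight %||% rep(1, nrow(pairs))
  des <- .gdm_design(pairs, predictors, include_geo)
  X <- des$X
  p <- ncol(X)

  dbar <- sum(w * d) / sum(w)
  alpha0 <- -log(1 - dbar)
  null_dev <- .gdm_deviance(d, rep(dbar, length(d)), w)

  fn <- function(par) {
    mu <- 1 - exp(-(par[1] + if (p) drop(X %*% par[-1]) else 0))
    .gdm_deviance(d, mu, w)
  }
  gr <- function(par) {
    eta <- par[1] + (if (p) drop(X %*% par[-1]) else 0)
    mu <- 1 - exp(-eta)
    mu_c <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    # dD/deta = 2w * (-d/mu + (1-d)/(1-mu)) * exp(-eta)
    core <- 2 * w * (-d / mu_c + (1 - d) / (1 - mu_c)) * exp(-eta)
    c(sum(core), if (p) drop(crossprod(X, core)) else NULL)
  }
  starts <- list(rep(0, p + 1), c(alpha0, rep(0, p)))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, fn, gr, method = "L-BFGS-B",
                 lower = rep(0, p + 1),
                 control = list(maxit = 500, factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!best$convergence %in% c(0, 52) && best$value > null_dev + 1e-6) {
    stop("GDM fit failed to converge: ", best$message,
         " (deviance ", format(best$value), ")")
  }
  dev <- min(best$value, null_dev)
  structure(list(intercept = best$par[1],
                 coefficients = setNames(best$par[-1], colnames(X)),
                 bases = des$bases,
                 predictors = names(des$bases),
                 include_geo = include_geo,
                 deviance = dev,
                 null_deviance = null_dev,
                 deviance_explained = 100 * (1 - dev / null_dev),
                 n_pairs = nrow(pairs),
                 gd_scale = attr(pairs, "gd_scale"),
                 convergence = best$convergence),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat("GDM model:", length(x$predictors), "predictor(s) [",
      paste(x$predictors, collapse = ", "), "]\n")
  cat(sprintf("  deviance %.4f (null %.4f), deviance explained %.2f%%\n",
              x$deviance, x$null_deviance, x$deviance_explained))
  invisible(x)
}

#' Predict dissimilarities from a fitted GDM
#'
#' Applies the stored bases (clamping to their knot ranges) and the fitted
#' non-negative coefficients through the link mu = 1 - exp(-eta).
#'
#' @param model A [fit_gdm()] model.
#' @param pairs A site-pair table carrying the model's predictor columns.
#' @return Numeric vector of predicted dissimilarities in \[0, 1).
#' @export
predict_gdm <- function(model, pairs) {
  stopifnot(inherits(model, "gdm_model"))
  env_preds <- setdiff(model$predictors, "geo")
  des <- .gdm_design(pairs, env_preds, model$include_geo,
                     bases = model$bases)
  eta <- model$intercept +
    (if (ncol(des$X)) drop(des$X %*% model$coefficients) else 0)
  1 - exp(-eta)
}

#' @export
predict.gdm_model <- function(object, newdata, ...) {
  predict_gdm(object, newdata)
}

#' Percent deviance explained of a fitted GDM
#'
#' @param model A [fit_gdm()] model.
#' @return Percentage in (-Inf, 100\]; intercept-only models give 0.
#' @export
deviance_explained <- function(model) {
  stopifnot(inherits(model, "gdm_model"))
  model$deviance_explained
}

#' Fitted spline curve of one predictor
#'
#' The partial transform f(x) = sum_k beta_k I_k(x) on a grid over the
#' predictor's knot range; the numerical content of GDM spline panels.
#'
#' @param model A [fit_gdm()] model.
#' @param predictor Predictor name (e.g. `"geo"`).
#' @param grid Optional x grid; default 200 points over the knot range.
#' @return data.frame with columns `x` and `f`.
#' @export
gdm_spline_curve <- function(model, predictor, grid = NULL) {
  stopifnot(inherits(model, "gdm_model"))
  b <- model$bases[[predictor]]
  if (is.null(b)) stop("unknown predictor '", predictor, "'")
  if (is.null(grid)) {
    grid <- seq(b$knots[1], b$knots[3], length.out = 200)
  }
  beta <- model$coefficients[paste0(predictor, "_s", 1:3)]
  data.frame(x = grid, f = drop(ispline_evaluate(b, grid) %*% beta))
}
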