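test_that("I-spline basis endpoints, monotonicity, quadrature oracle", {
  set.seed(1)
  vals <- runif(200, 2, 9)
  b <- ispline_basis(vals, "x")
  q <- b$knots
  expect_equal(unname(ispline_evaluate(b, q[1])[1, ]), c(0, 0, 0))
  expect_equal(unname(ispline_evaluate(b, q[3])[1, ]), c(1, 1, 1))
  grid <- seq(q[1], q[3], length.out = 500)
  m <- ispline_evaluate(b, grid)
  expect_true(all(diff(m[, 1]) >= 0))
  expect_true(all(diff(m[, 2]) >= 0))
  expect_true(all(diff(m[, 3]) >= 0))
  expect_true(all(m >= 0 & m <= 1))
  # clamping outside the knot range
  expect_equal(unname(ispline_evaluate(b, q[1] - 10)[1, ]), c(0, 0, 0))
  expect_equal(unname(ispline_evaluate(b, q[3] + 10)[1, ]), c(1, 1, 1))
  # numeric integration of the M-spline densities reproduces the basis
  xs <- seq(q[1], q[3], length.out = 2001)
  for (k in 1:3) {
    dens <- oracle_mspline_density(xs, q, k)
    integ <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
    expect_equal(m[, k],
                 stats::approx(xs[-1], integ, xout = grid, yleft = 0,
                               rule = 2)$y,
                 tolerance = 1e-4)
  }
  expect_error(ispline_basis(rep(3, 10)), "degenerate")
})

test_that("pair table: distance filter, scaling, enumeration oracle", {
  # 3 localities: two within ~5 km, one far away
  loc <- data.frame(sample = sprintf("s%d", 1:6),
                    locality = rep(c("A", "B", "C"), each = 2),
                    lat = rep(c(-30, -30.04, -32), each = 2),
                    lon = rep(c(150, 150, 150), each = 2))
  set.seed(2)
  gd <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(gd) <- list(loc$sample, loc$sample)
  pairs <- build_pair_table(gd, loc, min_geo_km = 10)
  # A-B pairs (~4.4 km) and within-locality pairs excluded: only pairs
  # spanning C remain: 4 samples x 2 = 8 pairs
  expect_equal(nrow(pairs), 8)
  expect_true(all(pairs$loc1 == "C" | pairs$loc2 == "C"))
  expect_true(all(pairs$observed >= 0 & pairs$observed < 1))
  expect_equal(max(pairs$observed), 1 / (1 + 1e-6))
  # brute-force double loop on a simulated landscape
  sim <- fixture_landscape(seed = 5, n_localities = 8, n_loci = 100)
  gd2 <- gower_distance(genotype_covariance(sim$genotypes))
  p2 <- build_pair_table(gd2, sim$localities, sim$env)
  cnt <- 0
  n <- nrow(gd2)
  loctab <- sim$localities
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dd <- geo_distance(loctab$lat[i], loctab$lon[i],
                       loctab$lat[j], loctab$lon[j])
    if (dd > 10) cnt <- cnt + 1
  }
  expect_equal(nrow(p2), cnt)
  expect_error(build_pair_table(gd, loc, min_geo_km = 1e6), "filtered out")
})

test_that("intercept-only fit is the weighted-mean MLE with zero DE", {
  sim <- fixture_landscape(seed = 7)
  pairs <- fixture_pairs(sim)
  m <- fit_gdm(pairs, include_geo = FALSE)
  dbar <- mean(pairs$observed)
  expect_equal(1 - exp(-m$intercept), dbar, tolerance = 1e-6)
  expect_equal(deviance_explained(m), 0, tolerance = 1e-6)
})

test_that("noiseless generative data are recovered almost exactly", {
  sim <- fixture_landscape(seed = 19)
  pairs <- fixture_pairs(sim)
  b <- ispline_basis(pairs$geo_km, "geo")
  beta_true <- c(0.3, 0.8, 0.4)
  alpha_true <- 0.1
  f_true <- drop(ispline_evaluate(b, pairs$geo_km) %*% beta_true)
  pairs$observed <- 1 - exp(-(alpha_true + f_true))
  m <- fit_gdm(pairs)
  expect_gt(deviance_explained(m), 99)
  grid <- seq(b$knots[1], b$knots[3], length.out = 100)
  fit_curve <- gdm_spline_curve(m, "geo", grid)$f
  true_curve <- drop(ispline_evaluate(b, grid) %*% beta_true)
  expect_lt(max(abs(fit_curve - true_curve)), 0.02 * max(true_curve))
})

test_that("prediction obeys the link, bounds and monotonicity", {
  sim <- fixture_landscape(seed = 23)
  pairs <- fixture_pairs(sim)
  m <- fit_gdm(pairs, "precip_annual")
  pred <- predict_gdm(m, pairs)
  expect_true(all(pred >= 0 & pred < 1))
  # zero coefficients -> constant 1 - exp(-alpha)
  m0 <- m
  m0$coefficients[] <- 0
  expect_equal(unique(round(predict_gdm(m0, pairs), 12)),
               round(1 - exp(-m0$intercept), 12))
  # increasing geographic distance never decreases the prediction
  ord <- order(pairs$geo_km)
  same_env <- pairs[ord, ]
  for (v in c("precip_annual")) {
    same_env[[paste0("x1_", v)]] <- 0
    same_env[[paste0("x2_", v)]] <- 0
  }
  pr <- predict_gdm(m, same_env)
  expect_true(all(diff(pr) >= -1e-12))
  # hand-evaluated link on a 2-pair toy
  toy <- pairs[1:2, ]
  des_geo <- ispline_evaluate(m$bases$geo, toy$geo_km)
  des_env <- abs(ispline_evaluate(m$bases$precip_annual,
                                  toy$x1_precip_annual) -
                   ispline_evaluate(m$bases$precip_annual,
                                    toy$x2_precip_annual))
  eta <- m$intercept + cbind(des_geo, des_env) %*% m$coefficients
  expect_equal(predict_gdm(m, toy), drop(1 - exp(-eta)))
  expect_error(predict_gdm(m, pairs[, !grepl("precip", names(pairs))]),
               "unknown predictor")
})

test_that("deviance explained: bounds, nesting, affine invariance", {
  sim <- fixture_landscape(seed = 29)
  pairs <- fixture_pairs(sim)
  m_geo <- fit_gdm(pairs)
  expect_lte(deviance_explained(m_geo), 100)
  # nested-model monotonicity over several simulated data sets
  for (s in 1:5) {
    p <- fixture_pairs(fixture_landscape(seed = 60 + s, n_localities = 10,
                                         n_loci = 200))
    de0 <- deviance_explained(fit_gdm(p))
    de1 <- deviance_explained(fit_gdm(p, "precip_annual"))
    expect_gte(de1, de0 - 1e-3)
  }
  # affine rescaling of an environmental predictor leaves DE unchanged
  m1 <- fit_gdm(pairs, "precip_annual")
  pairs2 <- pairs
  pairs2$x1_precip_annual <- 3.7 * pairs2$x1_precip_annual - 11
  pairs2$x2_precip_annual <- 3.7 * pairs2$x2_precip_annual - 11
  m2 <- fit_gdm(pairs2, "precip_annual")
  expect_equal(deviance_explained(m2), deviance_explained(m1),
               tolerance = 1e-4)
  # deviance value agrees with the independent oracle
  pred <- predict_gdm(m1, pairs)
  expect_equal(m1$deviance, oracle_gdm_deviance(pairs$observed, pred),
               tolerance = 1e-8)
})

test_that("constant predictors are excluded with a warning", {
  sim <- fixture_landscape(seed = 31, n_localities = 8, n_loci = 100)
  pairs <- fixture_pairs(sim)
  pairs$x1_flat <- 1
  pairs$x2_flat <- 1
  expect_warning(m <- fit_gdm(pairs, "flat"), "constant")
  expect_false("flat" %in% m$predictors)
})
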