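test_that("morphospace PCA matches a dense covariance eigendecomposition", {
  set.seed(11)
  m <- matrix(rnorm(5 * 7), 5, 7)
  rownames(m) <- letters[1:5]
  sp <- shape_pca(m)
  ev_oracle <- eigen(cov(m), symmetric = TRUE)$values
  expect_equal(sp$eigenvalues, ev_oracle[seq_along(sp$eigenvalues)],
               tolerance = 1e-10)
  # trace conservation
  expect_equal(sum(sp$eigenvalues), sum(diag(cov(m))), tolerance = 1e-10)
  # orthonormal eigenvectors, uncorrelated scores
  V <- sp$eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-10)
  sc <- score_matrix(sp)
  cc <- cov(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])) / max(diag(cc)), 1e-10)
  # variance fractions non-increasing
  expect_true(all(diff(sp$variance_fraction) <= 1e-12))
})

test_that("collinear shape data load entirely on PC1", {
  v <- rnorm(6)
  m <- outer(seq(0, 1, length.out = 8), v)
  sp <- shape_pca(m + matrix(rnorm(48, sd = 1e-12), 8, 6))
  expect_equal(sp$variance_fraction[1], 1, tolerance = 1e-6)
})

test_that("PCA reconstruction reproduces the tangent data with all axes", {
  set.seed(12)
  m <- matrix(rnorm(10 * 6), 10, 6)
  sp <- shape_pca(m)
  rec <- shapes_from_scores(sp, score_matrix(sp))
  expect_lt(max(abs(rec - m)), 1e-8)
})

test_that("eigenvector signs follow the largest-loading convention", {
  set.seed(13)
  m <- matrix(rnorm(9 * 4), 9, 4)
  V <- shape_pca(m)$eigenvectors
  for (j in seq_len(ncol(V))) {
    expect_gt(V[which.max(abs(V[, j])), j], 0)
  }
  # deterministic: same data, same axes, even after row reordering plus
  # global sign flips of the input deviations
  expect_equal(shape_pca(m)$eigenvectors, V)
})

test_that("allometry regression recognizes perfect collinearity and nulls", {
  set.seed(14)
  n <- 40
  x <- rnorm(n)
  names(x) <- paste0("s", 1:n)
  v <- rnorm(8)
  y <- outer(x, v)
  rownames(y) <- names(x)
  fit <- allometry_regression(y, x, n_perm = 99)
  expect_equal(fit$percent_explained, 100, tolerance = 1e-8)
  expect_equal(fit$p_value, 1 / 100)
  # independent shape: small explained fraction
  y0 <- matrix(rnorm(n * 8), n, 8, dimnames = list(names(x), NULL))
  fit0 <- allometry_regression(y0, x, n_perm = 99)
  expect_lt(fit0$percent_explained, 25)
  expect_error(allometry_regression(y, rep(1, n), n_perm = 99), "constant")
  expect_error(allometry_regression(y, x, n_perm = 5), "n_perm")
})

test_that("allometric correction is idempotent in the estimation space", {
  set.seed(15)
  tr <- ape::rphylo(60, 1, 0)
  x <- drop(simulate_bm(tr, 0.25, 0))
  y <- simulate_bm(tr, diag(1e-4, 10)) + outer(x, rnorm(10, sd = 0.02))
  fit <- allometry_regression(y, x, tree = tr, n_perm = 49)
  refit <- allometry_regression(fit$residual_shapes, x, tree = tr, n_perm = 49)
  expect_lt(refit$percent_explained, 0.1)
  # species-space path as well
  fit_sp <- allometry_regression(y, x, n_perm = 49)
  refit_sp <- allometry_regression(fit_sp$residual_shapes, x, n_perm = 49)
  expect_lt(refit_sp$percent_explained, 0.1)
  # residuals orthogonal to the fitted size direction (species space)
  xc <- x - mean(x)
  expect_lt(max(abs(crossprod(fit_sp$residual_shapes, xc))), 1e-8)
})

test_that("regression scores project onto the allometric axis", {
  set.seed(16)
  b <- rnorm(6)
  u <- b / sqrt(sum(b^2))
  # orthogonal shapes score zero
  orth <- matrix(rnorm(5 * 6), 5, 6)
  orth <- orth - tcrossprod(orth %*% u, u)
  expect_lt(max(abs(regression_score(orth, b))), 1e-10)
  # shape = c * unit slope scores c (after centering)
  cs <- c(-1, 0, 2)
  shp <- outer(cs, u)
  expect_equal(regression_score(shp, b), cs - mean(cs), ignore_attr = TRUE)
  expect_error(regression_score(shp, rep(0, 6)), "zero")
})

test_that("univariate regression of the score reproduces the multivariate fit", {
  set.seed(17)
  n <- 50
  x <- rnorm(n); names(x) <- paste0("s", 1:n)
  y <- outer(x, rnorm(8, sd = 0.1)) + matrix(rnorm(n * 8, sd = 0.05), n, 8)
  rownames(y) <- names(x)
  fit <- allometry_regression(y, x, n_perm = 49)
  sc <- regression_score(y, fit$slope_vector)
  xc <- x - mean(x)
  pred_ss_uni <- sum(xc * sc)^2 / sum(xc^2)
  pred_ss_multi <- fit$percent_explained / 100 * sum(sweep(y, 2, colMeans(y))^2)
  expect_equal(pred_ss_uni, pred_ss_multi, tolerance = 1e-6)
})

test_that("thin-plate splines interpolate exactly and reproduce affine maps", {
  src <- skull_template(9) * 3
  fit_id <- tps_fit(src, src)
  expect_lt(fit_id$bending_energy, 1e-12)
  expect_lt(max(abs(predict(fit_id) - src)), 1e-10)
  A <- matrix(c(1.3, 0.2, -0.1, 0.8), 2, 2)
  tgt <- src %*% A + 1.5
  fit_aff <- tps_fit(src, tgt)
  expect_lt(max(abs(fit_aff$weights)), 1e-10)
  expect_lt(fit_aff$bending_energy, 1e-12)
  probes <- random_config(11, 2)
  expect_lt(max(abs(predict(fit_aff, probes) - (probes %*% A + 1.5))), 1e-8)
})

test_that("non-affine warps have positive bending energy and match an independent solve", {
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  tgt <- g
  tgt[5, ] <- tgt[5, ] + c(0.4, -0.3)
  fit <- tps_fit(g, tgt)
  expect_gt(fit$bending_energy, 1e-8)
  expect_lt(max(abs(predict(fit) - tgt)), 1e-10)
  set.seed(18)
  probes <- matrix(runif(20, 0, 2), 10, 2)
  expect_lt(max(abs(predict(fit, probes) - oracle_tps_probes(g, tgt, probes))),
            1e-8)
})

test_that("3D thin-plate splines interpolate and keep non-negative energy", {
  set.seed(19)
  src <- random_config(10, 3)
  tgt <- src + matrix(rnorm(30, sd = 0.2), 10, 3)
  fit <- tps_fit(src, tgt)
  expect_lt(max(abs(predict(fit) - tgt)), 1e-8)
  expect_gte(fit$bending_energy, 0)
  probes <- random_config(6, 3)
  expect_lt(max(abs(predict(fit, probes) - oracle_tps_probes(src, tgt, probes))),
            1e-8)
})

test_that("degenerate TPS source configurations are rejected", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(tps_fit(line, line + 1), "degenerate")
})

test_that("a small TPS warp composed with its inverse fit is near-identity", {
  set.seed(20)
  src <- skull_template(12) * 3
  tgt <- src + matrix(rnorm(24, sd = 1e-4), 12, 2)
  fwd <- tps_fit(src, tgt)
  bwd <- tps_fit(tgt, src)
  probes <- src * 0.8 + 0.1
  round_trip <- predict(bwd, predict(fwd, probes))
  expect_lt(max(abs(round_trip - probes)), 1e-6)
})

test_that("warping toward an ancestral shape maps landmarks exactly", {
  set.seed(21)
  sp_shape <- skull_template(10) * 2
  anc <- sp_shape + matrix(rnorm(20, sd = 0.05), 10, 2)
  expect_lt(max(abs(warp_to_node(sp_shape, sp_shape, sp_shape) - sp_shape)),
            1e-9)
  expect_lt(max(abs(warp_to_node(sp_shape, anc, sp_shape) - anc)), 1e-9)
  grid1 <- tps_grid(tps_fit(sp_shape, anc), n = 8)
  grid2 <- tps_grid(tps_fit(sp_shape, anc), n = 8)
  expect_identical(grid1, grid2)
})
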