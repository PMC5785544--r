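make_pairs <- function(emb, adu, groups, sizes_e = 3, sizes_a = 10) {
  n <- nrow(emb)
  ontogeny_pairs(
    species_id = sprintf("sp%02d", seq_len(n)),
    group = groups,
    embryo_shape = lapply(seq_len(n), function(i) emb[i, ]),
    adult_shape = lapply(seq_len(n), function(i) adu[i, ]),
    embryo_size = rep_len(sizes_e, n),
    adult_size = rep_len(sizes_a, n)
  )
}

test_that("identical groups have zero angle and length difference with p near 1", {
  set.seed(71)
  emb <- matrix(rnorm(8), 4, 2)
  adu <- emb + matrix(c(1, 0), 4, 2, byrow = TRUE)
  pairs <- make_pairs(rbind(emb, emb), rbind(adu, adu),
                      rep(c("g1", "g2"), each = 4))
  res <- trajectory_stats(pairs, n_perm = 99, seed = 1)
  expect_equal(res$pairwise$angle_deg, 0, tolerance = 1e-6)
  expect_equal(res$pairwise$length_difference, 0, tolerance = 1e-12)
  expect_gte(res$pairwise$p_length, 0.99)
})

test_that("opposite trajectory directions give a 180 degree angle", {
  emb <- matrix(0, 4, 3)
  adu1 <- matrix(c(1, 0, 0), 4, 3, byrow = TRUE)
  adu2 <- matrix(c(-1, 0, 0), 4, 3, byrow = TRUE)
  pairs <- make_pairs(rbind(emb, emb), rbind(adu1, adu2),
                      rep(c("g1", "g2"), each = 4))
  res <- trajectory_stats(pairs, n_perm = 9, seed = 1)
  expect_equal(res$pairwise$angle_deg, 180, tolerance = 1e-8)
})

test_that("toy trajectories match hand arithmetic and exhaustive enumeration", {
  # group 1: vectors (1,0),(1,0),(1,0); group 2: (0,2),(0,2),(0,2)
  emb <- matrix(0, 6, 2)
  adu <- rbind(matrix(c(1, 0), 3, 2, byrow = TRUE),
               matrix(c(0, 2), 3, 2, byrow = TRUE))
  # add distinct embryo offsets so species are distinguishable
  set.seed(72)
  off <- matrix(rnorm(12, sd = 0.05), 6, 2)
  pairs <- make_pairs(emb + off, adu + off, rep(c("g1", "g2"), each = 3))
  res <- trajectory_stats(pairs, n_perm = 1999, seed = 3)
  expect_equal(sort(res$groups$path_length), c(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$pairwise$angle_deg, 90, tolerance = 1e-8)
  expect_equal(res$pairwise$length_difference, 1, tolerance = 1e-10)

  # exhaustive null over all 20 assignments of 6 species into groups of 3
  emb_m <- do.call(rbind, pairs$embryo_shape)
  adu_m <- do.call(rbind, pairs$adult_shape)
  stats <- vapply(enumerate_group_assignments(6, 3), function(idx) {
    v1 <- colMeans(adu_m[idx, ]) - colMeans(emb_m[idx, ])
    v2 <- colMeans(adu_m[-idx, ]) - colMeans(emb_m[-idx, ])
    c(dlen = abs(sqrt(sum(v1^2)) - sqrt(sum(v2^2))),
      ang = acos(max(-1, min(1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi)
  }, numeric(2))
  p_len_exact <- mean(stats["dlen", ] >= res$pairwise$length_difference)
  p_ang_exact <- mean(stats["ang", ] >= res$pairwise$angle_deg)
  expect_lt(abs(res$pairwise$p_length - p_len_exact), 0.05)
  expect_lt(abs(res$pairwise$p_angle - p_ang_exact), 0.05)
})

test_that("trajectory statistics are invariant to a common rotation of tangent space", {
  set.seed(73)
  emb <- matrix(rnorm(16), 8, 2)
  adu <- emb + matrix(rnorm(16, 0.5), 8, 2)
  groups <- rep(c("g1", "g2"), each = 4)
  r1 <- trajectory_stats(make_pairs(emb, adu, groups), n_perm = 49, seed = 5)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  r2 <- trajectory_stats(make_pairs(emb %*% R, adu %*% R, groups),
                         n_perm = 49, seed = 5)
  expect_equal(r1$groups$path_length, r2$groups$path_length, tolerance = 1e-10)
  expect_equal(r1$pairwise$angle_deg, r2$pairwise$angle_deg, tolerance = 1e-8)
})

test_that("groups of one species are rejected", {
  emb <- matrix(0, 3, 2); adu <- emb + 1
  pairs <- make_pairs(emb, adu, c("g1", "g1", "g2"))
  expect_error(trajectory_stats(pairs, n_perm = 9), "fewer than 2")
})

test_that("planted heterochronic modes are classified correctly", {
  modes <- c("acceleration", "hypermorphosis", "predisplacement", "truncation")
  expected <- c(acceleration = "acceleration",
                hypermorphosis = "hypermorphosis",
                predisplacement = "predisplacement",
                truncation = "paedomorphic_pattern")
  for (mode in modes) {
    sim <- simulate_ontogeny(mode = mode, n_per_group = 12, q = 8, seed = 80)
    res <- heterochrony_regression(sim$pairs, ancestor = "lizard",
                                   descendant = "snake",
                                   durations = sim$durations,
                                   n_perm = 199, seed = 81)
    expect_identical(res$classification, unname(expected[mode]))
  }
})

test_that("heterochrony evidence table reproduces the stored decision", {
  sim <- simulate_ontogeny(mode = "acceleration", n_per_group = 10, q = 6,
                           seed = 82)
  res <- heterochrony_regression(sim$pairs, "lizard", "snake",
                                 durations = sim$durations, n_perm = 99,
                                 seed = 83)
  ev <- setNames(res$evidence$value, res$evidence$statistic)
  expect_equal(unname(ev["slope_ratio"]), res$slope_ratio)
  expect_gt(ev[["slope_ratio"]], 1.5)
  expect_lte(ev[["p_slope"]], res$alpha)
  expect_identical(res$classification, "acceleration")
})

test_that("degenerate size ranges are rejected", {
  emb <- matrix(rnorm(8), 4, 2)
  pairs <- make_pairs(emb, emb + 1, rep(c("g1", "g2"), each = 2),
                      sizes_e = 5, sizes_a = 5)
  expect_error(
    heterochrony_regression(pairs, "g1", "g2", n_perm = 9),
    "degenerate size range"
  )
})

test_that("duration ANOVA matches hand arithmetic and detects strong shifts", {
  # two groups of three: (10, 11, 12) and (13, 14, 15); F = 13.5
  d <- c(10, 11, 12, 13, 14, 15)
  g <- rep(c("a", "b"), each = 3)
  res <- duration_anova(d, g)
  # SSB = 6*1.5^2 = 13.5 on 1 df; SSW = 4 on 4 df -> F = 13.5
  expect_equal(res$f_statistic, 13.5)
  expect_equal(res$df1, 1)
  set.seed(74)
  d2 <- c(rnorm(20, 50, 1), rnorm(20, 55, 1))
  expect_lt(duration_anova(d2, rep(c("a", "b"), each = 20))$p_value, 1e-6)
  expect_error(duration_anova(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("the descendant ontogeny points toward the planted adult direction", {
  sim <- simulate_ontogeny(mode = "acceleration", n_per_group = 12, q = 10,
                           seed = 84)
  tr <- trajectory_stats(sim$pairs, n_perm = 9, seed = 1)
  snake_dir <- tr$groups$direction[[which(tr$groups$group == "snake")]]
  b0 <- sim$truth$slope_ancestor
  expect_gt(sum(snake_dir * b0), 0)
})
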