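test_that("independent contrasts match the closed form and an independent recursion", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  x <- matrix(c(0, 1), 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(abs(drop(pic_contrasts(tr, x))), 1 / sqrt(2))
  # identical tip values give all-zero contrasts
  tr8 <- ape::rphylo(8, 1, 0)
  same <- matrix(5, 8, 2, dimnames = list(tr8$tip.label, NULL))
  expect_lt(max(abs(pic_contrasts(tr8, same))), 1e-12)
  # 8-tip random tree vs the published recursion
  set.seed(31)
  v <- setNames(rnorm(8), tr8$tip.label)
  got <- drop(pic_contrasts(tr8, matrix(v, ncol = 1,
                                        dimnames = list(names(v), NULL))))
  oracle <- oracle_pic(tr8, v)
  expect_lt(max(abs(abs(got[names(oracle)]) - abs(oracle))), 1e-10)
})

test_that("weighted squared-change parsimony solves the two-tip closed form", {
  tr <- ape::read.tree(text = "(A:1,B:3);")
  anc <- ancestors_scp(tr, setNames(c(0, 1), c("A", "B")), mode = "weighted")
  expect_equal(unname(anc$node_states[1, 1]), 0.25)
  # constant tips reconstruct constant ancestors in both modes
  tr6 <- ape::rphylo(6, 1, 0)
  cx <- matrix(3, 6, 2, dimnames = list(tr6$tip.label, NULL))
  for (mode in c("weighted", "unweighted")) {
    expect_lt(max(abs(ancestors_scp(tr6, cx, mode = mode)$node_states - 3)),
              1e-10)
  }
})

test_that("squared-change parsimony agrees with a numerical minimizer oracle", {
  set.seed(32)
  for (rep in 1:4) {
    tr <- ape::rphylo(6, 1, 0)
    x <- matrix(rnorm(12), 6, 2, dimnames = list(tr$tip.label, NULL))
    for (mode in c("weighted", "unweighted")) {
      got <- ancestors_scp(tr, x, mode = mode)$node_states
      expect_lt(max(abs(got - oracle_scp(tr, x, mode))), 1e-6)
    }
  }
})

test_that("weighted squared-change parsimony equals the ML states under Brownian motion", {
  set.seed(33)
  tr <- ape::rphylo(10, 1, 0)
  x <- setNames(rnorm(10), tr$tip.label)
  got <- drop(ancestors_scp(tr, x, mode = "weighted")$node_states)
  ml <- ape::ace(x, tr, method = "ML")$ace
  expect_lt(max(abs(got[names(ml)] - ml)), 1e-5)
})

test_that("star-tree unweighted estimates stay within the tip range", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  x <- matrix(c(0, 1, 4, 2), 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  est <- ancestors_scp(tr, x, mode = "unweighted")$node_states
  expect_true(all(est >= 0 & est <= 4))
})

test_that("univariate K agrees with an established univariate implementation", {
  set.seed(34)
  tr <- ape::rphylo(20, 1, 0)
  x <- drop(simulate_bm(tr, 1, 0))
  got <- physignal_K(tr, x, n_perm = 9, seed = 1)$K
  ref <- picante::Kcalc(x[tr$tip.label], tr)
  expect_equal(got, as.numeric(ref), tolerance = 1e-8)
  expect_error(physignal_K(tr, setNames(rep(1, 20), tr$tip.label), n_perm = 9),
               "zero among-tip variance")
})

test_that("Brownian simulations honour degenerate and moment structure", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tips0 <- simulate_bm(tr, 0, root = c(2, 3), seed = 1)
  expect_true(all(tips0[, 1] == 2 & tips0[, 2] == 3))
  # tip variance over replicates matches rate x root-to-tip length
  set.seed(35)
  reps <- vapply(1:2000, function(i) simulate_bm(tr, 1.7, 0)["A", 1],
                 numeric(1))
  expect_equal(var(reps), 1.7 * 2, tolerance = 0.1 * 1.7 * 2)
  # sister covariance matches shared path length
  sib <- t(vapply(1:2000, function(i) drop(simulate_bm(tr, 1, 0)[c("A", "B"), 1]),
                  numeric(2)))
  expect_equal(cov(sib[, 1], sib[, 2]), 1, tolerance = 0.12)
  expect_error(simulate_bm(tr, matrix(c(1, 2, 2, 1), 2, 2), c(0, 0)),
               "semidefinite")
})

test_that("ancestral size mapping is consistent with the shape code path", {
  tr <- ape::rphylo(8, 1, 0)
  sizes <- setNames(exp(rnorm(8)), tr$tip.label)
  got <- map_size_evolution(tr, sizes)
  via_shape <- ancestors_scp(tr, log(sizes), mode = "weighted")$node_states
  expect_equal(got$size, unname(exp(via_shape[, 1])))
  same <- setNames(rep(2.5, 8), tr$tip.label)
  expect_equal(map_size_evolution(tr, same)$size, rep(2.5, 7), tolerance = 1e-9)
  expect_error(map_size_evolution(tr, same - 3), "positive")
})

test_that("a planted size decrease yields an intermediate clade ancestor", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1,E:1):2);")
  sizes <- setNames(c(1, 1.2, 1.1, 20, 22), c("A", "B", "C", "D", "E"))
  est <- map_size_evolution(tr, sizes)
  mrca_de <- ape::getMRCA(tr, c("D", "E"))
  anc_de <- est$size[est$node == mrca_de]
  root_sz <- est$size[est$node == ape::Ntip(tr) + 1]
  expect_true(anc_de > root_sz && anc_de < 22)
})

test_that("ancestral reconstruction commutes with the PCA projection", {
  set.seed(36)
  tr <- ape::rphylo(12, 1, 0)
  x <- simulate_bm(tr, diag(0.5, 5))
  sp <- shape_pca(x)
  sc <- score_matrix(sp)
  anc_scores <- ancestors_scp(tr, sc, mode = "weighted")$node_states
  anc_shapes <- ancestors_scp(tr, x, mode = "weighted")$node_states
  proj <- sweep(anc_shapes, 2, sp$mean_shape) %*% sp$eigenvectors
  expect_lt(max(abs(anc_scores - proj)), 1e-8)
})

test_that("polytomies are resolved and weighted reconstruction still works", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:2);")
  x <- setNames(c(0, 1, 2, 3), c("A", "B", "C", "D"))
  est <- ancestors_scp(tr, x, mode = "weighted")
  expect_true(all(is.finite(est$node_states)))
  expect_true(ape::is.binary(est$tree))
})
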