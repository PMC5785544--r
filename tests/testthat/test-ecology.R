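test_that("two-group MANOVA reduces to the Hotelling T-squared relation", {
  set.seed(51)
  n1 <- 7; n2 <- 9; m <- 3
  x1 <- matrix(rnorm(n1 * m), n1, m)
  x2 <- matrix(rnorm(n2 * m), n2, m) + 1
  scores <- rbind(x1, x2)
  labels <- rep(c("g1", "g2"), c(n1, n2))
  res <- manova_shape_ecology(scores, labels)
  d <- colMeans(x1) - colMeans(x2)
  Sp <- (crossprod(sweep(x1, 2, colMeans(x1))) +
           crossprod(sweep(x2, 2, colMeans(x2)))) / (n1 + n2 - 2)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(Sp) %*% d)
  expect_equal(res$wilks, 1 / (1 + T2 / (n1 + n2 - 2)), tolerance = 1e-8)
})

test_that("extreme separation is overwhelmingly significant; tiny classes error", {
  set.seed(52)
  scores <- rbind(matrix(rnorm(20), 10, 2),
                  cbind(rnorm(10) + 10, rnorm(10)))
  labels <- rep(c("a", "b"), each = 10)
  expect_lt(manova_shape_ecology(scores, labels)$p_value, 1e-6)
  expect_error(manova_shape_ecology(scores, c(rep("a", 19), "b")), "'b'")
})

test_that("phylogenetic MANOVA guards its inputs and is seed-reproducible", {
  set.seed(53)
  tr <- ape::rphylo(20, 1, 0)
  x <- simulate_bm(tr, diag(1, 3))
  labels <- setNames(rep(c("u", "v"), each = 10), tr$tip.label)
  expect_error(phylo_manova(tr, x, labels, n_sim = 0), "positive")
  r1 <- phylo_manova(tr, x, labels, n_sim = 59, seed = 4)
  r2 <- phylo_manova(tr, x, labels, n_sim = 59, seed = 4)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$wilks, wilks_lambda(x[tr$tip.label, ], labels[tr$tip.label]))
})

test_that("clade-driven separation is caught by the phylogenetic null", {
  # labels assigned by clade membership on pure BM data: an ordinary MANOVA
  # sees separation, the BM null recognises it as expected under phylogeny
  set.seed(54)
  std_sig <- phylo_sig <- logical(20)
  for (i in 1:20) {
    tr <- ape::rphylo(24, 1, 0)
    x <- simulate_bm(tr, diag(1, 2))
    half <- clade_split_labels(tr)
    res <- phylo_manova(tr, x, half, n_sim = 99)
    std_sig[i] <- res$p_value_standard <= 0.05
    phylo_sig[i] <- res$p_value <= 0.05
  }
  expect_gt(mean(std_sig), mean(phylo_sig))
  expect_gte(mean(!phylo_sig), 0.7)
})

test_that("label-independent shifts remain significant under the phylogenetic null", {
  set.seed(55)
  hits <- logical(10)
  for (i in 1:10) {
    tr <- ape::rphylo(24, 1, 0)
    x <- simulate_bm(tr, diag(1, 2))
    labels <- setNames(sample(rep(c("u", "v"), each = 12)), tr$tip.label)
    x[names(labels)[labels == "v"], ] <-
      x[names(labels)[labels == "v"], ] + 8
    hits[i] <- phylo_manova(tr, x, labels, n_sim = 99)$p_value <= 0.05
  }
  expect_gte(mean(hits), 0.9)
})

test_that("per-axis ANOVA F matches hand arithmetic on a printed fixture", {
  # 3 classes x 3 observations, axis values chosen for exact arithmetic
  scores <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), ncol = 1)
  labels <- rep(c("a", "b", "c"), each = 3)
  # group means 2, 5, 8; SSB = 3*(9+0+9) = 54 on 2 df (MSB = 27);
  # SSW = 2+2+2 = 6 on 6 df (MSW = 1); F = 27
  res <- anova_posthoc(scores, labels, n_perm = 99, seed = 1)
  expect_equal(res$anova$f_statistic, 27)
  expect_equal(res$anova$p_value, summary(aov(scores[, 1] ~ factor(labels)))[[1]]$`Pr(>F)`[1])
})

test_that("post hoc pairwise tests flag only pairs involving a shifted class", {
  set.seed(56)
  scores <- matrix(rnorm(60, sd = 0.5), ncol = 1)
  labels <- rep(c("a", "b", "c"), each = 20)
  scores[labels == "c", 1] <- scores[labels == "c", 1] + 10
  res <- anova_posthoc(scores, labels, n_perm = 199, seed = 2)
  pw <- res$pairwise
  with_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adjusted[with_c] <= 0.05))
  expect_true(all(pw$p_adjusted[!with_c] > 0.05))
})

test_that("the discriminant model agrees with an established LDA implementation", {
  set.seed(57)
  n <- 30
  scores <- rbind(matrix(rnorm(n * 3), n, 3),
                  matrix(rnorm(n * 3), n, 3) + 2,
                  cbind(matrix(rnorm(n * 2), n, 2) - 2, rnorm(n)))
  labels <- rep(c("p", "q", "r"), each = n)
  fit <- lda_fit(scores, labels)
  post <- predict(fit, scores)
  ref <- MASS::lda(scores, grouping = labels)
  ref_post <- predict(ref, scores)$posterior
  expect_lt(max(abs(as.matrix(post[, c("p", "q", "r")]) - ref_post)), 1e-6)
  expect_equal(rowSums(as.matrix(post[, c("p", "q", "r")])),
               rep(1, 3 * n), tolerance = 1e-12)
})

test_that("well separated classes cross-validate nearly perfectly; permuted labels are at chance", {
  set.seed(58)
  scores <- rbind(matrix(rnorm(40), 20, 2),
                  matrix(rnorm(40), 20, 2) + 6)
  labels <- rep(c("x", "y"), each = 20)
  cv <- cross_validate(scores, labels)
  expect_gte(cv$accuracy, 0.95)
  expect_equal(unname(rowSums(cv$confusion)), unname(table(labels)),
               ignore_attr = TRUE)
  # five balanced classes with permuted labels: accuracy near 1/5
  scores5 <- matrix(rnorm(100 * 4), 100, 4)
  labels5 <- sample(rep(ecology_levels(), each = 20))
  cv5 <- cross_validate(scores5, labels5)
  expect_lt(abs(cv5$accuracy - 0.2), 0.15)
})

test_that("posteriors respect symmetry, priors and the training basis", {
  scores <- rbind(matrix(rnorm(20, sd = 0.5), 10, 2) - 2,
                  matrix(rnorm(20, sd = 0.5), 10, 2) + 2)
  labels <- rep(c("l", "r"), each = 10)
  fit <- lda_fit(scores, labels, prior_policy = "uniform")
  mid <- matrix(colMeans(fit$class_means), 1, 2)
  post <- predict(fit, mid)
  expect_equal(post$l, 0.5, tolerance = 1e-6)
  expect_equal(post$r, 0.5, tolerance = 1e-6)
  expect_error(predict(fit, matrix(0, 1, 3)), "basis mismatch")
})

test_that("LDA accuracy is invariant to invertible affine transforms of the basis", {
  set.seed(59)
  scores <- rbind(matrix(rnorm(60), 30, 2),
                  matrix(rnorm(60), 30, 2) + 1.5)
  labels <- rep(c("x", "y"), each = 30)
  A <- matrix(c(2, 0.5, -1, 1), 2, 2)
  shifted <- scores %*% A + 3
  p1 <- predict(lda_fit(scores, labels), scores)$predicted_class
  p2 <- predict(lda_fit(shifted, labels), shifted)$predicted_class
  expect_identical(p1, p2)
})

test_that("ancestral ecology predictions are maximal at the training class means", {
  set.seed(60)
  scores <- do.call(rbind, lapply(1:5, function(i) {
    matrix(rnorm(30, sd = 0.4), 15, 2) + 3 * i
  }))
  labels <- rep(ecology_levels(), each = 15)
  fit <- lda_fit(scores, labels)
  pred <- predict_ancestral_ecology(fit, fit$class_means)
  expect_identical(pred$predicted_class, rownames(fit$class_means))
  expect_identical(pred$basis, rep("uncorrected", 5))
  posts <- as.matrix(pred[, ecology_levels()])
  expect_equal(rowSums(posts), rep(1, 5), tolerance = 1e-12)
})
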