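# Independent reference implementations used to validate the package's
# statistics. These deliberately use different algorithms (brute force,
# enumeration, generic optimizers) than the code under test.

# squared-change parsimony by generic numerical minimization of the
# weighted sum of squared changes along branches
oracle_scp <- function(tree, x, mode = "weighted") {
  tree <- squamorph::resolve_tree(tree)
  x <- as.matrix(x)
  x <- x[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  m <- tree$Nnode
  w <- if (mode == "weighted") tree$edge.length else rep(1, nrow(tree$edge))
  est <- matrix(NA_real_, m, ncol(x))
  for (j in seq_len(ncol(x))) {
    obj <- function(v) {
      vals <- c(x[, j], v)
      sum((vals[tree$edge[, 1]] - vals[tree$edge[, 2]])^2 / w)
    }
    start <- rep(mean(x[, j]), m)
    est[, j] <- optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))$par
  }
  rownames(est) <- (n + 1):(n + m)
  est
}

# independent-contrast recursion written straight from the published
# algorithm (node values by precision weighting, branch-length inflation)
oracle_pic <- function(tree, x) {
  tree <- ape::reorder.phylo(squamorph::resolve_tree(tree), "postorder")
  n <- length(tree$tip.label)
  x <- x[tree$tip.label]
  vals <- c(unname(x), rep(NA_real_, tree$Nnode))
  blen <- numeric(n + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  contrasts <- setNames(rep(NA_real_, tree$Nnode), (n + 1):(n + tree$Nnode))
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  for (nd in unique(tree$edge[, 1])) {
    ch <- kids[[as.character(nd)]]
    stopifnot(length(ch) == 2)
    b1 <- blen[ch[1]]; b2 <- blen[ch[2]]
    contrasts[as.character(nd)] <- (vals[ch[1]] - vals[ch[2]]) / sqrt(b1 + b2)
    vals[nd] <- (vals[ch[1]] / b1 + vals[ch[2]] / b2) / (1 / b1 + 1 / b2)
    blen[nd] <- blen[nd] + b1 * b2 / (b1 + b2)
  }
  contrasts
}

# alternating-minimization Procrustes consensus, rotations via polar
# decomposition computed from an eigendecomposition
oracle_gpa_consensus <- function(configs, iters = 200) {
  center_scale <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  polar_rotation <- function(M) {
    e <- eigen(crossprod(M), symmetric = TRUE)
    inv_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                                   length(e$values)) %*% t(e$vectors)
    R <- M %*% inv_sqrt
    if (det(R) < 0) {
      sv <- svd(M)
      u <- sv$u; u[, ncol(u)] <- -u[, ncol(u)]
      R <- u %*% t(sv$v)
    }
    R
  }
  X <- lapply(configs, center_scale)
  cons <- X[[1]]
  for (i in seq_len(iters)) {
    X <- lapply(X, function(m) m %*% polar_rotation(crossprod(m, cons)))
    cons <- Reduce(`+`, X) / length(X)
    cons <- cons / sqrt(sum(cons^2))
  }
  cons
}

# thin-plate spline probe mapping via an explicitly assembled linear
# system and loop-based kernel evaluation
oracle_tps_probes <- function(source, target, probes) {
  k <- nrow(source); d <- ncol(source)
  U <- function(r) {
    if (d == 2) { if (r == 0) 0 else r^2 * log(r^2) } else -r
  }
  K <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    K[i, j] <- U(sqrt(sum((source[i, ] - source[j, ])^2)))
  }
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1, d + 1)))
  sol <- qr.solve(L, rbind(target, matrix(0, d + 1, d)))
  W <- sol[1:k, , drop = FALSE]
  A <- sol[(k + 1):(k + d + 1), , drop = FALSE]
  out <- matrix(0, nrow(probes), d)
  for (i in seq_len(nrow(probes))) {
    u <- vapply(seq_len(k), function(j) {
      U(sqrt(sum((probes[i, ] - source[j, ])^2)))
    }, numeric(1))
    out[i, ] <- drop(c(1, probes[i, ]) %*% A) + drop(u %*% W)
  }
  out
}

# all distinct reassignments of species to two groups of fixed sizes
enumerate_group_assignments <- function(n_total, n_group1) {
  combn(n_total, n_group1, simplify = FALSE)
}

random_config <- function(k = 10, d = 2, sd = 1) {
  matrix(rnorm(k * d, sd = sd), k, d)
}

random_similarity <- function(d = 2) {
  th <- runif(1, 0, 2 * pi)
  R <- if (d == 2) {
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else {
    qr.Q(qr(matrix(rnorm(9), 3, 3)))
  }
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, scale = exp(runif(1, -1, 1)), shift = rnorm(d, sd = 5))
}

apply_similarity <- function(m, tr) {
  tr$scale * m %*% tr$R + matrix(tr$shift, nrow(m), ncol(m), byrow = TRUE)
}

# group labels by membership in the clade whose size is closest to half the
# tips: separation that is purely phylogenetic
clade_split_labels <- function(tree) {
  n <- length(tree$tip.label)
  best <- NULL; best_gap <- Inf
  for (nd in (n + 2):(n + tree$Nnode)) {
    sz <- length(squamorph:::clade_tips(tree, nd))
    gap <- abs(sz - n / 2)
    if (sz >= 2 && sz <= n - 2 && gap < best_gap) {
      best <- nd; best_gap <- gap
    }
  }
  inside <- tree$tip.label[squamorph:::clade_tips(tree, best)]
  setNames(ifelse(tree$tip.label %in% inside, "u", "v"), tree$tip.label)
}
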