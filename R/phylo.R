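#' Tree preparation for comparative analyses
#'
#' Resolves polytomies arbitrarily (zero-length inserted branches) and
#' floors zero branch lengths at `eps = 1e-8 * tree depth` where divisions
#' by branch length occur. Composite trees assembled from several published
#' topologies often contain polytomies, so this is done silently but
#' deterministically.
#'
#' @param tree A rooted `phylo`.
#' @param eps_scale Epsilon as a fraction of maximum root-to-tip depth.
#' @return A bifurcating `phylo` with strictly positive branch lengths.
#' @export
resolve_tree <- function(tree, eps_scale = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth <= 0) depth <- 1
  eps <- eps_scale * depth
  tree$edge.length[tree$edge.length < eps] <- eps
  tree
}

match_tips <- function(tree, x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) {
    if (nrow(x) != length(tree$tip.label)) {
      abort("tip data rows must be named by tip label or match tip count")
    }
    rownames(x) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, rownames(x))
  if (length(missing)) {
    abort(sprintf("no data for tips: %s", paste(missing, collapse = ", ")))
  }
  x[tree$tip.label, , drop = FALSE]
}

#' Phylogenetically independent contrasts for multivariate data
#'
#' Column-wise standardized contrasts ([ape::pic()]): differences between
#' daughter lineages scaled by the square root of their summed (corrected)
#' branch lengths, the transformation that renders tip observations
#' independent under Brownian motion.
#'
#' @param tree Rooted `phylo`; polytomies are resolved via [resolve_tree()].
#' @param x `n x q` matrix of tip values, rows named by tip label.
#' @return `(n-1) x q` matrix of contrasts.
#' @export
pic_contrasts <- function(tree, x) {
  tree <- resolve_tree(tree)
  x <- match_tips(tree, x)
  apply(x, 2, function(v) ape::pic(setNames(v, rownames(x)), tree))
}

#' Evolutionary rate (covariance) matrix from independent contrasts
#'
#' The standard Brownian-motion rate matrix estimate
#' `crossprod(contrasts) / (n - 1)`, used to parameterize null simulations.
#'
#' @inheritParams pic_contrasts
#' @return `q x q` positive semidefinite matrix.
#' @export
evol_rate_matrix <- function(tree, x) {
  p <- pic_contrasts(tree, x)
  crossprod(p) / nrow(p)
}

scp_weights <- function(tree, mode) {
  switch(mode,
    unweighted = rep(1, nrow(tree$edge)),
    weighted = tree$edge.length,
    abort(sprintf("unknown mode '%s'", mode))
  )
}

#' Linear operator of squared-change parsimony
#'
#' Minimizing the weighted sum of squared changes along branches is a
#' quadratic problem whose stationarity conditions form a sparse linear
#' system in the internal-node states; this returns the dense solve
#' `A` such that `internal states = A %*% tip states`, which can be reused
#' across many datasets on the same tree (e.g. inside simulation nulls).
#'
#' @param tree Rooted `phylo` (resolved internally).
#' @param mode `"unweighted"` (all branch weights 1) or `"weighted"`
#'   (weights = branch lengths; equivalent to the maximum-likelihood
#'   ancestral states under Brownian motion).
#' @return List with `A` (`Nnode x Ntip`), `tree` (the resolved tree),
#'   `node_ids` (ape node numbers of the internal nodes).
#' @export
scp_operator <- function(tree, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  tree <- resolve_tree(tree)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  w <- scp_weights(tree, mode)
  if (any(w <= 0)) abort("non-positive branch weights after adjustment")
  L <- matrix(0, m, m)
  B <- matrix(0, m, n)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - n
    ch <- tree$edge[e, 2]
    iw <- 1 / w[e]
    L[p, p] <- L[p, p] + iw
    if (ch > n) {
      ci <- ch - n
      L[ci, ci] <- L[ci, ci] + iw
      L[p, ci] <- L[p, ci] - iw
      L[ci, p] <- L[ci, p] - iw
    } else {
      B[p, ch] <- B[p, ch] + iw
    }
  }
  A <- tryCatch(solve(L, B), error = function(e) {
    abort("singular squared-change parsimony system (all-zero branch lengths?)")
  })
  list(A = A, tree = tree, node_ids = n + seq_len(m))
}

#' Squared-change parsimony ancestral state reconstruction
#'
#' Estimates internal-node states minimizing the sum over branches of
#' (squared change) / weight, with weight 1 (unweighted) or branch length
#' (weighted). The weighted solution equals the generalized-least-squares /
#' maximum-likelihood ancestral states under Brownian motion, so ancestral
#' nodes are always estimated intermediate in morphospace relative to their
#' descendants.
#'
#' @param tree Rooted `phylo`.
#' @param x `n x q` matrix of tip states (rows named by tip label) or a
#'   named vector.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return Object of class `ancestral_estimates`: `node_states`
#'   (`Nnode x q`, rownames = ape node numbers, first row = root), `mode`,
#'   `tree` (resolved).
#' @export
ancestors_scp <- function(tree, x, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  op <- scp_operator(tree, mode)
  x <- match_tips(op$tree, x)
  st <- op$A %*% x
  rownames(st) <- op$node_ids
  structure(list(node_states = st, mode = mode, tree = op$tree),
            class = "ancestral_estimates")
}

#' @export
print.ancestral_estimates <- function(x, ...) {
  cat(sprintf("Ancestral estimates (%s squared-change parsimony): %d nodes, %d traits\n",
              x$mode, nrow(x$node_states), ncol(x$node_states)))
  invisible(x)
}

#' @exportS3Method
tidy.ancestral_estimates <- function(x, ...) {
  st <- x$node_states
  if (is.null(colnames(st))) colnames(st) <- paste0("trait", seq_len(ncol(st)))
  tibble(node = as.integer(rownames(st)), as_tibble(st))
}

#' Ancestral skull size mapped onto the phylogeny
#'
#' Squared-change parsimony on log centroid size (sizes are strictly
#' positive and evolve multiplicatively), exponentiated for reporting --
#' the same machinery as for shape, applied to the 1-dimensional size
#' trait.
#'
#' @param tree Rooted `phylo`.
#' @param sizes Named vector of positive tip centroid sizes.
#' @param mode As in [ancestors_scp()].
#' @return Tibble with `node` and `size` (one row per internal node).
#' @export
map_size_evolution <- function(tree, sizes, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (any(sizes <= 0)) abort("centroid sizes must be positive")
  anc <- ancestors_scp(tree, log(sizes), mode = mode)
  tibble(node = as.integer(rownames(anc$node_states)),
         size = unname(exp(anc$node_states[, 1])))
}

#' Multivariate phylogenetic signal (K statistic)
#'
#' The multivariate generalization of Blomberg's K: the ratio of the mean
#' squared error of tip data measured from the phylogenetically-weighted
#' root estimate to the phylogenetically-corrected mean squared error,
#' scaled by its expectation under Brownian motion. K has expectation 1
#' under Brownian motion; K < 1 means relatives resemble each other less
#' than Brownian motion predicts. Significance is by permuting whole
#' multivariate rows across tips (preserving trait covariance), with the
#' `(b + 1) / (m + 1)` p-value convention.
#'
#' @param tree Rooted `phylo` with at least 4 tips.
#' @param x `n x q` tip data, rows named by tip label.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `physignal` with `K`, `p_value`, `n_perm`,
#'   `observed_rank`, `perm_K`.
#' @export
physignal_K <- function(tree, x, n_perm = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  tree <- resolve_tree(tree)
  n <- length(tree$tip.label)
  if (n < 4L) abort("phylogenetic signal needs at least 4 tips")
  x <- match_tips(tree, x)
  if (sum(scale(x, scale = FALSE)^2) <= 0) abort("zero among-tip variance")
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  invC <- solve(C)
  one <- rep(1, n)
  denom_a <- sum(invC)
  expected <- (sum(diag(C)) - n / denom_a) / (n - 1)

  k_stat <- function(xx) {
    a <- colSums(invC %*% xx) / denom_a
    xc <- sweep(xx, 2, a)
    num <- sum(xc^2)
    den <- sum(xc * (invC %*% xc))
    (num / den) / expected
  }

  K_obs <- k_stat(x)
  perm_K <- vapply(seq_len(n_perm), function(i) {
    k_stat(x[sample.int(n), , drop = FALSE])
  }, numeric(1))
  b <- sum(perm_K >= K_obs)
  structure(
    list(K = K_obs, p_value = (b + 1) / (n_perm + 1), n_perm = n_perm,
         observed_rank = n_perm + 1L - b, perm_K = perm_K),
    class = "physignal"
  )
}

#' @export
print.physignal <- function(x, ...) {
  cat(sprintf("Multivariate phylogenetic signal: K = %.3f, p = %.4g (%d permutations)\n",
              x$K, x$p_value, x$n_perm))
  invisible(x)
}

#' @exportS3Method
glance.physignal <- function(x, ...) {
  tibble(K = x$K, p_value = x$p_value, n_perm = x$n_perm)
}

sigma_sqrt <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!isSymmetric(unname(sigma), tol = 1e-8)) abort("rate covariance must be symmetric")
  ei <- eigen(sigma, symmetric = TRUE)
  if (min(ei$values) < -1e-8 * max(abs(ei$values), 1)) {
    abort("rate covariance must be positive semidefinite")
  }
  ei$vectors %*% (sqrt(pmax(ei$values, 0)) * t(ei$vectors))
}

#' Simulate multivariate Brownian motion along a phylogeny
#'
#' Independent multivariate normal increments per branch with covariance
#' `branch length * rate`, accumulated from the root.
#'
#' @param tree Rooted `phylo`.
#' @param rate `q x q` positive semidefinite rate covariance (a scalar is
#'   taken as `rate * diag(q)` with `q = length(root)`).
#' @param root Numeric root state (length `q`).
#' @param seed Optional integer seed.
#' @param internal If `TRUE` also return internal-node states.
#' @return `n x q` matrix of tip states (rows named by tip label); with
#'   `internal = TRUE`, a list with `tips` and `nodes`.
#' @export
simulate_bm <- function(tree, rate, root = NULL, seed = NULL, internal = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree needs branch lengths")
  if (length(rate) == 1L) {
    q <- max(length(root), 1L)
    rate <- diag(as.numeric(rate), q)
  }
  q <- ncol(rate)
  if (is.null(root)) root <- rep(0, q)
  stopifnot(length(root) == q)
  Lr <- sigma_sqrt(rate)
  n <- length(tree$tip.label)
  ntot <- n + tree$Nnode
  states <- matrix(NA_real_, ntot, q)
  states[n + 1L, ] <- root
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))        # preorder: parents before children
  z <- matrix(rnorm(nrow(po$edge) * q), nrow(po$edge), q) %*% Lr
  for (e in ord) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    states[ch, ] <- states[p, ] + sqrt(po$edge.length[e]) * z[e, ]
  }
  tips <- states[seq_len(n), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  if (internal) {
    nodes <- states[(n + 1L):ntot, , drop = FALSE]
    rownames(nodes) <- (n + 1L):ntot
    list(tips = tips, nodes = nodes)
  } else {
    tips
  }
}
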