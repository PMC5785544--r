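# closed-form generalized-least-squares ancestral states under Brownian
# motion: root by phylogenetically weighted mean, other nodes by the GLS
# conditional expectation using shared-path covariances
oracle_gls_anc <- function(tree, x) {
  tree <- squamorph::resolve_tree(tree)
  x <- as.matrix(x)[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  C <- matrix(depth[M[1:n, 1:n]], n, n)
  invC <- solve(C)
  one <- rep(1, n)
  a0 <- drop(t(one) %*% invC %*% x) / sum(invC)
  xc <- sweep(x, 2, a0)
  est <- matrix(NA_real_, tree$Nnode, ncol(x))
  for (j in seq_len(tree$Nnode)) {
    nd <- n + j
    cj <- depth[M[nd, 1:n]]
    est[j, ] <- a0 + drop(t(cj) %*% invC %*% xc)
  }
  rownames(est) <- (n + 1):(n + tree$Nnode)
  est
}
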