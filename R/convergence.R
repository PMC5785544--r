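#' Distance-based convergence measures C1-C4
#'
#' Stayton's measures compare the current phenotypic distance between
#' putatively convergent taxa (`Dtip`) with the maximum phenotypic
#' distance (`Dmax`) attained between their two lineages at any point
#' since their most recent common ancestor, using squared-change-parsimony
#' (maximum-likelihood under Brownian motion) reconstructions for internal
#' nodes:
#' \itemize{
#'   \item `C1 = (Dmax - Dtip) / Dmax`, the proportion of the maximum
#'     divergence closed by subsequent evolution (1 = complete
#'     convergence);
#'   \item `C2 = Dmax - Dtip`, the same quantity in shape-distance units;
#'   \item `C3 = C2 /` (total evolutionary change summed along the two
#'     focal lineages);
#'   \item `C4 = C2 /` (total evolutionary change over the whole clade
#'     descended from the focal MRCA).
#' }
#' With more than two focal taxa, `Dtip` and `Dmax` (and the lineage
#' totals) are averaged over all focal pairs; `min`/`max` aggregation is
#' available. Significance is the fraction of Brownian-motion simulations
#' (rate matrix estimated from the data by independent contrasts,
#' ancestral states re-estimated inside every replicate) whose measure is
#' at least the observed one, with the `(b + 1) / (m + 1)` convention.
#'
#' @param tree Rooted `phylo`.
#' @param x `n x q` matrix of tip shape data (tangent coordinates or
#'   scores), rows named by tip label.
#' @param focal_taxa Character vector (>= 2 distinct tip labels) of the
#'   putatively convergent taxa.
#' @param n_sim Brownian-motion simulations for the significance test;
#'   0 skips the test.
#' @param seed Optional integer seed.
#' @param aggregate How to combine focal pairs: `"mean"` (default),
#'   `"min"`, `"max"`.
#' @return Object of class `convergence_result` with `C1`-`C4`,
#'   `p_values` (named, when simulated), `Dtip`, `Dmax`, `n_sim`.
#' @export
stayton_C <- function(tree, x, focal_taxa, n_sim = 1000L, seed = NULL,
                      aggregate = c("mean", "min", "max")) {
  aggregate <- match.arg(aggregate)
  if (!is.null(seed)) set.seed(seed)
  focal_taxa <- unique(as.character(focal_taxa))
  if (length(focal_taxa) < 2L) abort("need at least 2 distinct focal taxa")
  op <- scp_operator(tree, "weighted")
  tree <- op$tree
  if (!all(focal_taxa %in% tree$tip.label)) {
    abort(sprintf("focal taxa not in tree: %s",
                  paste(setdiff(focal_taxa, tree$tip.label), collapse = ", ")))
  }
  x <- match_tips(tree, x)
  paths <- focal_pair_paths(tree, focal_taxa)
  obs <- stayton_measures(x, op$A %*% x, tree, paths, aggregate)
  p_values <- NULL
  if (n_sim > 0L) {
    rate <- evol_rate_matrix(tree, x)
    exceed <- c(C1 = 0, C2 = 0, C3 = 0, C4 = 0)
    for (i in seq_len(n_sim)) {
      xs <- simulate_bm(tree, rate)
      sim <- stayton_measures(xs, op$A %*% xs, tree, paths, aggregate)
      exceed <- exceed + (unlist(sim[c("C1", "C2", "C3", "C4")]) >=
                            unlist(obs[c("C1", "C2", "C3", "C4")]))
    }
    p_values <- (exceed + 1) / (n_sim + 1)
  }
  structure(
    c(obs, list(p_values = p_values, n_sim = n_sim,
                focal_taxa = focal_taxa, aggregate = aggregate)),
    class = "convergence_result"
  )
}

# per focal pair: node paths from each tip back to the pair MRCA, plus the
# edge set of the clade below the overall focal MRCA (for C4)
focal_pair_paths <- function(tree, focal_taxa) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  lineage <- function(tip) {
    nd <- tip
    out <- nd
    while (nd != root) { nd <- parent[nd]; out <- c(out, nd) }
    out
  }
  tips <- match(focal_taxa, tree$tip.label)
  lins <- lapply(tips, lineage)
  pairs <- utils::combn(seq_along(tips), 2, simplify = FALSE)
  pair_info <- lapply(pairs, function(pr) {
    l1 <- lins[[pr[1]]]; l2 <- lins[[pr[2]]]
    mrca <- l1[which(l1 %in% l2)[1]]
    list(
      path1 = l1[seq_len(which(l1 == mrca))],
      path2 = l2[seq_len(which(l2 == mrca))],
      tip1 = tips[pr[1]], tip2 = tips[pr[2]], mrca = mrca
    )
  })
  all_mrca <- if (length(tips) == 2L) pair_info[[1]]$mrca else {
    common <- Reduce(intersect, lins)
    common[1]
  }
  clade_edges <- which(edges_in_clade(tree, all_mrca))
  list(pairs = pair_info, clade_edges = clade_edges, parent = parent, n = n)
}

edges_in_clade <- function(tree, node) {
  n <- length(tree$tip.label)
  inside <- rep(FALSE, n + tree$Nnode)
  inside[node] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))     # preorder
  keep <- rep(FALSE, nrow(tree$edge))
  edge_index <- match(
    paste(po$edge[, 1], po$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  for (e in ord) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (inside[p]) {
      inside[ch] <- TRUE
      keep[edge_index[e]] <- TRUE
    }
  }
  keep
}

stayton_measures <- function(tipx, ancx, tree, paths, aggregate) {
  n <- paths$n
  state <- function(node) {
    if (node <= n) tipx[node, ] else ancx[node - n, ]
  }
  agg <- switch(aggregate, mean = mean, min = min, max = max)
  dtips <- dmaxs <- ltots <- numeric(length(paths$pairs))
  for (i in seq_along(paths$pairs)) {
    pr <- paths$pairs[[i]]
    s1 <- do.call(rbind, lapply(pr$path1, state))
    s2 <- do.call(rbind, lapply(pr$path2, state))
    dtips[i] <- sqrt(sum((s1[1, ] - s2[1, ])^2))
    d2 <- outer(rowSums(s1^2), rowSums(s2^2), `+`) - 2 * tcrossprod(s1, s2)
    dmaxs[i] <- sqrt(max(d2, 0))
    seg <- function(s) {
      if (nrow(s) < 2L) return(0)
      sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
    }
    ltots[i] <- seg(s1) + seg(s2)
  }
  Dtip <- agg(dtips); Dmax <- agg(dmaxs); Ltot <- agg(ltots)
  C2 <- max(Dmax - Dtip, 0)
  # total change over the whole clade below the focal MRCA
  clade_tot <- 0
  for (e in paths$clade_edges) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    clade_tot <- clade_tot + sqrt(sum((state(p) - state(ch))^2))
  }
  list(
    C1 = if (Dmax > 0) C2 / Dmax else 0,
    C2 = C2,
    C3 = if (Ltot > 0) C2 / Ltot else 0,
    C4 = if (clade_tot > 0) C2 / clade_tot else 0,
    Dtip = Dtip, Dmax = Dmax
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("Convergence of {%s}:\n", paste(x$focal_taxa, collapse = ", ")))
  cat(sprintf("  C1 = %.3f  C2 = %.4g  C3 = %.3f  C4 = %.3f  (Dtip %.4g, Dmax %.4g)\n",
              x$C1, x$C2, x$C3, x$C4, x$Dtip, x$Dmax))
  if (!is.null(x$p_values)) {
    cat(sprintf("  p-values (%d BM simulations): C1 %.4g, C2 %.4g, C3 %.4g, C4 %.4g\n",
                x$n_sim, x$p_values["C1"], x$p_values["C2"],
                x$p_values["C3"], x$p_values["C4"]))
  }
  invisible(x)
}

#' @exportS3Method
tidy.convergence_result <- function(x, ...) {
  tibble(
    measure = c("C1", "C2", "C3", "C4"),
    value = c(x$C1, x$C2, x$C3, x$C4),
    p_value = if (is.null(x$p_values)) NA_real_ else unname(x$p_values)
  )
}
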