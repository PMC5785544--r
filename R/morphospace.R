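#' Principal-component morphospace of tangent shape coordinates
#'
#' Eigendecomposition of the specimen (or species) covariance matrix of
#' tangent coordinates. Scores are centered; each eigenvector's sign is
#' fixed so its largest-magnitude loading is positive, making axis
#' polarities deterministic (published axis polarities are arbitrary).
#'
#' @param x A [gpa_align()] fit, a `species_shapes` tibble, or a plain
#'   `n x q` matrix of tangent coordinates (rows named).
#' @param n_axes Number of axes to retain; default all with positive
#'   variance (at most `n - 1`).
#' @return Object of class `morphospace`: `eigenvectors` (`q x m`),
#'   `eigenvalues`, `variance_fraction`, `scores` (tibble with `id` and
#'   `PC*` columns), `mean_shape` (length-`q` vector), `k`, `d` when known.
#' @export
shape_pca <- function(x, n_axes = NULL) {
  k <- d <- NULL
  if (inherits(x, "gpa_alignment")) {
    m <- x$tangent; k <- x$k; d <- x$d
  } else if (inherits(x, "species_shapes")) {
    m <- shape_matrix(x); k <- attr(x, "k"); d <- attr(x, "d")
  } else {
    m <- as.matrix(x)
  }
  n <- nrow(m)
  if (n < 3L) abort("PCA needs at least 3 observations")
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  if (sum(mc^2) <= 0) abort("zero total shape variance")
  sv <- svd(mc)
  ev <- sv$d^2 / (n - 1)
  keep <- which(ev > max(ev) * 1e-12)
  if (!is.null(n_axes)) keep <- keep[seq_len(min(n_axes, length(keep)))]
  V <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  scores <- mc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  total_var <- sum(mc^2) / (n - 1)
  out <- list(
    eigenvectors = V,
    eigenvalues = ev[keep],
    variance_fraction = ev[keep] / total_var,
    scores = tibble(id = rownames(m) %||% as.character(seq_len(n)),
                    as_tibble(scores)),
    mean_shape = mu,
    total_variance = total_var,
    k = k, d = d
  )
  class(out) <- "morphospace"
  out
}

#' Extract the numeric score matrix from a morphospace
#' @param x A `morphospace`.
#' @param n_axes Optionally keep only the first `n_axes` columns.
#' @return Numeric matrix, rows named by `id`.
#' @export
score_matrix <- function(x, n_axes = NULL) {
  stopifnot(inherits(x, "morphospace"))
  m <- as.matrix(x$scores[, -1, drop = FALSE])
  rownames(m) <- x$scores$id
  if (!is.null(n_axes)) m <- m[, seq_len(min(n_axes, ncol(m))), drop = FALSE]
  m
}

#' Smallest number of axes reaching a cumulative variance threshold
#' @param x A `morphospace`.
#' @param threshold Cumulative fraction of total variance, default 0.9.
#' @return Integer number of axes.
#' @export
axes_for_variance <- function(x, threshold = 0.9) {
  stopifnot(inherits(x, "morphospace"))
  m <- which(cumsum(x$variance_fraction) > threshold)
  if (!length(m)) length(x$variance_fraction) else m[1]
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("Morphospace: %d observations, %d axes retained\n",
              nrow(x$scores), length(x$eigenvalues)))
  vf <- x$variance_fraction
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% (PC1+PC2 %.1f%% of total variation)\n",
              100 * vf[1], 100 * vf[min(2, length(vf))],
              100 * sum(vf[seq_len(min(2, length(vf)))])))
  invisible(x)
}

#' @exportS3Method
tidy.morphospace <- function(x, ...) x$scores

#' @exportS3Method
glance.morphospace <- function(x, ...) {
  vf <- x$variance_fraction
  tibble(
    n = nrow(x$scores),
    n_axes = length(x$eigenvalues),
    pc1_fraction = vf[1],
    pc2_fraction = if (length(vf) > 1) vf[2] else NA_real_,
    pc12_fraction = sum(vf[seq_len(min(2, length(vf)))]),
    total_variance = x$total_variance
  )
}

#' Reconstruct shapes from morphospace scores
#'
#' Inverse of the PCA projection: `mean_shape + scores %*% t(eigenvectors)`.
#' With all axes retained this reproduces the tangent data exactly.
#'
#' @param x A `morphospace`.
#' @param scores Numeric matrix of scores (columns matching retained axes;
#'   fewer columns are padded with zeros).
#' @return Matrix of tangent-space shape vectors, one row per score row.
#' @export
shapes_from_scores <- function(x, scores) {
  stopifnot(inherits(x, "morphospace"))
  scores <- as.matrix(scores)
  m <- ncol(x$eigenvectors)
  if (ncol(scores) < m) {
    scores <- cbind(scores, matrix(0, nrow(scores), m - ncol(scores)))
  }
  sweep(scores %*% t(x$eigenvectors), 2, x$mean_shape, `+`)
}

#' Plot a morphospace (PC1 vs PC2)
#'
#' @param object A `morphospace`.
#' @param labels Optional data frame with `id` plus grouping columns; the
#'   first extra column is mapped to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.morphospace <- function(object, labels = NULL, ...) {
  df <- object$scores
  vf <- 100 * object$variance_fraction
  p <- if (!is.null(labels)) {
    df <- left_join(df, as_tibble(labels), by = "id")
    grp <- setdiff(names(labels), "id")[1]
    ggplot(df, aes(.data$PC1, .data$PC2, colour = .data[[grp]]))
  } else {
    ggplot(df, aes(.data$PC1, .data$PC2))
  }
  p + geom_point() +
    labs(x = sprintf("PC1 (%.1f%%)", vf[1]),
         y = sprintf("PC2 (%.1f%%)", vf[min(2, length(vf))])) +
    theme_minimal()
}

#' Phylomorphospace plot
#'
#' Projects the phylogeny into the morphospace: tips at their scores,
#' internal nodes at squared-change parsimony estimates, branches drawn as
#' segments.
#'
#' @param space A `morphospace` whose ids are tree tip labels.
#' @param tree A rooted `phylo`.
#' @param mode Ancestral estimation mode, see [ancestors_scp()].
#' @param labels Optional tip grouping as in [autoplot.morphospace()].
#' @return A ggplot object.
#' @export
plot_phylomorphospace <- function(space, tree, mode = "weighted",
                                  labels = NULL) {
  sc <- score_matrix(space, 2)
  anc <- ancestors_scp(tree, sc, mode = mode)
  nodes <- rbind(sc[tree$tip.label, , drop = FALSE], anc$node_states)
  edges <- tibble(
    x = nodes[tree$edge[, 1], 1], y = nodes[tree$edge[, 1], 2],
    xend = nodes[tree$edge[, 2], 1], yend = nodes[tree$edge[, 2], 2]
  )
  p <- autoplot(space, labels = labels)
  p + geom_segment(data = edges,
                   aes(x = .data$x, y = .data$y,
                       xend = .data$xend, yend = .data$yend),
                   inherit.aes = FALSE, linewidth = 0.2, colour = "grey50")
}
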