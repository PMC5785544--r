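#' Multivariate allometry regression of shape on log centroid size
#'
#' Regresses tangent shape coordinates on log centroid size. When a tree is
#' supplied, the slope is estimated from phylogenetically independent
#' contrasts (regression through the origin on contrasts) and the explained
#' fraction is computed from the contrast fit; significance is a
#' permutation test against the null of total independence between size
#' and shape, permuting (and sign-flipping) the standardized size
#' contrasts, which are the exchangeable units under that null (for the
#' non-phylogenetic fit, sizes are permuted across specimens directly).
#' Residual shapes (species
#' space, centered, minus `log_size * slope`) are retained for
#' allometry-corrected analyses.
#'
#' @param shape `n x q` matrix of tangent coordinates, rows named.
#' @param log_size Named numeric vector of log centroid sizes.
#' @param tree Optional rooted `phylo`; when supplied names must match its
#'   tips and the fit is on independent contrasts.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `allometry_fit`: `slope_vector` (length `q`,
#'   shape change per unit log size), `percent_explained` (contrast space
#'   when a tree is given), `percent_explained_species` (ordinary species
#'   space fit, reported alongside), `p_value`, `residual_shapes`,
#'   `n_perm`, `phylogenetic`.
#' @export
allometry_regression <- function(shape, log_size, tree = NULL,
                                 n_perm = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 10L) abort("n_perm must be at least 10")
  shape <- as.matrix(shape)
  if (is.null(names(log_size)) && !is.null(rownames(shape))) {
    names(log_size) <- rownames(shape)
  }
  if (sd(log_size) == 0) abort("log_size is constant")

  pct_from <- function(xc, yc) {
    # regression through the origin of centered/contrast responses on xc
    sxx <- sum(xc^2)
    b <- drop(crossprod(yc, xc)) / sxx
    pred_ss <- sum(xc^2) * sum(b^2)
    list(slope = b, pred_ss = pred_ss, pct = 100 * pred_ss / sum(yc^2))
  }

  # species-space fit (always computed: both accountings are reported)
  xs <- if (!is.null(rownames(shape))) log_size[rownames(shape)] else log_size
  xc_sp <- xs - mean(xs)
  yc_sp <- sweep(shape, 2, colMeans(shape))
  fit_sp <- pct_from(xc_sp, yc_sp)

  if (!is.null(tree)) {
    tree <- resolve_tree(tree)
    shape_t <- match_tips(tree, shape)
    x_t <- log_size[tree$tip.label]
    yc <- pic_contrasts(tree, shape_t)
    xc <- drop(pic_contrasts(tree, matrix(x_t, ncol = 1,
                                          dimnames = list(tree$tip.label, NULL))))
    fit <- pct_from(xc, yc)
    # contrasts are the exchangeable units under the independence null
    # (they are iid and sign-symmetric under Brownian motion); permuting
    # raw sizes across tips would produce non-tree-structured
    # pseudo-data whose standardized contrasts have a different scale
    perm_stat <- vapply(seq_len(n_perm), function(i) {
      xpc <- sample(xc) * sample(c(-1, 1), length(xc), replace = TRUE)
      pct_from(xpc, yc)$pred_ss
    }, numeric(1))
    slope <- fit$slope
    pct <- fit$pct
  } else {
    fit <- fit_sp
    perm_stat <- vapply(seq_len(n_perm), function(i) {
      xp <- xc_sp[sample.int(length(xc_sp))]
      pct_from(xp, yc_sp)$pred_ss
    }, numeric(1))
    slope <- fit$slope
    pct <- fit$pct
  }
  p_value <- (sum(perm_stat >= fit$pred_ss) + 1) / (n_perm + 1)
  residual_shapes <- yc_sp - tcrossprod(xc_sp, slope)
  rownames(residual_shapes) <- rownames(shape)

  structure(
    list(slope_vector = slope,
         percent_explained = pct,
         percent_explained_species = fit_sp$pct,
         p_value = p_value,
         residual_shapes = residual_shapes,
         n_perm = n_perm,
         phylogenetic = !is.null(tree)),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "Allometry (%s): %.2f%% of shape variation explained by log size, p = %.4g\n",
    if (x$phylogenetic) "independent contrasts" else "species space",
    x$percent_explained, x$p_value))
  invisible(x)
}

#' @exportS3Method
glance.allometry_fit <- function(x, ...) {
  tibble(
    percent_explained = x$percent_explained,
    percent_explained_species = x$percent_explained_species,
    p_value = x$p_value,
    slope_magnitude = sqrt(sum(x$slope_vector^2)),
    n_perm = x$n_perm,
    phylogenetic = x$phylogenetic
  )
}

#' Regression score along the allometric axis
#'
#' Projects centered shapes onto the unit-normalized slope vector -- the
#' standard one-dimensional summary used to plot shape against log size.
#'
#' @param shape `n x q` matrix of tangent coordinates.
#' @param slope_vector Length-`q` regression slope (nonzero).
#' @return Numeric vector of scores, named by row.
#' @export
regression_score <- function(shape, slope_vector) {
  nrm <- sqrt(sum(slope_vector^2))
  if (nrm <= 0) abort("slope vector is zero")
  drop(sweep(as.matrix(shape), 2, colMeans(shape)) %*% (slope_vector / nrm))
}
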