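#' Fit a thin-plate spline mapping between landmark configurations
#'
#' Exact interpolation of `source` landmarks onto `target` landmarks with
#' the thin-plate spline: an affine part plus radial-basis warp
#' coefficients. The kernel is `U(r) = r^2 log(r^2)` in 2D and `U(r) = -r`
#' in 3D (the sign that keeps the constrained system positive
#' semidefinite). The bending energy is the warp quadratic form; it is
#' non-negative and zero exactly when the target is an affine image of the
#' source.
#'
#' @param source,target `k x d` coordinate matrices (`k >= d + 1`,
#'   non-degenerate source).
#' @return Object of class `tps_map` with `affine` (`(d+1) x d`),
#'   `weights` (`k x d`), `bending_energy`, `source`, `d`; use
#'   [predict.tps_map()] to map points.
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(all(dim(source) == dim(target)))
  k <- nrow(source); d <- ncol(source)
  if (!d %in% 2:3) abort("TPS supports 2D and 3D configurations")
  if (k < d + 1) abort("need at least d + 1 landmarks")
  if (qr(cbind(1, source))$rank < d + 1) {
    abort("degenerate source landmarks (collinear/coplanar)")
  }
  K <- tps_kernel_matrix(source, source, d)
  P <- cbind(1, source)
  Lmat <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- rbind(target, matrix(0, d + 1, d))
  sol <- solve(Lmat, rhs)
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[(k + 1):(k + d + 1), , drop = FALSE]
  be <- sum(W * (K %*% W))
  structure(
    list(affine = A, weights = W, bending_energy = max(be, 0),
         source = source, d = d),
    class = "tps_map"
  )
}

tps_kernel_matrix <- function(a, b, d) {
  # pairwise distances between rows of a and rows of b
  r2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  r2[r2 < 0] <- 0
  if (d == 2L) {
    out <- r2 * log(r2)
    out[r2 == 0] <- 0
    out
  } else {
    -sqrt(r2)
  }
}

#' Map points through a fitted thin-plate spline
#'
#' @param object A [tps_fit()] mapping.
#' @param newdata `m x d` matrix of probe points (defaults to the source
#'   landmarks, which map exactly onto the target).
#' @param ... Unused.
#' @return `m x d` matrix of warped points.
#' @export
predict.tps_map <- function(object, newdata = NULL, ...) {
  pts <- if (is.null(newdata)) object$source else as.matrix(newdata)
  U <- tps_kernel_matrix(pts, object$source, object$d)
  cbind(1, pts) %*% object$affine + U %*% object$weights
}

#' @export
print.tps_map <- function(x, ...) {
  cat(sprintf("Thin-plate spline map: %d landmarks in %dD, bending energy %.4g\n",
              nrow(x$source), x$d, x$bending_energy))
  invisible(x)
}

#' Warp probe points from a species shape toward an ancestral shape
#'
#' Applies the thin-plate spline fitted from the closest species'
#' configuration to a reconstructed ancestral configuration -- the standard
#' way to visualize an estimated ancestral morphology as a deformation of
#' the nearest observed one. Landmarks themselves map exactly onto the
#' ancestral landmarks.
#'
#' @param species_shape `k x d` configuration of the closest species (in
#'   the common aligned frame).
#' @param ancestral_shape `k x d` reconstructed ancestral configuration.
#' @param probes `m x d` matrix of probe points (outline or grid points);
#'   defaults to the species landmarks.
#' @return `m x d` matrix of warped probe points.
#' @export
warp_to_node <- function(species_shape, ancestral_shape, probes = NULL) {
  fit <- tps_fit(species_shape, ancestral_shape)
  predict(fit, newdata = probes)
}

#' Deformation grid for visualizing a thin-plate spline warp
#'
#' @param fit A `tps_map`.
#' @param n Grid resolution per axis (2D only).
#' @param pad Fractional padding around the source bounding box.
#' @return Tibble with original (`x`, `y`) and warped (`wx`, `wy`) grid
#'   positions.
#' @export
tps_grid <- function(fit, n = 20L, pad = 0.1) {
  stopifnot(inherits(fit, "tps_map"))
  if (fit$d != 2L) abort("deformation grids are drawn for 2D warps")
  rng <- apply(fit$source, 2, range)
  span <- rng[2, ] - rng[1, ]
  xs <- seq(rng[1, 1] - pad * span[1], rng[2, 1] + pad * span[1], length.out = n)
  ys <- seq(rng[1, 2] - pad * span[2], rng[2, 2] + pad * span[2], length.out = n)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  w <- predict(fit, newdata = g)
  tibble(x = g[, 1], y = g[, 2], wx = w[, 1], wy = w[, 2])
}
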