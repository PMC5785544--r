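#' Ordinary Procrustes rotation of one configuration onto another
#'
#' Finds the orthogonal matrix `R` minimizing `||moving %*% R - target||`
#' over rotations (determinant +1), via the singular value decomposition of
#' the cross-covariance matrix. Both configurations are expected centered
#' and at unit centroid size. Reflections are disallowed by default:
#' consistently digitized lateral views should never need one, and a
#' mirrored specimen indicates a data error rather than biology.
#'
#' @param moving,target `k x d` centered, unit-size coordinate matrices.
#' @param allow_reflection If `TRUE` the best orthogonal matrix is used
#'   even when it has determinant -1.
#' @return List with `rotated` (the transformed `moving`), `rotation`, and
#'   `distance` (root summed squared residual).
#' @export
opa_align <- function(moving, target, allow_reflection = FALSE) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  stopifnot(all(dim(moving) == dim(target)))
  M <- crossprod(moving, target)          # d x d
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    # determinant correction: flip the singular vector pair of the smallest
    # singular value (deterministic tie-break for degenerate optima)
    if (sv$d[length(sv$d)] < .Machine$double.eps^0.5 * sv$d[1]) {
      warn("near rank-deficient cross-covariance; rotation tie broken deterministically")
    }
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(sv$v)
  }
  rotated <- moving %*% R
  list(rotated = rotated, rotation = R,
       distance = sqrt(sum((rotated - target)^2)))
}

#' Generalized Procrustes Analysis with tangent projection
#'
#' Superimposes all configurations by iteratively centering, scaling to
#' unit centroid size, rotating each onto the current consensus, and
#' updating the consensus to the (re-normalized) mean, until the consensus
#' change drops below `tol`. Aligned shapes are then projected orthogonally
#' onto the tangent space at the consensus, where ordinary multivariate
#' statistics are valid for small shape variation. Centroid sizes are
#' recorded before scaling. The final frame is canonicalized by rotating
#' the consensus to its principal axes (deterministic sign convention), so
#' the output depends only on the shapes, not on how specimens were
#' positioned, scaled or rotated when digitized.
#'
#' @param landmarks A [landmark_tbl()] (or list of `k x d` matrices).
#' @param tol Convergence tolerance on the consensus update.
#' @param max_iter Maximum number of GPA iterations.
#' @return An object of class `gpa_alignment` with elements `aligned`
#'   (`n x (k*d)` matrix, rows named by specimen), `consensus` (`k x d`),
#'   `centroid_sizes`, `tangent` (`n x (k*d)`, column-centered),
#'   `iterations`, `converged`, `residual_history`, `k`, `d`.
#' @export
gpa_align <- function(landmarks, tol = 1e-10, max_iter = 100L) {
  if (inherits(landmarks, "landmark_tbl")) {
    ids <- landmarks$specimen_id
    coords <- landmarks$coords
  } else {
    coords <- landmarks
    ids <- names(coords) %||% paste0("spec_", seq_along(coords))
  }
  n <- length(coords)
  if (n < 3L) abort("GPA needs at least 3 configurations")
  k <- nrow(coords[[1]]); d <- ncol(coords[[1]])

  cs <- numeric(n)
  X <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sweep(as.matrix(coords[[i]]), 2, colMeans(coords[[i]]))
    cs[i] <- sqrt(sum(m^2))
    if (cs[i] <= 0) abort("configuration with zero centroid size")
    X[[i]] <- m / cs[i]
  }

  consensus <- X[[1]]
  resid_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[[i]] <- opa_align(X[[i]], consensus)$rotated
    new_cons <- Reduce(`+`, X) / n
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    resid_hist <- c(resid_hist,
                    sum(vapply(X, function(m) sum((m - new_cons)^2),
                               numeric(1))))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }

  # canonical orientation: principal axes of the consensus, signs fixed so
  # the largest-magnitude loading per axis is positive, determinant kept +1
  rot <- canonical_rotation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) X[[i]] <- opa_align(X[[i]] %*% rot, consensus)$rotated

  aligned <- flatten_configs(X)
  rownames(aligned) <- ids
  cvec <- as.vector(consensus)            # unit norm
  proj <- aligned - tcrossprod(aligned %*% cvec, cvec)
  tangent <- sweep(proj, 2, colMeans(proj))
  rownames(tangent) <- ids
  names(cs) <- ids

  structure(
    list(aligned = aligned, consensus = consensus, centroid_sizes = cs,
         tangent = tangent, iterations = iter, converged = converged,
         residual_history = resid_hist, k = k, d = d),
    class = "gpa_alignment"
  )
}

canonical_rotation <- function(consensus) {
  sv <- svd(consensus)
  V <- sv$v
  for (j in seq_len(ncol(V))) {
    ax <- consensus %*% V[, j]
    if (ax[which.max(abs(ax))] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, ncol(V)] <- -V[, ncol(V)]
  V
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes alignment: %d specimens, %d landmarks in %dD\n",
    nrow(x$aligned), x$k, x$d))
  cat(sprintf("  iterations: %d (%s), final residual SS: %.3g\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              tail(x$residual_history, 1)))
  invisible(x)
}

#' @exportS3Method
tidy.gpa_alignment <- function(x, ...) {
  tibble(
    specimen_id = rownames(x$aligned),
    centroid_size = unname(x$centroid_sizes),
    procrustes_distance = sqrt(rowSums(
      sweep(x$aligned, 2, as.vector(x$consensus))^2))
  )
}

#' @exportS3Method
glance.gpa_alignment <- function(x, ...) {
  tibble(
    n = nrow(x$aligned), k = x$k, d = x$d,
    iterations = x$iterations, converged = x$converged,
    residual_ss = tail(x$residual_history, 1)
  )
}

#' Species-level mean shapes and sizes
#'
#' Averages specimens within species after one joint GPA (so all stages
#' share one coordinate frame): arithmetic means in tangent space, and
#' geometric means of centroid size (sizes averaged on the log scale, then
#' exponentiated). Tree tips index species, while several specimens per
#' species may have been digitized, so this is the bridge from specimens to
#' comparative analyses.
#'
#' @param alignment A [gpa_align()] fit.
#' @param metadata Data frame with `specimen_id` mapped to `species_id`
#'   (a `landmark_tbl` works); optionally a `stage` column.
#' @param stage If non-`NULL`, keep only specimens at this stage; species
#'   with no specimen at the stage are dropped with a warning.
#' @return A tibble of class `species_shapes` with columns `species_id`,
#'   `n_specimens`, `size` and list-column `shape` (tangent row vectors);
#'   use [shape_matrix()] to extract the `n x (k*d)` matrix.
#' @export
species_means <- function(alignment, metadata, stage = NULL) {
  stopifnot(inherits(alignment, "gpa_alignment"))
  md <- as_tibble(metadata)[, intersect(c("specimen_id", "species_id", "stage"),
                                        names(metadata))]
  ids <- rownames(alignment$tangent)
  if (!all(ids %in% md$specimen_id)) {
    abort(sprintf("specimen '%s' is not mapped to a species",
                  setdiff(ids, md$specimen_id)[1]))
  }
  md <- md[match(ids, md$specimen_id), ]
  keep <- rep(TRUE, length(ids))
  if (!is.null(stage)) {
    if (!"stage" %in% names(md)) abort("metadata has no stage column")
    keep <- md$stage == stage
    dropped <- setdiff(unique(md$species_id), unique(md$species_id[keep]))
    if (length(dropped)) {
      warn(sprintf("%d species have no specimen at stage '%s' and are excluded",
                   length(dropped), stage))
    }
  }
  sp <- md$species_id[keep]
  tg <- alignment$tangent[keep, , drop = FALSE]
  sz <- alignment$centroid_sizes[keep]
  usp <- unique(sp)
  shape <- lapply(usp, function(s) colMeans(tg[sp == s, , drop = FALSE]))
  out <- tibble(
    species_id = usp,
    n_specimens = unname(vapply(usp, function(s) sum(sp == s), integer(1))),
    size = unname(vapply(usp, function(s) exp(mean(log(sz[sp == s]))),
                         numeric(1))),
    shape = shape
  )
  attr(out, "k") <- alignment$k
  attr(out, "d") <- alignment$d
  class(out) <- c("species_shapes", class(out))
  out
}

#' Extract a shape matrix from a tibble with a `shape` list-column
#'
#' @param x A tibble with columns `species_id` and `shape` (list of equal
#'   length numeric vectors), e.g. from [species_means()].
#' @return Numeric matrix with one row per species, rownames `species_id`.
#' @export
shape_matrix <- function(x) {
  m <- do.call(rbind, x$shape)
  rownames(m) <- x$species_id
  m
}
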