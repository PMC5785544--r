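#' Landmark configuration tables
#'
#' A landmark table holds one row per specimen with the specimen's landmark
#' configuration stored as a `k x d` coordinate matrix in a list-column.
#' All configurations in one table must share the same number of landmarks
#' `k` and dimensionality `d` (2 or 3); missing (non-finite) coordinates are
#' a hard error, mirroring the practice of excluding structures absent in
#' some lineages rather than imputing them.
#'
#' @param specimen_id Character vector of unique specimen identifiers.
#' @param species_id Character vector mapping specimens to species.
#' @param coords List of `k x d` numeric matrices (landmark coordinates, in
#'   physical length units once any digitizing scale has been applied).
#' @param scale Positive numeric vector of physical-units-per-pixel (or
#'   voxel) factors; recorded, already applied to `coords` when relevant.
#' @param stage Character vector of life stages: `"adult"`, `"juvenile"` or
#'   `"embryo_stage_<S>"` with an integer stage code.
#'
#' @return A tibble of class `landmark_tbl` with columns `specimen_id`,
#'   `species_id`, `stage`, `scale`, `coords`.
#' @export
landmark_tbl <- function(specimen_id, species_id, coords,
                         scale = 1, stage = "adult") {
  if (!is.list(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  out <- tibble(
    specimen_id = as.character(specimen_id),
    species_id  = as.character(species_id),
    stage       = rep_len(as.character(stage), length(coords)),
    scale       = rep_len(as.numeric(scale), length(coords)),
    coords      = coords
  )
  class(out) <- c("landmark_tbl", class(out))
  check_landmark_tbl(out)
  out
}

check_landmark_tbl <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  dims <- vapply(x$coords, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    abort(sprintf(
      "all configurations must share the same landmark count and dimension; specimen '%s' is %dx%d, expected %dx%d",
      x$specimen_id[bad], dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1]
    ))
  }
  if (!dims[2, 1] %in% c(2L, 3L)) {
    abort(sprintf("landmark dimension must be 2 or 3, got %d", dims[2, 1]))
  }
  ok <- vapply(x$coords, function(m) all(is.finite(m)), logical(1))
  if (!all(ok)) {
    abort(sprintf(
      "specimen '%s' has missing or non-finite coordinates; missing landmarks are not supported",
      x$specimen_id[which(!ok)[1]]
    ))
  }
  if (any(!is.finite(x$scale) | x$scale <= 0)) {
    abort("scale factors must be positive and finite")
  }
  if (anyDuplicated(x$specimen_id)) {
    abort(sprintf("duplicated specimen_id '%s'",
                  x$specimen_id[anyDuplicated(x$specimen_id)]))
  }
  invisible(x)
}

#' Number of landmarks and dimension of a landmark table
#' @param x A `landmark_tbl`.
#' @return Integer vector `c(k, d)`.
#' @export
landmark_dim <- function(x) {
  stopifnot(nrow(x) > 0L)
  dim(x$coords[[1]])
}

#' Validate a dataset of landmark configurations plus species metadata
#'
#' Checks the joint invariants of a study dataset: homogeneous landmark
#' configurations, at least 3 specimens (the minimum for a non-degenerate
#' superimposition), every specimen's species present in the metadata, and
#' metadata ecology labels drawn from the five recognised habitat
#' categories (or `NA` for unknown).
#'
#' @param landmarks A `landmark_tbl`.
#' @param metadata A data frame with columns `species_id`, `ecology`,
#'   `clade`, `stage` (only `species_id` and `ecology` are checked).
#' @return `landmarks`, invisibly. Errors name the first violation found.
#' @export
validate_dataset <- function(landmarks, metadata) {
  check_landmark_tbl(landmarks)
  if (nrow(landmarks) < 3L) {
    abort(sprintf("a dataset needs at least 3 configurations, got %d",
                  nrow(landmarks)))
  }
  if (!"species_id" %in% names(metadata)) {
    abort("metadata must have a species_id column")
  }
  missing <- setdiff(unique(landmarks$species_id), metadata$species_id)
  if (length(missing)) {
    abort(sprintf("species '%s' has configurations but no metadata row",
                  missing[1]))
  }
  if ("ecology" %in% names(metadata)) {
    bad <- setdiff(stats::na.omit(unique(metadata$ecology)), ecology_levels())
    if (length(bad)) {
      abort(sprintf(
        "unknown ecology '%s'; must be one of %s (or NA when unknown)",
        bad[1], paste(ecology_levels(), collapse = ", ")
      ))
    }
  }
  invisible(landmarks)
}

#' The five habitat categories
#'
#' Habitat preference simplified into five main categories: aquatic
#' (including marine and semi-aquatic), terrestrial (surface locomotion and
#' foraging), leaf-litter (terrestrial but under vegetation layers or
#' debris), fossorial (living and foraging underground), and arboreal.
#'
#' @return Character vector of the five category names.
#' @export
ecology_levels <- function() {
  c("aquatic", "terrestrial", "leaf_litter", "fossorial", "arboreal")
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks to
#' their centroid -- the standard geometric size measure, used throughout
#' as the proxy for total skull size. Scales linearly under uniform
#' scaling of the configuration.
#'
#' @param config A `k x d` coordinate matrix, or a `landmark_tbl` (in which
#'   case one size per specimen is returned, named by `specimen_id`).
#' @return Positive numeric scalar (or vector for a table input).
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_tbl")) {
    return(setNames(vapply(config$coords, centroid_size, numeric(1)),
                    config$specimen_id))
  }
  m <- as.matrix(config)
  if (nrow(m) < 2L) abort("centroid size needs at least 2 landmarks")
  cen <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(cen^2))
  if (cs <= 0) abort("all landmarks coincide: centroid size is zero")
  cs
}

# internal: stack a list of k x d matrices into an n x (k*d) row matrix,
# vectorizing each configuration column-major (x1..xk, y1..yk, ...)
flatten_configs <- function(coords) {
  do.call(rbind, lapply(coords, as.vector))
}

unflatten_config <- function(v, k, d) {
  matrix(v, nrow = k, ncol = d)
}
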