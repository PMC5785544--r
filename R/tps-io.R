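#' Read a TPS landmark file
#'
#' Parses the flat-file dialect emitted by the tpsDig family of digitizers:
#' records start with `LM=<k>` (2D) or `LM3=<k>` (3D), followed by `k`
#' whitespace-separated coordinate lines, and optional `ID=`, `IMAGE=` and
#' `SCALE=` lines. `ID=` is preferred for the specimen identifier, falling
#' back to `IMAGE=` (extension stripped) and then the record's position in
#' the file.
#'
#' @param path Path to a TPS file.
#' @param scale_policy `"apply"` multiplies each record's coordinates by its
#'   `SCALE=` factor (converting pixels to physical units); `"ignore"`
#'   leaves coordinates as digitized. Records without `SCALE=` get scale 1.
#' @param species_from Optional function mapping a specimen id to a species
#'   id; defaults to the identity (one specimen per species).
#' @return A [landmark_tbl()] with one row per record.
#' @export
read_tps <- function(path, scale_policy = c("apply", "ignore"),
                     species_from = identity) {
  scale_policy <- match.arg(scale_policy)
  if (!file.exists(path)) abort(sprintf("TPS file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lm_at <- grep("^\\s*LM3?=", lines)
  if (!length(lm_at)) {
    return(landmark_tbl(character(), character(), list())[0, ])
  }
  ends <- c(lm_at[-1] - 1L, length(lines))
  recs <- vector("list", length(lm_at))
  k_seen <- NA_integer_
  for (r in seq_along(lm_at)) {
    block <- lines[lm_at[r]:ends[r]]
    header <- block[1]
    d <- if (grepl("^\\s*LM3=", header)) 3L else 2L
    k <- suppressWarnings(as.integer(sub("^\\s*LM3?=\\s*", "", header)))
    if (is.na(k)) {
      abort(sprintf("record %d: cannot parse landmark count from '%s'",
                    r, trimws(header)))
    }
    if (is.na(k_seen)) k_seen <- k
    if (k != k_seen) {
      abort(sprintf(
        "record %d: inconsistent landmark count %d (file uses %d)",
        r, k, k_seen
      ))
    }
    coord_lines <- grep("^\\s*[-+0-9.eE]", block[-1], value = FALSE)
    body <- block[-1]
    is_kv <- grepl("^\\s*[A-Za-z]+\\s*=", body)
    coord_txt <- body[!is_kv & nzchar(trimws(body))]
    if (length(coord_txt) < k) {
      abort(sprintf("record %d: expected %d coordinate lines, found %d",
                    r, k, length(coord_txt)))
    }
    coord_txt <- coord_txt[seq_len(k)]
    vals <- lapply(seq_along(coord_txt), function(i) {
      parts <- strsplit(trimws(coord_txt[i]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(parts))
      if (anyNA(v) || length(v) != d) {
        abort(sprintf(
          "record %d, line %d: non-numeric or malformed coordinate '%s'",
          r, lm_at[r] + i, trimws(coord_txt[i])
        ))
      }
      v
    })
    m <- do.call(rbind, vals)
    kv <- body[is_kv]
    get_kv <- function(key) {
      hit <- grep(paste0("^\\s*", key, "\\s*="), kv, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub("^[^=]*=", "", hit[1]))
    }
    id <- get_kv("ID")
    if (is.na(id) || !nzchar(id)) {
      img <- get_kv("IMAGE")
      id <- if (!is.na(img) && nzchar(img)) sub("\\.[A-Za-z0-9]+$", "", img)
            else sprintf("record_%d", r)
    }
    sc <- suppressWarnings(as.numeric(get_kv("SCALE")))
    if (is.na(sc)) sc <- 1
    if (scale_policy == "apply") m <- m * sc
    recs[[r]] <- list(id = id, coords = m, scale = sc)
  }
  landmark_tbl(
    specimen_id = vapply(recs, `[[`, character(1), "id"),
    species_id  = vapply(recs, function(x) species_from(x$id), character(1)),
    coords      = lapply(recs, `[[`, "coords"),
    scale       = vapply(recs, `[[`, numeric(1), "scale")
  )
}

#' Write landmark configurations to a TPS file
#'
#' Emits one `LM=` (or `LM3=`) record per configuration with full-precision
#' coordinates, an `ID=` line and a `SCALE=` line, so that
#' `read_tps(write_tps(x), scale_policy = "ignore")` reproduces the
#' coordinates exactly.
#'
#' @param landmarks A [landmark_tbl()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  check_landmark_tbl(landmarks)
  if (nrow(landmarks) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  kd <- landmark_dim(landmarks)
  tag <- if (kd[2] == 3L) "LM3=" else "LM="
  out <- unlist(lapply(seq_len(nrow(landmarks)), function(i) {
    m <- landmarks$coords[[i]]
    c(
      paste0(tag, kd[1]),
      apply(m, 1, function(row) {
        paste(formatC(row, format = "g", digits = 17), collapse = " ")
      }),
      paste0("ID=", landmarks$specimen_id[i]),
      paste0("SCALE=", formatC(landmarks$scale[i], format = "g", digits = 17))
    )
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] adding the dataset checks the
#' comparative machinery relies on: labelled, unique tips and branch
#' lengths. Trees without branch lengths get unit lengths with a warning
#' (topology-only analyses remain possible by design).
#'
#' @param path Path to a Newick file holding a single tree, or a Newick
#'   string.
#' @return An [ape::read.tree()] `phylo` object, rooted, with branch
#'   lengths.
#' @export
read_newick <- function(path) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) abort(sprintf("could not parse a Newick tree from %s", path))
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) abort("expected a single tree")
    tr <- tr[[1]]
  }
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)) ||
      anyNA(tr$tip.label)) {
    abort("all tips must be labelled")
  }
  if (anyDuplicated(tr$tip.label)) {
    abort(sprintf("duplicated tip label '%s'",
                  tr$tip.label[anyDuplicated(tr$tip.label)]))
  }
  if (is.null(tr$edge.length)) {
    warn("tree has no branch lengths; setting all branch lengths to 1")
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (any(tr$edge.length < 0)) abort("negative branch lengths")
  if (!ape::is.rooted(tr)) abort("tree must be rooted")
  tr
}

#' Flag shape outliers in a Procrustes alignment
#'
#' Flags specimens whose Procrustes distance to the consensus exceeds
#' `mean + threshold_sd * SD` of all such distances -- the quality-control
#' step used to catch digitizing errors (mirrored, mislabelled or grossly
#' displaced landmarks) before analysis. Specimens are only flagged, never
#' removed.
#'
#' @param alignment A [gpa_align()] fit.
#' @param threshold_sd Positive multiple of the standard deviation.
#' @return Character vector of flagged specimen ids (possibly empty).
#' @export
qc_outliers <- function(alignment, threshold_sd = 3) {
  stopifnot(inherits(alignment, "gpa_alignment"))
  if (threshold_sd < 0) abort("threshold_sd must be non-negative")
  n <- nrow(alignment$aligned)
  if (n < 3L) abort("outlier QC needs at least 3 specimens")
  cons <- as.vector(alignment$consensus)
  d <- sqrt(rowSums(sweep(alignment$aligned, 2, cons)^2))
  cut <- mean(d) + threshold_sd * sd(d)
  names(d)[d > cut]
}
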