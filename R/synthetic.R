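#' Template skull-outline configuration
#'
#' A fixed, elongated egg-shaped outline polygon (snout pointing along
#' +x), centered and scaled to unit centroid size. Synthetic tangent-space
#' deviations are embedded around this template to produce landmark
#' configurations.
#'
#' @param k Number of outline landmarks.
#' @return `k x 2` coordinate matrix.
#' @export
skull_template <- function(k = 20L) {
  t <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  r <- 1 + 0.25 * cos(t)
  m <- cbind(1.6 * r * cos(t), r * sin(t))
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# projection onto the tangent directions at a template: the orthogonal
# complement of translations, rotation and scaling of the template, so
# planted structure survives a Procrustes superimposition
tangent_projector <- function(template) {
  k <- nrow(template); d <- ncol(template)
  stopifnot(d == 2L)
  basis <- cbind(
    c(rep(1, k), rep(0, k)),                  # x translation
    c(rep(0, k), rep(1, k)),                  # y translation
    c(-template[, 2], template[, 1]),         # rotation generator
    as.vector(template)                       # scaling direction
  )
  qb <- qr.Q(qr(basis))
  diag(2 * k) - tcrossprod(qb)
}

#' Define a synthetic study scenario
#'
#' Bundles the parameters of a complete synthetic study: a pure-birth
#' tree (rescaled to unit depth), tip shapes evolving by multivariate
#' Brownian motion in tangent space, habitat classes evolving as a Markov
#' process with class-specific shape shifts, an independently planted
#' convergent fossorial regime in two distant clades (one within each
#' basal half of the tree), a planted allometric component tying shape to
#' log centroid size, non-phylogenetic specimen noise, and paired
#' embryo/adult configurations with group-specific ontogenetic slopes.
#'
#' @param seed Integer seed; the same seed yields a bit-identical study.
#' @param n_tips Number of species.
#' @param k,d Landmarks per configuration and dimensionality.
#' @param bm_sd Brownian-motion tip standard deviation per tangent
#'   coordinate over the unit-depth tree.
#' @param noise_sd Non-phylogenetic per-tip noise standard deviation per
#'   coordinate (drives the phylogenetic signal below the Brownian
#'   expectation of 1, the moderate-signal regime).
#' @param ecology_effect,fossorial_effect Class shift magnitudes as
#'   multiples of the typical Brownian displacement norm
#'   `sqrt(k * d) * bm_sd`; the fossorial shift is shared between the two
#'   planted clades (that sharing is the convergence).
#' @param allometric_fraction Planted percent (in `[0, 100)`) of
#'   contrast-space shape variance explained by log size, relative to the
#'   Brownian + noise variance.
#' @param size_sd Standard deviation of tip log centroid size.
#' @param root_log_size Root log centroid size.
#' @param mk_rate Transition rate of the habitat Markov process among the
#'   four non-fossorial classes.
#' @param fossorial_attraction In `[0, 1)`: strength of an
#'   Ornstein-Uhlenbeck-style pull of the fossorial tips toward the shared
#'   fossorial optimum (their Brownian deviation is shrunk by this factor
#'   before the shared shift is added). 0 (the default) keeps the
#'   analytically transparent fixed-shift regime; values near 1 emulate
#'   selection much stronger than drift, for convergence power studies.
#' @param onto_mode Planted heterochronic mode for the embryo/adult data:
#'   `"acceleration"`, `"hypermorphosis"`, `"predisplacement"`,
#'   `"truncation"` or `"none"`.
#' @param n_onto Species per ontogeny group.
#' @param jitter Re-embed configurations with random rotations,
#'   translations and digitizing scales (exercises the superimposition).
#' @return List of class `synthetic_scenario`.
#' @export
scenario <- function(seed = 1L, n_tips = 300L, k = 20L, d = 2L,
                     bm_sd = 0.01, noise_sd = 0.01,
                     ecology_effect = 1, fossorial_effect = 2.5,
                     allometric_fraction = 6, size_sd = 0.5,
                     root_log_size = log(10), mk_rate = 0.3,
                     fossorial_attraction = 0,
                     onto_mode = "acceleration", n_onto = 15L,
                     jitter = TRUE) {
  if (allometric_fraction >= 100 || allometric_fraction < 0) {
    abort("allometric_fraction must be in [0, 100)")
  }
  structure(
    list(seed = as.integer(seed), n_tips = as.integer(n_tips),
         k = as.integer(k), d = as.integer(d),
         tree_model = "pure_birth",
         bm_sd = bm_sd, noise_sd = noise_sd,
         ecology_effect = ecology_effect,
         fossorial_effect = fossorial_effect,
         allometric_fraction = allometric_fraction,
         size_sd = size_sd, root_log_size = root_log_size,
         mk_rate = mk_rate,
         fossorial_attraction = fossorial_attraction,
         onto_mode = onto_mode,
         n_onto = as.integer(n_onto), jitter = jitter),
    class = "synthetic_scenario"
  )
}

# deterministically pick two disjoint clades of intermediate size, one in
# each basal half of the tree where possible, to host the convergent
# regime. Clades subtended by a very short stem branch are avoided: the
# planted habitat shift happens along the stem, and a crown ancestor
# separated from its non-fossorial relatives by a negligible stem is
# unidentifiable by any reconstruction (inverse-branch-length weighting
# couples it to the parent), which is not the scenario being emulated --
# the motivating case is an ancient shift followed by a crown radiation
pick_fossorial_clades <- function(tree, clade, min_stem_frac = 0.05) {
  n <- length(tree$tip.label)
  lo <- max(3, ceiling(0.04 * n)); hi <- max(4, ceiling(0.15 * n))
  cands <- (n + 2L):(n + tree$Nnode)
  tipsets <- lapply(cands, function(nd) tree$tip.label[clade_tips(tree, nd)])
  sizes <- lengths(tipsets)
  depth <- max(ape::node.depth.edgelength(tree))
  stems <- vapply(cands, function(nd) {
    tree$edge.length[tree$edge[, 2] == nd]
  }, numeric(1))
  ok <- which(sizes >= lo & sizes <= hi & stems >= min_stem_frac * depth)
  if (length(ok) < 2L) {
    ok <- which(sizes >= lo & sizes <= hi)
    ok <- ok[order(-stems[ok])]
  }
  if (length(ok) < 2L) abort("no clades of suitable size for the planted regime")
  in_half <- function(idx, half) {
    vapply(idx, function(i) all(clade[tipsets[[i]]] == half), logical(1))
  }
  first <- ok[in_half(ok, "snake")]
  first <- if (length(first)) first[1] else ok[1]
  rest <- ok[vapply(ok, function(i) {
    !any(tipsets[[i]] %in% tipsets[[first]]) &&
      !any(tipsets[[first]] %in% tipsets[[i]])
  }, logical(1))]
  if (!length(rest)) abort("no disjoint second clade for the planted regime")
  second <- rest[in_half(rest, "lizard")]
  second <- if (length(second)) second[1] else rest[1]
  c(cands[first], cands[second])
}

clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  po <- ape::reorder.phylo(tree, "postorder")
  inside <- rep(FALSE, n + tree$Nnode)
  inside[node] <- TRUE
  for (e in rev(seq_len(nrow(po$edge)))) {
    if (inside[po$edge[e, 1]]) inside[po$edge[e, 2]] <- TRUE
  }
  which(inside[seq_len(n)])
}

clade_nodes <- function(tree, node) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  inside <- rep(FALSE, n + tree$Nnode)
  inside[node] <- TRUE
  for (e in rev(seq_len(nrow(po$edge)))) {
    if (inside[po$edge[e, 1]]) inside[po$edge[e, 2]] <- TRUE
  }
  which(inside)
}

#' Simulate habitat evolution as a continuous-time Markov process
#'
#' Gillespie jumps along each branch from the root state, returning both
#' tip and internal-node states (the truth is never hidden from tests).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param rate_matrix `s x s` generator (rows sum to zero, non-negative
#'   off-diagonals), dimnames giving the state names.
#' @param root_state State name at the root.
#' @param seed Optional integer seed.
#' @return List with `tip_states` (named by tip label) and `node_states`
#'   (named by ape node number).
#' @export
simulate_ecology_mk <- function(tree, rate_matrix, root_state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- as.matrix(rate_matrix)
  states <- rownames(Q) %||% colnames(Q) %||% as.character(seq_len(nrow(Q)))
  dimnames(Q) <- list(states, states)
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) abort("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8 * max(abs(Q), 1))) {
    abort("generator rows must sum to zero")
  }
  n <- length(tree$tip.label)
  lab <- character(n + tree$Nnode)
  lab[n + 1L] <- root_state
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(po$edge)))) {
    s <- lab[po$edge[e, 1]]
    t_left <- po$edge.length[e]
    repeat {
      out_rate <- -Q[s, s]
      if (out_rate <= 0) break
      wait <- rexp(1, out_rate)
      if (wait > t_left) break
      t_left <- t_left - wait
      pr <- Q[s, ]; pr[s] <- 0
      s <- sample(states, 1, prob = pr / sum(pr))
    }
    lab[po$edge[e, 2]] <- s
  }
  list(
    tip_states = setNames(lab[seq_len(n)], tree$tip.label),
    node_states = setNames(lab[(n + 1L):(n + tree$Nnode)],
                           (n + 1L):(n + tree$Nnode))
  )
}

#' Simulate a complete synthetic study
#'
#' Generates the full data structure the pipeline consumes: landmark
#' configurations per species, a time-calibrated tree, species metadata
#' (ecology, clade, stage), paired embryo/adult ontogenies, developmental
#' durations, and the complete generating truth (node states, labels,
#' planted parameters). With `dir` set, everything is also written in the
#' standard external formats (TPS, Newick, CSV).
#'
#' @param scn A [scenario()].
#' @param dir Optional output directory for TPS/Newick/CSV files.
#' @return List of class `synthetic_study`: `landmarks` ([landmark_tbl()]),
#'   `tree`, `metadata`, `ontogeny` ([ontogeny_pairs()]), `durations`,
#'   and `truth` (tip tangent matrix, log sizes, labels, node states and
#'   labels, planted vectors, fossorial clade nodes).
#' @export
simulate_study <- function(scn, dir = NULL) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed)
  n <- scn$n_tips
  q <- scn$k * scn$d
  template <- skull_template(scn$k)
  Pt <- tangent_projector(template)
  proj <- function(v) {
    if (is.matrix(v)) v %*% Pt else drop(Pt %*% v)
  }

  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth

  # basal split defines the two major clades
  root_kids <- tree$edge[tree$edge[, 1] == n + 1L, 2]
  cladeA_tips <- tree$tip.label[clade_tips(tree, root_kids[1])]
  clade <- ifelse(tree$tip.label %in% cladeA_tips, "snake", "lizard")
  names(clade) <- tree$tip.label

  # planted convergent fossorial regime: one clade in each basal half
  foss_nodes <- pick_fossorial_clades(tree, clade)
  foss_tips <- unique(tree$tip.label[unlist(lapply(foss_nodes, clade_tips,
                                                   tree = tree))])
  foss_all_nodes <- unique(unlist(lapply(foss_nodes, clade_nodes, tree = tree)))

  # habitat labels for the rest: Markov process over the four
  # non-fossorial classes, overridden to fossorial inside planted clades
  other <- setdiff(ecology_levels(), "fossorial")
  Qm <- matrix(scn$mk_rate / 3, 4, 4, dimnames = list(other, other))
  diag(Qm) <- -scn$mk_rate
  mk <- simulate_ecology_mk(tree, Qm, root_state = "terrestrial")
  ecology <- mk$tip_states
  ecology[foss_tips] <- "fossorial"
  node_ecology <- mk$node_states
  node_in_foss <- intersect(as.integer(names(node_ecology)), foss_all_nodes)
  node_ecology[as.character(node_in_foss)] <- "fossorial"

  # shape components (all planted vectors live in tangent space)
  bm_rate <- scn$bm_sd^2
  base <- simulate_bm(tree, diag(bm_rate, q), rep(0, q), internal = TRUE)
  tips_bm <- proj(base$tips)
  disp <- sqrt(q) * scn$bm_sd
  shift_vec <- function(effect) {
    v <- proj(rnorm(q))
    v / sqrt(sum(v^2)) * effect * disp
  }
  shifts <- lapply(setNames(ecology_levels(), ecology_levels()), function(e) {
    if (e == "fossorial") shift_vec(scn$fossorial_effect)
    else if (e == "terrestrial") rep(0, q)        # reference class
    else shift_vec(scn$ecology_effect)
  })
  shift_mat <- do.call(rbind, shifts[ecology])
  if (scn$fossorial_attraction > 0) {
    sel <- ecology[tree$tip.label] == "fossorial"
    tips_bm[sel, ] <- (1 - scn$fossorial_attraction) * tips_bm[sel, ]
  }

  log_size <- drop(simulate_bm(tree, scn$size_sd^2, scn$root_log_size))
  noise <- proj(matrix(rnorm(n * q, sd = scn$noise_sd), n, q))
  base_tangent <- tips_bm + shift_mat + noise
  rownames(base_tangent) <- tree$tip.label

  # allometric component scaled so the planted fraction is the stated
  # percent of the realized contrast-space shape variance (whatever the
  # other components happened to contribute)
  f <- scn$allometric_fraction / 100
  beta <- proj(rnorm(q)); beta <- beta / sqrt(sum(beta^2))
  if (f > 0) {
    xc <- drop(pic_contrasts(tree, matrix(log_size, ncol = 1,
                                          dimnames = list(tree$tip.label, NULL))))
    yc <- pic_contrasts(tree, base_tangent)
    b0 <- drop(crossprod(yc, xc)) / sum(xc^2)
    resid_ss <- sum(yc^2) - sum(xc^2) * sum(b0^2)
    beta <- beta * sqrt(f / (1 - f) * resid_ss / sum(xc^2))
  } else {
    beta <- beta * 0
  }
  allo <- tcrossprod(log_size - mean(log_size), beta)
  tangent <- base_tangent + allo
  rownames(tangent) <- tree$tip.label

  # embed as landmark configurations around the template
  coords <- lapply(seq_len(n), function(i) {
    m <- template + unflatten_config(tangent[i, ], scn$k, scn$d)
    m <- sweep(m, 2, colMeans(m))
    m <- m / sqrt(sum(m^2)) * exp(log_size[i])
    if (scn$jitter) {
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      m <- m %*% R + matrix(runif(2, -5, 5), scn$k, 2, byrow = TRUE)
    }
    m
  })
  landmarks <- landmark_tbl(
    specimen_id = tree$tip.label, species_id = tree$tip.label,
    coords = coords, scale = 1, stage = "adult"
  )

  metadata <- tibble(
    species_id = tree$tip.label,
    ecology = unname(ecology[tree$tip.label]),
    clade = unname(clade[tree$tip.label]),
    stage = "adult"
  )

  onto <- simulate_ontogeny(
    mode = scn$onto_mode, n_per_group = scn$n_onto, q = q,
    projector = Pt, seed = NULL
  )

  study <- list(
    landmarks = landmarks, tree = tree, metadata = metadata,
    ontogeny = onto$pairs, durations = onto$durations,
    truth = list(
      tangent = tangent, log_size = log_size,
      ecology = ecology, clade = clade,
      node_ecology = node_ecology,
      node_tangent = base$nodes,
      fossorial_clade_nodes = foss_nodes,
      shifts = shifts, beta = beta,
      onto_truth = onto$truth,
      scenario = scn
    )
  )
  class(study) <- "synthetic_study"
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Simulate paired embryo/adult ontogenies with a planted heterochronic mode
#'
#' Two groups share a common ontogenetic direction; the descendant group's
#' regression against log size is modified according to the planted mode:
#' doubled slope with equal size ranges and durations (acceleration),
#' equal slope extended to 1.5x the maximum size (hypermorphosis), equal
#' slope with the shape shifted along the trajectory (predisplacement), or
#' equal slope truncated at 60 percent of the ancestor's ontogenetic span
#' (truncation, the paedomorphic pattern).
#'
#' @param mode One of `"acceleration"`, `"hypermorphosis"`,
#'   `"predisplacement"`, `"truncation"`, `"none"`.
#' @param n_per_group Species per group.
#' @param q Tangent-space dimensionality.
#' @param slope_norm Ancestor slope magnitude (shape change per unit log
#'   size).
#' @param noise_sd Residual shape noise per coordinate.
#' @param projector Optional `q x q` tangent projector (kept for embedding
#'   consistency with [simulate_study()]).
#' @param groups Names of the ancestor-like and descendant groups.
#' @param seed Optional integer seed.
#' @return List with `pairs` ([ontogeny_pairs()]), `durations` (tibble:
#'   group, duration), and `truth` (slope vectors and mode).
#' @export
simulate_ontogeny <- function(mode = "acceleration", n_per_group = 15L,
                              q = 40L, slope_norm = 0.05, noise_sd = 0.003,
                              projector = NULL, groups = c("lizard", "snake"),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  proj <- function(v) if (is.null(projector)) v else drop(projector %*% v)
  b0 <- proj(rnorm(q)); b0 <- b0 / sqrt(sum(b0^2)) * slope_norm
  slope_mult <- c(1, switch(mode,
    acceleration = 2, hypermorphosis = 1, predisplacement = 1,
    truncation = 1, none = 1))
  shift <- switch(mode, predisplacement = 6 * slope_norm, 0)
  emb_range <- log(c(2.5, 3.5))
  adu_range_anc <- log(c(8, 12))
  adu_range <- list(
    adu_range_anc,
    switch(mode,
      hypermorphosis = log(c(8, 18)),
      truncation = log(c(5, 6.6)),
      adu_range_anc)
  )
  rows <- list()
  durs <- list()
  for (g in 1:2) {
    bg <- b0 * slope_mult[g]
    a0 <- if (g == 2) shift * b0 / slope_norm else rep(0, q)
    x_e <- runif(n_per_group, emb_range[1], emb_range[2])
    x_a <- runif(n_per_group, adu_range[[g]][1], adu_range[[g]][2])
    # anchor: shape at the embryonic mean size is the same for both groups,
    # so slope differences express as divergence toward the adult
    x0 <- mean(emb_range)
    mk_shape <- function(x) {
      lapply(x, function(xx) {
        a0 + bg * (xx - x0) + proj(rnorm(q, sd = noise_sd))
      })
    }
    rows[[g]] <- tibble(
      species_id = sprintf("%s_%02d", groups[g], seq_len(n_per_group)),
      group = groups[g],
      embryo_shape = mk_shape(x_e),
      adult_shape = mk_shape(x_a),
      embryo_size = exp(x_e),
      adult_size = exp(x_a)
    )
    durs[[g]] <- tibble(
      group = groups[g],
      duration = exp(rnorm(n_per_group, log(60), 0.15))
    )
  }
  pairs <- bind_rows(rows)
  class(pairs) <- c("ontogeny_pairs", class(pairs))
  list(
    pairs = pairs,
    durations = bind_rows(durs),
    truth = list(mode = mode, slope_ancestor = b0,
                 slope_descendant = b0 * slope_mult[2], shift = shift)
  )
}

#' Write a synthetic study to disk in the standard external formats
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed): `landmarks.tps`,
#'   `tree.nwk`, `metadata.csv`, `truth_tips.csv`, `truth_nodes.csv`,
#'   `ontogeny_shapes.csv`, `durations.csv`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tps(study$landmarks, file.path(dir, "landmarks.tps"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  write.csv(study$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  tr <- study$truth
  write.csv(
    data.frame(species_id = rownames(tr$tangent),
               ecology = tr$ecology[rownames(tr$tangent)],
               clade = tr$clade[rownames(tr$tangent)],
               log_size = tr$log_size,
               tr$tangent, check.names = FALSE),
    file.path(dir, "truth_tips.csv"), row.names = FALSE
  )
  write.csv(
    data.frame(node = names(tr$node_ecology), ecology = tr$node_ecology),
    file.path(dir, "truth_nodes.csv"), row.names = FALSE
  )
  ont <- study$ontogeny
  emb <- flatten_configs(ont$embryo_shape)
  adu <- flatten_configs(ont$adult_shape)
  colnames(emb) <- colnames(adu) <- paste0("s", seq_len(ncol(emb)))
  write.csv(
    rbind(
      data.frame(species_id = ont$species_id, group = ont$group,
                 stage = "embryo", size = ont$embryo_size, emb,
                 check.names = FALSE),
      data.frame(species_id = ont$species_id, group = ont$group,
                 stage = "adult", size = ont$adult_size, adu,
                 check.names = FALSE)
    ),
    file.path(dir, "ontogeny_shapes.csv"), row.names = FALSE
  )
  write.csv(study$durations, file.path(dir, "durations.csv"), row.names = FALSE)
  invisible(dir)
}
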