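#' Run the full analysis pipeline on a study
#'
#' Orchestrates every stage end-to-end: Procrustes superimposition and
#' outlier QC, species means, morphospace PCA, multivariate phylogenetic
#' signal, ancestral shape and size reconstruction, convergence of the
#' fossorial taxa, ecology MANOVA / phylogenetic MANOVA / discriminant
#' prediction of ancestral habitats (on allometry-uncorrected and
#' -corrected bases), allometry regression, ontogenetic trajectory
#' comparison and heterochrony classification. Writes the CSV and figure
#' interfaces when `out_dir` is given and returns all fitted objects.
#'
#' @param study A [simulate_study()] result, or a list with the same
#'   elements assembled from files ([read_study()]).
#' @param out_dir Optional output directory for CSVs and figures.
#' @param n_perm Permutations for permutation tests.
#' @param n_sim Brownian-motion simulations for simulation-based tests.
#' @param variance_threshold Cumulative variance rule for retaining score
#'   axes in the ecological analyses (default 0.9).
#' @param seed Integer seed controlling every randomized stage.
#' @param quiet Suppress stage progress messages.
#' @return List of class `pipeline_result` with elements `gpa`, `species`,
#'   `space`, `signal`, `ancestors`, `ancestral_sizes`, `convergence`,
#'   `manova`, `phylo_manova`, `lda`, `loo`, `ancestral_ecology`,
#'   `ancestral_ecology_corrected`, `allometry`, `trajectory`,
#'   `heterochrony`, `duration`, `outliers`, `n_axes`.
#' @export
run_pipeline <- function(study, out_dir = NULL, n_perm = 999L,
                         n_sim = 500L, variance_threshold = 0.9,
                         seed = 1L, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  set.seed(seed)
  tree <- study$tree
  md <- study$metadata

  say("GPA: %d specimens", nrow(study$landmarks))
  gpa <- gpa_align(study$landmarks)
  outliers <- qc_outliers(gpa, threshold_sd = 3)
  if (length(outliers)) say("QC flagged %d outlier specimen(s)", length(outliers))
  species <- species_means(gpa, study$landmarks, stage = "adult")

  tangent <- shape_matrix(species)
  sizes <- setNames(species$size, species$species_id)
  say("PCA morphospace on %d species x %d coordinates",
      nrow(tangent), ncol(tangent))
  space <- shape_pca(species)
  n_axes <- axes_for_variance(space, variance_threshold)
  say("retained %d axes (>%.0f%% of variance)", n_axes,
      100 * variance_threshold)

  say("phylogenetic signal (%d permutations)", n_perm)
  signal <- physignal_K(tree, tangent, n_perm = n_perm)

  ancestors <- ancestors_scp(tree, tangent, mode = "weighted")
  ancestral_sizes <- map_size_evolution(tree, sizes)

  focal <- md$species_id[!is.na(md$ecology) & md$ecology == "fossorial"]
  convergence <- NULL
  if (length(focal) >= 2L) {
    say("convergence of %d fossorial taxa (%d BM simulations)",
        length(focal), n_sim)
    convergence <- stayton_C(tree, tangent, focal, n_sim = n_sim)
  }

  scores_all <- score_matrix(space, n_axes)
  labels_all <- setNames(md$ecology, md$species_id)[rownames(scores_all)]
  rare <- names(which(table(labels_all) < 2))
  keep_sp <- !is.na(labels_all) & !labels_all %in% rare
  if (any(!keep_sp)) {
    say("dropping %d species (unknown ecology or class with < 2 members) from group tests",
        sum(!keep_sp))
  }
  scores <- scores_all[keep_sp, , drop = FALSE]
  labels <- labels_all[keep_sp]
  say("ecology tests on %d axes", n_axes)
  mano <- manova_shape_ecology(scores, labels)
  pmano <- phylo_manova(ape::keep.tip(tree, rownames(scores)), scores,
                        labels, n_sim = n_sim)
  lda <- lda_fit(scores, labels)
  loo <- cross_validate(scores, labels)
  anc_scores <- ancestors_scp(tree, scores_all, mode = "weighted")$node_states
  anc_ecol <- predict_ancestral_ecology(lda, anc_scores, basis = "uncorrected")

  say("allometry regression on independent contrasts (%d permutations)",
      n_perm)
  allometry <- allometry_regression(tangent, log(sizes), tree = tree,
                                    n_perm = n_perm)
  corr_space <- shape_pca(allometry$residual_shapes)
  m_corr <- axes_for_variance(corr_space, variance_threshold)
  corr_scores_all <- score_matrix(corr_space, m_corr)
  lda_corr <- lda_fit(corr_scores_all[keep_sp, , drop = FALSE], labels)
  anc_corr <- ancestors_scp(tree, corr_scores_all, mode = "weighted")$node_states
  anc_ecol_corr <- predict_ancestral_ecology(lda_corr, anc_corr,
                                             basis = "allometry_corrected")

  trajectory <- heterochrony <- duration <- NULL
  if (!is.null(study$ontogeny)) {
    say("ontogenetic trajectories and heterochrony")
    trajectory <- trajectory_stats(study$ontogeny, n_perm = n_perm)
    grp <- unique(study$ontogeny$group)
    heterochrony <- heterochrony_regression(
      study$ontogeny, ancestor = grp[1], descendant = grp[2],
      durations = study$durations, n_perm = n_perm
    )
    duration <- duration_anova(study$durations$duration,
                               study$durations$group)
  }

  out <- structure(
    list(gpa = gpa, species = species, space = space, signal = signal,
         ancestors = ancestors, ancestral_sizes = ancestral_sizes,
         convergence = convergence, manova = mano, phylo_manova = pmano,
         lda = lda, loo = loo, ancestral_ecology = anc_ecol,
         ancestral_ecology_corrected = anc_ecol_corr,
         allometry = allometry, trajectory = trajectory,
         heterochrony = heterochrony, duration = duration,
         outliers = outliers, n_axes = n_axes),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, study, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  g <- glance(x$space)
  cat("Pipeline result\n")
  cat(sprintf("  PC1+PC2: %.1f%% of shape variation\n", 100 * g$pc12_fraction))
  cat(sprintf("  phylogenetic signal K = %.3f (p = %.4g)\n",
              x$signal$K, x$signal$p_value))
  if (!is.null(x$convergence)) {
    cat(sprintf("  fossorial convergence C1 = %.3f (p = %.4g)\n",
                x$convergence$C1, x$convergence$p_values["C1"]))
  }
  cat(sprintf("  allometry: %.2f%% (p = %.4g)\n",
              x$allometry$percent_explained, x$allometry$p_value))
  cat(sprintf("  extant LOO accuracy: %.1f%%\n", 100 * x$loo$accuracy))
  if (!is.null(x$heterochrony)) {
    cat(sprintf("  heterochrony: %s (slope ratio %.2f)\n",
                x$heterochrony$classification, x$heterochrony$slope_ratio))
  }
  invisible(x)
}

write_pipeline_outputs <- function(res, study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write.csv(tidy(res$gpa), p("gpa_summary.csv"), row.names = FALSE)
  tg <- shape_matrix(res$species)
  write.csv(data.frame(species_id = rownames(tg),
                       size = res$species$size, tg, check.names = FALSE),
            p("species_tangent.csv"), row.names = FALSE)
  write.csv(tidy(res$space), p("scores.csv"), row.names = FALSE)
  write.csv(data.frame(axis = seq_along(res$space$eigenvalues),
                       eigenvalue = res$space$eigenvalues,
                       variance_fraction = res$space$variance_fraction),
            p("eigenvalues.csv"), row.names = FALSE)
  write.csv(glance(res$signal), p("signal.csv"), row.names = FALSE)
  write.csv(tidy(res$ancestors), p("ancestral_shapes.csv"), row.names = FALSE)
  write.csv(res$ancestral_sizes, p("ancestral_sizes.csv"), row.names = FALSE)
  if (!is.null(res$convergence)) {
    write.csv(tidy(res$convergence), p("convergence.csv"), row.names = FALSE)
  }
  write.csv(cbind(res$manova, phylo_p = res$phylo_manova$p_value),
            p("manova.csv"), row.names = FALSE)
  write.csv(bind_rows(res$ancestral_ecology,
                      res$ancestral_ecology_corrected),
            p("ancestral_ecology.csv"), row.names = FALSE)
  write.csv(glance(res$allometry), p("allometry.csv"), row.names = FALSE)
  if (!is.null(res$trajectory)) {
    write.csv(tidy(res$trajectory), p("trajectory.csv"), row.names = FALSE)
    write.csv(tidy(res$heterochrony), p("heterochrony.csv"), row.names = FALSE)
    write.csv(res$duration, p("duration_anova.csv"), row.names = FALSE)
  }
  # figures
  eco <- study$metadata[, c("species_id", "ecology")]
  names(eco)[1] <- "id"
  ggplot2::ggsave(p("morphospace.png"),
                  plot_phylomorphospace(res$space, study$tree, labels = eco),
                  width = 7, height = 5, dpi = 120)
  rs <- regression_score(shape_matrix(res$species),
                         res$allometry$slope_vector)
  df <- tibble(log_size = log(res$species$size), score = rs)
  ggplot2::ggsave(
    p("allometry_regression.png"),
    ggplot(df, aes(.data$log_size, .data$score)) + geom_point() +
      labs(x = "log centroid size", y = "regression score") + theme_minimal(),
    width = 6, height = 4, dpi = 120
  )
  invisible(out_dir)
}

#' Read a study written by [write_study()] back from disk
#'
#' @param dir Directory holding `landmarks.tps`, `tree.nwk`,
#'   `metadata.csv` and optionally `ontogeny_shapes.csv`/`durations.csv`.
#' @return A list shaped like a [simulate_study()] result (without truth).
#' @export
read_study <- function(dir) {
  landmarks <- read_tps(file.path(dir, "landmarks.tps"))
  tree <- read_newick(file.path(dir, "tree.nwk"))
  metadata <- as_tibble(read.csv(file.path(dir, "metadata.csv")))
  ontogeny <- durations <- NULL
  osf <- file.path(dir, "ontogeny_shapes.csv")
  if (file.exists(osf)) {
    os <- read.csv(osf)
    scol <- grep("^s[0-9]+$", names(os))
    emb <- os[os$stage == "embryo", ]
    adu <- os[os$stage == "adult", ]
    adu <- adu[match(emb$species_id, adu$species_id), ]
    ontogeny <- ontogeny_pairs(
      species_id = emb$species_id, group = emb$group,
      embryo_shape = lapply(seq_len(nrow(emb)),
                            function(i) as.numeric(emb[i, scol])),
      adult_shape = lapply(seq_len(nrow(adu)),
                           function(i) as.numeric(adu[i, scol])),
      embryo_size = emb$size, adult_size = adu$size
    )
  }
  df <- file.path(dir, "durations.csv")
  if (file.exists(df)) durations <- as_tibble(read.csv(df))
  list(landmarks = landmarks, tree = tree, metadata = metadata,
       ontogeny = ontogeny, durations = durations)
}
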