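#' Paired embryo/adult shape observations
#'
#' One row per species: tangent-space shape vectors and centroid sizes for
#' a fixed-stage embryo (stage 10, the late pre-hatchling stage that
#' anchors all trajectories) and an adult, both aligned within one common
#' GPA so that ontogenetic and evolutionary shape changes live in the same
#' coordinate frame.
#'
#' @param species_id Character vector.
#' @param group Clade label per species (e.g. lizard / alethinophidian /
#'   scolecophidian).
#' @param embryo_shape,adult_shape Lists of equal-length numeric tangent
#'   vectors.
#' @param embryo_size,adult_size Positive centroid sizes.
#' @param embryo_stage Integer stage code(s); stages other than 10 are
#'   accepted but flagged as non-comparable with a warning.
#' @return Tibble of class `ontogeny_pairs`.
#' @export
ontogeny_pairs <- function(species_id, group, embryo_shape, adult_shape,
                           embryo_size, adult_size, embryo_stage = 10L) {
  stage <- rep_len(as.integer(embryo_stage), length(species_id))
  if (any(stage != 10L)) {
    warn("embryo stages other than 10 present; trajectories may not be comparable")
  }
  if (any(embryo_size <= 0) || any(adult_size <= 0)) {
    abort("centroid sizes must be positive")
  }
  out <- tibble(
    species_id = as.character(species_id),
    group = as.character(group),
    embryo_shape = embryo_shape,
    adult_shape = adult_shape,
    embryo_size = as.numeric(embryo_size),
    adult_size = as.numeric(adult_size),
    embryo_stage = stage
  )
  class(out) <- c("ontogeny_pairs", class(out))
  out
}

group_trajectories <- function(pairs) {
  gs <- unique(pairs$group)
  emb <- flatten_configs(pairs$embryo_shape)
  adu <- flatten_configs(pairs$adult_shape)
  lapply(setNames(gs, gs), function(g) {
    sel <- pairs$group == g
    v <- colMeans(adu[sel, , drop = FALSE]) - colMeans(emb[sel, , drop = FALSE])
    list(n = sum(sel), vector = v, length = sqrt(sum(v^2)),
         embryo_mean = colMeans(emb[sel, , drop = FALSE]),
         adult_mean = colMeans(adu[sel, , drop = FALSE]))
  })
}

angle_deg <- function(u, v) {
  cc <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cc))) * 180 / pi
}

#' Geometric comparison of ontogenetic shape trajectories
#'
#' Each group's trajectory is the vector from its mean embryo shape to its
#' mean adult shape; the comparison quantifies path length (the vector
#' norm), direction (unit vector) and the pairwise angle between group
#' trajectories. Significance of length differences and angles is by
#' permutation of species (with their embryo/adult pair) across groups,
#' with the `(b + 1) / (m + 1)` convention.
#'
#' @param pairs An [ontogeny_pairs()] table with >= 2 groups, each with
#'   >= 2 species.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Object of class `trajectory_comparison`: `groups` (tibble:
#'   group, n, path_length, direction list-column), `pairwise` (tibble:
#'   group1, group2, angle_deg, length_difference, p_length, p_angle),
#'   `n_perm`.
#' @export
trajectory_stats <- function(pairs, n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_groups(pairs$group)
  trj <- group_trajectories(pairs)
  gs <- names(trj)
  combos <- utils::combn(gs, 2, simplify = FALSE)
  obs <- lapply(combos, function(pr) {
    c(dlen = abs(trj[[pr[1]]]$length - trj[[pr[2]]]$length),
      ang = angle_deg(trj[[pr[1]]]$vector, trj[[pr[2]]]$vector))
  })
  exceed_len <- exceed_ang <- numeric(length(combos))
  for (i in seq_len(n_perm)) {
    pp <- pairs
    pp$group <- sample(pairs$group)
    tp <- group_trajectories(pp)
    for (j in seq_along(combos)) {
      pr <- combos[[j]]
      dl <- abs(tp[[pr[1]]]$length - tp[[pr[2]]]$length)
      an <- angle_deg(tp[[pr[1]]]$vector, tp[[pr[2]]]$vector)
      exceed_len[j] <- exceed_len[j] + (dl >= obs[[j]]["dlen"])
      exceed_ang[j] <- exceed_ang[j] + (an >= obs[[j]]["ang"])
    }
  }
  groups <- tibble(
    group = gs,
    n = vapply(trj, `[[`, numeric(1), "n"),
    path_length = vapply(trj, `[[`, numeric(1), "length"),
    direction = lapply(trj, function(t) t$vector / t$length)
  )
  pairwise <- tibble(
    group1 = vapply(combos, `[`, character(1), 1),
    group2 = vapply(combos, `[`, character(1), 2),
    angle_deg = vapply(obs, `[[`, numeric(1), "ang"),
    length_difference = vapply(obs, `[[`, numeric(1), "dlen"),
    p_length = (exceed_len + 1) / (n_perm + 1),
    p_angle = (exceed_ang + 1) / (n_perm + 1)
  )
  structure(list(groups = groups, pairwise = pairwise, n_perm = n_perm),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat("Ontogenetic trajectory comparison\n")
  print(x$groups[, c("group", "n", "path_length")])
  print(x$pairwise)
  invisible(x)
}

#' @exportS3Method
tidy.trajectory_comparison <- function(x, ...) x$pairwise

# per-group multivariate regression of shape on log size
group_slopes <- function(shape, logsize, group) {
  gs <- unique(group)
  lapply(setNames(gs, gs), function(g) {
    sel <- group == g
    x <- logsize[sel]
    y <- shape[sel, , drop = FALSE]
    if (diff(range(x)) <= 0) abort(sprintf("group '%s' has a degenerate size range", g))
    xc <- x - mean(x)
    b <- drop(crossprod(y, xc)) / sum(xc^2)
    a <- colMeans(y) - b * mean(x)
    list(slope = b, intercept = a, magnitude = sqrt(sum(b^2)),
         n = sum(sel), min_size = min(x), max_size = max(x))
  })
}

#' Heterochrony analysis by multivariate regression of shape on log size
#'
#' Regresses shape on log centroid size (a proxy for developmental time)
#' separately in an ancestor-like and a descendant group, then classifies
#' the global heterochronic mode from the regression geometry and,
#' optionally, developmental durations:
#' \itemize{
#'   \item acceleration -- descendant slope magnitude significantly larger
#'     (one-sided residual-randomization permutation test) with
#'     statistically indistinguishable developmental duration;
#'   \item hypermorphosis -- indistinguishable slopes, descendant extending
#'     to larger size (or significantly longer duration);
#'   \item predisplacement -- indistinguishable slopes and ranges, but the
#'     descendant shifted along the common trajectory direction;
#'   \item paedomorphic_pattern -- the descendant's adult mean lies within
#'     the ancestor's ontogenetic segment (trajectory truncation);
#'   \item none -- no gate met.
#' }
#'
#' @param pairs An [ontogeny_pairs()] table (embryos and adults expanded
#'   internally into one observation each).
#' @param ancestor,descendant Group labels in `pairs$group` playing the
#'   ancestor-like and descendant roles.
#' @param durations Optional data frame with columns `group` and
#'   `duration` (days of embryonic development) fed to [duration_anova()].
#' @param n_perm Permutations for the slope and shift tests.
#' @param alpha Significance level for the classification gates. The
#'   default is 0.01: each negative gate (e.g. "durations
#'   indistinguishable") carries its own type-I error, which at 0.05 would
#'   cap attainable classification accuracy at about 95 percent even for
#'   arbitrarily strong planted effects; 0.01 keeps gate errors well below
#'   effect-driven errors while strong effects still clear the positive
#'   gates comfortably.
#' @param seed Optional integer seed.
#' @return Object of class `heterochrony_result`: per-group `slopes`
#'   (slope vector, magnitude, intercept, size range), `slope_angle_deg`,
#'   `slope_ratio`, `p_slope`, `p_shift`, `duration_stats`,
#'   `classification`, and the `evidence` tibble making the label
#'   auditable.
#' @export
heterochrony_regression <- function(pairs, ancestor, descendant,
                                    durations = NULL, n_perm = 1000L,
                                    alpha = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c(ancestor, descendant) %in% pairs$group))
  keep <- pairs$group %in% c(ancestor, descendant)
  pairs <- pairs[keep, ]
  shape <- rbind(flatten_configs(pairs$embryo_shape),
                 flatten_configs(pairs$adult_shape))
  logsize <- c(log(pairs$embryo_size), log(pairs$adult_size))
  group <- rep(pairs$group, 2)

  sl <- group_slopes(shape, logsize, group)
  b_a <- sl[[ancestor]]; b_d <- sl[[descendant]]
  slope_angle <- angle_deg(b_a$slope, b_d$slope)
  slope_ratio <- b_d$magnitude / b_a$magnitude

  # residual randomization under the null of a common slope (group
  # intercepts retained): permuting those residuals preserves everything
  # except a group difference in slope
  gfac <- factor(group)
  xc_by_g <- logsize - ave(logsize, gfac)
  fit_common_b <- drop(crossprod(shape, xc_by_g)) / sum(xc_by_g^2)
  fitted_null <- matrix(ave(shape[, 1], gfac), nrow(shape), ncol(shape))
  for (j in seq_len(ncol(shape))) fitted_null[, j] <- ave(shape[, j], gfac)
  fitted_null <- fitted_null + tcrossprod(xc_by_g, fit_common_b)
  resid_null <- shape - fitted_null

  stat_obs <- b_d$magnitude - b_a$magnitude
  exceed <- 0
  for (i in seq_len(n_perm)) {
    ys <- fitted_null + resid_null[sample.int(nrow(shape)), , drop = FALSE]
    sp <- group_slopes(ys, logsize, group)
    exceed <- exceed +
      ((sp[[descendant]]$magnitude - sp[[ancestor]]$magnitude) >= stat_obs)
  }
  p_slope <- (exceed + 1) / (n_perm + 1)

  # shift along the common trajectory direction at the grand mean size
  u <- fit_common_b / sqrt(sum(fit_common_b^2))
  xbar <- mean(logsize)
  at_mean <- function(s) s$intercept + s$slope * xbar
  shift_obs <- sum((at_mean(b_d) - at_mean(b_a)) * u)
  fitted_flat <- tcrossprod(logsize - xbar, fit_common_b) +
    matrix(colMeans(shape), nrow(shape), ncol(shape), byrow = TRUE)
  resid_flat <- shape - fitted_flat
  exceed_s <- 0
  for (i in seq_len(n_perm)) {
    ys <- fitted_flat + resid_flat[sample.int(nrow(shape)), , drop = FALSE]
    sp <- group_slopes(ys, logsize, group)
    sh <- sum((at_mean(sp[[descendant]]) - at_mean(sp[[ancestor]])) * u)
    exceed_s <- exceed_s + (abs(sh) >= abs(shift_obs))
  }
  p_shift <- (exceed_s + 1) / (n_perm + 1)

  dur <- if (!is.null(durations)) {
    duration_anova(durations$duration, durations$group)
  } else NULL

  # truncation: project the descendant adult mean onto the ancestor's
  # ontogenetic segment (embryo mean -> adult mean)
  emb <- flatten_configs(pairs$embryo_shape)
  adu <- flatten_configs(pairs$adult_shape)
  sel_a <- pairs$group == ancestor
  sel_d <- pairs$group == descendant
  v <- colMeans(adu[sel_a, , drop = FALSE]) - colMeans(emb[sel_a, , drop = FALSE])
  tpar <- sum((colMeans(adu[sel_d, , drop = FALSE]) -
                 colMeans(emb[sel_a, , drop = FALSE])) * v) / sum(v^2)

  extension <- b_d$max_size > b_a$max_size + log(1.1) ||
    (!is.null(dur) && dur$p_value <= alpha &&
       mean(durations$duration[durations$group == descendant]) >
         mean(durations$duration[durations$group == ancestor]))
  truncated <- tpar > 0 && tpar < 0.95 && b_d$max_size < b_a$max_size

  classification <- if (p_slope <= alpha && slope_ratio > 1 &&
                        (is.null(dur) || dur$p_value > alpha)) {
    "acceleration"
  } else if (p_slope > alpha && truncated) {
    "paedomorphic_pattern"
  } else if (p_slope > alpha && extension) {
    "hypermorphosis"
  } else if (p_slope > alpha && p_shift <= alpha) {
    "predisplacement"
  } else {
    "none"
  }

  evidence <- tibble(
    statistic = c("slope_magnitude_ancestor", "slope_magnitude_descendant",
                  "slope_ratio", "slope_angle_deg", "p_slope",
                  "trajectory_shift", "p_shift", "truncation_parameter",
                  "max_log_size_ancestor", "max_log_size_descendant",
                  "duration_F", "duration_p"),
    value = c(b_a$magnitude, b_d$magnitude, slope_ratio, slope_angle,
              p_slope, shift_obs, p_shift, tpar, b_a$max_size, b_d$max_size,
              if (is.null(dur)) NA_real_ else dur$f_statistic,
              if (is.null(dur)) NA_real_ else dur$p_value)
  )

  structure(
    list(slopes = sl, slope_angle_deg = slope_angle,
         slope_ratio = slope_ratio, p_slope = p_slope, p_shift = p_shift,
         duration_stats = dur, truncation_parameter = tpar,
         classification = classification, evidence = evidence,
         ancestor = ancestor, descendant = descendant, alpha = alpha,
         n_perm = n_perm),
    class = "heterochrony_result"
  )
}

#' @export
print.heterochrony_result <- function(x, ...) {
  cat(sprintf(
    "Heterochrony (%s vs %s): slope ratio %.2f (p = %.4g), angle %.1f deg\n",
    x$descendant, x$ancestor, x$slope_ratio, x$p_slope, x$slope_angle_deg))
  cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

#' @exportS3Method
tidy.heterochrony_result <- function(x, ...) x$evidence

#' @exportS3Method
glance.heterochrony_result <- function(x, ...) {
  tibble(classification = x$classification, slope_ratio = x$slope_ratio,
         p_slope = x$p_slope, p_shift = x$p_shift,
         slope_angle_deg = x$slope_angle_deg)
}

#' One-way ANOVA of developmental durations
#'
#' Compares total duration of embryonic development (incubation or
#' gestation, days) across groups; feeds the acceleration-vs-hypermorphosis
#' gate of the heterochrony classification.
#'
#' @param durations Numeric vector of durations.
#' @param labels Group labels (>= 2 groups, each >= 2 species).
#' @param log_scale Analyse log durations.
#' @return Tibble with `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
duration_anova <- function(durations, labels, log_scale = FALSE) {
  labels <- check_groups(labels)
  y <- if (log_scale) log(durations) else durations
  s <- summary(aov(y ~ labels))[[1]]
  tibble(f_statistic = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
         p_value = s$`Pr(>F)`[1])
}
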