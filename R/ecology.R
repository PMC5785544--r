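#' Wilks' lambda for a one-way multivariate layout
#'
#' `det(W) / det(T)` with `W` the within-group and `T` the total
#' cross-product matrix; small values indicate strong group separation.
#' Exposed because the phylogenetic MANOVA recomputes it for every
#' Brownian-motion simulation.
#'
#' @param scores `n x m` numeric matrix.
#' @param labels Factor (or coercible) of group labels, length `n`.
#' @return Numeric scalar in (0, 1].
#' @export
wilks_lambda <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  tc <- sweep(scores, 2, colMeans(scores))
  Tm <- crossprod(tc)
  Wm <- matrix(0, ncol(scores), ncol(scores))
  for (g in levels(labels)) {
    xg <- scores[labels == g, , drop = FALSE]
    wc <- sweep(xg, 2, colMeans(xg))
    Wm <- Wm + crossprod(wc)
  }
  det(Wm) / det(Tm)
}

check_groups <- function(labels, min_size = 2L) {
  labels <- factor(labels)
  tabs <- table(labels)
  if (length(tabs) < 2L) abort("need at least 2 groups")
  small <- names(tabs)[tabs < min_size]
  if (length(small)) {
    abort(sprintf("group '%s' has fewer than %d members", small[1], min_size))
  }
  labels
}

#' MANOVA of shape scores on ecology
#'
#' Standard one-way MANOVA (Wilks' lambda with its F approximation) of
#' morphospace scores on habitat category.
#'
#' @param scores `n x m` score matrix (rows named consistently with
#'   `labels` order).
#' @param labels Group labels, length `n`.
#' @return Tibble with `wilks`, `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
manova_shape_ecology <- function(scores, labels) {
  labels <- check_groups(labels)
  scores <- as.matrix(scores)
  fit <- manova(scores ~ labels)
  tab <- summary(fit, test = "Wilks")$stats
  tibble(
    wilks = tab[1, "Wilks"],
    f_statistic = tab[1, "approx F"],
    df1 = tab[1, "num Df"],
    df2 = tab[1, "den Df"],
    p_value = tab[1, "Pr(>F)"]
  )
}

#' Phylogenetic MANOVA by Brownian-motion simulation
#'
#' Compares the observed Wilks' lambda against the null distribution of
#' Wilks' lambda computed on datasets simulated under multivariate
#' Brownian motion along the tree (rate matrix estimated from the data via
#' independent contrasts), with the group labels held fixed. Closely
#' related species share both ancestry and, often, habitat, so an ordinary
#' MANOVA overstates the evidence that ecology structures shape; the
#' simulation null absorbs the separation expected from phylogeny alone.
#'
#' @param tree Rooted `phylo`.
#' @param scores `n x m` score matrix, rows named by tip label.
#' @param labels Named (or tip-ordered) group labels.
#' @param n_sim Number of Brownian-motion simulations (must be positive).
#' @param seed Optional integer seed.
#' @return Tibble with `wilks`, `p_value` (simulation-based,
#'   `(b + 1) / (n_sim + 1)`), `p_value_standard` (ordinary MANOVA), and
#'   `n_sim`.
#' @export
phylo_manova <- function(tree, scores, labels, n_sim = 1000L, seed = NULL) {
  if (n_sim < 1L) abort("n_sim must be positive")
  if (!is.null(seed)) set.seed(seed)
  tree <- resolve_tree(tree)
  scores <- match_tips(tree, scores)
  if (!is.null(names(labels))) labels <- labels[tree$tip.label]
  labels <- check_groups(labels)
  obs <- wilks_lambda(scores, labels)
  rate <- evol_rate_matrix(tree, scores)
  sims <- vapply(seq_len(n_sim), function(i) {
    wilks_lambda(simulate_bm(tree, rate), labels)
  }, numeric(1))
  std <- manova_shape_ecology(scores, labels)
  tibble(
    wilks = obs,
    p_value = (sum(sims <= obs) + 1) / (n_sim + 1),
    p_value_standard = std$p_value,
    n_sim = n_sim
  )
}

#' Per-axis ANOVAs with post hoc pairwise comparisons
#'
#' One-way ANOVA of each score axis on the group labels, followed by
#' permutation tests on all pairwise group mean differences with Holm
#' correction (a conservative default; the choice of correction is
#' recorded in the output).
#'
#' @param scores `n x m` score matrix.
#' @param labels Group labels.
#' @param n_perm Permutations for the pairwise tests.
#' @param seed Optional integer seed.
#' @return List with `anova` (tibble: axis, f_statistic, p_value) and
#'   `pairwise` (tibble: axis, group1, group2, difference, p_value,
#'   p_adjusted).
#' @export
anova_posthoc <- function(scores, labels, n_perm = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- check_groups(labels)
  scores <- as.matrix(scores)
  axes <- colnames(scores) %||% paste0("axis", seq_len(ncol(scores)))
  an <- lapply(seq_len(ncol(scores)), function(j) {
    fit <- aov(scores[, j] ~ labels)
    s <- summary(fit)[[1]]
    tibble(axis = axes[j], f_statistic = s$`F value`[1],
           p_value = s$`Pr(>F)`[1])
  })
  pairs <- utils::combn(levels(labels), 2, simplify = FALSE)
  pw <- lapply(seq_len(ncol(scores)), function(j) {
    v <- scores[, j]
    rows <- lapply(pairs, function(pr) {
      sel <- labels %in% pr
      vv <- v[sel]; ll <- droplevels(labels[sel])
      obs <- abs(diff(tapply(vv, ll, mean)))
      perm <- vapply(seq_len(n_perm), function(i) {
        lp <- sample(ll)
        abs(diff(tapply(vv, lp, mean)))
      }, numeric(1))
      tibble(axis = axes[j], group1 = pr[1], group2 = pr[2],
             difference = unname(obs),
             p_value = (sum(perm >= obs) + 1) / (n_perm + 1))
    })
    bind_rows(rows)
  })
  pw <- bind_rows(pw)
  pw <- pw |> group_by(.data$axis) |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = "holm")) |>
    ungroup()
  list(anova = bind_rows(an), pairwise = pw)
}

#' Fit a linear discriminant model of habitat on shape scores
#'
#' Gaussian equal-covariance discriminant model: class means, pooled
#' within-class covariance, and priors, yielding class posterior
#' probabilities for new score vectors. If the pooled covariance is
#' near-singular (condition number above 1e10) it is shrunk toward the
#' identity scaled by `1e-6 * trace / m`, and this is reported.
#'
#' @param scores `n x m` score matrix.
#' @param labels Class labels (>= 2 classes, each with >= 2 members).
#' @param prior_policy `"proportional"` (class frequencies; the common
#'   default of the field's toolchain) or `"uniform"`.
#' @return Object of class `discriminant_model`: `class_means`,
#'   `pooled_covariance`, `priors`, `discriminant_axes`, `regularized`,
#'   `m`.
#' @export
lda_fit <- function(scores, labels, prior_policy = c("proportional", "uniform")) {
  prior_policy <- match.arg(prior_policy)
  labels <- check_groups(labels)
  scores <- as.matrix(scores)
  m <- ncol(scores)
  g <- nlevels(labels)
  mus <- matrix(0, g, m, dimnames = list(levels(labels), colnames(scores)))
  for (l in levels(labels)) {
    mus[l, ] <- colMeans(scores[labels == l, , drop = FALSE])
  }
  Wm <- matrix(0, m, m)
  for (l in levels(labels)) {
    xc <- sweep(scores[labels == l, , drop = FALSE], 2, mus[l, ])
    Wm <- Wm + crossprod(xc)
  }
  Wm <- Wm / (nrow(scores) - g)
  regularized <- FALSE
  if (kappa(Wm, exact = FALSE) > 1e10) {
    Wm <- Wm + diag(1e-6 * sum(diag(Wm)) / m, m)
    regularized <- TRUE
    inform("pooled within-class covariance near singular; shrunk toward diagonal")
  }
  invW <- tryCatch(solve(Wm), error = function(e) {
    abort("singular pooled covariance even after regularization; retain fewer axes")
  })
  priors <- switch(prior_policy,
    proportional = as.numeric(table(labels)) / length(labels),
    uniform = rep(1 / g, g)
  )
  names(priors) <- levels(labels)
  # between-class structure for discriminant axes (at most g - 1)
  grand <- colMeans(scores)
  Bm <- matrix(0, m, m)
  for (i in seq_len(g)) {
    dmu <- mus[i, ] - grand
    Bm <- Bm + priors[i] * tcrossprod(dmu)
  }
  ei <- eigen(invW %*% Bm)
  n_axes <- min(g - 1L, m)
  axes <- Re(ei$vectors[, seq_len(n_axes), drop = FALSE])
  structure(
    list(class_means = mus, pooled_covariance = Wm, inv_covariance = invW,
         priors = priors, discriminant_axes = axes,
         regularized = regularized, m = m),
    class = "discriminant_model"
  )
}

#' Posterior class probabilities from a discriminant model
#'
#' @param object A [lda_fit()] model.
#' @param newdata `n x m` score matrix in the same axis basis as training.
#' @param ... Unused.
#' @return Tibble with `id`, one posterior column per class, and
#'   `predicted_class` (the argmax). Posteriors sum to 1 per row.
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$m) {
    abort(sprintf("basis mismatch: model trained on %d axes, data has %d",
                  object$m, ncol(x)))
  }
  classes <- rownames(object$class_means)
  lp <- vapply(seq_along(classes), function(i) {
    dx <- sweep(x, 2, object$class_means[i, ])
    -0.5 * rowSums((dx %*% object$inv_covariance) * dx) +
      log(object$priors[i])
  }, numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x))
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp) / rowSums(exp(lp))
  colnames(post) <- classes
  out <- tibble(
    id = rownames(x) %||% as.character(seq_len(nrow(x))),
    as_tibble(post),
    predicted_class = classes[max.col(post, ties.method = "first")]
  )
  out
}

#' Leave-one-out cross-validation of the discriminant model
#'
#' @param scores `n x m` score matrix.
#' @param labels Class labels.
#' @param prior_policy Passed to [lda_fit()].
#' @return List with `accuracy` and `confusion` (rows = true class,
#'   columns = predicted; rows sum to class counts).
#' @export
cross_validate <- function(scores, labels,
                           prior_policy = c("proportional", "uniform")) {
  prior_policy <- match.arg(prior_policy)
  labels <- check_groups(labels)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- lda_fit(scores[-i, , drop = FALSE], droplevels(labels[-i]),
                   prior_policy = prior_policy)
    pred[i] <- predict(fit, scores[i, , drop = FALSE])$predicted_class
  }
  conf <- table(true = labels, predicted = factor(pred, levels = levels(labels)))
  list(accuracy = mean(pred == as.character(labels)), confusion = conf)
}

#' Predict ancestral habitat categories from reconstructed shape scores
#'
#' Applies a discriminant model trained on extant species to
#' squared-change-parsimony ancestral score estimates, yielding a posterior
#' probability over the habitat categories for every internal node. Run on
#' both allometry-uncorrected and allometry-corrected bases to check
#' robustness of the inferred ancestral ecology.
#'
#' @param model A [lda_fit()] model trained on extant scores.
#' @param ancestral_scores `Nnode x m` matrix of ancestral score estimates
#'   (e.g. `ancestors_scp(tree, scores)$node_states`), rows named by node.
#' @param basis Label recorded in the output (`"uncorrected"` or
#'   `"allometry_corrected"`).
#' @return Tibble with `node`, `basis`, per-class posterior columns and
#'   `predicted_class`.
#' @export
predict_ancestral_ecology <- function(model, ancestral_scores,
                                      basis = c("uncorrected",
                                                "allometry_corrected")) {
  basis <- match.arg(basis)
  out <- predict(model, ancestral_scores)
  names(out)[1] <- "node"
  mutate(out, basis = basis, .after = "node")
}
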