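#' Principal component analysis of an autoscaled abundance matrix
#'
#' Full singular-value decomposition of the (already column-standardized)
#' square-root autoscaled species matrix, with components ordered by decreasing
#' variance and a deterministic sign convention: each loading column's
#' largest-magnitude entry is positive. The transform tag is enforced because
#' the angular statistic is defined on this specific input scale.
#'
#' @param X a [transformed_matrix] with tag `"sqrt_autoscaled"`.
#' @return list of class `pca_model`: `loadings` (features x components,
#'   orthonormal columns), `scores` (samples x components), `explained_variance`
#'   (per component, n-1 convention), `center` (column means removed, here ~0).
#' @export
pca_fit <- function(X) {
  require_transform(X, "sqrt_autoscaled")
  M <- unclass(X)
  center <- colMeans(M)
  Mc <- sweep(M, 2, center)
  sv <- svd(Mc)
  ncomp <- sum(sv$d > max(dim(Mc)) * .Machine$double.eps * max(sv$d, 1))
  d <- sv$d[seq_len(ncomp)]
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  # deterministic signs: largest-|entry| of each loading column positive
  flip <- vapply(seq_len(ncomp), function(j) {
    i <- which.max(abs(V[, j]))
    sign(V[i, j])
  }, 1)
  flip[flip == 0] <- 1
  V <- sweep(V, 2, flip, "*")
  U <- sweep(U, 2, flip, "*")
  scores <- U %*% diag(d, ncomp)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncomp))
  rownames(scores) <- rownames(M)
  rownames(V) <- colnames(M)
  structure(list(loadings = V, scores = scores,
                 explained_variance = d^2 / (nrow(M) - 1), center = center),
            class = "pca_model")
}

#' Screen principal components against a binary outcome
#'
#' Fits one univariate logistic regression per principal component
#' (outcome ~ PC score) and keeps components with a two-sided Wald p below
#' `alpha`. If the fit warns of separation / non-convergence, the
#' likelihood-ratio p is used instead and the component is flagged.
#'
#' @param model a `pca_model` from [pca_fit()].
#' @param outcome 0/1 vector per sample (both classes must be present).
#' @param alpha significance level (unadjusted, per screening convention).
#' @return list: `significant_pcs` (integer indices), `screening_table`
#'   (data.frame pc, coefficient, p, flagged).
#' @export
screen_pcs <- function(model, outcome, alpha = 0.05) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2) stop("screening outcome must contain both classes")
  ncomp <- ncol(model$scores)
  res <- lapply(seq_len(ncomp), function(j) {
    s <- model$scores[, j]
    flagged <- FALSE
    fit <- withCallingHandlers(
      stats::glm(outcome ~ s, family = stats::binomial()),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (flagged) {
      # separation or non-convergence: fall back to the likelihood-ratio test
      null <- stats::glm(outcome ~ 1, family = stats::binomial())
      p <- stats::pchisq(null$deviance - fit$deviance, df = 1, lower.tail = FALSE)
    } else {
      p <- summary(fit)$coefficients["s", "Pr(>|z|)"]
    }
    data.frame(pc = j, coefficient = unname(stats::coef(fit)["s"]),
               p = p, flagged = flagged)
  })
  tab <- do.call(rbind, res)
  list(significant_pcs = tab$pc[tab$p < alpha], screening_table = tab)
}

#' Cohort centroids in a score subspace
#'
#' @param scores samples x components score matrix (restricted to the screened
#'   components).
#' @param cohorts cohort label per sample.
#' @param min_n minimum cohort size (default 3).
#' @return matrix of centroids, one row per cohort.
#' @export
cohort_centroid <- function(scores, cohorts, min_n = 3) {
  scores <- as.matrix(scores)
  f <- factor(cohorts)
  sizes <- table(f)
  small <- names(sizes)[sizes < min_n]
  if (length(small))
    stop("cohort(s) below the minimum of ", min_n, " samples: ",
         paste(small, collapse = ", "))
  cent <- t(vapply(levels(f), function(lev)
    colMeans(scores[f == lev, , drop = FALSE]), numeric(ncol(scores))))
  if (ncol(scores) == 1) cent <- matrix(cent, ncol = 1, dimnames = list(levels(f), NULL))
  cent
}

#' Angle between two centroid vectors
#'
#' Arccosine of the (clipped) cosine similarity, in degrees within
#' `[0, 180]`. Centroids indistinct from the origin carry no direction.
#'
#' @param u,v numeric vectors of equal length.
#' @param tol norm tolerance, default `1e-8 * sqrt(length(u))`.
#' @return angle in degrees.
#' @export
angle_between <- function(u, v, tol = 1e-8 * sqrt(length(u))) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= tol || nv <= tol) stop("centroid indistinct from origin")
  cs <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cs))) * 180 / pi
}

#' Interpret a mean centroid angle
#'
#' Maps a mean angle to a qualitative band: below the first boundary the two
#' cohorts have a similar composition, between the boundaries they are
#' dissimilar/uncorrelated (orthogonal near 90 degrees), above the second they
#' are inversely correlated. The boundaries operationalize a deliberately
#' coarse reading of cosine similarity and are configurable.
#'
#' @param mean_angle degrees in `[0, 180]`.
#' @param bands two increasing boundaries in degrees, default `c(60, 120)`.
#' @return character interpretation.
#' @export
interpret_angle <- function(mean_angle, bands = c(60, 120)) {
  stopifnot(length(bands) == 2, bands[1] < bands[2])
  ifelse(mean_angle < bands[1], "similar composition",
         ifelse(mean_angle < bands[2], "dissimilar composition",
                "inversely correlated"))
}

#' Bootstrap cohort-centroid angles in the screened PC subspace
#'
#' The core cohort-geometry statistic. PCA and the GLM screen are fit once on
#' the full data; each bootstrap iteration resamples samples with replacement
#' within each cohort (stratified), recomputes all cohort centroids on the
#' screened principal components, and records every pairwise centroid angle.
#' Per pair, the mean and SD over iterations are reported together with an
#' interpretation band of the mean. The screening outcome is membership of
#' `reference_cohort` versus all other samples.
#'
#' Holding the subspace fixed keeps angles commensurable across iterations; a
#' sensitivity variant that refits the PCA within each iteration (with sign
#' alignment of the loadings to the full-data fit) is available via
#' `refit_pca_per_iteration`.
#'
#' @param X [transformed_matrix] with tag `"sqrt_autoscaled"` (species level).
#' @param metadata aligned `sample_metadata` (row order matching `X`).
#' @param reference_cohort cohort label serving as the screening outcome and
#'   the 0-degree axis of the protractor display.
#' @param n_iter bootstrap iterations (default 500).
#' @param alpha screening significance level.
#' @param seed integer seed.
#' @param bands interpretation band boundaries in degrees.
#' @param min_n minimum samples per cohort.
#' @param refit_pca_per_iteration logical; refit PCA within each resample.
#' @param max_redraws resamples yielding a near-zero centroid are redrawn at
#'   most this many times per iteration.
#' @return list of class `angular_result`: `significant_pcs`,
#'   `screening_table`, `pairs` (data.frame cohort_a, cohort_b, mean_angle,
#'   sd_angle, interpretation), `iterations` (matrix n_iter x pairs),
#'   `plugin_angles` (full-data angles), `reference_cohort`.
#' @export
bootstrap_angles <- function(X, metadata, reference_cohort, n_iter = 500,
                             alpha = 0.05, seed = NULL, bands = c(60, 120),
                             min_n = 3, refit_pca_per_iteration = FALSE,
                             max_redraws = 100) {
  require_transform(X, "sqrt_autoscaled")
  cohorts <- as.character(metadata$cohort)
  if (!reference_cohort %in% cohorts)
    stop("reference cohort '", reference_cohort, "' not present")
  sizes <- table(cohorts)
  small <- names(sizes)[sizes < min_n]
  if (length(small))
    stop("cohort(s) with fewer than ", min_n, " samples: ",
         paste(small, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  model <- pca_fit(X)
  outcome <- as.integer(cohorts == reference_cohort)
  scr <- screen_pcs(model, outcome, alpha = alpha)
  if (!length(scr$significant_pcs))
    stop("no principal components passed screening at alpha = ", alpha,
         "; the angular statistic has no subspace to work in")
  S <- model$scores[, scr$significant_pcs, drop = FALSE]

  levs <- sort(unique(cohorts))
  idx_by <- split(seq_along(cohorts), cohorts)
  prs <- utils::combn(levs, 2)
  pair_names <- paste(prs[1, ], prs[2, ], sep = " vs ")

  plugin_cent <- cohort_centroid(S, cohorts, min_n = min_n)
  plugin <- vapply(seq_len(ncol(prs)), function(i)
    angle_between(plugin_cent[prs[1, i], ], plugin_cent[prs[2, i], ]), 1)
  names(plugin) <- pair_names

  angles <- matrix(NA_real_, n_iter, ncol(prs),
                   dimnames = list(NULL, pair_names))
  tol <- 1e-8 * sqrt(ncol(S))
  for (it in seq_len(n_iter)) {
    for (redraw in seq_len(max_redraws + 1)) {
      take <- unlist(lapply(idx_by, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]), use.names = FALSE)
      Sb <- if (refit_pca_per_iteration) {
        mb <- pca_fit(sqrt_autoscale(transformed_matrix(unclass(X)[take, , drop = FALSE],
                                                        "sqrt_autoscaled")))
        # align the refit loadings' signs to the full-data fit
        ncmp <- min(ncol(mb$loadings), ncol(model$loadings))
        al <- sign(colSums(mb$loadings[, seq_len(ncmp), drop = FALSE] *
                             model$loadings[, seq_len(ncmp), drop = FALSE]))
        al[al == 0] <- 1
        keep <- intersect(scr$significant_pcs, seq_len(ncmp))
        sweep(mb$scores[, keep, drop = FALSE], 2, al[keep], "*")
      } else S[take, , drop = FALSE]
      cb <- cohort_centroid(Sb, cohorts[take], min_n = 1)
      norms <- sqrt(rowSums(cb^2))
      if (all(norms > tol)) break
      if (redraw == max_redraws + 1)
        stop("bootstrap centroid degenerate after ", max_redraws, " redraws")
    }
    angles[it, ] <- vapply(seq_len(ncol(prs)), function(i)
      angle_between(cb[prs[1, i], ], cb[prs[2, i], ]), 1)
  }
  pairs <- data.frame(cohort_a = prs[1, ], cohort_b = prs[2, ],
                      mean_angle = colMeans(angles),
                      sd_angle = apply(angles, 2, stats::sd),
                      row.names = NULL)
  pairs$interpretation <- interpret_angle(pairs$mean_angle, bands = bands)
  structure(list(significant_pcs = scr$significant_pcs,
                 screening_table = scr$screening_table,
                 pairs = pairs, iterations = angles, plugin_angles = plugin,
                 reference_cohort = reference_cohort, bands = bands),
            class = "angular_result")
}
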