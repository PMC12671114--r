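#' Distance matrix container
#'
#' @param D symmetric non-negative matrix with zero diagonal; dimnames are
#'   sample ids.
#' @param metric one of `"jsd"`, `"bray_curtis"`, `"euclidean_clr"`,
#'   `"euclidean"`.
#' @return object of class `distance_matrix`.
#' @export
distance_matrix <- function(D, metric) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be non-negative")
  structure(D, metric = metric, class = c("distance_matrix", "matrix", "array"))
}

#' Jensen-Shannon divergence distance
#'
#' The square root of the Jensen-Shannon divergence between per-sample
#' composition vectors (natural-log entropies, `0 ln 0 = 0`):
#' \eqn{d(P,Q) = \sqrt{H(M) - (H(P)+H(Q))/2}}, \eqn{M = (P+Q)/2}. The square
#' root is a metric, bounded by \eqn{\sqrt{\ln 2}}. In the enterotyping
#' pipeline it is applied to genus-level relative abundances.
#'
#' @param table an [abundance_table] (rows renormalized to proportions).
#' @return a [distance_matrix] with metric `"jsd"`.
#' @export
jsd_distance <- function(table) {
  P <- as_proportions(table)
  n <- nrow(P)
  # plogp rows; 0 ln 0 = 0
  plogp <- P * log(P)
  plogp[P == 0] <- 0
  h <- -rowSums(plogp)          # H(P_i)
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n - 1)) {
    j <- seq(i + 1, n)
    M <- sweep(P[j, , drop = FALSE], 2, P[i, ], "+") / 2
    mlogm <- M * log(M)
    mlogm[M == 0] <- 0
    hm <- -rowSums(mlogm)
    jsd <- hm - (h[i] + h[j]) / 2
    D[i, j] <- D[j, i] <- sqrt(pmax(jsd, 0))
  }
  distance_matrix(D, "jsd")
}

#' Partitioning Around Medoids
#'
#' k-medoids clustering minimizing the total distance of samples to their
#' cluster medoid. BUILD phase greedily seeds medoids; SWAP phase exchanges a
#' medoid with a non-medoid whenever that strictly lowers the total cost,
#' iterated to a local optimum. `restarts` additional runs start from random
#' medoid sets (restart 0 is the deterministic BUILD start) and the lowest-cost
#' solution is returned. Ties in assignment go to the lowest-index medoid.
#'
#' @param D a [distance_matrix] (or symmetric matrix).
#' @param k number of clusters, `2 <= k < n`.
#' @param restarts number of random restarts in addition to the BUILD start.
#' @param seed optional integer seed for the restart initializations.
#' @return list with `medoids` (indices), `medoid_ids`, `assignments`
#'   (integer cluster per sample, named), `cost`.
#' @export
pam_cluster <- function(D, k, restarts = 10, seed = NULL) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n (n = ", n, ")")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  run_swap <- function(med) {
    repeat {
      dmed <- D[, med, drop = FALSE]
      nearest <- max.col(-dmed, ties.method = "first")
      cost <- sum(dmed[cbind(seq_len(n), nearest)])
      best_delta <- 0; best_swap <- NULL
      d1 <- dmed[cbind(seq_len(n), nearest)]
      # second-nearest medoid distance
      d2 <- if (k == 1) rep(Inf, n) else {
        tmp <- dmed
        tmp[cbind(seq_len(n), nearest)] <- Inf
        apply(tmp, 1, min)
      }
      nonmed <- setdiff(seq_len(n), med)
      for (mi in seq_len(k)) {
        removed_nearest <- nearest == mi
        base <- ifelse(removed_nearest, d2, d1)
        for (h in nonmed) {
          newd <- pmin(base, D[, h])
          delta <- sum(newd) - cost
          if (delta < best_delta - 1e-12) {
            best_delta <- delta
            best_swap <- c(mi, h)
          }
        }
      }
      if (is.null(best_swap)) break
      med[best_swap[1]] <- best_swap[2]
    }
    dmed <- D[, med, drop = FALSE]
    nearest <- max.col(-dmed, ties.method = "first")
    list(med = med, assign = nearest,
         cost = sum(dmed[cbind(seq_len(n), nearest)]))
  }

  # BUILD: first medoid minimizes total distance; each next greedily minimizes
  # the cost of the grown set
  med <- which.min(colSums(D))
  while (length(med) < k) {
    cur <- apply(D[, med, drop = FALSE], 1, min)
    cand <- setdiff(seq_len(n), med)
    gain <- vapply(cand, function(h) sum(pmin(cur, D[, h])), 1)
    med <- c(med, cand[which.min(gain)])
  }
  best <- run_swap(med)
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      res <- run_swap(sort(sample.int(n, k)))
      if (res$cost < best$cost - 1e-12) best <- res
    }
  }
  ids <- rownames(D) %||% as.character(seq_len(n))
  assignments <- best$assign
  names(assignments) <- ids
  med <- as.integer(unname(best$med))
  list(medoids = med, medoid_ids = ids[med],
       assignments = assignments, cost = best$cost)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion, each scaled by its degrees
#' of freedom: \eqn{CH = [B/(k-1)] / [W/(n-k)]} with B and W sums of squared
#' Euclidean distances to cluster / global centroids. In the enterotyping
#' pipeline it is evaluated on PCoA coordinates (all positive-eigenvalue axes)
#' of the JSD distance matrix.
#'
#' @param coords numeric matrix of sample coordinates (samples x axes).
#' @param assignments integer/factor cluster label per sample.
#' @return the CH index (scalar).
#' @export
calinski_harabasz <- function(coords, assignments) {
  coords <- as.matrix(coords)
  f <- factor(assignments)
  k <- nlevels(f); n <- nrow(coords)
  if (k < 2) stop("need at least 2 clusters")
  if (k >= n) stop("CH undefined when every cluster is a singleton (k = n)")
  gc <- colMeans(coords)
  W <- 0; B <- 0
  for (lev in levels(f)) {
    idx <- which(f == lev)
    cc <- colMeans(coords[idx, , drop = FALSE])
    W <- W + sum(sweep(coords[idx, , drop = FALSE], 2, cc)^2)
    B <- B + length(idx) * sum((cc - gc)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and returns coordinates
#' for positive eigenvalues (via [stats::cmdscale()]). Negative eigenvalues are
#' reported, not corrected.
#'
#' @param D a [distance_matrix].
#' @param m number of axes requested; truncated with a warning if it exceeds
#'   the number of positive eigenvalues.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), `positive_fraction` (sum of positive eigenvalues over sum of
#'   absolute eigenvalues).
#' @export
pcoa <- function(D, m = NULL) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- min(sum(eig > 1e-9 * max(abs(eig))), ncol(fit$points))
  if (is.null(m)) m <- npos
  if (m > npos) {
    warning("requested ", m, " axes but only ", npos,
            " positive eigenvalues; truncating")
    m <- npos
  }
  coords <- fit$points[, seq_len(m), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(m))
  list(coordinates = coords, eigenvalues = eig,
       positive_fraction = sum(eig[eig > 0]) / sum(abs(eig)))
}

#' Enterotype discovery pipeline
#'
#' Genus-level JSD distance, PAM clustering for each k in `k_range`,
#' Calinski-Harabasz model selection on PCoA coordinates, and per-cluster
#' driver-genus summaries. `chosen_k` maximizes CH (ties to the smaller k)
#' unless a `force_k` override is given; the full CH curve is always reported
#' so a deliberate override (as when a study prefers a finer partition over
#' the CH optimum) remains informed.
#'
#' @param table genus-level [abundance_table].
#' @param k_range integer vector of cluster counts to scan.
#' @param restarts PAM random restarts.
#' @param seed integer seed for PAM restarts.
#' @param force_k optional user-chosen k overriding the CH maximum.
#' @param n_top number of driver genera reported per cluster.
#' @return list of class `enterotype_result`: `chosen_k`, `ch_by_k`,
#'   `assignments`, `medoid_ids`, `top_genera`, `pcoa` (coordinates +
#'   eigenvalues), `distance`.
#' @export
enterotype_pipeline <- function(table, k_range = 2:6, restarts = 10,
                                seed = NULL, force_k = NULL, n_top = 5) {
  n <- nrow(table)
  if (any(k_range < 2) || any(k_range >= n))
    stop("k_range must lie within [2, n-1]")
  D <- jsd_distance(table)
  emb <- pcoa(D)
  fits <- lapply(k_range, function(k)
    pam_cluster(D, k, restarts = restarts,
                seed = if (is.null(seed)) NULL else seed + k))
  ch <- vapply(seq_along(k_range), function(i)
    calinski_harabasz(emb$coordinates, fits[[i]]$assignments), 1)
  names(ch) <- as.character(k_range)
  chosen_k <- if (!is.null(force_k)) {
    if (!force_k %in% k_range) stop("force_k must be in k_range")
    force_k
  } else k_range[which.max(ch)]   # which.max takes the first (smallest k) tie
  fit <- fits[[match(chosen_k, k_range)]]

  P <- as_proportions(table) * 100
  top <- lapply(sort(unique(fit$assignments)), function(cl) {
    idx <- fit$assignments == cl
    med <- apply(P[idx, , drop = FALSE], 2, stats::median)
    ord <- order(med, decreasing = TRUE)[seq_len(min(n_top, ncol(P)))]
    data.frame(cluster = cl, genus = colnames(P)[ord],
               median_abundance = unname(med[ord]))
  })
  structure(list(chosen_k = chosen_k, ch_by_k = ch,
                 assignments = fit$assignments, medoid_ids = fit$medoid_ids,
                 cost = fit$cost, top_genera = do.call(rbind, top),
                 pcoa = emb, distance = D),
            class = "enterotype_result")
}
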