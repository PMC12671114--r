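#' Build a design matrix from explanatory variables
#'
#' Treatment-coded dummies for factors/characters, 0/1 flags and numeric
#' columns as-is; no intercept column (the intercept is handled by centering).
#' Aliased (linearly dependent) columns are dropped with a warning; constant
#' columns are dropped with a warning.
#'
#' @param vars data.frame of explanatory variables.
#' @return numeric matrix with full column rank, plus attribute `dropped`.
#' @keywords internal
build_design <- function(vars) {
  vars <- as.data.frame(vars)
  const <- vapply(vars, function(v) length(unique(v)) < 2, TRUE)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(names(vars)[const], collapse = ", "))
    vars <- vars[, !const, drop = FALSE]
  }
  if (!ncol(vars)) stop("no usable explanatory variables")
  mm <- stats::model.matrix(~ ., data = vars)[, -1, drop = FALSE]
  mm_c <- sweep(mm, 2, colMeans(mm))
  q <- qr(mm_c)
  dropped <- character()
  if (q$rank < ncol(mm_c)) {
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- colnames(mm_c)[-keep]
    warning("dropping aliased design column(s): ", paste(dropped, collapse = ", "))
    mm <- mm[, sort(keep), drop = FALSE]
  }
  structure(mm, dropped = dropped)
}

rda_core <- function(Yc, Xc) {
  # Yc, Xc column-centered; returns R2 and rank
  q <- qr(Xc)
  Qx <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  fitted_ss <- sum(crossprod(Qx, Yc)^2)
  total_ss <- sum(Yc^2)
  list(R2 = fitted_ss / total_ss, rank = q$rank, Q = Qx)
}

ezekiel_adjust <- function(R2, n, m) 1 - (1 - R2) * (n - 1) / (n - m - 1)

#' Redundancy analysis (global fit)
#'
#' Least-squares projection of a column-centered multivariate response onto the
#' column space of the explanatory design (with intercept). The explained
#' fraction is \eqn{R^2 = tr(\hat Y^T \hat Y)/tr(Y_c^T Y_c)}; the adjusted
#' value uses the Ezekiel correction
#' \eqn{1 - (1-R^2)(n-1)/(n-m-1)} with m the design rank (intercept excluded).
#'
#' @param Y response: a [transformed_matrix] (typically clr species abundances,
#'   optionally column-bound with an autoscaled functional block) or numeric
#'   matrix. Columns are centered internally.
#' @param X data.frame of explanatory variables (factors become treatment-coded
#'   dummies; 0/1 flags stay numeric).
#' @return list of class `rda_result`: `R2`, `adjR2`, `n`, `m` (design rank),
#'   `dropped` (aliased/constant columns removed).
#' @export
rda_fit <- function(Y, X) {
  Ym <- unclass(as.matrix(Y))
  n <- nrow(Ym)
  X <- as.data.frame(X)
  if (nrow(X) != n) stop("Y and X must have the same number of rows")
  mm <- build_design(X)
  if (n <= ncol(mm) + 1)
    stop("need n > number of design columns + 1 (n = ", n, ", columns = ", ncol(mm), ")")
  Yc <- sweep(Ym, 2, colMeans(Ym))
  Xc <- sweep(mm, 2, colMeans(mm))
  core <- rda_core(Yc, Xc)
  structure(list(R2 = core$R2,
                 adjR2 = ezekiel_adjust(core$R2, n, core$rank),
                 n = n, m = core$rank, dropped = attr(mm, "dropped")),
            class = "rda_result")
}

#' Marginal (single-variable) variance partitioning
#'
#' One single-variable redundancy analysis per named explanatory variable, plus
#' the joint all-variable model. Because predictors are generally correlated,
#' the marginal fractions need not sum to the joint fraction; this mirrors
#' per-variable "variance explained" bar charts.
#'
#' @inheritParams rda_fit
#' @return list of class `partition_result`: `per_variable` (data.frame
#'   variable, R2, adjR2), `joint` (the full-model `rda_result`).
#' @export
marginal_partition <- function(Y, X) {
  X <- as.data.frame(X)
  rows <- lapply(names(X), function(v) {
    if (length(unique(X[[v]])) < 2) {
      warning("variable '", v, "' is constant; reported as undefined")
      return(data.frame(variable = v, R2 = NA_real_, adjR2 = NA_real_))
    }
    fit <- rda_fit(Y, X[, v, drop = FALSE])
    data.frame(variable = v, R2 = fit$R2, adjR2 = fit$adjR2)
  })
  usable <- names(X)[vapply(X, function(v) length(unique(v)) >= 2, TRUE)]
  joint <- suppressWarnings(rda_fit(Y, X[, usable, drop = FALSE]))
  structure(list(per_variable = do.call(rbind, rows), joint = joint),
            class = "partition_result")
}

#' Forward stepwise redundancy analysis
#'
#' Forward selection over candidate explanatory variables with the
#' two-stopping-rule scheme: selection only begins if a global permutation test
#' of the all-candidate model is significant (guarding family-wise type-I
#' error); at each step the candidate giving the largest adjusted-R-squared
#' gain is proposed and admitted only if (a) its conditional permutation
#' p-value (permuting the residuals of the current model) is below `alpha` and
#' (b) the extended model's adjusted R-squared does not exceed the global
#' all-candidate adjusted R-squared ceiling. Selection stops when no candidate
#' is admissible.
#'
#' @inheritParams rda_fit
#' @param candidates data.frame of candidate explanatory variables.
#' @param alpha admission significance level.
#' @param n_perm number of residual permutations per test.
#' @param seed integer seed for the permutations.
#' @param global_test apply the global pre-test (default TRUE).
#' @return list of class `stepwise_result`: `selected` (variables in order),
#'   `trace` (data.frame step, variable, adjR2, perm_p), `global_adjR2`,
#'   `global_p` (NA when the pre-test is disabled).
#' @export
stepwise_rda <- function(Y, candidates, alpha = 0.05, n_perm = 999, seed = NULL,
                         global_test = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  Ym <- unclass(as.matrix(Y))
  n <- nrow(Ym)
  candidates <- as.data.frame(candidates)
  usable <- names(candidates)[vapply(candidates, function(v) length(unique(v)) >= 2, TRUE)]
  candidates <- candidates[, usable, drop = FALSE]
  Yc <- sweep(Ym, 2, colMeans(Ym))
  total_ss <- sum(Yc^2)
  global <- rda_fit(Yc, candidates)
  ceiling_adj <- global$adjR2

  global_p <- NA_real_
  if (global_test) {
    mm_all <- suppressWarnings(build_design(candidates))
    Xc_all <- sweep(mm_all, 2, colMeans(mm_all))
    qa <- qr(Xc_all)
    Qa <- qr.Q(qa)[, seq_len(qa$rank), drop = FALSE]
    m_all <- qa$rank
    total <- sum(Yc^2)
    ss_exp <- sum(crossprod(Qa, Yc)^2)
    F_g <- (ss_exp / m_all) / ((total - ss_exp) / (n - m_all - 1))
    ss_perm <- vapply(seq_len(n_perm), function(i)
      sum(crossprod(Qa, Yc[sample.int(n), , drop = FALSE])^2), 1)
    F_p <- (ss_perm / m_all) / ((total - ss_perm) / (n - m_all - 1))
    global_p <- (1 + sum(F_p >= F_g - 1e-12)) / (1 + n_perm)
    if (global_p >= alpha)
      return(structure(list(selected = character(),
                            trace = data.frame(step = integer(),
                                               variable = character(),
                                               adjR2 = numeric(),
                                               perm_p = numeric()),
                            global_adjR2 = ceiling_adj, global_p = global_p),
                       class = "stepwise_result"))
  }

  selected <- character()
  trace <- data.frame(step = integer(), variable = character(),
                      adjR2 = numeric(), perm_p = numeric())
  cur_Q <- NULL   # orthonormal basis of the current (centered) design
  cur_rank <- 0

  design_cols <- function(v) {
    mm <- stats::model.matrix(~ ., data = candidates[, v, drop = FALSE])[, -1, drop = FALSE]
    sweep(mm, 2, colMeans(mm))
  }

  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    # residuals of Y on current model
    R <- if (cur_rank) Yc - cur_Q %*% crossprod(cur_Q, Yc) else Yc
    ss_res <- sum(R^2)
    # evaluate adjR2 gain per candidate
    stats_by <- lapply(remaining, function(v) {
      Xv <- design_cols(v)
      Xr <- if (cur_rank) Xv - cur_Q %*% crossprod(cur_Q, Xv) else Xv
      qv <- qr(Xr)
      if (qv$rank == 0) return(list(adjR2 = -Inf))
      Qv <- qr.Q(qv)[, seq_len(qv$rank), drop = FALSE]
      ss_add <- sum(crossprod(Qv, R)^2)
      R2_new <- 1 - (ss_res - ss_add) / total_ss
      list(adjR2 = ezekiel_adjust(R2_new, n, cur_rank + qv$rank),
           Qv = Qv, ss_add = ss_add, q = qv$rank)
    })
    adj <- vapply(stats_by, function(s) s$adjR2, 1)
    best_i <- which.max(adj)
    best <- stats_by[[best_i]]
    cur_adj <- if (cur_rank) ezekiel_adjust(1 - ss_res / total_ss, n, cur_rank) else 0
    if (!is.finite(best$adjR2) || best$adjR2 <= cur_adj) break
    if (best$adjR2 > ceiling_adj + 1e-12) break

    # conditional permutation test: permute rows of the current-model residuals
    qf <- best$q
    df2 <- n - cur_rank - qf - 1
    F_obs <- (best$ss_add / qf) / ((ss_res - best$ss_add) / df2)
    if (qf == 1) {
      # one GEMM over all permutations of the single residualized column
      perm_mat <- vapply(seq_len(n_perm), function(i) best$Qv[sample.int(n), 1],
                         numeric(n))
      ss_perm <- rowSums(crossprod(perm_mat, R)^2)
    } else {
      ss_perm <- vapply(seq_len(n_perm), function(i) {
        sum(crossprod(best$Qv[sample.int(n), , drop = FALSE], R)^2)
      }, 1)
    }
    F_perm <- (ss_perm / qf) / ((ss_res - ss_perm) / df2)
    p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
    if (p >= alpha) break

    v <- remaining[best_i]
    selected <- c(selected, v)
    Xsel <- design_cols(selected)
    qs <- qr(Xsel)
    cur_Q <- qr.Q(qs)[, seq_len(qs$rank), drop = FALSE]
    cur_rank <- qs$rank
    trace <- rbind(trace, data.frame(step = length(selected), variable = v,
                                     adjR2 = best$adjR2, perm_p = p))
  }
  structure(list(selected = selected, trace = trace,
                 global_adjR2 = ceiling_adj, global_p = global_p),
            class = "stepwise_result")
}

#' Distances for beta-diversity analyses
#'
#' Bray-Curtis on relative abundances (via [vegan::vegdist()]) or Euclidean
#' distance on clr-transformed abundances.
#'
#' @param table an [abundance_table].
#' @param metric `"bray_curtis"` or `"euclidean_clr"`.
#' @param pseudocount passed to [clr_transform()] for `"euclidean_clr"`.
#' @return a [distance_matrix].
#' @export
beta_distance <- function(table, metric = c("bray_curtis", "euclidean_clr"),
                          pseudocount = NULL) {
  metric <- match.arg(metric)
  if (metric == "bray_curtis") {
    D <- as.matrix(vegan::vegdist(as_proportions(table), method = "bray"))
    diag(D) <- 0
  } else {
    Z <- unclass(clr_transform(table, pseudocount))
    D <- as.matrix(stats::dist(Z))
  }
  distance_matrix(D, metric)
}

#' PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the pseudo-F statistic is computed from the Gower-centered matrix
#' \eqn{G = -\tfrac12 J D^2 J} and the hat matrix of the design,
#' \eqn{F = [tr(HG)/m] / [tr((I-H)G)/ (n-m-1)]}, and its significance from free
#' permutation of sample labels. The p-value uses the add-one rule
#' \eqn{p = (1 + \#\{F_\pi \ge F\}) / (1 + n_{perm})}.
#'
#' @param D a [distance_matrix].
#' @param design grouping vector/factor, or data.frame of explanatory
#'   variables.
#' @param n_perm number of permutations (warning below 99).
#' @param seed integer seed.
#' @return list of class `permanova_result`: `F`, `R2` (partial), `p`,
#'   `n_perm`, `perm_F` summary (quantiles).
#' @export
permanova <- function(D, design, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 99) warning("fewer than 99 permutations gives a coarse p-value")
  Dm <- unclass(as.matrix(D))
  n <- nrow(Dm)
  if (!is.data.frame(design)) {
    g <- factor(design)
    if (nlevels(g) < 2) stop("grouping must contain at least 2 groups")
    if (any(table(g) < 2)) stop("every group needs at least 2 samples")
    design <- data.frame(group = g)
  }
  mm <- build_design(design)
  Xc <- sweep(mm, 2, colMeans(mm))
  q <- qr(Xc)
  Qx <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  m <- q$rank
  if (n - m - 1 <= 0) stop("not enough residual degrees of freedom")
  A <- -0.5 * Dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  H <- tcrossprod(Qx)
  tr_G <- sum(diag(G))
  f_of <- function(Hm) {
    ss_b <- sum(Hm * G)          # tr(HG), both symmetric
    (ss_b / m) / ((tr_G - ss_b) / (n - m - 1))
  }
  F_obs <- f_of(H)
  ss_b_obs <- sum(H * G)
  perm_F <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    f_of(H[p, p])
  }, 1)
  pval <- (1 + sum(perm_F >= F_obs - 1e-12)) / (1 + n_perm)
  structure(list(F = F_obs, R2 = ss_b_obs / tr_G, p = pval, n_perm = n_perm,
                 perm_F_quantiles = stats::quantile(perm_F, c(.5, .9, .95, .99))),
            class = "permanova_result")
}
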