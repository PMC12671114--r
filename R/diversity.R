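#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \ln p_i} over the nonzero entries of a renormalized
#' abundance vector, in nats. Computed with [vegan::diversity()].
#'
#' @param x non-negative abundance or proportion vector (or a samples x taxa
#'   matrix / [abundance_table], in which case one value per sample is
#'   returned). Renormalized internally.
#' @return Shannon index (nats), one per sample.
#' @export
shannon <- function(x) {
  if (is.matrix(x)) {
    m <- unclass(x)
    if (any(m < 0)) stop("negative abundances")
    if (any(rowSums(m) <= 0)) stop("all-zero sample")
    return(vegan::diversity(m, index = "shannon"))
  }
  if (any(x < 0)) stop("negative abundances")
  if (sum(x) <= 0) stop("all-zero abundance vector")
  unname(vegan::diversity(x / sum(x), index = "shannon"))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample rank-sum test. `mode = "exact"` enumerates the complete
#' permutation distribution of the rank-sum (midranks under ties), feasible for
#' small groups; `mode = "normal"` uses the normal approximation with tie and
#' continuity correction (via [stats::wilcox.test()]). `mode = "auto"` picks
#' exact when `length(x) + length(y) <= 12`.
#'
#' @param x,y numeric vectors, both nonempty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `statistic` (Mann-Whitney U for `x`) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  m <- length(x); n <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(statistic = m * n / 2, p.value = 1))
  }
  if (mode == "auto") mode <- if (m + n <= 12) "exact" else "normal"
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (mode == "exact") {
    combs <- utils::combn(m + n, m)
    w <- colSums(matrix(r[combs], nrow = m))
    W_obs <- sum(r[seq_len(m)])
    eps <- 1e-9
    p_lo <- mean(w <= W_obs + eps)
    p_hi <- mean(w >= W_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = unname(U), p.value = p))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(U), p.value = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment ([stats::p.adjust()] with
#' `method = "BH"`), with input validation.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Alpha-diversity comparison across cohorts
#'
#' Per-sample Shannon index at the table's rank, per-cohort summaries, and all
#' pairwise cohort comparisons by Wilcoxon rank-sum with BH correction.
#'
#' @param table an [abundance_table] (species level in the standard pipeline).
#' @param metadata aligned `sample_metadata` (see [align_samples()]).
#' @param mode test mode passed to [wilcoxon_rank_sum()].
#' @return list of class `diversity_result`: `per_sample` (data.frame
#'   sample_id, cohort, shannon), `per_cohort` (median, IQR, n),
#'   `pairwise` (cohort pair, statistic, p, q).
#' @export
diversity_pipeline <- function(table, metadata, mode = "auto") {
  al <- align_samples(table, metadata)
  H <- shannon(al$table)
  per_sample <- data.frame(sample_id = sample_ids(al$table),
                           cohort = al$metadata$cohort, shannon = unname(H))
  coh <- split(per_sample$shannon, per_sample$cohort)
  per_cohort <- data.frame(
    cohort = names(coh),
    n = vapply(coh, length, 1L),
    median = vapply(coh, stats::median, 1),
    iqr = vapply(coh, stats::IQR, 1),
    row.names = NULL)
  prs <- utils::combn(names(coh), 2)
  pw <- lapply(seq_len(ncol(prs)), function(i) {
    t <- wilcoxon_rank_sum(coh[[prs[1, i]]], coh[[prs[2, i]]], mode = mode)
    data.frame(cohort_a = prs[1, i], cohort_b = prs[2, i],
               statistic = t$statistic, p = t$p.value)
  })
  pairwise <- do.call(rbind, pw)
  pairwise$q <- bh_adjust(pairwise$p)
  structure(list(per_sample = per_sample, per_cohort = per_cohort,
                 pairwise = pairwise), class = "diversity_result")
}
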