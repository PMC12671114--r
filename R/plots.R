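#' PCoA scatter of enterotype clusters
#'
#' First two principal coordinates, colored by cohort, point shape by cluster.
#'
#' @param result an `enterotype_result`.
#' @param metadata aligned `sample_metadata` (for cohort colors); optional.
#' @param file optional SVG path; when given the plot is written there.
#' @return invisibly, the coordinates plotted.
#' @export
plot_pcoa <- function(result, metadata = NULL, file = NULL) {
  co <- result$pcoa$coordinates
  if (ncol(co) < 2) stop("need at least two PCoA axes to plot")
  cl <- result$assignments
  colv <- if (!is.null(metadata)) as.integer(factor(metadata$cohort)) else 1
  if (!is.null(file)) {
    grDevices::svg(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  eig <- result$pcoa$eigenvalues
  pct <- 100 * eig[1:2] / sum(eig[eig > 0])
  plot(co[, 1], co[, 2], col = colv, pch = cl,
       xlab = sprintf("Axis 1 (%.1f%%)", pct[1]),
       ylab = sprintf("Axis 2 (%.1f%%)", pct[2]),
       main = sprintf("PCoA (JSD), k = %d", result$chosen_k))
  invisible(co[, 1:2])
}

#' Protractor plot of cohort centroid angles
#'
#' Draws each non-reference cohort as a ray at its mean angle from the
#' reference cohort (the 0-degree axis), with an arc indicating +/- one SD,
#' on a half-circle protractor.
#'
#' @param result an `angular_result`.
#' @param file optional SVG path.
#' @return invisibly, the pairs involving the reference cohort.
#' @export
plot_protractor <- function(result, file = NULL) {
  ref <- result$reference_cohort
  pr <- result$pairs
  pr <- pr[pr$cohort_a == ref | pr$cohort_b == ref, , drop = FALSE]
  if (!nrow(pr)) stop("no pairs involve the reference cohort")
  pr$other <- ifelse(pr$cohort_a == ref, pr$cohort_b, pr$cohort_a)
  if (!is.null(file)) {
    grDevices::svg(file, width = 6, height = 4)
    on.exit(grDevices::dev.off())
  }
  plot(NA, xlim = c(-1.15, 1.15), ylim = c(-0.1, 1.2), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = paste0("Centroid angles vs ", ref))
  th <- seq(0, pi, length.out = 181)
  graphics::lines(cos(th), sin(th), col = "grey70")
  graphics::segments(0, 0, 1, 0, lwd = 2)
  graphics::text(1.08, 0, ref, adj = 0)
  for (i in seq_len(nrow(pr))) {
    a <- pr$mean_angle[i] * pi / 180
    graphics::segments(0, 0, cos(a), sin(a), col = i + 1, lwd = 2)
    band <- seq(max(0, pr$mean_angle[i] - pr$sd_angle[i]),
                min(180, pr$mean_angle[i] + pr$sd_angle[i]), length.out = 50) * pi / 180
    graphics::lines(0.95 * cos(band), 0.95 * sin(band), col = i + 1, lwd = 3)
    graphics::text(1.08 * cos(a), 1.08 * sin(a), pr$other[i],
                   adj = c(0.5, 0), col = i + 1, cex = 0.8)
  }
  invisible(pr)
}

#' Bar chart of marginal explained-variance fractions
#'
#' @param partition a `partition_result` from [marginal_partition()].
#' @param file optional SVG path.
#' @return invisibly, the per-variable table.
#' @export
plot_variance_bars <- function(partition, file = NULL) {
  tab <- partition$per_variable
  tab <- tab[order(-tab$adjR2), , drop = FALSE]
  if (!is.null(file)) {
    grDevices::svg(file, width = 6, height = 4)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(100 * pmax(tab$adjR2, 0), names.arg = tab$variable,
                    las = 2, ylab = "adjusted R² (%)",
                    main = sprintf("Joint model: %.1f%%", 100 * partition$joint$adjR2))
  invisible(tab)
}
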