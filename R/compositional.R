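#' Transformed feature matrices
#'
#' Downstream stages require specific transforms (the angular statistic takes
#' square-root autoscaled abundances, association models take clr), so the
#' transform is carried as provenance on the matrix and enforced at the point
#' of use.
#'
#' @param values numeric matrix, samples x features.
#' @param tag one of `"relabund"`, `"sqrt"`, `"sqrt_autoscaled"`, `"clr"`,
#'   `"functional"`.
#' @param pseudocount pseudocount used (clr only).
#' @param constant_features labels of features that were constant and zeroed
#'   (autoscaling only).
#' @return object of class `transformed_matrix`.
#' @export
transformed_matrix <- function(values, tag, pseudocount = NULL,
                               constant_features = character()) {
  structure(as.matrix(values), transform_tag = tag, pseudocount = pseudocount,
            constant_features = constant_features,
            class = c("transformed_matrix", "matrix", "array"))
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("<transformed_matrix:%s> %d samples x %d features\n",
              attr(x, "transform_tag"), nrow(x), ncol(x)))
  invisible(x)
}

transform_tag <- function(x) attr(x, "transform_tag")

require_transform <- function(x, tag) {
  if (!inherits(x, "transformed_matrix") || !identical(transform_tag(x), tag))
    stop("expected a transformed_matrix with tag '", tag, "', got '",
         if (inherits(x, "transformed_matrix")) transform_tag(x) else class(x)[1], "'")
  invisible(x)
}

#' Centered log-ratio transform
#'
#' Per sample, proportions are shifted by a pseudocount, re-closed, and mapped
#' to \eqn{\ln(x_i / g(x))} where \eqn{g} is the geometric mean of the sample.
#' Rows of the result sum to zero. The default pseudocount is half the smallest
#' nonzero proportion in the whole table, a scale-aware zero-replacement.
#'
#' @param table an [abundance_table] (or non-negative matrix).
#' @param pseudocount positive real; default half the minimum nonzero
#'   proportion across the table.
#' @return a [transformed_matrix] with tag `"clr"`.
#' @export
clr_transform <- function(table, pseudocount = NULL) {
  m <- unclass(table)
  if (any(m < 0)) stop("clr_transform requires non-negative input")
  p <- sweep(m, 1, rowSums(m), "/")
  if (is.null(pseudocount)) {
    nz <- p[p > 0]
    if (!length(nz)) stop("all-zero table")
    pseudocount <- min(nz) / 2
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  x <- p + pseudocount
  x <- sweep(x, 1, rowSums(x), "/")
  lx <- log(x)
  out <- lx - rowMeans(lx)
  transformed_matrix(out, "clr", pseudocount = pseudocount)
}

#' Square-root transform with per-feature autoscaling
#'
#' Element-wise square root of per-sample proportions, then each feature
#' (column) is centered and divided by its sample standard deviation (n-1
#' convention). Constant features cannot be scaled; they are set to zero and
#' recorded in the `constant_features` attribute.
#'
#' @param table an [abundance_table] (or non-negative matrix). A matrix that is
#'   already a `transformed_matrix` with tag `"sqrt_autoscaled"` is
#'   re-standardized (idempotent).
#' @return a [transformed_matrix] with tag `"sqrt_autoscaled"`.
#' @export
sqrt_autoscale <- function(table) {
  if (inherits(table, "transformed_matrix") &&
      identical(transform_tag(table), "sqrt_autoscaled")) {
    s <- unclass(table)
  } else {
    m <- unclass(table)
    if (any(m < 0)) stop("sqrt_autoscale requires non-negative input")
    s <- sqrt(sweep(m, 1, rowSums(m), "/"))
  }
  mu <- colMeans(s)
  sd <- apply(s, 2, stats::sd)
  const <- sd <= .Machine$double.eps * 100
  sd[const] <- 1
  out <- sweep(sweep(s, 2, mu, "-"), 2, sd, "/")
  out[, const] <- 0
  transformed_matrix(out, "sqrt_autoscaled",
                     constant_features = colnames(s)[const] %||% character())
}

#' Autoscale an arbitrary feature matrix (z-score per column)
#'
#' Used to put functional-profile blocks on the same scale as taxonomic blocks
#' before joint modeling.
#'
#' @param m numeric matrix, samples x features.
#' @return a [transformed_matrix] with tag `"autoscaled"`.
#' @export
autoscale <- function(m) {
  m <- unclass(m)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  const <- sd <= .Machine$double.eps * 100
  sd[const] <- 1
  out <- sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  out[, const] <- 0
  transformed_matrix(out, "autoscaled",
                     constant_features = colnames(m)[const] %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
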