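#' Univariate medication-feature screening
#'
#' Step one of the two-step association analysis: for every (feature,
#' covariate) pair a Gaussian linear model `feature ~ covariate` is fit and the
#' slope tested; Benjamini-Hochberg correction is applied jointly across all
#' feature x covariate tests, and pairs with adjusted p below the threshold
#' pass to the multivariate step.
#'
#' @param features a [transformed_matrix] (clr taxa or autoscaled functional
#'   modules), samples x features.
#' @param covariates data.frame of 0/1 exposure flags (each must have both
#'   levels present).
#' @param q_threshold BH-adjusted significance threshold for screening.
#' @return data.frame with columns feature, covariate, estimate, p, q, passed.
#' @export
univariate_screen <- function(features, covariates, q_threshold = 0.05) {
  Fm <- unclass(as.matrix(features))
  covariates <- as.data.frame(covariates)
  keep_feat <- apply(Fm, 2, function(v) stats::sd(v) > 0)
  if (any(!keep_feat))
    warning("skipping ", sum(!keep_feat), " constant feature(s)")
  Fm <- Fm[, keep_feat, drop = FALSE]
  n <- nrow(Fm)
  Fc <- sweep(Fm, 2, colMeans(Fm))
  rows <- lapply(names(covariates), function(cv) {
    x <- as.numeric(covariates[[cv]])
    if (length(unique(x)) < 2)
      stop("covariate '", cv, "' must have both levels present")
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    beta <- as.numeric(crossprod(xc, Fc)) / sxx       # all features at once
    rss <- colSums(Fc^2) - beta^2 * sxx
    se <- sqrt(rss / (n - 2) / sxx)
    tstat <- beta / se
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    data.frame(feature = colnames(Fm), covariate = cv,
               estimate = beta, p = p, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  tab$passed <- tab$q < q_threshold
  tab
}

#' Multivariate association models
#'
#' Step two: for every feature with at least one screened covariate, a single
#' Gaussian linear model is fit containing all of that feature's screened
#' medications plus age and sex. No further multiplicity correction is applied
#' (the gate is the BH-screened first step). Perfectly collinear medications
#' are dropped (aliased) and flagged.
#'
#' @param features as in [univariate_screen()].
#' @param screened output of [univariate_screen()] (only rows with
#'   `passed = TRUE` are used).
#' @param covariates data.frame of the medication flags referenced by
#'   `screened`.
#' @param metadata aligned `sample_metadata` providing `age` and `sex`.
#' @return data.frame with columns feature, covariate, estimate, p, aliased.
#'   Adjustment terms (age, sex) are included with `role = "adjustment"`.
#' @export
multivariate_fit <- function(features, screened, covariates, metadata) {
  Fm <- unclass(as.matrix(features))
  covariates <- as.data.frame(covariates)
  hits <- screened[screened$passed, , drop = FALSE]
  if (!nrow(hits)) return(data.frame(feature = character(), covariate = character(),
                                     estimate = numeric(), p = numeric(),
                                     aliased = logical(), role = character()))
  sex_num <- as.numeric(factor(metadata$sex)) - 1
  out <- lapply(unique(hits$feature), function(ft) {
    meds <- hits$covariate[hits$feature == ft]
    df <- data.frame(covariates[, meds, drop = FALSE],
                     age = metadata$age, sex = sex_num, check.names = FALSE)
    y <- Fm[, ft]
    fit <- stats::lm(y ~ ., data = df)
    cf <- summary(fit)$coefficients
    co <- stats::coef(fit)[-1]
    aliased <- names(co)[is.na(co)]
    aliased <- sub("`", "", sub("`$", "", aliased))
    res <- data.frame(feature = ft,
                      covariate = rownames(cf)[-1],
                      estimate = cf[-1, "Estimate"],
                      p = cf[-1, "Pr(>|t|)"], row.names = NULL)
    res$covariate <- gsub("`", "", res$covariate)
    if (length(aliased))
      res <- rbind(res, data.frame(feature = ft, covariate = aliased,
                                   estimate = NA_real_, p = NA_real_))
    res$aliased <- res$covariate %in% aliased
    res$role <- ifelse(res$covariate %in% c("age", "sex"), "adjustment", "medication")
    res
  })
  do.call(rbind, out)
}

#' Two-step medication-microbiome association analysis
#'
#' Runs the univariate BH-gated screen followed by per-feature multivariate
#' models adjusted for age and sex, and derives the heatmap subset of features
#' showing at least `min_hits` significant multivariate medication
#' associations.
#'
#' @param features a [transformed_matrix] with tag `"clr"` (taxa) or
#'   `"autoscaled"` (functional modules).
#' @param metadata aligned `sample_metadata` (uses its medication flag columns,
#'   `age`, `sex`).
#' @param q_threshold univariate BH threshold.
#' @param p_threshold multivariate significance threshold used for the heatmap
#'   subset.
#' @param min_hits minimum number of significant multivariate associations for
#'   a feature to enter the heatmap subset.
#' @return list of class `association_result`: `univariate`, `multivariate`,
#'   `heatmap_features`.
#' @export
two_step_association <- function(features, metadata, q_threshold = 0.05,
                                 p_threshold = 0.05, min_hits = 2) {
  if (!transform_tag(features) %in% c("clr", "autoscaled"))
    stop("association models expect clr taxa or autoscaled functional profiles")
  med_cols <- attr(metadata, "medication_cols")
  if (is.null(med_cols) || !length(med_cols))
    stop("metadata carries no medication flag columns")
  both <- vapply(metadata[, med_cols, drop = FALSE],
                 function(v) length(unique(v)) == 2, TRUE)
  if (any(!both))
    warning("dropping single-level medication flag(s): ",
            paste(med_cols[!both], collapse = ", "))
  med_cols <- med_cols[both]
  covs <- as.data.frame(metadata)[, med_cols, drop = FALSE]
  uni <- univariate_screen(features, covs, q_threshold = q_threshold)
  multi <- multivariate_fit(features, uni, covs, metadata)
  med_multi <- multi[multi$role == "medication" & !multi$aliased, , drop = FALSE]
  nhits <- table(med_multi$feature[med_multi$p < p_threshold])
  heat <- names(nhits)[nhits >= min_hits]
  structure(list(univariate = uni, multivariate = multi,
                 heatmap_features = heat),
            class = "association_result")
}

#' Bootstrap point-biserial correlation
#'
#' Pearson correlation between a continuous feature and a 0/1 outcome,
#' with a nonparametric bootstrap (resampling samples with replacement) for the
#' mean and a percentile confidence interval. Resamples containing one outcome
#' class only are redrawn (counted, capped).
#'
#' @param values numeric feature vector.
#' @param outcome 0/1 vector, both classes present.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level of the percentile interval.
#' @param max_redraws cap on redraws of degenerate resamples.
#' @return list of class `biserial_result`: `r`, `boot_mean`, `ci` (length 2),
#'   `n_boot`, `redraws`.
#' @export
biserial_bootstrap <- function(values, outcome, n_boot = 1000, seed = NULL,
                               conf = 0.95, max_redraws = 10000) {
  outcome <- as.numeric(outcome)
  if (length(unique(outcome)) < 2) stop("outcome must contain both classes")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  r <- stats::cor(values, outcome)
  boots <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcome[idx])) == 2 && stats::sd(values[idx]) > 0) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) stop("too many degenerate bootstrap resamples")
    }
    boots[b] <- stats::cor(values[idx], outcome[idx])
  }
  a <- (1 - conf) / 2
  structure(list(r = r, boot_mean = mean(boots),
                 ci = unname(stats::quantile(boots, c(a, 1 - a))),
                 n_boot = n_boot, redraws = redraws),
            class = "biserial_result")
}
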