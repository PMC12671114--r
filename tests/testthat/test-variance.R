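test_that("RDA matches closed forms", {
  set.seed(61)
  # univariate response, binary predictor: R2 equals squared point-biserial r
  y <- matrix(rnorm(40), 40, 1)
  x <- rbinom(40, 1, 0.5)
  f <- rda_fit(y, data.frame(x = x))
  expect_equal(f$R2, as.numeric(cor(y, x))^2, tolerance = 1e-10)

  # Ezekiel adjustment worked example: R2=0.5, n=11, m=1
  expect_equal(1 - (1 - 0.5) * 10 / 9, 0.44444444, tolerance = 1e-7)

  # X orthogonal to Y -> R2 = 0
  y2 <- matrix(c(1, -1, 1, -1), 4, 1)
  x2 <- c(1, 1, -1, -1)
  expect_equal(rda_fit(y2, data.frame(x = x2))$R2, 0, tolerance = 1e-12)

  # Y = X identity response -> R2 = 1
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  f3 <- rda_fit(as.matrix(X), X)
  expect_equal(f3$R2, 1, tolerance = 1e-12)
})

test_that("RDA agrees with the vegan reference implementation", {
  set.seed(62)
  Y <- matrix(rnorm(30 * 8), 30, 8)
  X <- data.frame(a = rnorm(30), g = factor(rep(c("u", "v", "w"), 10)))
  ours <- rda_fit(Y, X)
  ref <- vegan::rda(Y ~ a + g, data = X)
  expect_equal(ours$R2, unname(vegan::RsquareAdj(ref)$r.squared), tolerance = 1e-10)
  expect_equal(ours$adjR2, unname(vegan::RsquareAdj(ref)$adj.r.squared),
               tolerance = 1e-10)
})

test_that("design degeneracies are dropped with warnings", {
  set.seed(63)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  x <- rbinom(20, 1, 0.5)
  expect_warning(f <- rda_fit(Y, data.frame(a = x, b = x, c = rnorm(20))),
                 "aliased")
  expect_equal(f$m, 2)
  expect_warning(marginal_partition(Y, data.frame(a = x, k = rep(1, 20))),
                 "constant")
})

test_that("marginal partition reports per-variable and joint fits", {
  set.seed(64)
  Y <- matrix(rnorm(50 * 6), 50, 6)
  X <- data.frame(a = rbinom(50, 1, 0.5), b = rnorm(50))
  part <- marginal_partition(Y, X)
  expect_equal(part$per_variable$variable, c("a", "b"))
  expect_true(all(part$per_variable$R2 <= part$joint$R2 + 1e-12))
  expect_true(all(part$per_variable$adjR2 <= part$per_variable$R2))
})

test_that("stepwise selection admits a strong single candidate and stops", {
  set.seed(65)
  x <- rbinom(60, 1, 0.5)
  Y <- outer(x, rnorm(10)) + matrix(rnorm(600, 0, 0.5), 60, 10)
  st <- stepwise_rda(Y, data.frame(x = x), alpha = 0.05, n_perm = 199, seed = 1)
  expect_equal(st$selected, "x")
  expect_equal(nrow(st$trace), 1)
  expect_lt(st$trace$perm_p, 0.05)
  expect_lt(st$global_p, 0.05)
  # identical seed, identical result
  st2 <- stepwise_rda(Y, data.frame(x = x), alpha = 0.05, n_perm = 199, seed = 1)
  expect_identical(st$trace, st2$trace)
})

test_that("stepwise trace has nondecreasing adjusted R2 and respects the ceiling", {
  set.seed(66)
  x1 <- rbinom(80, 1, 0.5); x2 <- rbinom(80, 1, 0.5)
  Y <- outer(x1, rnorm(12)) + 0.7 * outer(x2, rnorm(12)) +
    matrix(rnorm(960, 0, 0.8), 80, 12)
  cands <- data.frame(x1 = x1, x2 = x2, n1 = rbinom(80, 1, 0.5),
                      n2 = rbinom(80, 1, 0.5))
  st <- stepwise_rda(Y, cands, alpha = 0.05, n_perm = 199, seed = 2)
  if (nrow(st$trace) > 1) expect_true(all(diff(st$trace$adjR2) >= -1e-12))
  expect_true(all(st$trace$adjR2 <= st$global_adjR2 + 1e-12))
})

test_that("PERMANOVA agrees with exhaustive enumeration and the classical F", {
  set.seed(67)
  m <- matrix(runif(6 * 5), 6, 5)
  tab <- tiny_table(m / rowSums(m) * 100)
  D <- beta_distance(tab, "bray_curtis")
  g <- rep(c("a", "b"), each = 3)
  pm <- permanova(D, g, n_perm = 999, seed = 1)

  # complete enumeration of all 20 assignments
  Dm <- unclass(as.matrix(D)); A <- -0.5 * Dm^2
  J <- diag(6) - 1 / 6; G <- J %*% A %*% J
  f_of <- function(gg) {
    xc <- scale(as.integer(gg == "a"), scale = FALSE)
    Q <- xc / sqrt(sum(xc^2)); H <- tcrossprod(Q)
    ssb <- sum(H * G)
    ssb / ((sum(diag(G)) - ssb) / 4)
  }
  Fs <- apply(utils::combn(6, 3), 2, function(ix) {
    gg <- rep("b", 6); gg[ix] <- "a"; f_of(gg)
  })
  p_exact <- mean(Fs >= f_of(g) - 1e-12)
  expect_lt(abs(pm$p - p_exact), 0.05)

  # Euclidean distance: pseudo-F equals the classical RDA F
  set.seed(68)
  Y <- matrix(rnorm(20 * 5), 20, 5)
  rownames(Y) <- paste0("s", 1:20)
  De <- as.matrix(dist(Y)); dimnames(De) <- list(rownames(Y), rownames(Y))
  grp <- rep(c("a", "b"), each = 10)
  pm2 <- permanova(distance_matrix(De, "euclidean"), grp, n_perm = 99, seed = 1)
  r <- rda_fit(Y, data.frame(g = grp))
  F_classic <- (r$R2 / r$m) / ((1 - r$R2) / (r$n - r$m - 1))
  expect_equal(pm2$F, F_classic, tolerance = 1e-9)
})

test_that("PERMANOVA matches adonis2 and uses the add-one rule", {
  set.seed(69)
  tab <- random_table(18, 12, seed = 69)
  D <- beta_distance(tab, "bray_curtis")
  g <- rep(c("a", "b", "c"), each = 6)
  pm <- permanova(D, g, n_perm = 199, seed = 3)
  ad <- vegan::adonis2(stats::as.dist(unclass(D)) ~ g, permutations = 199)
  expect_equal(pm$F, ad$F[1], tolerance = 1e-9)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-9)
  expect_gt(pm$p, 0)   # never exactly zero

  # perfectly separated clusters: p = 1/(n_perm+1) (n large enough that a
  # random permutation essentially never reproduces the split)
  pts <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
               matrix(rnorm(20, 50, 0.05), 10, 2))
  Dp <- as.matrix(dist(pts)); dimnames(Dp) <- list(1:20, 1:20)
  pm3 <- permanova(distance_matrix(Dp, "euclidean"),
                   rep(c("a", "b"), each = 10), n_perm = 199, seed = 4)
  expect_equal(pm3$p, 1 / 200)

  pm4 <- permanova(D, g, n_perm = 199, seed = 3)
  expect_identical(pm$p, pm4$p)   # same seed, same p
  expect_error(permanova(D, rep("a", 18)), "2 groups")
})
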