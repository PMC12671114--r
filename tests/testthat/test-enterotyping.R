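test_that("JSD distance matches hand-computed values and bounds", {
  tab <- tiny_table(matrix(c(50, 50, 100, 0), 2, 2, byrow = TRUE))
  D <- jsd_distance(tab)
  # H(M)=0.56233, H(P)=0.69315, H(Q)=0 -> sqrt(0.21576)
  expect_equal(unclass(D)[1, 2], 0.4645014, tolerance = 1e-6)

  tab2 <- tiny_table(matrix(c(100, 0, 0, 100), 2, 2, byrow = TRUE))
  expect_equal(unclass(jsd_distance(tab2))[1, 2], sqrt(log(2)), tolerance = 1e-12)

  tab3 <- tiny_table(matrix(c(30, 70, 30, 70), 2, 2, byrow = TRUE))
  expect_equal(unclass(jsd_distance(tab3))[1, 2], 0)
})

test_that("sqrt-JSD satisfies the metric axioms on random triples", {
  set.seed(7)
  viol <- 0
  for (i in 1:300) {
    P <- matrix(rexp(3 * 10), 3, 10)
    tab <- tiny_table(P / rowSums(P) * 100)
    D <- unclass(jsd_distance(tab))
    if (max(abs(D - t(D))) > 1e-12) viol <- viol + 1
    if (D[1, 2] > D[1, 3] + D[2, 3] + 1e-12 ||
        D[1, 3] > D[1, 2] + D[2, 3] + 1e-12 ||
        D[2, 3] > D[1, 2] + D[1, 3] + 1e-12) viol <- viol + 1
    if (max(D) > sqrt(log(2)) + 1e-12) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("PAM recovers the obvious partition and the exhaustive optimum", {
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  D <- as.matrix(dist(x)); dimnames(D) <- list(paste0("p", 1:6), paste0("p", 1:6))
  fit <- pam_cluster(distance_matrix(D, "euclidean"), 2, restarts = 0)
  expect_equal(sort(fit$medoids), c(2, 5))
  expect_equal(unname(fit$assignments), c(1, 1, 1, 2, 2, 2))

  set.seed(8)
  for (i in 1:30) {
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    fit <- pam_cluster(distance_matrix(D, "euclidean"), k, restarts = 10, seed = i)
    combs <- utils::combn(n, k)
    best <- min(apply(combs, 2, function(med)
      sum(apply(D[, med, drop = FALSE], 1, min))))
    expect_equal(fit$cost, best, tolerance = 1e-12)
  }

  # all-identical points: zero cost, valid assignment
  D0 <- matrix(0, 4, 4, dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  f0 <- pam_cluster(distance_matrix(D0, "euclidean"), 2, restarts = 0)
  expect_equal(f0$cost, 0)
  expect_true(all(f0$assignments %in% 1:2))

  expect_error(pam_cluster(distance_matrix(D0, "euclidean"), 4), "k must")
})

test_that("PAM agrees with the reference implementation on cost", {
  skip_if_not_installed("cluster")
  set.seed(9)
  pts <- matrix(rnorm(25 * 3), 25, 3)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(1:25, 1:25)
  ours <- pam_cluster(distance_matrix(D, "euclidean"), 3, restarts = 10, seed = 2)
  ref <- cluster::pam(stats::as.dist(D), 3)
  ref_cost <- sum(apply(D[, ref$medoids, drop = FALSE], 1, min))
  expect_lte(ours$cost, ref_cost + 1e-9)
})

test_that("Calinski-Harabasz is scale- and relabeling-invariant and ranks separation", {
  set.seed(10)
  co <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
              matrix(rnorm(20, 5, 0.2), 10, 2))
  lab <- rep(1:2, each = 10)
  ch <- calinski_harabasz(co, lab)
  expect_equal(calinski_harabasz(co * 2, lab), ch, tolerance = 1e-9)
  expect_equal(calinski_harabasz(co, 3 - lab), ch, tolerance = 1e-9)

  # two tight far clusters: k=2 beats any k=3 split
  lab3 <- lab; lab3[1:5] <- 3
  expect_gt(ch, calinski_harabasz(co, lab3))
  expect_error(calinski_harabasz(co, seq_len(20)), "singleton|k = n")
})

test_that("PCoA reproduces Euclidean geometry and equilateral configurations", {
  # 3 points with all pairwise distances 1: two equal positive eigenvalues
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(paste0("s", 1:3), paste0("s", 1:3))
  emb <- pcoa(distance_matrix(D, "euclidean"))
  pos <- emb$eigenvalues[emb$eigenvalues > 1e-9]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_equal(as.matrix(dist(emb$coordinates)), D, tolerance = 1e-9,
               ignore_attr = TRUE)

  set.seed(11)
  pts <- matrix(rnorm(12 * 4), 12, 4)
  D2 <- as.matrix(dist(pts)); dimnames(D2) <- list(1:12, 1:12)
  emb2 <- pcoa(distance_matrix(D2, "euclidean"))
  expect_equal(as.matrix(dist(emb2$coordinates)), D2, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("enterotype pipeline recovers planted clusters and honours forced k", {
  skip_if_not_installed("mclust")
  spec <- synthetic_spec(cohorts = c(A = 30, B = 30), n_species = 100,
                         n_genera = 20, n_enterotypes = 3,
                         enterotype_dominance = 5, shift_scale = 0,
                         shift_vectors = matrix(0, 2, 2), zero_rate = 0.2,
                         seed = 21)
  dat <- simulate_cohorts(spec)
  res <- enterotype_pipeline(dat$genus, k_range = 2:6, restarts = 5, seed = 1)
  expect_equal(res$chosen_k, 3)
  expect_gte(mclust::adjustedRandIndex(res$assignments, dat$truth$enterotypes), 0.9)

  # each planted cluster's top genus is its planted driver
  top1 <- res$top_genera[!duplicated(res$top_genera$cluster), ]
  drivers <- paste0("k__Bacteria|g__", dat$truth$driver_genera)
  expect_setequal(top1$genus, drivers)

  forced <- enterotype_pipeline(dat$genus, k_range = 2:6, restarts = 5,
                                seed = 1, force_k = 5)
  expect_equal(forced$chosen_k, 5)
  expect_equal(forced$ch_by_k, res$ch_by_k)   # CH curve unchanged by override
  expect_equal(length(unique(forced$assignments)), 5)
})
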