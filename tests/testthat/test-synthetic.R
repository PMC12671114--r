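test_that("simulated tables satisfy the abundance invariants and determinism", {
  spec <- synthetic_spec(cohorts = c(A = 15, B = 15, C = 15), n_species = 80,
                         n_genera = 16, zero_rate = 0.3, seed = 51)
  dat <- simulate_cohorts(spec)
  expect_s3_class(dat$species, "abundance_table")
  expect_true(all(unclass(dat$species) >= 0))
  expect_equal(unname(rowSums(dat$species)), rep(100, 45), tolerance = 1e-9)
  expect_equal(unname(rowSums(dat$genus)), rep(100, 45), tolerance = 1e-9)
  # structural zeros never hit a sample's top-3 taxa
  expect_true(all(rowSums(unclass(dat$species) > 0) >= 3))

  dat2 <- simulate_cohorts(spec)
  expect_identical(unclass(dat$species), unclass(dat2$species))
  expect_identical(dat$metadata$age, dat2$metadata$age)

  dat3 <- simulate_cohorts(spec, seed = 99)
  expect_false(identical(unclass(dat$species), unclass(dat3$species)))
})

test_that("metadata flags are consistent and cohort labels correct", {
  spec <- synthetic_spec(cohorts = c(X = 20, Y = 10), n_species = 40,
                         n_genera = 8,
                         med_rates = list(med_J01 = c(0.8, 0.1),
                                          med_H02 = c(0.3, 0.3)),
                         disease_cohorts = "X", seed = 52)
  dat <- simulate_cohorts(spec)
  md <- dat$metadata
  expect_equal(table(md$cohort)[["X"]], 20)
  expect_equal(md$any_medication,
               as.integer(md$med_J01 | md$med_H02))
  expect_equal(unique(md$disease[md$cohort == "X"]), 1L)
  expect_equal(unique(md$disease[md$cohort == "Y"]), 0L)
})

test_that("antipodal shifts give a planted angle of 180 degrees", {
  v <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE)
  spec <- synthetic_spec(cohorts = c(A = 10, B = 10), n_species = 40,
                         n_genera = 8, shift_vectors = v, shift_scale = 1,
                         n_enterotypes = 1, seed = 53)
  dat <- simulate_cohorts(spec)
  expect_equal(dat$truth$angles["A", "B"], 180)
})

test_that("off-center shift configurations are re-centered with a message", {
  v <- matrix(c(2, 0, 1, 0), 2, 2, byrow = TRUE)   # weighted sum nonzero
  expect_message(spec <- synthetic_spec(cohorts = c(A = 10, B = 10),
                                        n_species = 40, n_genera = 8,
                                        shift_vectors = v, seed = 54),
                 "re-centering")
  expect_equal(colSums(spec$shift_vectors), c(0, 0))
})

test_that("infeasible geometry is rejected before sampling", {
  expect_error(cohort_geometry(c(0, 90), c(1, 1)), "weighted sum")
  geom <- cohort_geometry(c(0, 180), c(1, 1))
  expect_equal(attr(geom, "angles")[1, 2], 180)
})

test_that("cohort separation and angle estimability grow with shift magnitude", {
  # column centering makes any two cohort centroids exactly antipodal, so the
  # informative monotone quantities are the centroid norm (separation) and the
  # deviation of estimated multi-cohort angles from their planted values
  run <- function(scale) {
    spec <- angle_recovery_spec(seed = 55)
    spec$shift_scale <- scale
    dat <- simulate_cohorts(spec)
    X <- sqrt_autoscale(dat$species)
    cent <- rowsum(unclass(X), dat$metadata$cohort) /
      as.vector(table(dat$metadata$cohort))
    prs <- utils::combn(rownames(cent), 2)
    est <- vapply(seq_len(ncol(prs)), function(i)
      angle_between(cent[prs[1, i], ], cent[prs[2, i], ]), 1)
    planted <- mapply(function(a, b) dat$truth$angles[a, b], prs[1, ], prs[2, ])
    c(err = mean(abs(est - planted)), norm = mean(sqrt(rowSums(cent^2))))
  }
  res <- vapply(c(0.5, 1.5, 4), run, c(err = 1, norm = 1))
  expect_true(all(diff(res["norm", ]) > 0))   # separation grows
  expect_true(all(diff(res["err", ]) < 0))    # planted geometry emerges
})

test_that("variance-fraction calibration hits its target and edge cases", {
  base <- synthetic_spec(cohorts = c(A = 40, B = 40), n_species = 100,
                         n_genera = 20, n_enterotypes = 1, shift_scale = 0,
                         shift_vectors = matrix(0, 2, 2),
                         med_rates = list(med_J01 = c(0.5, 0.5)),
                         dispersion = 1, zero_rate = 0, seed = 56)
  set.seed(56)
  effect <- rnorm(100) * rbinom(100, 1, 0.3)
  expect_equal(calibrate_variance_fraction(effect, 0, base), effect * 0)
  expect_error(calibrate_variance_fraction(effect, 0.95, base), "0.9")
  expect_error(calibrate_variance_fraction(effect * 0, 0.1, base), "zero")

  cal <- calibrate_variance_fraction(effect, 0.08, base, covariate = "med_J01",
                                     seed = 3)
  vals <- vapply(1:15, function(r) {
    sp <- base; sp$covariate_effects$med_J01 <- cal
    dat <- simulate_cohorts(sp, seed = 800 + r)
    rda_fit(clr_transform(dat$species),
            as.data.frame(dat$metadata)[, "med_J01", drop = FALSE])$adjR2
  }, 1)
  expect_lt(abs(mean(vals) - 0.08), 0.02)
})

test_that("orthogonal calibrated covariates contribute additively", {
  base <- synthetic_spec(cohorts = c(A = 40, B = 40), n_species = 100,
                         n_genera = 20, n_enterotypes = 1, shift_scale = 0,
                         shift_vectors = matrix(0, 2, 2),
                         med_rates = list(med_J01 = c(0.5, 0.5),
                                          med_H02 = c(0.5, 0.5)),
                         dispersion = 1, zero_rate = 0, seed = 57)
  set.seed(57)
  e1 <- c(rnorm(50), rep(0, 50))    # disjoint supports -> orthogonal effects
  e2 <- c(rep(0, 50), rnorm(50))
  c1 <- calibrate_variance_fraction(e1, 0.05, base, covariate = "med_J01", seed = 4)
  c2 <- calibrate_variance_fraction(e2, 0.05, base, covariate = "med_H02", seed = 5)
  joints <- vapply(1:15, function(r) {
    sp <- base; sp$covariate_effects <- list(med_J01 = c1, med_H02 = c2)
    dat <- simulate_cohorts(sp, seed = 900 + r)
    rda_fit(clr_transform(dat$species),
            as.data.frame(dat$metadata)[, c("med_J01", "med_H02")])$adjR2
  }, 1)
  expect_lt(abs(mean(joints) - 0.10), 0.025)
})
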