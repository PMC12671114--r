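# small in-code fixtures shared across test files

tiny_table <- function(values, rank = "genus", samples = NULL, taxa = NULL) {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(samples)) paste0("s", seq_len(nrow(m))) else samples
  colnames(m) <- if (is.null(taxa)) paste0("t", seq_len(ncol(m))) else taxa
  abundance_table(m, rank)
}

random_table <- function(n, t, rank = "genus", seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * t), n, t)
  m <- m / rowSums(m) * 100
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(t)))
  abundance_table(m, rank)
}

write_metaphlan_fixture <- function(path, two_col_header = FALSE) {
  header <- if (two_col_header)
    "clade_name\tNCBI_tax_id\tS1\tS2" else "clade_name\tS1\tS2"
  pad <- function(x) if (two_col_header) sub("\t", "\t0\t", x) else x
  lines <- c(
    "#mpa_vJan21 synthetic fixture",
    paste0("#", header),
    pad("k__A\t100\t100"),
    pad("k__A|g__g1\t60\t30"),
    pad("k__A|g__g2\t40\t70"),
    pad("k__A|g__g1|s__x\t60\t30"),
    pad("k__A|g__g2|s__y\t25\t70"),
    pad("k__A|g__g2|s__z\t15\t0"),
    pad("k__A|g__g2|s__z|t__sgb1\t15\t0"))
  writeLines(lines, path)
  path
}

# calibrated study used by the angle-recovery checks; one draw per seed
angle_study_errors <- function(seed, n_iter = 300) {
  spec <- angle_recovery_spec(seed = seed)
  dat <- simulate_cohorts(spec)
  res <- bootstrap_angles(sqrt_autoscale(dat$species), dat$metadata,
                          reference_cohort = "REF", n_iter = n_iter,
                          seed = seed + 10000L)
  est <- res$pairs
  planted <- mapply(function(a, b) dat$truth$angles[a, b],
                    est$cohort_a, est$cohort_b)
  abs(est$mean_angle - planted)
}
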