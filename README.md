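# micompass

Cross-cohort comparison of gut microbiome composition from shotgun-metagenomic
profiles: who differs from whom, along which community axes, and how much of
the variation metadata and medication can explain.

Clinical microbiome studies routinely face the question of how a disease
cohort's gut community relates to other patient groups and to healthy
references — similar, unrelated, or systematically inverted — and how much of
the compositional variance is attributable to disease, medication exposure
(ATC 3rd-level groups), age and sex. `micompass` implements that full analysis
chain for MetaPhlAn-style relative-abundance tables plus per-sample metadata,
and ships a synthetic multi-cohort generator with planted ground truth so
every stage can be validated end to end.

## The statistics at the core

* **Cohort-centroid angular similarity.** Species abundances are square-root
  transformed and autoscaled, decomposed by PCA, and each principal component
  is screened with a univariate logistic GLM against membership of a reference
  cohort (keep PCs with *P* < 0.05). In the screened subspace each cohort is
  represented by the centroid of its sample scores, and for every cohort pair
  the angle

  θ(A,B) = arccos( x̄_A · x̄_B / (‖x̄_A‖ ‖x̄_B‖) )

  is recorded over stratified bootstrap iterations (default 500), giving a
  mean ± SD per pair. Small mean angles indicate similar composition,
  angles near 90° unrelated composition, angles near 180° an inverted
  abundance profile.
* **Enterotyping.** Square-root Jensen–Shannon divergence on genus profiles
  (a metric bounded by √ln 2), partitioning-around-medoids clustering
  (BUILD + SWAP, random restarts), Calinski–Harabasz model selection on PCoA
  coordinates, and per-cluster driver-genus summaries.
* **Variance partitioning.** Redundancy analysis of the clr-transformed
  species matrix: marginal (single-variable) and joint explained-variance
  fractions with the Ezekiel adjustment 1 − (1−R²)(n−1)/(n−m−1), forward
  stepwise selection with a global permutation pre-test, conditional
  permutation tests and an adjusted-R² ceiling, plus PERMANOVA on
  Bray–Curtis (or Euclidean-clr) distances.
* **Medication–taxon association.** Two-step regression: a univariate screen
  of every (feature, medication) pair with one joint Benjamini–Hochberg
  correction, then one multivariate Gaussian model per screened feature
  containing its screened medications plus age and sex, with no further
  multiplicity correction. Bootstrap point-biserial correlation
  (1,000 resamples) links features to a binary outcome.
* **Alpha diversity.** Shannon index (nats, species level) with pairwise
  Wilcoxon rank-sum cohort comparisons and BH correction.

## Worked example

```r
library(micompass)

# a synthetic five-cohort study with planted centroid geometry:
# four satellite cohorts at 45/90/135/180 degrees from a reference cohort
spec <- angle_recovery_spec(seed = 1)
dat  <- simulate_cohorts(spec)

res <- bootstrap_angles(sqrt_autoscale(dat$species), dat$metadata,
                        reference_cohort = "REF", n_iter = 500, seed = 1)
subset(res$pairs, cohort_a == "REF")
```

```
  cohort_a cohort_b mean_angle sd_angle         interpretation
1      REF   SAT135  133.35319 1.183349   inversely correlated
2      REF   SAT180  174.92466 1.775350   inversely correlated
3      REF    SAT45   50.33220 1.922677    similar composition
4      REF    SAT90   89.00386 1.262101 dissimilar composition
```

The planted angles (135°, 180°, 45°, 90°) are recovered within a few degrees:
a satellite cohort at 45° shares its dominant community axes with the
reference, one at 180° carries the same axes with inverted abundances, and
one at 90° varies along unrelated axes. `res$significant_pcs` lists the
screened components and `res$plugin_angles` the full-data angles.

The same dataset runs through the rest of the pipeline:

```r
div <- diversity_pipeline(dat$species, dat$metadata)   # Shannon + pairwise tests
ent <- enterotype_pipeline(dat$genus, k_range = 2:6, seed = 1)
prt <- marginal_partition(clr_transform(dat$species),
                          as.data.frame(dat$metadata)[, c("disease", "any_medication",
                                                          "age", "sex")])
```

Or from the shell via the dispatcher:

```r
run_cli(c("simulate", "--seed", "1", "--outdir", "sim"))
run_cli(c("all", "--abundance", "sim/abundance.tsv",
          "--metadata", "sim/metadata.tsv", "--seed", "1", "--outdir", "out"))
```

which writes per-stage TSV tables and a JSON run manifest; identical seeds
give byte-identical outputs.

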