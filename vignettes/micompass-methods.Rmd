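---
title: "Methods: cohort geometry, enterotyping and variance partitioning in micompass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort geometry, enterotyping and variance partitioning in micompass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micompass)
```

`micompass` compares gut microbiome composition across patient cohorts. This
vignette is the package's own account of the statistical machinery: the models
and their assumptions, the tunable parameters, what the synthetic generator
does and does not emulate, and the numerical choices made where the design was
genuinely open. No empirical claim is made here beyond what the package's
tests and `scripts/acceptance.R` compute.

## Input model and transforms

The universal input is a samples × taxa matrix of relative abundances in
percent at a single taxonomic rank, as produced by merging per-sample profiler
output, plus per-sample metadata (cohort, age, sex, 0/1 medication-exposure
flags at the ATC 3rd level, a disease flag). Relative abundances are
compositional: only ratios carry information, and every analysis first maps
them to a scale where Euclidean operations are defensible.

* `clr_transform()` — centered log-ratio: per sample,
  $z_i = \ln(x_i / g(x))$ with $g$ the geometric mean after adding a
  pseudocount and re-closing. Rows sum to zero by construction. The
  pseudocount default is **half the smallest nonzero proportion in the whole
  table**: a scale-aware zero replacement. There is no canonical choice; the
  value is carried on the result object and overridable.
* `sqrt_autoscale()` — element-wise square root of proportions, then each
  taxon column centered and divided by its sample SD (n−1 convention
  throughout the package). Constant columns are set to zero and flagged, not
  dropped, to keep dimensions stable. This is the input scale of the angular
  statistic.

The transform is carried as a tag on the matrix, and downstream stages refuse
the wrong tag: angles require `sqrt_autoscaled`, association models `clr`.
Silently mixing transforms is the main practical foot-gun in this kind of
pipeline, so it is a type error here.

## The cohort-centroid angular statistic

The question "is cohort B's gut composition similar to, unrelated to, or the
inverse of cohort A's?" is answered geometrically:

1. PCA (full SVD) of the sqrt-autoscaled species matrix. A deterministic sign
   convention (largest-magnitude loading entry positive) makes runs
   reproducible.
2. **Screening**: one univariate logistic GLM per component, outcome =
   membership of the *reference cohort* versus all other samples; components
   with Wald $P < \alpha$ ($\alpha = 0.05$, unadjusted) are retained. If a fit
   reports separation or non-convergence the likelihood-ratio p-value is used
   and the component flagged.
3. **Centroids**: per cohort, the mean score vector on the retained
   components (unweighted; a variance-weighted variant would be easy but the
   centroid is defined as a plain mean).
4. **Angles**: $\theta = \arccos(\cos\text{-similarity})$ in degrees, for
   every cohort pair, over `n_iter` stratified bootstrap iterations (samples
   resampled with replacement within cohort). The mean and SD per pair are
   reported, with linear (not circular) summaries — angles live on the
   bounded range [0°, 180°], where the linear mean is the conventional
   report.
5. **Interpretation bands**: below 60° similar composition, 60–120°
   dissimilar/uncorrelated (orthogonal near 90°), above 120° inversely
   correlated. The bands operationalize a deliberately coarse protractor-style
   reading of cosine similarity; both boundaries are configurable.

Two design points were genuinely open and are worth recording:

* **What the iterations vary.** The package holds the PCA and the screened
  subspace fixed and bootstraps samples within cohort. Refitting the PCA in
  every iteration makes axes and signs incommensurable across iterations
  (angles between centroids from different bases are not comparable), whereas
  a fixed subspace yields well-defined per-pair SDs. The alternative — refit
  with sign alignment to the full-data loadings — is implemented behind
  `refit_pca_per_iteration = TRUE` for sensitivity analysis.
* **Degenerate centroids.** A resample whose centroid is numerically at the
  origin has no direction; such iterations are redrawn (at most 100 times,
  then an error). Cohorts need ≥ 3 samples; smaller ones are refused by name.

### Geometry of what is identifiable

PCA scores are column-centered, so cohort centroids are deviations from the
grand mean. Planted shift vectors $v_c$ are therefore only identifiable
*after* centering: the generator requires (or re-centers to) configurations
with $\sum_c n_c v_c = 0$ and records the angles of exactly those vectors as
ground truth. Two consequences matter for validation design:

* With two cohorts, the centroids are exactly antipodal whatever the signal
  strength, so "the angle grows with magnitude" is not a meaningful
  monotonicity check; the package's property tests instead verify that the
  centroid norm grows and the deviation of estimated multi-cohort angles from
  their planted values shrinks as the shift magnitude increases.
* The reference-vs-rest screening outcome separates along the direction of
  the reference cohort's own shift vector. A principal component orthogonal
  to that direction carries no mean separation and is screened out, which
  collapses the measured geometry. The validation configuration therefore
  places the principal axes of the between-cohort scatter at ±45° to the
  reference direction with a clear eccentricity, so both in-plane components
  always carry screening signal.

## The validation study (`angle_recovery_spec()`)

Five cohorts of 60 samples (a reference plus satellites at 45°, 90°, 135° and
180°; all ten pairwise angles lie in {45, 90, 135, 180}), 200 species in 40
genera. Directions (0°, −45°, 90°, −135°, 180°) and magnitudes solving the
weighted-sum-zero and axis-at-45° constraints give the planted geometry. The
signal amplitude is calibrated — the recovery property is defined *at
calibrated signal strength* — against two error mechanisms that pull in
opposite directions:

* at weak signal, sampling noise and the ~5% of noise components that pass
  screening by chance contaminate the centroids and bias angles toward 90°;
* at strong signal, the square-root/closure map's curvature and the
  variance-dependent autoscale shrinkage distort the planted plane
  (log-normal effects of several log-units are far outside the linear range
  of $\sqrt{\mathrm{softmax}}$), and structural zeros add further distortion.

The shipped operating point (shift scale 5, dispersion 0.5, structural-zero
rate 0.05, baseline spread 0.7 — see `angle_recovery_spec()`) was chosen once,
on seeds disjoint from those used by the test suite, such that bootstrap mean
angles recover every planted pair within a 10° band in at least 90% of draws.
Two failure mechanisms bracket it: below it, centroid noise and
chance-screened components bias angles toward 90°; above it, map curvature
creates a third structured component that can rotate the between-cohort axes
until one in-plane component loses its screening signal. A flatter baseline
and low structural-zero rate keep that curvature component small.

## Enterotyping

Genus-level profiles are compared by the square root of the Jensen–Shannon
divergence (natural-log entropies, $0\ln 0 = 0$), which is a proper metric
bounded by $\sqrt{\ln 2}$. Clustering is partitioning around medoids written
in-package: greedy BUILD seeding, then SWAP moves accepted only on strict cost
improvement (determinism), best of `restarts` random restarts (default 10;
restart 0 is the deterministic BUILD solution). Ties in assignment go to the
lowest-index medoid. The from-scratch implementation is cross-checked in the
test suite against exhaustive enumeration on small instances and against the
reference implementation in the `cluster` package.

Model selection scans k with the Calinski–Harabasz index computed on PCoA
coordinates of the JSD matrix (all positive-eigenvalue axes): CH needs
centroids, and the PCoA embedding is the standard way to obtain them from a
non-Euclidean distance. Negative eigenvalues are reported, never corrected.
`chosen_k` maximizes CH with ties to the smaller k, but a `force_k` override
is accepted and the full CH curve always reported — a study may deliberately
prefer a finer partition than the CH optimum, and that choice should be
informed, not silent. Per-cluster "driver genera" are the top genera by median
relative abundance.

Validation plants enterotypes as log-scale boosts (dominance 5 versus
dispersion 1 — dominance well above noise) on disjoint driver genera in three
cohorts of 40; the CH-selected k and the adjusted Rand index against the
planted labels are recomputed by the acceptance script.

## Variance partitioning

`rda_fit()` is redundancy analysis reduced to its computational core: the
column-centered response matrix is projected onto the column space of the
explanatory design (treatment-coded dummies, 0/1 flags as numeric), and
$R^2 = \mathrm{tr}(\hat Y^\top \hat Y)/\mathrm{tr}(Y_c^\top Y_c)$, adjusted by
Ezekiel's formula $1-(1-R^2)(n-1)/(n-m-1)$. Aliased and constant columns are
dropped with warnings. The implementation is verified against
`vegan::RsquareAdj` to 1e-10 and against the closed form
$R^2 = r_{pb}^2$ for a univariate response on a binary predictor.

Per-variable "variance explained" values are **marginal** single-variable
fits: with correlated predictors these need not sum to the joint fraction,
which is exactly the behavior of per-variable bar charts whose parts exceed
the joint total. The joint all-variable fit is always reported alongside.

`stepwise_rda()` is forward selection with three guards:

1. a **global permutation pre-test** of the all-candidate model — selection
   only starts if it is significant (the two-stopping-rule scheme: testing
   only the best of k candidates is a selection-biased test, so without the
   global guard the family-wise false-selection rate runs well above the
   nominal level);
2. a **conditional permutation test** of the best candidate (residuals of the
   current model permuted; computed as a single matrix product over all
   permutations);
3. an **adjusted-R² ceiling**: a step may not push the model's adjusted R²
   above the all-candidate ceiling.

Permutation p-values always use the add-one rule $(1+\#\{F_\pi \ge F\})/(1+B)$
and are therefore never exactly zero. Note one structural property found while
validating: when every remaining candidate is null, the ceiling blocks the
last truly informative variable about half the time (the candidate-model and
all-candidate adjusted R² are equal in expectation), so selection is
deliberately conservative near the boundary — the package's consistency
property is that *no null candidate is selected ahead of an informative one*,
not that every informative variable is always admitted.

`permanova()` computes the pseudo-F from the Gower-centered matrix
$G = -\tfrac12 J D^{(2)} J$ and the design hat matrix, with free permutation
of sample labels. The default distance is Bray–Curtis on proportions
(`euclidean_clr` selectable). On Euclidean distances the pseudo-F equals the
classical RDA F, which the tests assert; type-I error is recomputed by the
acceptance script (nominal 0.05, 199 permutations, 200 null data sets —
permutation counts in simulations are 199 rather than the interactive default
of 999, a resolution entirely adequate for α = 0.05 decisions).

## Two-step association analysis

Step one fits one Gaussian linear model per (feature, medication flag) pair on
clr abundances (or autoscaled functional modules) and applies a single
Benjamini–Hochberg correction across *all* feature × covariate tests — one
screening step, one correction; per-covariate BH pooling would be a different
(laxer) guarantee. Step two fits, per feature with at least one screened
medication, one multivariate Gaussian model containing all its screened
medications plus age and sex, with no further multiplicity correction — the
BH-gated first step is the error control, and the gating invariant (no
multivariate entry without a screened univariate pair) is asserted on every
run. Age and sex enter only the multivariate step, read off the design's
ordering of screening before adjustment; perfectly collinear medications are
aliased, dropped and flagged. A Gaussian identity link on clr values is the
standard reading for transformed abundances.

The heatmap export keeps features with at least two significant multivariate
medication associations (threshold configurable), mirroring the convention of
reporting only multiply-supported features.

`biserial_bootstrap()` computes the point-biserial correlation (identically
Pearson against a 0/1 outcome — the tests assert equality) with percentile
intervals over 1,000 resamples; one-class resamples are redrawn and counted.

## Alpha diversity

Shannon index in nats at species level (the convention of the ecology package
the calculation delegates to), pairwise cohort comparison by Wilcoxon rank-sum
with BH correction. The exact mode enumerates all $\binom{m+n}{m}$ group
assignments of the rank sum (midranks under ties), used for small groups; the
normal approximation applies tie and continuity corrections. All cohort pairs
are computed; any reference-group display is presentation only.

## The synthetic generator

`simulate_cohorts()` draws, per sample,
$\log a = \text{baseline} + \text{enterotype boost} + \text{cohort shift} +
\sum_k \beta_k x_k + \varepsilon$, exponentiates, applies structural zeros
(never to a sample's top-3 taxa, avoiding empty samples), and closes rows to
100%. The log-normal (logistic-normal after closure) base model was chosen
over a Dirichlet-multinomial because the angular statistic lives in a
transformed Euclidean space and the log-space effect geometry must be
controllable directly. Cohort shifts live in a low-dimensional geometry space
embedded through a random orthonormal basis; covariates (medication flags with
per-cohort exposure rates, disease, standardized age, sex) add planted effect
vectors. Defaults — 5 cohorts × 60 samples, 200 species in 40 genera, 3
enterotypes, dispersion 1, baseline SD 1.5, structural-zero rate 0.2,
per-cohort age means spanning 50–65 years (SD 10) — describe a desk-scale
study with cohort sizes comparable to multi-cohort clinical datasets.

`calibrate_variance_fraction()` scales an effect vector until the expected
marginal RDA adjusted R² on clr output matches a target, by Monte-Carlo
iteration on the ratio model $f(s) = as^2/(as^2+b)$; targets above 0.9 are
refused as unattainable under the noise model.

What the generator does **not** emulate: phylogenetic correlation among taxa,
longitudinal sampling, sequencing-depth artefacts, batch effects, and the
heavy taxonomic tail of real metagenomes. Passing the recovery tests
demonstrates that the estimators recover what they claim from data satisfying
their assumptions — not that real cohort geometry is this clean.

## Numerical conventions

* Sample SD (n−1) everywhere; clr rows sum to 0 within 1e-9; autoscaled
  columns mean 0 / variance 1 within 1e-9.
* JSD entries clipped at 0 before the square root; symmetric within 1e-12.
* PAM accepts only strictly improving swaps; assignment ties go to the
  lowest-index medoid; restart RNG is seeded and recorded.
* Angle cosines are clipped to [−1, 1]; centroid norms below
  $10^{-8}\sqrt{d}$ are degenerate.
* Result TSVs print 12 significant digits — lossless round-trips and
  byte-identical reruns under a fixed seed.
* Simulation problem sizes in tests and the acceptance script (20 seeds × 300
  bootstrap iterations for angle recovery, 50 replicates for calibration
  checks, 200 null data sets for type-I rates, 199 permutations per test) are
  the package's chosen desk-scale study conditions.

## Known limitations

* The angular statistic inherits the screening step's failure mode: if no
  principal component separates the reference cohort, there is no subspace
  and the run errors out (by design, loudly).
* CH-based k selection assumes roughly convex clusters in PCoA space;
  genuinely nested or gradient-like community structure will not yield a
  clean optimum (the full CH curve is always available).
* Marginal RDA fractions on correlated predictors overlap; they answer "how
  much could this variable alone explain", not "how much does it add".
* The two-step association design tests medications one at a time in the
  screen; strongly collinear exposures reach the multivariate step together
  and may alias.
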