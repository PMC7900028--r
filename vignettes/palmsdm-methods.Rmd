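---
title: "Models and design choices in palmsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in palmsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(palmsdm)
```

palmsdm quantifies three things about an invasive/native species pair:
how much of the climate space they share, how much of each other's
ecological role they could usurp, and where on the map both are forecast
to occur now and under future climates. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The niche-overlap model

Overlap is measured in an environmental ordination, not in geography.
The background climate table (all cells of the study region, or a
background sample) is standardized per variable and decomposed by PCA on
the correlation matrix — appropriate because bioclimatic variables mix
units (°C, mm, unitless ratios). Only the first two axes are used
downstream, following the convention of the PCA-env framework.

Each species becomes an occupancy density on an `R × R` grid (default
`R = 100`) bounded by the minimum and maximum background scores per axis:
a product-Gaussian kernel density of its occurrence scores, normalized to
sum to one. Bandwidths follow Silverman's rule per axis on the occurrence
scores; a species with fewer than two distinct scores borrows the
background bandwidth. Overlap is Schoener's statistic

$$D = 1 - \tfrac12 \sum_{ij} |z_{1,ij} - z_{2,ij}| \in [0, 1].$$

**Availability correction.** Dividing the occurrence density by the
background availability density ("occupancy" in the strict sense)
down-weights climates that are simply common. We expose this as
`availability_correct` but default it to **off**, for a validation
reason: when occurrences are sampled in proportion to suitability cell by
cell (as our generator does, and as presence records approximately are),
the *uncorrected* density in niche space is the image of the geographic
occurrence process, so its D converges to the brute-force, cell-level D
computed from the true suitability surfaces — the quantity our recovery
experiments check. The corrected variant estimates a different (also
legitimate) quantity: overlap of suitability rather than of occurrence
mass. Users comparing species across very different backgrounds may
prefer `availability_correct = TRUE`.

**Similarity test.** The null asks: would this much overlap arise if one
species' niche sat anywhere in the available climate? Each replicate
translates the second species' density so its centroid lands on a
background cell drawn with probability proportional to the background
mass in that cell (a random *geographic* background point, mapped into
niche space), truncating at the grid edge and renormalizing; the p-value
is the +1-corrected rank of the observed D, so its floor is
`1/(n_reps + 1)`. Defaults: `n_reps = 1000`, one-sided "greater".
Two design points deserve note:

- Relocating *both* densities (an option, `shift = "both"`) doubles the
  edge-truncation artifacts and measurably over-rejects in our
  simulations; the single-shift default is better behaved.
- Under data generated by re-sampling species at random niche centers the
  test is slightly liberal, because a translated density keeps the shape
  it acquired at its original position while a species genuinely centered
  elsewhere adapts its shape to the local availability. This is a known
  approximation of translation-based nulls. Under data generated by the
  test's own relocation mechanism (`relocate_grid()`), rejection at
  α = 0.05 is calibrated; the test suite verifies exactly that.

## Suitability algorithms

All four algorithms map a cell's environment to `[0, 1]` and propagate
nodata; the instance-based ones retain their training matrices.

- **Bioclim (envelope score).** Per variable, the query's percentile *p*
  in the training distribution with the mean-rank convention
  `p = (rank − 1)/(n − 1)` (ties averaged); cell score
  `min_v 2 min(p, 1 − p)`, zero outside any training min–max. The
  convention matters — others shift hand-computed scores — so it is fixed
  and documented.
- **Domain (Gower).** Suitability `1 − min_t d(x, t)` with
  `d = mean_v |x_v − t_v| / range_v(training)`; zero-range variables are
  dropped with a warning.
- **SVM.** Two-class RBF presence-vs-background machine (kernlab), with
  background weighted down in inverse proportion to its count so classes
  carry equal total weight. Scores are decision values passed through a
  Platt-style logistic calibration fitted on the training data; this is
  deterministic given the seed (which fixes the kernel-width heuristic)
  and robust to the sign convention of the underlying library.
- **Maxent-style.** L1-penalized logistic regression (glmnet) on linear +
  quadratic features standardized on the pooled data, the penalized-GLM
  equivalence of the maximum-entropy model family restricted to those
  feature classes (hinge/product features are out of scope). The penalty
  is `reg_mult × λ_max / 100`, reached by a warm-started path (a single
  small λ can fail under complete separation); suitability is the
  complementary log-log transform `1 − exp(−e^η)`.

**Variable selection** retains factors of the background correlation
matrix by the Kaiser criterion applied with a small boundary tolerance
(eigenvalue > 1 − 0.05). The tolerance exists because a genuinely
independent variable's population eigenvalue is exactly 1, and any
sampling noise drops it just below the strict cut; without the tolerance
the criterion discards such variables unpredictably. Loadings are
varimax-rotated and the strongest-loading variable represents each
factor, substituting the next contributor when a candidate correlates at
`|r| ≥ 0.7` (default `r_max`) with an already-selected variable.

## Ensembles, thresholds, areas

Each algorithm is refitted on `n_rep = 10` bootstrap 75/25
training/testing partitions of presences and background; each replicate
map gets a TSS (sensitivity + specificity − 1) at the cut maximizing
sensitivity + specificity on its held-out test data, with candidate cuts
the sorted unique predicted values (the exact optimum over achievable
confusion tables; ties resolve to the lowest cut). Replicates with
TSS ≤ 0.5 are excluded from the ensemble; the rest are min–max rescaled
and averaged per cell with TSS weights. An all-zero map stays zero when
rescaled (an envelope predicting "nowhere" is information, not a missing
scale); other constant maps go to 0.5 with a warning. The per-cell SD of
the rescaled contributing maps is the uncertainty surface.

Note a statistical property the test suite documents: at the *optimal*
cut the TSS of a skill-less map is positively biased in finite samples
(it is a Kolmogorov–Smirnov-type statistic), so "TSS ≈ 0 for random
maps" holds at a fixed cut, not at the selected one.

Thresholds for binarization: MTP (minimum suitability at training
presences), P10 (10th percentile of those), maxSS (as in TSS
evaluation), eqSS (cut minimizing |sens − spec|). The final rule is a
configuration key per species (`threshold_rule`), defaulting to P10 for
the native and MTP for the invader — the pair of rules an expert
assessment settled on in the motivating study system. Areas use the
small-cell spherical approximation
`(111.320 Δlon cos φ)(110.574 Δlat)` km² at the cell-center latitude;
equal-area reprojection is out of scope at desk scale. Future projection
re-predicts the stored replicate models on the future layers and
re-ensembles with the TSS weights earned on current data; binarization
reuses the current-climate thresholds (a flag exists to recompute, but
there is no future truth to evaluate new thresholds against).

## The synthetic-data generator

The generator exists so every estimator in the package can be checked
against known truth; its defaults are the package's study conditions.

- **Climate.** White noise smoothed by a Gaussian filter (SD
  `autocorr_length` cells), then empirically orthonormalized and mixed
  through the Cholesky factor of a compound-symmetric correlation matrix:
  inter-layer correlation is exact by construction, spatial
  autocorrelation is controlled by the filter width. Layers are
  standardized; they emulate the *statistical* texture of bioclim
  variables, not their actual covariance or any GCM physics.
- **Species.** Suitability is Gaussian in environmental space,
  `s = exp(−d²/2c)` with `d²` the Mahalanobis distance from the niche
  center. When a target prevalence (fraction of cells with `s > 0.5`) is
  given, `c` is calibrated on the realized landscape so the suitable
  fraction is exact.
- **Occurrences.** Bernoulli per cell with probability `s × effort`, one
  record per success at the cell center plus sub-half-cell jitter (so
  disaggregation has work to do); `effort` is set from a target expected
  count. This emulates proportional sampling, not the spatial biases of
  real databases (roadside clustering, country borders, uneven effort).
- **Interactions and traits.** Bird assemblages with exact shared/unique
  counts, lognormal traits (all three real traits are strictly positive).

Two consequences of these conditions, measured during development and
worth knowing when reading the tests: with a smooth Gaussian suitability
and proportional sampling, (i) the achievable TSS has a ceiling set by
the truth itself (imperfect discrimination is a property of the data, not
the models), which the TSS > 0.5 ensemble filter only clears at low
prevalence — the workflow defaults therefore simulate a prevalence-0.1
species; and (ii) the maxSS threshold sits near the mean background
suitability, so binary areas are recovered well at moderate prevalence
(the recovery experiment uses 0.3 and admits all positive-skill
replicates) but carry a positive bias of a few tens of percent at low
prevalence. Passing recovery tests therefore validates the estimators
under proportional sampling; they do not certify performance under the
sampling pathologies of real occurrence data.

## Problem sizes

The validation experiments run at sizes chosen to keep the full suite
fast on a laptop while leaving the conclusions stable across seeds:
60 × 60-cell landscapes with 3–5 layers, 100–200 occurrences per species,
100 × 100 occupancy grids (60 × 60 in the 200-trial calibration run),
199–1000 randomization replicates, 10 bootstrap replicates × 4
algorithms, and 5–20 seeds per recovery experiment.

## Known limitations

- Occurrence cleaning implements the coordinate tests that need no
  external gazetteer (zero coordinates, |lat| = |lon|, duplicates,
  nodata cells); country-centroid and institution tests are out of scope.
- Greedy rarefaction does not maximize the retained record count (that
  problem is NP-hard); the tests bound it against an exhaustive oracle on
  small instances.
- Raster I/O is plain-text ESRI ASCII grid; polygons are GeoJSON.
- The niche-equivalency test (pooling and re-splitting occurrences) is
  not implemented; only the similarity test is.
- MaxEnt-style fitting omits hinge/threshold/product features, and no
  hyperparameter sweeps are performed anywhere — all settings are fixed
  and logged.
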