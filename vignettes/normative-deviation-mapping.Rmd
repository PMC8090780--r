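---
title: "Methods: normative deviation mapping with Gaussian processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative deviation mapping with Gaussian processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(normdev)
```

## The problem

A case-control contrast answers "where does the *average* patient
differ?". In heterogeneous disorders that average can be a poor
description of any individual. Normative deviation mapping inverts the
question: model the healthy-population distribution of a measure as a
function of covariates, then ask, for each person and each brain locus,
how far outside that distribution they fall. This vignette documents
the modelling choices in `normdev`, the synthetic data the package is
calibrated against, and what the tests do and do not establish.

## The normative model

Each voxel's gray-matter volume is regressed on standardized (age, sex)
with a Gaussian process. The covariance is the sum of a constant, a
linear, and a squared-exponential component plus i.i.d. Gaussian noise:

$$k(x,x') = v_c + v_l\,x^\top x' + v_f\,
\exp\!\left(-\tfrac{\|x-x'\|^2}{2\ell^2}\right) + v_n\,\delta_{xx'}.$$

The constant + linear parts absorb the mean trend (no explicit mean
function; targets are standardized per voxel by their training mean and
SD and de-standardized at prediction time), while the
squared-exponential admits smooth non-linearity in age. This is the
conventional kernel for normative modelling of lifespan imaging data:
age trends are near-linear over 20–70 years but need not be exactly so.
Sex enters as a covariate of one joint model rather than two separate
models, so male and female normative curves and their difference all
derive from one forward model.

The deviation score divides by the *total* predictive uncertainty,

$$Z = \frac{y - \hat y}{\sqrt{\sigma^2_{f} + \sigma^2_n}},$$

posterior variance plus noise variance, because the object being scored
is an *observation*, not a posterior mean. On healthy hold-out data
this makes Z standard normal when the model is right — which is exactly
what the calibration tests check (mean 0, SD 1, and tail exceedance
2.6 at its nominal 0.466% across 400 subjects × 3,392 voxels).

Healthy subjects are never scored in sample: a 10-fold cross-validation
(random, stratified by sex, fold sizes within one) scores each healthy
subject from a model trained on the other folds. Patients are scored by
the model trained on all healthy controls ("transfer"). Both
provenances are recorded in the deviation-map object.

### Hyperparameters and numerics

* **Optimization.** Hyperparameters maximize the log marginal
  likelihood via L-BFGS-B on log-parameters (bounds ±9/+6 in log space)
  with multi-restart (default 2; jittered initial values). The
  best-so-far criterion guarantees restarts never decrease the
  likelihood.
* **Tied covariance, per-voxel noise.** By default the four covariance
  hyperparameters are estimated once, by maximizing the *summed*
  marginal likelihood over a random subsample of 30 standardized
  voxels, and the noise variance $v_n$ is then profiled per voxel. The
  computational key is that all voxels share the covariate matrix: one
  symmetric eigendecomposition $K_f = Q\Lambda Q^\top$ per training set
  turns every per-voxel likelihood, noise profile, posterior mean and
  posterior variance into vectorized $O(n)$ operations with
  $(\Lambda + v_n)^{-1}$. A fully per-voxel mode
  (`hyperparams = "pervoxel"`) optimizes all five parameters per voxel
  and is practical for small voxel counts; on standardized targets the
  tied mode loses little, since per-voxel scale differences are
  absorbed by the target standardization and the per-voxel noise.
* **Degenerate inputs.** Eigenvalues are clamped at zero; if the system
  is still numerically singular a jitter of $10^{-6}\times$ the maximum
  diagonal is added and escalated tenfold up to $10^{-2}$ before
  erroring. Constant voxels (zero training SD) are fitted with unit
  scale and flagged. Queries outside the fitted age range warn
  (extrapolation is allowed — the forward model is evaluated at ages 20
  and 70) rather than error.

## Thresholds, scores, and extreme value statistics

Extreme deviations use strict per-tail inequalities ($Z < -z$,
$Z > +z$) at $z \in \{1.96, 2.6, 3.1\}$, the per-tail standard-normal
quantiles of $p < .05, .005, .001$ after conventional rounding. A
per-subject FDR alternative converts each voxel to a two-sided normal
$p = 2(1-\Phi(|Z|))$ and applies Benjamini–Hochberg across the
subject's in-mask voxels (the map is the subject's, so the correction
family is the subject's voxels). Percentages are always relative to the
total in-mask voxel count.

The threshold-free summary is the mean of the top 1% of |Z| per subject
(count = ceiling of 0.01·V; at least 100 voxels required). We read
"trimmed" as *the top 1% is itself the trim* — an optional switch
additionally discards the single most extreme value
(`trim_tip = TRUE`), the other defensible reading. A Gumbel
distribution is fitted to these per-subject summaries by maximum
likelihood (moment-based initialization, BFGS on location and
log-scale), returning QQ diagnostics; an all-identical sample is
reported as a degenerate fit with scale 0 rather than an error. Gumbel
is the default family because the statistic summarizes sample maxima of
light-tailed scores; a generalized extreme value fit (extra shape
parameter) is available where tail-class uncertainty matters.

## Group inference

Group comparisons use the Mann–Whitney U test: exact by full
enumeration of all $\binom{n_A+n_B}{n_A}$ assignments when the smaller
group has ≤ 8 subjects (correct under ties), otherwise the normal
approximation with tie and continuity correction. The Bonferroni–Holm
family is the set of pairwise group comparisons per metric per
threshold — the natural family for the three-group design; it is
configurable because other groupings are defensible. Correlations with
symptom scores default to Pearson (Spearman available), computed both
pooled across the patient groups (healthy controls carry no symptom
scores and are excluded) and within each group; the pooled/within
contrast is itself a finding of interest, since a pooled association
can be carried by group separation alone. Two-sided tests throughout;
directions are reported descriptively.

The voxel-wise GLM is ordinary least squares per voxel on a cell-means
group design (optional centred nuisance columns), with directional
pairwise contrasts. Inference is by label permutation — Freedman–Lane
residual permutation when nuisance columns are present — with
per-voxel one-sided uncorrected $p = (1 + \#\{t^\ast \ge t\})/(B+1)$
and family-wise correction from the permutation distribution of the
maximum |t| over in-mask voxels. The smallest achievable $p$ is
$1/(B+1)$; corrected never falls below uncorrected. No cluster
statistics or TFCE: max-statistic FWER is the minimal, assumption-light
reading, and the default design is group-only because age and sex are
already absorbed by the normative model.

Overlap maps are per-voxel proportions of subjects extreme at that
voxel within a group; peaks are reported with 0-based grid coordinates,
ties broken by lowest flat index with all tied peaks listed. A useful
exchange-of-summation identity — the group mean of per-subject extreme
percentages equals the in-mask mean of the overlap map — is used as a
cross-check in the tests.

## The synthetic cohort

No clinical MRI data ship with the package, so the generator is a
first-class module that emulates the *statistical* structure the
analysis relies on, at the default design of 400 healthy / 116 bipolar
/ 94 schizophrenia-like subjects on a 20×24×20 grid (ellipsoidal mask,
3,392 voxels, nominally 4 mm voxels):

* **Mean surface.** Baseline 0.5 (arbitrary units) plus a parcel-wise
  age slope (k-means parcellation of the mask into 8 contiguous
  parcels; slopes −0.004 to −0.001 units/year, steepest in the most
  anterior "frontal" parcels) plus a +0.02 male offset in those
  parcels. Age is centred at 45 years.
* **Noise.** White Gaussian noise smoothed by a separable Gaussian
  kernel (FWHM 2 voxels, emulating 8 mm smoothing at 4 mm resolution)
  and rescaled *per voxel* to SD 0.05 exactly — the rescale factor is
  analytic for a separable kernel, so spatial correlation is induced
  without disturbing the marginal SD and Z-calibration stays testable.
  Smoothing is applied to the noise, not the signal.
* **Lesions.** Patients carry idiosyncratic focal reductions: count per
  subject is gamma-Poisson (negative binomial, size 0.6) with means 0 /
  1.4 / 13 (HC / BP / SZ), modestly male-biased (1.5:1 within group,
  group means preserved); centres are drawn with 12:1 preference for
  the frontal parcels; each lesion is a cosine-tapered sphere of radius
  2.5 voxels with peak amplitude drawn from −0.18 to −0.10 units
  (about 2–3 predictive SDs at centre).

The lesion regime was calibrated once, during generator design, to
reproduce the joint phenomenon the analysis is about, and the choice is
worth recording. Deep, sparse lesions (many SDs at centre) maximize
*extreme-voxel* counts per unit of lesion mass but leave the
group-*mean* shift weak: almost all their mass lands in voxels that are
already far beyond the threshold, which is statistically wasted on the
mean contrast. Many shallow dips invert that: most of the tapered mass
sits *below* the extreme threshold where it still moves the group mean.
The defaults therefore use numerous shallow dips concentrated in
vulnerable parcels, which yields, stably across seeds: an SZ:HC
extreme-negative prevalence ratio around 3.5–4, FWER-significant HC>SZ
voxels concentrated in the vulnerable parcels, and peak SZ overlap of
roughly 10–14% — robust group effects coexisting with sparse individual
overlap, with healthy rates pinned at the theoretical normal tail. It
is also the more realistic reading of psychotic-disorder neurobiology:
subtle distributed gray-matter reduction of which only a minority of
loci cross any extreme threshold in any one person.

PANSS symptom scores are simulated as three subscales (positive,
negative, general) with group-specific means and SDs anchored to
typical clinic values (BP total ≈ 45, SZ total ≈ 60), a shared slope of
0.1 total points per lesion split across subscales, scale floors
(7/7/16), and inflated residual SDs (×1.5 variance). One structural
trade-off is documented rather than hidden: with group means anchored
and burden linked to both symptoms and deviations, the *pooled* patient
correlation between symptom totals and extreme-negative percentage
cannot be pushed below ≈0.2 without also destroying the group
separations; defaults land the pooled r around 0.2–0.37 across seeds,
with the within-group correlations much weaker — the qualitative
pattern (pooled, not within; negative, not positive tail) is the
calibrated property.

What the generator does *not* emulate: scanner/site effects, raw image
processing (segmentation, normalization, bias fields), non-Gaussian
population tails, age-by-sex interactions, or spatially varying noise
SD. Passing tests therefore demonstrate internal statistical validity
of the pipeline — calibration, error control, recovery, and the
dissociation under the stated data model — not robustness to
acquisition artefacts or site heterogeneity, which a real multi-site
study would need to address (e.g. by hierarchical normative models).

## Problem sizes and seeds

The test suite runs the full default conditions where the claim depends
on them (Z-calibration and the dissociation at 400×3,392 with 10-fold
CV and 1,000 permutations) and smaller grids (≈500–900 voxels, 60–500
subjects) for structural and property checks; null-calibration suites
use 5,000 Mann–Whitney/Holm replicates and 500 permutation-GLM
replicates at reduced permutation counts. All randomness flows from
explicit integer seeds: the generator consumes `config$seed`, fold
assignment and optimizer restarts consume the fit seed, and the
permutation stream its own seed, so every pipeline artifact is
bit-reproducible from the run configuration (the manifest records the
seeds and MD5 checksums).

## Known limitations

* Tied covariance hyperparameters are an approximation; voxels whose
  age trend differs qualitatively from the subsample consensus rely on
  the linear+SE kernel's flexibility at shared length-scales. The
  per-voxel mode exists but is slow at full mask sizes.
* The Mann–Whitney exact path enumerates only up to min(n) = 8 by
  default; beyond that the tie-corrected normal approximation is used
  (the tests bound its error against enumeration at the boundary).
* Max-|t| FWER is valid but conservative for directional questions;
  directional contrast pairs are reported instead of signed
  corrections.
* NIfTI output uses an identity affine (synthetic grids have no
  scanner geometry); real-data use should carry the source affine
  through `RNifti` headers.
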