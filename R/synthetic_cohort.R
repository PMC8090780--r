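#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the synthetic data model in one validated list.
#' Defaults emulate a case-control structural-MRI study: a healthy group
#' spanning ages 20-70 with smooth, regionally varying age-related
#' gray-matter decline and a small sex offset; patient groups (bipolar
#' disorder, BP; schizophrenia, SZ) that additionally carry idiosyncratic
#' focal gray-matter reductions ("lesions") whose centres are biased
#' towards designated vulnerable parcels. Noise is spatially correlated
#' (a white Gaussian field smoothed to `smoothing_fwhm_vox`) and rescaled
#' so every voxel has marginal standard deviation `noise_sd` exactly,
#' which keeps deviation-score calibration analytic.
#'
#' Default group sizes follow a 400/116/94 (HC/BP/SZ) design. Lesion
#' amplitude and rate defaults are calibrated so that, at the |Z| > 2.6
#' threshold, extreme negative deviations are roughly four times more
#' prevalent in the SZ group than in healthy controls while the
#' between-subject overlap of lesion locations stays sparse.
#'
#' @param n_hc,n_bp,n_sz group sizes.
#' @param dims 3D grid dimensions (ellipsoidal mask of ~3,700 voxels by
#'   default).
#' @param voxel_size voxel edge length, mm.
#' @param n_parcels number of contiguous parcels with distinct age slopes.
#' @param baseline_gm mean gray-matter volume, arbitrary units.
#' @param age_slope_range range of per-parcel age slopes (units/year);
#'   the steepest slopes are assigned to the designated anterior
#'   ("frontal") parcels.
#' @param n_frontal_parcels how many of the most anterior parcels are
#'   designated (steepest decline, sex offset, lesion vulnerability).
#' @param sex_offset additive male-female offset (units) applied in the
#'   designated parcels.
#' @param noise_sd marginal noise standard deviation per voxel, units.
#' @param smoothing_fwhm_vox FWHM, in voxels, of the Gaussian kernel
#'   applied to the noise field (2 voxels at 4 mm emulates 8 mm smoothing).
#' @param lesion_rate named vector `c(hc=, bp=, sz=)` of mean lesion
#'   counts per subject.
#' @param lesion_dispersion gamma-Poisson (negative binomial) size
#'   parameter of the per-subject lesion count; smaller values give
#'   heavier-tailed burden heterogeneity, `Inf` recovers a pure Poisson.
#' @param lesion_amplitude range (negative) of lesion peak amplitude,
#'   units; drawn uniformly per lesion.
#' @param lesion_radius_vox lesion radius in voxels (cosine-tapered
#'   sphere).
#' @param vulnerability_weight relative probability of a lesion centre
#'   falling in a designated parcel versus elsewhere.
#' @param sex_lesion_ratio male:female ratio of the per-subject lesion
#'   rate within each patient group (group means are preserved).
#' @param panss_beta increase in PANSS total per lesion.
#' @param panss_noise_sd residual SD of the PANSS subscales.
#' @param age_range permitted age range (years) for healthy subjects;
#'   patient ages use the same bounds.
#' @param seed integer seed; every generator draw derives from it.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_hc = 400, n_bp = 116, n_sz = 94,
                             dims = c(20, 24, 20),
                             voxel_size = c(4, 4, 4),
                             n_parcels = 8,
                             baseline_gm = 0.5,
                             age_slope_range = c(-0.004, -0.001),
                             n_frontal_parcels = 2,
                             sex_offset = 0.02,
                             noise_sd = 0.05,
                             smoothing_fwhm_vox = 2.0,
                             lesion_rate = c(hc = 0, bp = 1.4, sz = 13),
                             lesion_dispersion = 0.6,
                             lesion_amplitude = c(-0.18, -0.10),
                             lesion_radius_vox = 2.5,
                             vulnerability_weight = 12,
                             sex_lesion_ratio = 1.5,
                             panss_beta = 0.1,
                             panss_noise_sd = 1.5,
                             age_range = c(20, 70),
                             seed = 1L) {
  lesion_rate <- unlist(lesion_rate)
  if (is.null(names(lesion_rate)) && length(lesion_rate) == 3L)
    names(lesion_rate) <- c("hc", "bp", "sz")
  if (!all(c("hc", "bp", "sz") %in% names(lesion_rate)))
    stop("lesion_rate must be named c(hc=, bp=, sz=)")
  cfg <- list(n_hc = n_hc, n_bp = n_bp, n_sz = n_sz,
              dims = as.integer(dims), voxel_size = voxel_size,
              n_parcels = as.integer(n_parcels),
              baseline_gm = baseline_gm,
              age_slope_range = sort(age_slope_range),
              n_frontal_parcels = as.integer(n_frontal_parcels),
              sex_offset = sex_offset,
              noise_sd = noise_sd,
              smoothing_fwhm_vox = smoothing_fwhm_vox,
              lesion_rate = lesion_rate,
              lesion_dispersion = lesion_dispersion,
              lesion_amplitude = sort(lesion_amplitude),
              lesion_radius_vox = lesion_radius_vox,
              vulnerability_weight = vulnerability_weight,
              sex_lesion_ratio = sex_lesion_ratio,
              panss_beta = panss_beta,
              panss_noise_sd = panss_noise_sd,
              age_range = age_range,
              age_ref = mean(age_range),
              seed = as.integer(seed))
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num))) stop("generator_config: all values must be finite")
  if (any(c(n_hc, n_bp, n_sz) < 0)) stop("group sizes must be non-negative")
  if (any(lesion_rate < 0) || lesion_radius_vox < 0)
    stop("lesion rates and radius must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  class(cfg) <- "generator_config"
  cfg
}

# Truncated-normal draws via inverse-CDF; vectorised over n.
rtnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# Demographic presets: age mean/sd and male fraction per group, matching
# a typical severe-mental-illness case-control design (patients younger,
# SZ more often male).
.group_demographics <- list(
  HC = list(age_mean = 34, age_sd = 11.3, p_male = 0.5025),
  BP = list(age_mean = 31, age_sd = 10.8, p_male = 0.3534),
  SZ = list(age_mean = 28, age_sd = 9.2,  p_male = 0.5744)
)

# PANSS subscale means/SDs per patient group (positive, negative, global);
# totals are the sum of the three subscales.
.panss_presets <- list(
  BP = list(mean = c(pos = 9.3, neg = 9.6, glob = 25.5),
            sd   = c(pos = 3.2, neg = 5.3, glob = 5.3)),
  SZ = list(mean = c(pos = 13.4, neg = 15.7, glob = 30.6),
            sd   = c(pos = 4.3, neg = 6.4, glob = 7.6))
)

#' Generate a synthetic subject table
#'
#' Draws per-subject covariates (age, sex), diagnostic group, the latent
#' lesion count that drives the voxel generator, PANSS symptom scores for
#' patients (missing for healthy controls, with group means ordered
#' SZ > BP), and age of onset for patients. Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return A `data.frame` with columns `subject_id`, `age`, `sex`
#'   (0 = female, 1 = male), `group` (factor HC/BP/SZ), `panss_positive`,
#'   `panss_negative`, `panss_global`, `panss_total`, `age_of_onset`, and
#'   `lesion_burden_true` (generator ground truth; not used by the
#'   analysis stages).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  groups <- rep(c("HC", "BP", "SZ"), times = c(config$n_hc, config$n_bp, config$n_sz))
  n <- length(groups)
  empty <- data.frame(subject_id = character(0), age = numeric(0),
                      sex = integer(0), group = factor(character(0), levels = c("HC", "BP", "SZ")),
                      panss_positive = integer(0), panss_negative = integer(0),
                      panss_global = integer(0), panss_total = integer(0),
                      age_of_onset = numeric(0), lesion_burden_true = integer(0))
  if (n == 0L) return(empty)

  age <- numeric(n); sex <- integer(n)
  for (g in c("HC", "BP", "SZ")) {
    ii <- which(groups == g)
    if (!length(ii)) next
    d <- .group_demographics[[g]]
    age[ii] <- rtnorm(length(ii), d$age_mean, d$age_sd,
                      config$age_range[1], config$age_range[2])
    sex[ii] <- as.integer(stats::runif(length(ii)) < d$p_male)
  }

  # Latent lesion burden: Poisson with a male-biased rate, renormalised so
  # each group keeps its configured mean rate.
  rate <- numeric(n)
  lam <- config$lesion_rate
  r <- config$sex_lesion_ratio
  for (g in c("HC", "BP", "SZ")) {
    ii <- which(groups == g)
    if (!length(ii)) next
    lam_g <- lam[[tolower(g)]]
    w <- ifelse(sex[ii] == 1L, r, 1)
    rate[ii] <- lam_g * w / mean(w)
  }
  burden <- if (is.finite(config$lesion_dispersion))
    stats::rnbinom(n, mu = rate, size = config$lesion_dispersion)
  else stats::rpois(n, rate)

  panss <- matrix(NA_integer_, n, 3, dimnames = list(NULL, c("pos", "neg", "glob")))
  onset <- rep(NA_real_, n)
  for (g in c("BP", "SZ")) {
    ii <- which(groups == g)
    if (!length(ii)) next
    pre <- .panss_presets[[g]]
    lam_g <- lam[[tolower(g)]]
    share <- c(pos = 0.25, neg = 0.40, glob = 0.35)   # how the lesion effect splits
    floors <- c(pos = 7, neg = 7, glob = 16)          # PANSS scale minima
    for (s in c("pos", "neg", "glob")) {
      raw <- pre$mean[[s]] + config$panss_beta * share[[s]] * (burden[ii] - lam_g) +
        stats::rnorm(length(ii), 0, sqrt(pmax(pre$sd[[s]]^2 * config$panss_noise_sd, 0.25)))
      panss[ii, s] <- as.integer(round(pmax(raw, floors[[s]])))
    }
    dur <- abs(stats::rnorm(length(ii), 6, 4))
    onset[ii] <- pmax(pmin(age[ii] - dur, age[ii]), 15)
  }

  data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = age,
    sex = sex,
    group = factor(groups, levels = c("HC", "BP", "SZ")),
    panss_positive = panss[, "pos"],
    panss_negative = panss[, "neg"],
    panss_global = panss[, "glob"],
    panss_total = panss[, "pos"] + panss[, "neg"] + panss[, "glob"],
    age_of_onset = onset,
    lesion_burden_true = as.integer(burden))
}

# Separable Gaussian smoothing along each array axis. Returns both the
# smoother matrices (rows normalised to sum 1) and the per-voxel standard
# deviation factor of smoothed unit-variance white noise, which is exact
# for a separable kernel: sd(i,j,k) = ||G1[i,]|| ||G2[j,]|| ||G3[k,]||.
.smoothing_operator <- function(dims, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  mats <- lapply(dims, function(d) {
    x <- seq_len(d)
    G <- exp(-outer(x, x, `-`)^2 / (2 * sigma^2))
    G / rowSums(G)
  })
  rn <- lapply(mats, function(G) sqrt(rowSums(G^2)))
  sd_factor <- outer(outer(rn[[1]], rn[[2]], `*`), rn[[3]], `*`)
  list(mats = mats, sd_factor = sd_factor)
}

.apply_smoothing <- function(arr, mats) {
  d <- dim(arr)
  # axis 1
  m <- mats[[1]] %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(m, d)
  # axis 2
  a <- aperm(arr, c(2, 1, 3))
  m <- mats[[2]] %*% matrix(a, d[2], d[1] * d[3])
  arr <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  a <- aperm(arr, c(3, 1, 2))
  m <- mats[[3]] %*% matrix(a, d[3], d[1] * d[2])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

# Contiguous parcellation of the mask by k-means on voxel coordinates.
# Uses a fixed internal seed so the "atlas" depends only on the geometry,
# not on the cohort seed.
.parcellate <- function(vs, n_parcels) {
  coords <- vs$coords
  n_parcels <- min(n_parcels, nrow(coords))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20L)
  km <- stats::kmeans(coords, centers = n_parcels, nstart = 5, iter.max = 50)
  # relabel parcels by decreasing anteriority (axis-2 centroid) so parcel 1
  # is the most anterior ("frontal") parcel
  ord <- order(km$centers[, 2], decreasing = TRUE)
  relabel <- match(seq_len(n_parcels), ord)
  list(parcel = relabel[km$cluster], n = n_parcels)
}

#' Generate voxel-wise gray-matter data for a cohort
#'
#' Builds the deterministic mean surface (baseline + parcel-specific age
#' slope + sex offset in designated parcels), adds spatially correlated
#' Gaussian noise rescaled so every voxel has marginal SD `noise_sd`, and
#' injects per-patient focal lesions (cosine-tapered spheres with
#' negative amplitude) at centres drawn from a vulnerability-weighted
#' distribution over the mask. Lesion counts are taken from
#' `cohort$lesion_burden_true` so the voxel data are consistent with the
#' covariate table.
#'
#' @param cohort a table from [generate_cohort()].
#' @param config the same [generator_config()] used for the cohort.
#' @return A list with `voxel_space`, `gm` (subjects x voxels matrix) and
#'   `truth`, the ground-truth record (parcel map, slope map, sex-offset
#'   map, vulnerability weights, per-voxel noise SD, per-subject lesion
#'   voxels and deltas).
#' @export
generate_voxel_data <- function(cohort, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(cohort) == 0L) stop("cohort is empty")
  need <- c("subject_id", "age", "sex", "group", "lesion_burden_true")
  if (!all(need %in% names(cohort))) stop("cohort/config mismatch: missing columns")
  if (nrow(cohort) != config$n_hc + config$n_bp + config$n_sz)
    stop("cohort/config mismatch: row count does not match configured group sizes")

  vs <- voxel_space(ellipsoid_mask(config$dims), config$voxel_size)
  V <- n_voxels(vs)
  n <- nrow(cohort)
  par <- .parcellate(vs, config$n_parcels)

  # Per-parcel age slopes: steepest (most negative) in the anterior parcels.
  slopes_by_parcel <- seq(config$age_slope_range[1], config$age_slope_range[2],
                          length.out = par$n)
  slope_map <- slopes_by_parcel[par$parcel]
  frontal <- seq_len(min(config$n_frontal_parcels, par$n))
  sexoff_map <- ifelse(par$parcel %in% frontal, config$sex_offset, 0)
  vuln <- ifelse(par$parcel %in% frontal, config$vulnerability_weight, 1)

  mean_mat <- config$baseline_gm +
    outer(cohort$age - config$age_ref, slope_map) +
    outer(as.numeric(cohort$sex), sexoff_map)

  set.seed(config$seed + 1L)
  gm <- mean_mat
  if (config$noise_sd > 0) {
    sm <- .smoothing_operator(config$dims, config$smoothing_fwhm_vox)
    scale_arr <- config$noise_sd / sm$sd_factor
    for (i in seq_len(n)) {
      e <- array(stats::rnorm(prod(config$dims)), dim = config$dims)
      e <- .apply_smoothing(e, sm$mats) * scale_arr
      gm[i, ] <- gm[i, ] + mask_values(vs, e)
    }
  }

  # Lesions: spherical cosine-tapered dips; centres vulnerability-weighted.
  lesions <- vector("list", n)
  prob <- vuln / sum(vuln)
  R <- config$lesion_radius_vox
  for (i in seq_len(n)) {
    nb <- cohort$lesion_burden_true[i]
    if (is.na(nb) || nb == 0L) { lesions[[i]] <- NULL; next }
    delta <- numeric(V)
    centres <- sample.int(V, nb, replace = TRUE, prob = prob)
    amps <- stats::runif(nb, config$lesion_amplitude[1], config$lesion_amplitude[2])
    for (l in seq_len(nb)) {
      cc <- vs$coords[centres[l], ]
      d2 <- (vs$coords[, 1] - cc[1])^2 + (vs$coords[, 2] - cc[2])^2 +
        (vs$coords[, 3] - cc[3])^2
      hit <- which(d2 < R^2)
      w <- 0.5 * (1 + cos(pi * sqrt(d2[hit]) / R))
      delta[hit] <- delta[hit] + amps[l] * w
    }
    idx <- which(delta != 0)
    gm[i, idx] <- gm[i, idx] + delta[idx]
    lesions[[i]] <- list(voxels = idx, delta = delta[idx], centres = centres,
                         amplitudes = amps)
  }

  truth <- list(parcel_map = par$parcel,
                slopes_by_parcel = slopes_by_parcel,
                slope_map = slope_map,
                sex_offset_map = sexoff_map,
                vulnerability = vuln,
                frontal_parcels = frontal,
                noise_sd_map = rep(config$noise_sd, V),
                lesions = lesions,
                lesion_voxel_count = vapply(lesions, function(l)
                  if (is.null(l)) 0L else length(l$voxels), integer(1)))
  rownames(gm) <- cohort$subject_id
  list(voxel_space = vs, gm = gm, truth = truth)
}
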