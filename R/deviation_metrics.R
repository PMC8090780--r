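#' Threshold a deviation map into extreme-deviation masks
#'
#' Splits a subject's voxel-wise Z-scores at a per-tail threshold using
#' strict inequalities: negative extremes are Z < -z, positive extremes
#' Z > +z. The conventional thresholds correspond to per-tail normal
#' tail probabilities: p < .05 -> |Z| > 1.96, p < .005 -> |Z| > 2.6,
#' p < .001 -> |Z| > 3.1.
#'
#' @param z numeric vector of Z-scores (one subject, in-mask voxels).
#' @param z_thr positive threshold.
#' @return A list with logical vectors `negative` and `positive`.
#' @export
threshold_npm <- function(z, z_thr = 2.6) {
  stopifnot(z_thr > 0)
  list(negative = z < -z_thr, positive = z > z_thr)
}

#' FDR-threshold a deviation map
#'
#' Converts each voxel's Z to a two-sided normal p-value,
#' p = 2(1 - Phi(|Z|)), applies the Benjamini-Hochberg step-up procedure
#' across the subject's in-mask voxels, and splits surviving voxels by
#' the sign of Z.
#'
#' @param z numeric vector of Z-scores for one subject.
#' @param q FDR level (default 0.05).
#' @return A list with logical vectors `negative` and `positive`.
#' @export
fdr_threshold_npm <- function(z, q = 0.05) {
  stopifnot(q > 0, q < 1)
  p <- 2 * stats::pnorm(-abs(z))
  keep <- stats::p.adjust(p, method = "BH") <= q
  list(negative = keep & z < 0, positive = keep & z > 0)
}

#' Extreme-deviation percentage scores
#'
#' Per-subject summary: the percentage of in-mask voxels that are
#' extreme, relative to the total number of voxels in the brain mask.
#'
#' @param masks a list with logical `negative` and `positive` vectors
#'   (from [threshold_npm()] or [fdr_threshold_npm()]).
#' @param n_mask_voxels total in-mask voxel count (defaults to the mask
#'   length).
#' @return A list with `pct_negative` and `pct_positive` (0-100).
#' @export
extreme_percentages <- function(masks, n_mask_voxels = length(masks$negative)) {
  stopifnot(n_mask_voxels > 0)
  list(pct_negative = 100 * sum(masks$negative) / n_mask_voxels,
       pct_positive = 100 * sum(masks$positive) / n_mask_voxels)
}

#' Extreme-value summary statistic of a deviation map
#'
#' The mean of the top 1% of absolute Z-values across the subject's
#' in-mask voxels (ceiling used for the count), an untresholded
#' per-subject measure of the most extreme deviations. With
#' `trim_tip = TRUE` the single largest value is discarded before
#' averaging (an alternative reading of "trimmed").
#'
#' @param z numeric vector of Z-scores for one subject; needs at least
#'   100 voxels for the top 1% to be well defined.
#' @param top_fraction fraction of voxels averaged (default 0.01).
#' @param trim_tip discard the single most extreme value first.
#' @return Scalar summary.
#' @export
evs_statistic <- function(z, top_fraction = 0.01, trim_tip = FALSE) {
  V <- length(z)
  if (V < 100L) stop("need at least 100 voxels for the top-1% statistic")
  a <- sort(abs(z), decreasing = TRUE)
  m <- ceiling(top_fraction * V)
  if (trim_tip) { a <- a[-1]; m <- max(m - 1L, 1L) }
  mean(a[seq_len(m)])
}

# Gumbel density (location mu, scale beta > 0).
.dgumbel <- function(x, mu, beta, log = FALSE) {
  zz <- (x - mu) / beta
  ll <- -zz - exp(-zz) - log(beta)
  if (log) ll else exp(ll)
}

#' Fit an extreme value distribution to per-subject summaries
#'
#' Maximum-likelihood Gumbel fit (location mu, scale beta) to a sample
#' of extreme-value summary statistics, the classical limiting family
#' for sample maxima. A generalized extreme value fit (additional shape
#' parameter) is available as `family = "gev"`. Returns QQ diagnostics
#' alongside the estimates; an all-identical sample is reported as a
#' degenerate fit with scale 0.
#'
#' @param x numeric vector of extreme-value statistics, length >= 10.
#' @param family `"gumbel"` (default) or `"gev"`.
#' @return A list with `location`, `scale` (and `shape` for GEV),
#'   `loglik`, `degenerate`, and `qq` (sorted sample vs fitted
#'   quantiles).
#' @export
fit_extreme_value_distribution <- function(x, family = c("gumbel", "gev")) {
  family <- match.arg(family)
  if (length(x) < 10L) stop("need at least 10 values")
  if (any(!is.finite(x))) stop("non-finite inputs")
  if (stats::sd(x) == 0) {
    return(list(location = x[1], scale = 0, shape = if (family == "gev") 0,
                loglik = Inf, degenerate = TRUE, qq = NULL, family = family))
  }
  beta0 <- sqrt(6) * stats::sd(x) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0

  if (family == "gumbel") {
    nll <- function(p) -sum(.dgumbel(x, p[1], exp(p[2]), log = TRUE))
    opt <- stats::optim(c(mu0, log(beta0)), nll, method = "BFGS")
    mu <- opt$par[1]; beta <- exp(opt$par[2]); shape <- NULL
  } else {
    nll <- function(p) {
      mu <- p[1]; beta <- exp(p[2]); xi <- p[3]
      zz <- (x - mu) / beta
      if (abs(xi) < 1e-8) return(sum(zz + exp(-zz)) + length(x) * log(beta))
      t1 <- 1 + xi * zz
      if (any(t1 <= 0)) return(1e10)
      sum(log(beta) + (1 + 1 / xi) * log(t1) + t1^(-1 / xi))
    }
    opt <- stats::optim(c(mu0, log(beta0), 0.01), nll, method = "BFGS")
    mu <- opt$par[1]; beta <- exp(opt$par[2]); shape <- opt$par[3]
  }
  ppoints <- (seq_along(x) - 0.5) / length(x)
  qfit <- if (family == "gumbel" || abs(shape %||% 0) < 1e-8)
    mu - beta * log(-log(ppoints))
  else mu + beta * ((-log(ppoints))^(-shape) - 1) / shape
  list(location = mu, scale = beta, shape = shape,
       loglik = -opt$value, degenerate = FALSE,
       qq = data.frame(sample = sort(x), fitted = qfit), family = family)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extreme-deviation score table for a cohort
#'
#' Applies [threshold_npm()] at each requested threshold (plus an
#' optional FDR threshold) and [evs_statistic()] to every subject's
#' deviation map.
#'
#' @param dev a `deviation_maps` object (or a subjects x voxels Z
#'   matrix).
#' @param thresholds numeric Z thresholds (default 1.96, 2.6, 3.1).
#' @param fdr_q optional FDR level adding a `"fdr"` threshold row set.
#' @return A data.frame with one row per subject x threshold:
#'   `subject`, `threshold`, `pct_negative`, `pct_positive`, `evs_stat`.
#' @export
deviation_scores <- function(dev, thresholds = c(1.96, 2.6, 3.1), fdr_q = NULL) {
  Z <- if (inherits(dev, "deviation_maps")) dev$Z else dev
  n <- nrow(Z); V <- ncol(Z)
  ids <- rownames(Z) %||% sprintf("sub-%04d", seq_len(n))
  evs <- apply(Z, 1, evs_statistic)
  out <- list()
  for (thr in thresholds) {
    neg <- rowSums(Z < -thr); pos <- rowSums(Z > thr)
    out[[length(out) + 1L]] <- data.frame(
      subject = ids, threshold = sprintf("z%.2f", thr),
      pct_negative = 100 * neg / V, pct_positive = 100 * pos / V,
      evs_stat = evs)
  }
  if (!is.null(fdr_q)) {
    neg <- numeric(n); pos <- numeric(n)
    for (i in seq_len(n)) {
      mk <- fdr_threshold_npm(Z[i, ], fdr_q)
      neg[i] <- sum(mk$negative); pos[i] <- sum(mk$positive)
    }
    out[[length(out) + 1L]] <- data.frame(
      subject = ids, threshold = sprintf("fdr%.2f", fdr_q),
      pct_negative = 100 * neg / V, pct_positive = 100 * pos / V,
      evs_stat = evs)
  }
  do.call(rbind, out)
}
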