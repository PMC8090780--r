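#' Kernel configuration for the normative Gaussian process
#'
#' The covariance on standardized (age, sex) is a sum of a constant, a
#' linear, and a squared-exponential component plus i.i.d. Gaussian
#' noise:
#' \deqn{k(x, x') = v_c + v_l\, x^\top x' + v_f \exp(-\|x - x'\|^2 / 2\ell^2)}
#' This supports near-linear age trends while leaving room for smooth
#' nonlinearity; the constant and linear components absorb the mean
#' function so targets are modelled without an explicit mean model.
#'
#' @param variance_const,variance_linear,variance_rbf initial component
#'   variances (targets are standardized, so O(1) values are sensible).
#' @param lengthscale initial squared-exponential length-scale, in
#'   standardized covariate units.
#' @param noise_variance initial observation-noise variance.
#' @param n_restarts optimizer restarts with jittered initial values.
#' @param log_bounds lower/upper bounds on all log-hyperparameters.
#' @return A list of class `kernel_config`.
#' @export
kernel_config <- function(variance_const = 0.1, variance_linear = 0.5,
                          variance_rbf = 0.1, lengthscale = 1,
                          noise_variance = 0.5, n_restarts = 2,
                          log_bounds = c(-9, 6)) {
  stopifnot(variance_const > 0, variance_linear > 0, variance_rbf > 0,
            lengthscale > 0, noise_variance > 0, n_restarts >= 1)
  structure(list(variance_const = variance_const,
                 variance_linear = variance_linear,
                 variance_rbf = variance_rbf,
                 lengthscale = lengthscale,
                 noise_variance = noise_variance,
                 n_restarts = n_restarts,
                 log_bounds = log_bounds),
            class = "kernel_config")
}

# Noise-free kernel matrix between standardized covariate matrices.
# theta = c(log v_c, log v_l, log v_f, log ell).
.k_mat <- function(X1, X2, theta) {
  v <- exp(theta)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  v[1] + v[2] * tcrossprod(X1, X2) + v[3] * exp(-d2 / (2 * v[4]^2))
}

.k_diag <- function(X, theta) {
  v <- exp(theta)
  v[1] + v[2] * rowSums(X^2) + v[3]
}

# Symmetric eigendecomposition of the noise-free kernel with non-negative
# clamping; a tiny jitter is escalated if the decomposition leaves the
# system numerically singular for every admissible noise level.
.kernel_eig <- function(Xs, theta) {
  K <- .k_mat(Xs, Xs, theta)
  jit <- 0
  repeat {
    e <- eigen(K + diag(jit, nrow(K)), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    if (max(lam) == 0 || min(e$values) / max(lam) > -1e-8) break
    jit <- if (jit == 0) 1e-6 * max(diag(K)) else jit * 10
    if (jit > 1e-2 * max(diag(K))) stop("kernel matrix numerically singular")
  }
  list(Q = e$vectors, lambda = lam)
}

# Negative sum of per-voxel GP log marginal likelihoods for standardized
# targets Ys (n x V), shared covariance hyperparameters and shared noise.
# par = c(theta, log v_n).
.neg_lml_shared <- function(par, Xs, Ys) {
  eg <- tryCatch(.kernel_eig(Xs, par[1:4]), error = function(e) NULL)
  if (is.null(eg)) return(1e10)
  d <- eg$lambda + exp(par[5])
  A <- crossprod(eg$Q, Ys)
  n <- nrow(Ys); V <- ncol(Ys)
  0.5 * (V * sum(log(d)) + sum(colSums(A^2 / d)) + V * n * log(2 * pi))
}

# Per-voxel profile of the noise variance given the shared eigensystem.
# a2 = (Q'y)^2 for one voxel; returns the negative log marginal likelihood.
.neg_lml_noise <- function(log_vn, lambda, a2, n) {
  d <- lambda + exp(log_vn)
  0.5 * (sum(log(d)) + sum(a2 / d) + n * log(2 * pi))
}

.standardize_cov <- function(age, sex, center = NULL, scale = NULL) {
  X <- cbind(age = age, sex = as.numeric(sex))
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  list(Xs = Xs, center = center, scale = scale)
}

#' Fit per-voxel Gaussian-process normative models
#'
#' Models each voxel's gray-matter volume as a GP over standardized
#' (age, sex) with the [kernel_config()] covariance. Targets are
#' standardized per voxel by their training mean/SD and de-standardized
#' at prediction time. Hyperparameters maximize the log marginal
#' likelihood with multi-restart gradient-free/quasi-Newton optimization.
#'
#' Two hyperparameter modes are available. In `"tied"` mode (default) the
#' covariance hyperparameters are estimated once by maximizing the summed
#' marginal likelihood over a random voxel subsample, and the noise
#' variance is then profiled per voxel through the shared eigensystem —
#' this scales to thousands of voxels. In `"pervoxel"` mode every voxel
#' gets its own full 5-parameter optimization (practical for small voxel
#' counts).
#'
#' @param gm subjects x voxels matrix of (healthy) training volumes; a
#'   vector is treated as a single voxel.
#' @param covariates data.frame with numeric `age` and `sex` (0/1).
#' @param kernel a [kernel_config()].
#' @param seed integer seed for restarts and voxel subsampling.
#' @param hyperparams `"tied"` or `"pervoxel"`.
#' @param subsample number of voxels used for the tied-mode covariance
#'   fit.
#' @return An object of class `normative_fit`.
#' @export
fit_normative <- function(gm, covariates, kernel = kernel_config(),
                          seed = 1L, hyperparams = c("tied", "pervoxel"),
                          subsample = 30L) {
  hyperparams <- match.arg(hyperparams)
  if (is.vector(gm)) gm <- matrix(gm, ncol = 1)
  n <- nrow(gm); V <- ncol(gm)
  if (n < 20L) stop("need at least 20 training subjects")
  if (!all(c("age", "sex") %in% names(covariates)) ||
      anyNA(covariates$age) || anyNA(covariates$sex))
    stop("covariates must provide complete `age` and `sex`")
  if (nrow(covariates) != n) stop("covariates do not match gm rows")

  std <- .standardize_cov(covariates$age, covariates$sex)
  y_mu <- colMeans(gm)
  y_sd <- apply(gm, 2, stats::sd)
  flat <- which(y_sd == 0 | !is.finite(y_sd))
  y_sd[flat] <- 1
  Ys <- sweep(sweep(gm, 2, y_mu), 2, y_sd, `/`)

  set.seed(seed)
  k <- kernel
  init <- log(c(k$variance_const, k$variance_linear, k$variance_rbf,
                k$lengthscale, k$noise_variance))
  lb <- rep(k$log_bounds[1], 5); ub <- rep(k$log_bounds[2], 5)

  multi_start <- function(obj, p0) {
    best <- NULL
    for (r in seq_len(k$n_restarts)) {
      p <- if (r == 1) p0 else p0 + stats::rnorm(length(p0), 0, 1)
      p <- pmin(pmax(p, lb), ub)
      fit <- tryCatch(
        stats::optim(p, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("hyperparameter optimization failed")
    best
  }

  if (hyperparams == "tied") {
    sub <- if (V > subsample) sort(sample.int(V, subsample)) else seq_len(V)
    best <- multi_start(function(p) .neg_lml_shared(p, std$Xs, Ys[, sub, drop = FALSE]),
                        init)
    theta <- best$par[1:4]
    eg <- .kernel_eig(std$Xs, theta)
    A <- crossprod(eg$Q, Ys)
    vn <- numeric(V); lml <- numeric(V)
    for (v in seq_len(V)) {
      opt <- stats::optimize(.neg_lml_noise, interval = k$log_bounds,
                             lambda = eg$lambda, a2 = A[, v]^2, n = n)
      vn[v] <- exp(opt$minimum)
      lml[v] <- -opt$objective
    }
    theta_vox <- NULL
  } else {
    theta_vox <- matrix(NA_real_, V, 5)
    vn <- numeric(V); lml <- numeric(V)
    for (v in seq_len(V)) {
      best <- multi_start(function(p) .neg_lml_shared(p, std$Xs, Ys[, v, drop = FALSE]),
                          init)
      theta_vox[v, ] <- best$par
      vn[v] <- exp(best$par[5])
      lml[v] <- -best$value
    }
    theta <- NULL; eg <- NULL; A <- NULL
  }

  structure(list(mode = hyperparams, kernel = kernel,
                 theta = theta, theta_vox = theta_vox,
                 eig = eg, A = A, Ys = if (hyperparams == "pervoxel") Ys else NULL,
                 vn = vn, lml = lml,
                 Xs = std$Xs, x_center = std$center, x_scale = std$scale,
                 y_mu = y_mu, y_sd = y_sd, flat_voxels = flat,
                 n_train = n, n_voxels = V,
                 age_range_train = range(covariates$age),
                 seed = seed),
            class = "normative_fit")
}

#' @export
print.normative_fit <- function(x, ...) {
  cat(sprintf("normative_fit: %d voxels, %d training subjects, %s hyperparameters\n",
              x$n_voxels, x$n_train, x$mode))
  cat(sprintf("  mean log marginal likelihood per voxel: %.2f\n", mean(x$lml)))
  invisible(x)
}

#' Predict from a normative fit with predictive uncertainty
#'
#' Standard GP posterior mean and variance at new covariates, returned on
#' the original target scale. `var_function` is the posterior variance of
#' the latent function; `var_total` adds the per-voxel observation-noise
#' variance and is the denominator used for deviation Z-scores.
#' Covariates outside the fitted age range trigger a warning
#' (extrapolation is allowed), not an error.
#'
#' @param object a [fit_normative()] result.
#' @param covariates data.frame with `age` and `sex` for the query
#'   subjects.
#' @param ... unused.
#' @return A list of class `normative_prediction` with matrices `mean`,
#'   `var_function`, `var_total` (subjects x voxels).
#' @export
predict.normative_fit <- function(object, covariates, ...) {
  fit <- object
  if (!all(c("age", "sex") %in% names(covariates)))
    stop("covariates must provide `age` and `sex`")
  rng <- fit$age_range_train
  if (any(covariates$age < rng[1] | covariates$age > rng[2]))
    warning("query ages outside the fitted range; extrapolating")
  Xs <- .standardize_cov(covariates$age, covariates$sex,
                         fit$x_center, fit$x_scale)$Xs
  m <- nrow(Xs); V <- fit$n_voxels

  if (fit$mode == "tied") {
    Ks <- .k_mat(Xs, fit$Xs, fit$theta)           # m x n
    B <- Ks %*% fit$eig$Q                          # m x n
    D <- outer(fit$eig$lambda, fit$vn, `+`)        # n x V
    mean_s <- B %*% (fit$A / D)                    # m x V
    kss <- .k_diag(Xs, fit$theta)
    varf <- pmax(kss - (B^2) %*% (1 / D), 0)       # m x V
  } else {
    mean_s <- matrix(0, m, V); varf <- matrix(0, m, V)
    for (v in seq_len(V)) {
      th <- fit$theta_vox[v, 1:4]
      eg <- .kernel_eig(fit$Xs, th)
      a <- crossprod(eg$Q, fit$Ys[, v])
      d <- eg$lambda + fit$vn[v]
      Ks <- .k_mat(Xs, fit$Xs, th)
      B <- Ks %*% eg$Q
      mean_s[, v] <- B %*% (a / d)
      varf[, v] <- pmax(.k_diag(Xs, th) - (B^2) %*% (1 / d), 0)
    }
  }

  mean_out <- sweep(sweep(mean_s, 2, fit$y_sd, `*`), 2, fit$y_mu, `+`)
  varf_out <- sweep(varf, 2, fit$y_sd^2, `*`)
  vart_out <- sweep(varf_out, 2, fit$vn * fit$y_sd^2, `+`)
  structure(list(mean = mean_out, var_function = varf_out,
                 var_total = vart_out),
            class = "normative_prediction")
}

#' Deviation Z-maps from observations and normative predictions
#'
#' Z = (observed - predicted) / sqrt(var_total): the deviation of each
#' observation from the normative prediction normalized by the total
#' predictive uncertainty (posterior plus noise variance).
#'
#' @param observed subjects x voxels matrix (or vector for one subject).
#' @param prediction a `normative_prediction` with matching shape.
#' @param provenance `"transfer"` (scored by a model trained on an
#'   independent healthy sample) or `"cv"` (scored out-of-fold).
#' @return A list of class `deviation_maps` with the `Z` matrix and
#'   per-subject `provenance`.
#' @export
compute_z <- function(observed, prediction, provenance = "transfer") {
  if (is.vector(observed)) observed <- matrix(observed, nrow = nrow(prediction$mean))
  if (!identical(dim(observed), dim(prediction$mean)))
    stop("observed and prediction shapes differ")
  if (any(prediction$var_total <= 0))
    stop("var_total must be strictly positive")
  Z <- (observed - prediction$mean) / sqrt(prediction$var_total)
  if (any(!is.finite(Z))) stop("non-finite Z-scores")
  rownames(Z) <- rownames(observed)
  structure(list(Z = Z,
                 provenance = rep_len(provenance, nrow(Z)),
                 folds = NULL),
            class = "deviation_maps")
}

#' Cross-validated deviation maps for the healthy sample
#'
#' Assigns healthy subjects to k folds (random, stratified by sex, sizes
#' within one of each other), fits the normative model on each training
#' set and scores the held-out fold, so every healthy subject's Z-map is
#' out of sample.
#'
#' @param gm subjects x voxels matrix of healthy volumes.
#' @param covariates data.frame with `age` and `sex`.
#' @param k number of folds (default 10).
#' @param kernel a [kernel_config()].
#' @param seed seed controlling the fold assignment and fits.
#' @param hyperparams,subsample passed to [fit_normative()].
#' @return A `deviation_maps` object with `folds` recording the
#'   assignment; provenance is `"cv"` for every subject.
#' @export
crossvalidated_z <- function(gm, covariates, k = 10L, kernel = kernel_config(),
                             seed = 1L, hyperparams = "tied", subsample = 30L) {
  n <- nrow(gm)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds than subjects")
  set.seed(seed)
  # stratified, globally balanced assignment: shuffle within each sex
  # stratum, then deal a cyclic fold sequence across the concatenated
  # strata so both overall and per-stratum fold sizes differ by at most 1
  ord <- unlist(lapply(split(seq_len(n), covariates$sex), sample))
  folds <- integer(n)
  folds[ord] <- rep_len(sample.int(k), n)
  Z <- matrix(NA_real_, n, ncol(gm), dimnames = list(rownames(gm), NULL))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_normative(gm[tr, , drop = FALSE], covariates[tr, , drop = FALSE],
                         kernel = kernel, seed = seed + f,
                         hyperparams = hyperparams, subsample = subsample)
    # subjects at the age extremes always sit just outside their training
    # folds' range; that is not a user-facing extrapolation
    pred <- suppressWarnings(predict(fit, covariates[!tr, , drop = FALSE]))
    Z[!tr, ] <- compute_z(gm[!tr, , drop = FALSE], pred)$Z
  }
  structure(list(Z = Z, provenance = rep("cv", n), folds = folds),
            class = "deviation_maps")
}

#' Per-voxel predicted-observed correlation
#'
#' Out-of-sample model evaluation: Pearson correlation between predicted
#' and observed volumes per voxel, with optional display masks at
#' |r| > .4 and 1 - p > .95. Zero-variance voxels yield `NA`.
#'
#' @param predicted,observed subjects x voxels matrices.
#' @return A list with `r` (per-voxel correlation), `p` (two-sided), and
#'   logical masks `mask_r4` (|r| > 0.4) and `mask_p95` (1 - p > 0.95).
#' @export
evaluate_model <- function(predicted, observed) {
  if (!identical(dim(predicted), dim(observed)))
    stop("predicted and observed shapes differ")
  n <- nrow(observed)
  xc <- sweep(predicted, 2, colMeans(predicted))
  yc <- sweep(observed, 2, colMeans(observed))
  sx <- sqrt(colSums(xc^2)); sy <- sqrt(colSums(yc^2))
  denom <- sx * sy
  r <- ifelse(denom > 0, colSums(xc * yc) / denom, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
  list(r = r, p = p,
       mask_r4 = !is.na(r) & abs(r) > 0.4,
       mask_p95 = !is.na(p) & (1 - p) > 0.95)
}

#' Linearized forward-model slopes per sex
#'
#' Summarizes the normative model as the average yearly change of the
#' predicted volume over an age range, separately per sex, plus the
#' male-female slope difference: slope = (yhat(age_hi) - yhat(age_lo)) /
#' (age_hi - age_lo).
#'
#' @param fit a [fit_normative()] result.
#' @param age_range length-2 numeric, default c(20, 70).
#' @return A list with per-voxel vectors `slope_female`, `slope_male`,
#'   `difference` (male - female).
#' @export
forward_model_slopes <- function(fit, age_range = c(20, 70)) {
  stopifnot(inherits(fit, "normative_fit"), length(age_range) == 2)
  span <- diff(age_range)
  grid <- data.frame(age = rep(age_range, 2), sex = rep(c(0, 1), each = 2))
  pr <- suppressWarnings(predict(fit, grid))
  slope_f <- (pr$mean[2, ] - pr$mean[1, ]) / span
  slope_m <- (pr$mean[4, ] - pr$mean[3, ]) / span
  list(slope_female = slope_f, slope_male = slope_m,
       difference = slope_m - slope_f, age_range = age_range)
}
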