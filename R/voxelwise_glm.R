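#' Group design for the voxel-wise GLM
#'
#' Cell-means design (one indicator column per group) with optional
#' nuisance columns, plus the standard directional pairwise contrasts
#' (e.g. HC-SZ and SZ-HC).
#'
#' @param group factor/character of group labels.
#' @param nuisance optional numeric matrix/data.frame of nuisance
#'   covariates (centred internally).
#' @return A list with `X` (design matrix), `contrasts` (named list of
#'   contrast vectors), `group_cols` (indices of the permutable group
#'   columns), `nuisance_cols`.
#' @export
group_design <- function(group, nuisance = NULL) {
  g <- droplevels(factor(group))
  lv <- levels(g)
  X <- sapply(lv, function(l) as.numeric(g == l))
  colnames(X) <- lv
  nuis_cols <- integer(0)
  if (!is.null(nuisance)) {
    Znu <- scale(as.matrix(nuisance), scale = FALSE)
    colnames(Znu) <- colnames(Znu) %||% paste0("nuis", seq_len(ncol(Znu)))
    nuis_cols <- ncol(X) + seq_len(ncol(Znu))
    X <- cbind(X, Znu)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; collinear columns among: ",
         paste(colnames(X), collapse = ", "))
  }
  contrasts <- list()
  for (pr in utils::combn(lv, 2, simplify = FALSE)) {
    for (dir in list(pr, rev(pr))) {
      cv <- numeric(ncol(X))
      cv[match(dir[1], colnames(X))] <- 1
      cv[match(dir[2], colnames(X))] <- -1
      contrasts[[paste0(dir[1], "-", dir[2])]] <- cv
    }
  }
  list(X = X, contrasts = contrasts,
       group_cols = seq_along(lv), nuisance_cols = nuis_cols)
}

# Core OLS t-statistics for all voxels and contrasts.
# Returns list(t = voxels x contrasts, est, sigma2, flagged).
.glm_t <- function(Y, X, contrasts, XtXinv = NULL, df = NULL) {
  if (is.null(XtXinv)) XtXinv <- solve(crossprod(X))
  if (is.null(df)) df <- nrow(X) - qr(X)$rank
  XtY <- crossprod(X, Y)                      # k x V
  beta <- XtXinv %*% XtY                      # k x V
  rss <- colSums(Y^2) - colSums(beta * XtY)
  rss <- pmax(rss, 0)
  sigma2 <- rss / df
  C <- do.call(rbind, contrasts)              # c x k
  est <- C %*% beta                           # c x V
  cvc <- rowSums((C %*% XtXinv) * C)          # c
  se <- sqrt(outer(cvc, sigma2))              # c x V
  tmat <- est / se
  flagged <- se == 0
  tmat[flagged] <- 0
  tmat <- t(tmat); est <- t(est); flagged <- t(flagged)
  colnames(tmat) <- colnames(est) <- colnames(flagged) <- names(contrasts)
  list(t = tmat, est = est, sigma2 = sigma2, df = df, flagged = flagged)
}

#' Voxel-wise GLM contrasts on deviation maps
#'
#' Ordinary least squares per voxel with t-statistics for each contrast.
#' With a two-group cell-means design and no nuisance columns this
#' reduces exactly to the pooled-variance two-sample t-test. Voxels with
#' zero residual variance are reported as t = 0 and flagged.
#'
#' @param Z subjects x voxels matrix (deviation maps).
#' @param design a [group_design()] result.
#' @return A list with `t` (voxels x contrasts), `est` (contrast
#'   estimates), `sigma2`, `df`, `flagged` (zero-variance voxels).
#' @export
fit_glm <- function(Z, design) {
  X <- design$X
  if (nrow(Z) != nrow(X)) stop("Z and design row counts differ")
  if (nrow(X) < ncol(X) + 2) stop("too few subjects for the design")
  .glm_t(Z, X, design$contrasts)
}

#' Permutation inference for the voxel-wise GLM
#'
#' Permutes group labels (or, with nuisance covariates present,
#' Freedman-Lane residual permutation) to build the null distribution of
#' the per-voxel contrast t-statistics. Uncorrected per-voxel p-values
#' are one-sided in the contrast direction,
#' p = (1 + #\{t_perm >= t_obs\}) / (n_perm + 1); family-wise corrected
#' p-values use the permutation distribution of the maximum |t| across
#' in-mask voxels, so the smallest achievable p is 1/(n_perm + 1).
#' Directional contrast pairs (A-B and B-A) cover both tails.
#'
#' @param Z subjects x voxels matrix of deviation maps.
#' @param design a [group_design()] result.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return A list of class `glm_result`: `t`, `p_uncorrected`,
#'   `p_fwer` (both voxels x contrasts), `max_t_null` (n_perm x
#'   contrasts), `group_mean_z`, `df`, `n_perm`, `seed`.
#' @export
permutation_inference <- function(Z, design, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  X <- design$X
  n <- nrow(X)
  if (nrow(Z) != n) stop("Z and design row counts differ")
  XtXinv <- solve(crossprod(X))
  df <- n - qr(X)$rank
  obs <- .glm_t(Z, X, design$contrasts, XtXinv, df)
  V <- ncol(Z); nc <- length(design$contrasts)

  # Freedman-Lane: permute residuals from the nuisance-only model and add
  # the nuisance fit back before refitting the full model.
  has_nuis <- length(design$nuisance_cols) > 0
  if (has_nuis) {
    Xn <- X[, design$nuisance_cols, drop = FALSE]
    Xn1 <- cbind(1, Xn)
    Hn <- Xn1 %*% solve(crossprod(Xn1), t(Xn1))
    fit_n <- Hn %*% Z
    res_n <- Z - fit_n
  }

  set.seed(seed)
  count_unc <- matrix(0, V, nc)
  max_null <- matrix(NA_real_, n_perm, nc)
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    if (has_nuis) {
      Yb <- fit_n + res_n[pm, , drop = FALSE]
      tb <- .glm_t(Yb, X, design$contrasts, XtXinv, df)$t
    } else {
      Xp <- X[pm, , drop = FALSE]
      tb <- .glm_t(Z, Xp, design$contrasts, XtXinv, df)$t
    }
    count_unc <- count_unc + (tb >= obs$t)
    max_null[b, ] <- apply(abs(tb), 2, max)
  }
  p_unc <- (1 + count_unc) / (n_perm + 1)
  # max-|t| FWER: for each voxel/contrast, how often the null maximum
  # exceeds the observed statistic
  p_fwer <- matrix(NA_real_, V, nc)
  for (j in seq_len(nc)) {
    srt <- sort(max_null[, j])
    exceed <- n_perm - findInterval(obs$t[, j], srt, left.open = TRUE)
    p_fwer[, j] <- (1 + exceed) / (n_perm + 1)
  }
  p_fwer <- pmax(p_fwer, p_unc)
  colnames(p_unc) <- colnames(p_fwer) <- names(design$contrasts)

  grp_cols <- colnames(X)[design$group_cols]
  gmz <- sapply(grp_cols, function(gl) colMeans(Z[X[, gl] == 1, , drop = FALSE]))

  structure(list(t = obs$t, est = obs$est, flagged = obs$flagged,
                 p_uncorrected = p_unc, p_fwer = p_fwer,
                 max_t_null = max_null, group_mean_z = gmz,
                 df = df, n_perm = n_perm, seed = seed),
            class = "glm_result")
}
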