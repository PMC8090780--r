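#' Mann-Whitney U test with exact enumeration for small samples
#'
#' Computes U for group A (the number of (a, b) pairs with a > b, plus
#' half the ties). When the smaller group has at most `exact_max`
#' observations the permutation null is enumerated exhaustively over all
#' choose(nA+nB, nA) group assignments of the pooled values — exact even
#' under ties. Otherwise the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param a,b numeric vectors of scores for the two groups.
#' @param alternative `"two.sided"` (default), `"less"` (A tends
#'   smaller), or `"greater"`.
#' @param exact_max largest min(nA, nB) for which the null is
#'   enumerated (default 8).
#' @return A list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "less", "greater"),
                         exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  nA <- length(a); nB <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(nA)]) - nA * (nA + 1) / 2

  if (min(nA, nB) <= exact_max) {
    comb <- utils::combn(nA + nB, nA)
    rsum <- colSums(matrix(rk[comb], nrow = nA))
    Uperm <- rsum - nA * (nA + 1) / 2
    p_less <- mean(Uperm <= U)
    p_greater <- mean(Uperm >= U)
    p <- switch(alternative,
                less = p_less, greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    return(list(U = U, p = p, method = "exact enumeration"))
  }

  mu <- nA * nB / 2
  N <- nA + nB
  ties <- table(pooled)
  sig2 <- nA * nB / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(list(U = U, p = 1, method = "normal approximation"))
  sig <- sqrt(sig2)
  cc <- 0.5  # continuity correction
  p <- switch(alternative,
              less = stats::pnorm((U - mu + cc) / sig),
              greater = stats::pnorm(-(U - mu - cc) / sig),
              two.sided = min(1, 2 * stats::pnorm(-(abs(U - mu) - cc) / sig)))
  list(U = U, p = p, method = "normal approximation")
}

#' Bonferroni-Holm adjustment
#'
#' Step-down family-wise error control across a family of p-values
#' (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pairwise group comparisons of deviation scores
#'
#' Mann-Whitney tests for every pair of groups on a score column, with
#' Bonferroni-Holm correction across the pairs.
#'
#' @param scores data.frame containing the score and a `group` column.
#' @param metric name of the score column (e.g. `"pct_negative"`).
#' @param group_col name of the grouping column.
#' @return A data.frame with one row per pair: `group_a`, `group_b`,
#'   `metric`, `U`, `p_raw`, `p_holm`, `direction` (sign of the median
#'   difference A - B).
#' @export
compare_groups <- function(scores, metric, group_col = "group") {
  g <- droplevels(factor(scores[[group_col]]))
  lv <- levels(g)
  if (length(lv) < 2) stop("need at least two groups")
  pairs <- utils::combn(lv, 2)
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    metric = metric, U = NA_real_, p_raw = NA_real_,
                    direction = NA_character_)
  for (j in seq_len(ncol(pairs))) {
    xa <- scores[[metric]][g == pairs[1, j]]
    xb <- scores[[metric]][g == pairs[2, j]]
    mw <- mann_whitney(xa, xb)
    res$U[j] <- mw$U; res$p_raw[j] <- mw$p
    d <- stats::median(xa) - stats::median(xb)
    res$direction[j] <- if (d > 0) ">" else if (d < 0) "<" else "="
  }
  res$p_holm <- holm_adjust(res$p_raw)
  res
}

#' Correlate deviation scores with a clinical covariate
#'
#' Computes the score-covariate correlation pooled across patient groups
#' and within each group. Subjects with a missing covariate (healthy
#' controls have no symptom scores) are excluded.
#'
#' @param scores numeric vector of per-subject deviation scores.
#' @param covariate numeric vector (may contain NA).
#' @param group factor/character of group labels, same length.
#' @param pooled_groups groups entering the pooled correlation (default
#'   `c("BP", "SZ")`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A data.frame with rows for scope `"pooled"` and each group:
#'   `scope`, `n`, `r`, `p`. Zero-variance scopes yield `NA`.
#' @export
correlate_scores <- function(scores, covariate, group,
                             pooled_groups = c("BP", "SZ"),
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(covariate), length(scores) == length(group))
  one <- function(idx, scope) {
    ok <- idx & !is.na(covariate) & !is.na(scores)
    n <- sum(ok)
    if (n < 3 || stats::sd(scores[ok]) == 0 || stats::sd(covariate[ok]) == 0)
      return(data.frame(scope = scope, n = n, r = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(scores[ok], covariate[ok], method = method))
    data.frame(scope = scope, n = n, r = unname(ct$estimate), p = ct$p.value)
  }
  out <- one(group %in% pooled_groups, "pooled")
  for (gl in intersect(unique(as.character(group)), pooled_groups))
    out <- rbind(out, one(group == gl, gl))
  out
}

#' Prevalence ratio of extreme deviations between two groups
#'
#' Ratio of group mean extreme-deviation percentages (case over
#' control), reported to two decimals.
#'
#' @param mean_case,mean_control group means of the extreme percentage
#'   score (control mean must be positive).
#' @return Scalar ratio rounded to two decimals.
#' @export
prevalence_ratio <- function(mean_case, mean_control) {
  if (mean_control <= 0) stop("control mean must be positive")
  round(mean_case / mean_control, 2)
}
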