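test_that("thresholding uses strict per-tail inequalities and nests", {
  z <- c(-3.0, 2.7, 1.0)
  mk <- threshold_npm(z, 2.6)
  expect_equal(which(mk$negative), 1L)
  expect_equal(which(mk$positive), 2L)

  zero <- threshold_npm(rep(0, 10), 2.6)
  expect_false(any(zero$negative) || any(zero$positive))

  # ties at the boundary are excluded
  bd <- threshold_npm(c(-2.6, 2.6), 2.6)
  expect_false(any(bd$negative) || any(bd$positive))

  set.seed(1)
  zz <- rnorm(500, 0, 2)
  m196 <- threshold_npm(zz, 1.96); m26 <- threshold_npm(zz, 2.6)
  m31 <- threshold_npm(zz, 3.1)
  expect_true(all(m26$negative <= m196$negative))
  expect_true(all(m31$negative <= m26$negative))
  expect_true(all(m26$positive <= m196$positive))
  expect_true(all(m31$positive <= m26$positive))
})

test_that("FDR thresholding equals the step-up definition", {
  expect_false(any(unlist(fdr_threshold_npm(rep(0, 100)))))

  set.seed(2)
  z <- rnorm(1000); z[500] <- 10
  mk <- fdr_threshold_npm(z, 0.05)
  expect_true(mk$positive[500])
  expect_lte(sum(unlist(mk)), 5)

  # brute-force Benjamini-Hochberg oracle: sort p, find largest i with
  # p_(i) <= i q / m, reject all p <= that cutoff
  z <- rnorm(400, 0, 1.5)
  p <- 2 * pnorm(-abs(z))
  q <- 0.1
  ps <- sort(p)
  i_ok <- which(ps <= seq_along(ps) * q / length(ps))
  reject <- if (length(i_ok)) p <= ps[max(i_ok)] else rep(FALSE, length(p))
  mk <- fdr_threshold_npm(z, q)
  expect_equal(mk$negative | mk$positive, reject)
})

test_that("extreme percentages are relative to the mask size", {
  mk <- list(negative = c(rep(TRUE, 13), rep(FALSE, 987)),
             positive = rep(FALSE, 1000))
  pc <- extreme_percentages(mk)
  expect_equal(pc$pct_negative, 1.3)
  expect_equal(pc$pct_positive, 0)
  empty <- extreme_percentages(list(negative = logical(100), positive = logical(100)))
  expect_equal(empty$pct_negative, 0)
})

test_that("healthy extreme-negative rate matches the normal tail on calibrated maps", {
  dat <- small_dataset(n_hc = 300, dims = c(10, 12, 10), seed = 41)
  cv <- crossvalidated_z(dat$gm, dat$cohort[, c("age", "sex")], k = 10, seed = 4)
  sc <- deviation_scores(cv, thresholds = 2.6)
  expected <- 100 * pnorm(-2.6)  # 0.466%
  # across-subject mean is tightly determined; spatial smoothing only
  # widens the spread
  expect_lt(abs(mean(sc$pct_negative) - expected), 0.12)
})

test_that("the extreme-value summary is the mean of the top 1% absolute deviations", {
  expect_equal(evs_statistic(rep(2.5, 150)), 2.5)
  z <- c(4.0, -3.0, rep(0.1, 198))
  expect_equal(evs_statistic(z), 3.5)
  expect_error(evs_statistic(rnorm(50)), "100")

  # monotone: raising any |Z| cannot lower the statistic
  set.seed(3)
  z <- rnorm(300)
  s0 <- evs_statistic(z)
  for (i in c(1, 150, 300)) {
    z2 <- z; z2[i] <- z2[i] + sign(z2[i]) * 2
    expect_gte(evs_statistic(z2), s0)
  }
  # alternative trimmed reading drops the single most extreme value
  z <- c(10, 4, rep(0, 198))
  expect_equal(evs_statistic(z, trim_tip = TRUE), 4)
})

test_that("Gumbel maximum likelihood recovers known parameters", {
  set.seed(4)
  n <- 10000
  mu <- 3; beta <- 0.5
  x <- mu - beta * log(-log(runif(n)))   # inverse-CDF Gumbel sample
  fit <- fit_extreme_value_distribution(x)
  expect_lt(abs(fit$location / mu - 1), 0.02)
  expect_lt(abs(fit$scale / beta - 1), 0.02)
  expect_false(fit$degenerate)

  # location equivariance: shifting the sample shifts mu, not beta
  fit2 <- fit_extreme_value_distribution(x + 1.5)
  expect_equal(fit2$location, fit$location + 1.5, tolerance = 1e-3)
  expect_equal(fit2$scale, fit$scale, tolerance = 1e-3)

  degen <- fit_extreme_value_distribution(rep(2, 20))
  expect_true(degen$degenerate)
  expect_equal(degen$scale, 0)

  expect_error(fit_extreme_value_distribution(c(rnorm(10), Inf)), "finite")
  gev <- fit_extreme_value_distribution(x, family = "gev")
  expect_lt(abs(gev$shape), 0.05)  # true shape is 0
})

test_that("score tables order patient groups as expected on default synthetic data", {
  cfg <- generator_config(n_hc = 120, n_bp = 40, n_sz = 40,
                          dims = c(12, 14, 12), seed = 43)
  coh <- generate_cohort(cfg)
  vd <- generate_voxel_data(coh, cfg)
  hc <- coh$group == "HC"
  fit <- fit_normative(vd$gm[hc, ], coh[hc, c("age", "sex")], seed = 6)
  Z <- compute_z(vd$gm, suppressWarnings(predict(fit, coh[, c("age", "sex")])))$Z
  sc <- deviation_scores(Z, thresholds = 2.6, fdr_q = 0.05)
  sc$group <- coh$group[match(sc$subject, coh$subject_id)]
  z26 <- sc[sc$threshold == "z2.60", ]
  m <- tapply(z26$pct_negative, z26$group, mean)
  expect_gt(m[["SZ"]], m[["BP"]])
  expect_gte(m[["BP"]], m[["HC"]])
  expect_true(all(z26$pct_negative + z26$pct_positive <= 100))
  expect_true(all(c("z2.60", "fdr0.05") %in% sc$threshold))
})
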