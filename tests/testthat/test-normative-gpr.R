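test_that("a noise-free linear trend is recovered almost exactly", {
  set.seed(1)
  n <- 60
  age <- runif(n, 20, 70)
  sex <- rbinom(n, 1, 0.5)
  y <- -0.003 * age + 0.6
  fit <- fit_normative(y, data.frame(age = age, sex = sex), seed = 1)
  newage <- runif(40, 22, 68)
  pred <- predict(fit, data.frame(age = newage, sex = rbinom(40, 1, 0.5)))
  expect_gt(cor(pred$mean[, 1], -0.003 * newage + 0.6), 0.999)
  # interpolation at a training point reproduces the training target
  pred_tr <- predict(fit, data.frame(age = age[1], sex = sex[1]))
  expect_equal(pred_tr$mean[1, 1], y[1], tolerance = 1e-3)
})

test_that("the noise variance of a pure-noise voxel is recovered", {
  set.seed(2)
  n <- 400
  sigma <- 0.05
  y <- rnorm(n, 0.5, sigma)
  cov <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
  fit <- fit_normative(y, cov, seed = 2)
  vn_raw <- fit$vn * fit$y_sd^2  # de-standardized noise variance
  expect_lt(abs(vn_raw / sigma^2 - 1), 0.10)
})

test_that("duplicate training rows do not break the fit", {
  set.seed(3)
  cov <- data.frame(age = rep(c(30, 40, 50, 60), each = 6),
                    sex = rep(c(0, 1), 12))
  y <- 0.5 - 0.002 * cov$age + rnorm(24, 0, 0.02)
  expect_s3_class(fit_normative(y, cov, seed = 3), "normative_fit")
})

test_that("predictive uncertainty grows away from the training support", {
  set.seed(4)
  n <- 80
  cov <- data.frame(age = runif(n, 30, 50), sex = rbinom(n, 1, 0.5))
  y <- 0.5 - 0.002 * cov$age + rnorm(n, 0, 0.03)
  fit <- fit_normative(y, cov, seed = 4)
  inside <- predict(fit, data.frame(age = 40, sex = 0))
  far <- suppressWarnings(predict(fit, data.frame(age = 90, sex = 0)))
  expect_lte(inside$var_function[1, 1], far$var_function[1, 1])
  expect_true(all(inside$var_total >= inside$var_function))
  expect_true(all(inside$var_function >= 0))
})

test_that("Z-score arithmetic follows (y - yhat)/sqrt(var_total)", {
  pr <- fake_prediction(mean = matrix(1, 1, 1),
                        var_function = matrix(0.03, 1, 1),
                        noise_var = 0.01)
  z <- compute_z(matrix(1.4, 1, 1), pr)
  expect_equal(z$Z[1, 1], 2.0)
  z0 <- compute_z(matrix(1, 1, 1), pr)
  expect_equal(z0$Z[1, 1], 0)
  bad <- fake_prediction(matrix(1, 1, 1), matrix(0, 1, 1), 0)
  expect_error(compute_z(matrix(1, 1, 1), bad), "positive")
})

test_that("95% predictive intervals cover held-out healthy data", {
  dat <- small_dataset(n_hc = 400, dims = c(8, 10, 8), seed = 21)
  tr <- 1:300; te <- 301:400
  fit <- fit_normative(dat$gm[tr, ], dat$cohort[tr, c("age", "sex")], seed = 5)
  pred <- predict(fit, dat$cohort[te, c("age", "sex")])
  lo <- pred$mean - 1.96 * sqrt(pred$var_total)
  hi <- pred$mean + 1.96 * sqrt(pred$var_total)
  cover <- mean(dat$gm[te, ] >= lo & dat$gm[te, ] <= hi)
  expect_lt(abs(cover - 0.95), 0.02)
})

test_that("cross-validation scores every subject exactly once in balanced folds", {
  dat <- small_dataset(n_hc = 95, dims = c(6, 8, 6), seed = 23)
  cv <- crossvalidated_z(dat$gm, dat$cohort[, c("age", "sex")], k = 10, seed = 2)
  expect_false(anyNA(cv$Z))
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_lte(diff(range(table(cv$folds))), 1)
  expect_true(all(cv$provenance == "cv"))
  expect_error(crossvalidated_z(dat$gm, dat$cohort[, c("age", "sex")], k = 96),
               "folds")
})

test_that("leave-one-out cross-validation matches explicit per-subject refits", {
  dat <- small_dataset(n_hc = 30, dims = c(5, 6, 5), seed = 25)
  cov <- dat$cohort[, c("age", "sex")]
  cv <- suppressWarnings(
    crossvalidated_z(dat$gm, cov, k = 30, seed = 9))
  # oracle: refit without each subject by hand, using the same fold seeds
  for (i in c(4, 17, 28)) {
    f <- cv$folds[i]
    keep <- cv$folds != f
    fit <- fit_normative(dat$gm[keep, ], cov[keep, ], seed = 9 + f)
    pr <- suppressWarnings(predict(fit, cov[i, , drop = FALSE]))
    z_oracle <- compute_z(dat$gm[i, , drop = FALSE], pr)$Z
    expect_equal(unname(cv$Z[i, ]), unname(z_oracle[1, ]), tolerance = 1e-8)
  }
})

test_that("fold-wise Z variance is homogeneous on calibrated data", {
  dat <- small_dataset(n_hc = 200, dims = c(8, 10, 8), seed = 27)
  cv <- crossvalidated_z(dat$gm, dat$cohort[, c("age", "sex")], k = 10, seed = 3)
  # Brown-Forsythe/Levene: anova of |Z - fold median| on fold, using the
  # per-subject mean absolute deviation as the unit of analysis
  zrow <- rowMeans(abs(cv$Z - ave(cv$Z, cv$folds, FUN = median)))
  p <- anova(lm(zrow ~ factor(cv$folds)))[["Pr(>F)"]][1]
  expect_gt(p, 0.01)
})

test_that("restarts can only improve the marginal likelihood", {
  set.seed(6)
  n <- 50
  cov <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
  y <- 0.5 - 0.002 * cov$age + rnorm(n, 0, 0.03)
  f1 <- fit_normative(y, cov, kernel = kernel_config(n_restarts = 1), seed = 7)
  f3 <- fit_normative(y, cov, kernel = kernel_config(n_restarts = 4), seed = 7)
  expect_gte(sum(f3$lml), sum(f1$lml) - 1e-6)
})

test_that("model evaluation flags informative voxels and handles degenerate ones", {
  obs <- matrix(rnorm(200), 20, 10)
  ev <- evaluate_model(obs, obs)
  expect_equal(ev$r, rep(1, 10))
  set.seed(8)
  ev0 <- evaluate_model(matrix(rnorm(20000), 200, 100),
                        matrix(rnorm(20000), 200, 100))
  expect_lt(abs(mean(ev0$r)), 0.03)
  const <- obs; const[, 1] <- 5
  evc <- evaluate_model(obs, const)
  expect_true(is.na(evc$r[1]))
})

test_that("steep-decline parcels are the best predicted out of sample", {
  dat <- small_dataset(n_hc = 200, dims = c(10, 12, 10), seed = 29)
  tr <- 1:150; te <- 151:200
  fit <- fit_normative(dat$gm[tr, ], dat$cohort[tr, c("age", "sex")], seed = 11)
  pred <- predict(fit, dat$cohort[te, c("age", "sex")])
  ev <- evaluate_model(pred$mean, dat$gm[te, ])
  steepest <- dat$truth$parcel_map == which.min(dat$truth$slopes_by_parcel)
  shallow <- dat$truth$parcel_map == which.max(dat$truth$slopes_by_parcel)
  expect_gt(mean(ev$r[steepest]), mean(ev$r[shallow]))
})

test_that("forward-model slopes recover the generator truth", {
  dat <- small_dataset(n_hc = 300, dims = c(10, 12, 10), seed = 31)
  fit <- fit_normative(dat$gm, dat$cohort[, c("age", "sex")], seed = 13)
  sl <- forward_model_slopes(fit, dat$cfg$age_range)
  est <- (sl$slope_female + sl$slope_male) / 2
  relerr <- abs(est - dat$truth$slope_map) / abs(dat$truth$slope_map)
  expect_lt(median(relerr), 0.15)
  # sex enters as an age-constant offset, so the slope difference is ~0
  expect_lt(max(abs(sl$difference)), 5e-4)
})

test_that("a constant mean surface yields zero slopes", {
  set.seed(9)
  n <- 60
  cov <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
  y <- rep(0.5, n) + rnorm(n, 0, 1e-4)
  fit <- fit_normative(y, cov, seed = 15)
  sl <- forward_model_slopes(fit)
  expect_lt(abs(sl$slope_female[1]), 1e-5)
  expect_lt(abs(sl$slope_male[1]), 1e-5)
})

test_that("per-voxel hyperparameter mode agrees with tied mode on simple data", {
  set.seed(10)
  n <- 60
  cov <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
  Y <- cbind(0.5 - 0.002 * cov$age + rnorm(n, 0, 0.03),
             0.4 + 0.001 * cov$age + rnorm(n, 0, 0.05))
  ft <- fit_normative(Y, cov, seed = 17, hyperparams = "tied")
  fp <- fit_normative(Y, cov, seed = 17, hyperparams = "pervoxel")
  new <- data.frame(age = c(25, 45, 65), sex = c(0, 1, 0))
  pt <- predict(ft, new); pp <- predict(fp, new)
  expect_lt(max(abs(pt$mean - pp$mean)), 0.01)
  expect_true(all(pp$var_total > pp$var_function))
})
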