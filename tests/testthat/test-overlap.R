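test_that("overlap maps are subject proportions with well-defined peaks", {
  masks <- rbind(c(TRUE, FALSE, FALSE, TRUE),
                 c(FALSE, TRUE, FALSE, TRUE))
  # single-subject group: the map is the subject's own mask
  om1 <- overlap_map(masks[1, , drop = FALSE], "SZ")
  expect_equal(om1$SZ$proportion, c(1, 0, 0, 1))
  expect_equal(om1$SZ$peak_value, 1)

  # two subjects with disjoint masks: peak 0.5
  dis <- rbind(c(TRUE, FALSE, FALSE, FALSE), c(FALSE, TRUE, FALSE, FALSE))
  om2 <- overlap_map(dis, c("SZ", "SZ"))
  expect_equal(om2$SZ$peak_value, 0.5)
  expect_equal(om2$SZ$peak_index, c(1L, 2L))  # all ties, lowest first

  expect_error(overlap_map(masks, factor(c("SZ", "SZ"), levels = c("SZ", "HC"))),
               "empty group")
})

test_that("iid extreme probabilities give binomial-consistent overlap", {
  set.seed(1)
  n <- 200; V <- 500; q <- 0.05
  masks <- matrix(runif(n * V) < q, n, V)
  om <- overlap_map(masks, rep("HC", n))$HC
  expect_lt(abs(mean(om$proportion) - q), 0.005)
  # peak consistent with the max of V Binomial(n, q) draws
  qs <- qbinom(c(0.001, 0.999)^(1 / V), n, q) / n
  expect_gte(om$peak_value, qs[1])
  expect_lte(om$peak_value, qs[2])
})

test_that("overlap decreases monotonically with the threshold", {
  dat <- small_dataset(n_hc = 60, n_sz = 30, dims = c(10, 12, 10), seed = 51)
  hc <- dat$cohort$group == "HC"
  fit <- fit_normative(dat$gm[hc, ], dat$cohort[hc, c("age", "sex")], seed = 8)
  Z <- compute_z(dat$gm, suppressWarnings(
    predict(fit, dat$cohort[, c("age", "sex")])))$Z
  oms <- lapply(c(1.96, 2.6, 3.1), function(thr)
    overlap_map(Z < -thr, droplevels(dat$cohort$group))$SZ$proportion)
  expect_true(all(oms[[1]] >= oms[[2]]))
  expect_true(all(oms[[2]] >= oms[[3]]))
})

test_that("group-mean extreme percentage equals the overlap-map mean", {
  set.seed(2)
  masks <- matrix(runif(50 * 300) < 0.03, 50, 300)
  g <- rep(c("HC", "SZ"), c(20, 30))
  om <- overlap_map(masks, g)
  pct <- 100 * rowMeans(masks)
  for (lv in c("HC", "SZ"))
    expect_equal(mean(pct[g == lv]), 100 * mean(om[[lv]]$proportion))
})

test_that("sex stratification splits maps and reports peaks per stratum", {
  set.seed(3)
  masks <- matrix(runif(40 * 100) < 0.1, 40, 100)
  g <- rep("SZ", 40); sex <- rep(c(0, 1), 20)
  st <- stratified_overlap(masks, g, sex)
  expect_equal(nrow(st$peaks), 2)
  expect_setequal(st$peaks$stratum, c("0", "1"))

  # all-male group: female stratum skipped with a warning, male map = pooled
  expect_warning(st2 <- stratified_overlap(masks, g, rep(1, 40),
                                           vs = NULL) , NA)
  st_all <- stratified_overlap(masks, g, rep(1, 40))
  pooled <- overlap_map(masks, g)$SZ$proportion
  expect_equal(st_all$maps$SZ[["1"]]$proportion, pooled)
  expect_error(stratified_overlap(masks, g, c(NA, rep(1, 39))), "available")
})

test_that("male-biased lesion rates produce a stronger male overlap", {
  peaks_m <- numeric(4); peaks_f <- numeric(4)
  for (s in 1:4) {
    cfg <- generator_config(n_hc = 0, n_bp = 0, n_sz = 120,
                            dims = c(10, 12, 10), sex_lesion_ratio = 4,
                            seed = 60 + s)
    coh <- generate_cohort(cfg)
    vd <- generate_voxel_data(coh, cfg)
    # score against the known mean surface (no lesions, no noise model
    # needed): deviations in noise_sd units
    mu <- cfg$baseline_gm +
      outer(coh$age - cfg$age_ref, vd$truth$slope_map) +
      outer(as.numeric(coh$sex), vd$truth$sex_offset_map)
    Z <- (vd$gm - mu) / cfg$noise_sd
    st <- stratified_overlap(Z < -2.6, coh$group, coh$sex)
    peaks_f[s] <- st$peaks$peak_value[st$peaks$stratum == "0"]
    peaks_m[s] <- st$peaks$peak_value[st$peaks$stratum == "1"]
  }
  expect_true(all(peaks_m > peaks_f))
})
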