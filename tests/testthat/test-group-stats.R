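test_that("Mann-Whitney U and p behave correctly in canonical cases", {
  # identical multisets: U is exactly its null mean
  a <- c(1, 2, 3, 4)
  mw <- mann_whitney(a, a)
  expect_equal(mw$U, length(a)^2 / 2)
  expect_equal(mw$p, 1)

  # complete separation, one-sided: 1 of choose(6,3)=20 assignments
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(mw$p, 1 / 20)
  expect_equal(mw$U, 0)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  expect_equal(mann_whitney(rep(1, 30), rep(1, 40))$p, 1)
})

test_that("enumeration agrees with the exact distribution and the approximation", {
  set.seed(1)
  for (rep in 1:5) {
    a <- rnorm(7); b <- rnorm(6)
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # exact vs normal approximation at n = 8 vs 8
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    pe <- mann_whitney(a, b, exact_max = 8)$p
    pa <- mann_whitney(a, b, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Mann-Whitney type-I error is nominal under the null", {
  set.seed(2)
  nrep <- 5000
  rej <- logical(nrep)
  for (i in seq_len(nrep)) {
    x <- rnorm(50); y <- rnorm(50)
    rej[i] <- mann_whitney(x, y)$p < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))

  # direct-definition oracle: sort, multiply by (m - i + 1), enforce
  # monotonicity, cap at 1, restore order
  set.seed(3)
  p <- runif(12)
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  oracle <- numeric(m); oracle[o] <- adj
  expect_equal(holm_adjust(p), oracle)

  # adjusted significance set is a subset of the raw one
  expect_true(all(which(holm_adjust(p) < 0.05) %in% which(p < 0.05)))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm controls the family-wise error over all-null families", {
  set.seed(4)
  nrep <- 5000
  fwer <- logical(nrep)
  for (i in seq_len(nrep)) {
    p <- runif(3)  # three null comparisons
    fwer[i] <- any(holm_adjust(p) < 0.05)
  }
  expect_lte(mean(fwer), 0.055)  # <= alpha up to Monte-Carlo error
})

test_that("score-symptom correlations are computed pooled and per group", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- c("BP", "BP", "BP", "SZ", "SZ", "SZ")
  res <- correlate_scores(x, x, g)
  expect_equal(res$r[res$scope == "pooled"], 1)

  set.seed(5)
  cnt <- 0
  for (i in 1:200) {
    s <- rnorm(200); cvr <- rnorm(200)
    r <- correlate_scores(s, cvr, rep(c("BP", "SZ"), 100))$r[1]
    if (abs(r) < 0.15) cnt <- cnt + 1
  }
  expect_gte(cnt / 200, 0.93)

  # missing covariates (healthy controls) are dropped
  res <- correlate_scores(c(1, 2, 3, 4, 10, 12), c(NA, NA, 5, 6, 20, 22),
                          c("HC", "HC", "BP", "BP", "SZ", "SZ"))
  expect_equal(res$n[res$scope == "pooled"], 4)
  # zero variance is reported as missing
  resz <- correlate_scores(rep(1, 6), c(1, 2, 3, 4, 5, 6),
                           rep(c("BP", "SZ"), 3))
  expect_true(is.na(resz$r[1]))
})

test_that("prevalence ratios reproduce the reference arithmetic", {
  expect_equal(prevalence_ratio(0.90, 0.23), 3.91)
  expect_equal(prevalence_ratio(0.64, 0.16), 4.00)
  expect_equal(prevalence_ratio(1.09, 0.22), 4.95)
  expect_equal(prevalence_ratio(0.5, 0.5), 1.00)
  expect_error(prevalence_ratio(1, 0), "positive")
})

test_that("pairwise group comparisons carry Holm-corrected p-values", {
  set.seed(6)
  sc <- data.frame(pct_negative = c(rnorm(40, 0.2, 0.05), rnorm(40, 0.2, 0.05),
                                    rnorm(40, 0.9, 0.3)),
                   group = rep(c("HC", "BP", "SZ"), each = 40))
  cmp <- compare_groups(sc, "pct_negative")
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$p_holm >= cmp$p_raw))
  sz_rows <- cmp$group_b == "SZ"
  expect_true(all(cmp$p_holm[sz_rows] < 0.001))
  expect_true(all(cmp$direction[sz_rows] == "<"))
})
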