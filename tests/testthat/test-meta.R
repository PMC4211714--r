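test_that("standard errors derive from CI width by the normal quantile", {
  expect_equal(se_from_ci(30.4, 216.4), (216.4 - 30.4) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(round(se_from_ci(30.4, 216.4), 2), 47.45)
  expect_equal(se_from_ci(-1.96, 1.96), 1, tolerance = 1e-3)
  expect_equal(se_from_ci(-1.6449, 1.6449, level = 0.90), 1,
               tolerance = 1e-4)
  expect_error(se_from_ci(2, 2), "hi > lo")
})

test_that("fixed-effect pooling follows the inverse-variance closed form", {
  one <- meta_pool(5, se = 2, method = "fixed")
  expect_equal(one$beta_pooled, 5)
  expect_equal(one$se_pooled, 2)
  expect_equal(one$Q, 0)
  two <- meta_pool(c(5, 5), se = c(2, 2), method = "fixed")
  expect_equal(two$beta_pooled, 5)
  expect_equal(two$se_pooled, 2 / sqrt(2))
  expect_equal(two$Q, 0)
  m <- meta_pool(c(1, 2, 4), se = c(0.5, 1, 2), method = "fixed")
  w <- 1 / c(0.5, 1, 2)^2
  expect_equal(m$beta_pooled, sum(w * c(1, 2, 4)) / sum(w))
  expect_equal(m$weights_pct, 100 * w / sum(w))
  expect_equal(sum(m$weights_pct), 100, tolerance = 1e-6)
})

test_that("DerSimonian-Laird pooling matches metafor on random inputs", {
  set.seed(201)
  for (k in c(3, 5, 8)) {
    beta <- rnorm(k, 0, 2)
    se <- runif(k, 0.3, 1.5)
    m <- meta_pool(beta, se = se)
    ref <- metafor::rma(yi = beta, sei = se, method = "DL")
    expect_equal(m$beta_pooled, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(m$se_pooled, ref$se, tolerance = 1e-8)
    expect_equal(m$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(m$Q, ref$QE, tolerance = 1e-8)
    expect_equal(m$i2_pct, ref$I2, tolerance = 1e-6)
  }
})

test_that("published cohort rows pool to the published overall rows", {
  carb <- meta_from_estimates(table2_bw_carb())
  expect_equal(carb$beta_pooled, 41.0, tolerance = 0.1)
  expect_equal(carb$ci95[["lo"]], -32.3, tolerance = 0.1)
  expect_equal(carb$ci95[["hi"]], 114.3, tolerance = 0.1)
  expect_equal(carb$weights_pct, c(30.04, 30.65, 39.31), tolerance = 0.05)
  expect_gt(carb$tau2, 0)
  expect_equal(carb$i2_pct, 57.4, tolerance = 0.1)
  expect_equal(as.character(carb$band), "significant")

  fat <- meta_from_estimates(table2_bw_fat())
  expect_equal(fat$beta_pooled, 36.3, tolerance = 0.1)
  expect_equal(fat$ci95[["lo"]], -11.5, tolerance = 0.1)
  expect_equal(fat$ci95[["hi"]], 84.1, tolerance = 0.1)
  expect_equal(fat$weights_pct, c(29.41, 23.01, 47.58), tolerance = 0.05)
  expect_equal(fat$tau2, 0)      # between-study variance truncates to zero

  # waist rows (two cohorts each); printed-CI rounding propagates, so the
  # weight tolerance is wider
  wc_carb <- meta_pool(c(-0.7, 0.5), lo = c(-1.8, -0.1), hi = c(0.4, 1.0),
                       labels = c("DCH", "INTER99"))
  expect_equal(wc_carb$ci95[["lo"]], -1.1, tolerance = 0.1)
  expect_equal(wc_carb$ci95[["hi"]], 1.1, tolerance = 0.1)
  expect_equal(wc_carb$weights_pct, c(41.66, 58.34), tolerance = 0.2)
  wc_fat <- meta_pool(c(-0.8, 0.5), lo = c(-2.0, -0.1), hi = c(0.4, 1.1))
  expect_equal(wc_fat$beta_pooled, -0.1, tolerance = 0.1)
  expect_equal(wc_fat$weights_pct, c(41.50, 58.50), tolerance = 0.2)
})

test_that("heterogeneity bands use half-open bins with upward boundaries", {
  expect_equal(as.character(heterogeneity_band(10)), "no")
  expect_equal(as.character(heterogeneity_band(57.4)), "significant")
  expect_equal(as.character(heterogeneity_band(c(0, 25, 50, 75, 100))),
               c("no", "moderate", "significant", "extreme", "extreme"))
  expect_error(heterogeneity_band(101), "0, 100")
  expect_error(heterogeneity_band(-1), "0, 100")
})

test_that("random-effects pooling degenerates and scales correctly", {
  # tau2 = 0 implies fixed and random coincide exactly
  beta <- c(1.0, 1.1, 0.9); se <- c(1, 1, 1)
  r <- meta_pool(beta, se = se, method = "random")
  f <- meta_pool(beta, se = se, method = "fixed")
  expect_equal(r$tau2, 0)
  expect_identical(r$beta_pooled, f$beta_pooled)
  expect_identical(r$se_pooled, f$se_pooled)
  # identical studies: equal weights
  eq <- meta_pool(c(2, 2, 2), se = c(1, 1, 1))
  expect_equal(eq$weights_pct, rep(100 / 3, 3))
  # extreme heterogeneity: random-effects weights approach 1/k
  wild <- meta_pool(c(-1000, 0, 1000), se = c(0.01, 0.02, 0.03))
  expect_equal(wild$weights_pct, rep(100 / 3, 3), tolerance = 1e-4)
  # convexity: pooled estimate lies within the study range
  set.seed(202)
  for (i in 1:20) {
    b <- rnorm(4, 0, 5); s <- runif(4, 0.2, 2)
    for (meth in c("fixed", "random")) {
      m <- meta_pool(b, se = s, method = meth)
      expect_gte(m$beta_pooled, min(b))
      expect_lte(m$beta_pooled, max(b))
      expect_equal(sum(m$weights_pct), 100, tolerance = 1e-6)
    }
  }
  # scale equivariance
  m1 <- meta_pool(c(1, 2, 3), se = c(0.4, 0.6, 0.8))
  m2 <- meta_pool(10 * c(1, 2, 3), se = 10 * c(0.4, 0.6, 0.8))
  expect_equal(m2$beta_pooled, 10 * m1$beta_pooled)
  expect_equal(m2$se_pooled, 10 * m1$se_pooled)
  expect_equal(m2$weights_pct, m1$weights_pct)
  expect_equal(m2$i2_pct, m1$i2_pct)
  expect_identical(m2$band, m1$band)
})

test_that("meta output prints a forest table", {
  m <- meta_from_estimates(table2_bw_carb())
  txt <- forest_text(m)
  expect_length(txt, 4)
  expect_match(txt[4], "Overall")
  expect_output(print(m), "Random-effects")
})
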