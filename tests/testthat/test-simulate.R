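test_that("the same seed reproduces the dataset bit for bit", {
  cfg <- small_cfg(n = 120)
  a <- simulate_cohort(cfg, seed = 77)
  b <- simulate_cohort(cfg, seed = 77)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(a, c2))
  expect_error(simulate_cohort(cfg), "seed")
})

test_that("genotypes follow Hardy-Weinberg moments", {
  panel <- data.frame(snp_id = c("sA", "sB"), risk_allele = c("A", "C"),
                      trait = c("BMI", "BMI"),
                      risk_allele_freq = c(0.5, 0.001))
  g <- simulate_genotypes(10000, panel, seed = 404)
  expect_equal(mean(g$sA), 1.0, tolerance = 0.02)
  expect_equal(var(g$sA), 2 * 0.5 * 0.5, tolerance = 0.05)
  expect_lt(mean(g$sB), 0.01)          # p -> 0 limit: dosages almost all 0
  expect_true(all(g$sA %in% 0:2))
  gm <- simulate_genotypes(2000, small_panel(), missing_rate = 0.1,
                           seed = 405)
  miss <- mean(is.na(as.matrix(gm[small_panel()$snp_id])))
  expect_lt(abs(miss - 0.1), 0.01)
})

test_that("diet compositions close to 100 and track the configured center", {
  d0 <- simulate_diet(50, center = c(15, 45, 35, 5),
                      logratio_sd = c(0, 0, 0), seed = 406)
  expect_equal(d0$protein_e, rep(15, 50), tolerance = 1e-12)
  expect_equal(d0$fat_e, rep(35, 50), tolerance = 1e-12)

  d <- simulate_diet(5000, center = c(14.8, 47.5, 32.4, 3.0),
                     logratio_sd = c(0.22, 0.25, 0.9), seed = 407)
  tot <- d$protein_e + d$carbohydrate_e + d$fat_e + d$alcohol_e
  expect_equal(tot, rep(100, 5000), tolerance = 1e-10)
  expect_true(all(d[1:4] > 0))
  expect_equal(median(d$protein_e), 14.8, tolerance = 0.5 / 14.8)
})

test_that("outcomes are the planted linear model plus noise", {
  cfg <- small_cfg(n = 200, beta0 = 0, beta_protein_sub = 0,
                   beta_score = 0, beta_interaction = 0)
  cfg$noise_sd <- 0; cfg$wc_noise_sd <- 0
  cfg$covariate_effects[] <- 0
  cfg$wc_intercept <- 0; cfg$wc_couple <- 0
  set.seed(408)
  latent <- as.matrix(simulate_genotypes(200, small_panel())[
    small_panel()$snp_id])
  diet <- simulate_diet(200)
  covs <- data.frame(bw0_kg = rep(80, 200), height_cm = 170,
                     sex = "female", smoking = "never", fu_years = 5)
  out <- simulate_outcomes(latent, diet, covs, cfg)
  expect_equal(out$d_bw, rep(0, 200))
  expect_equal(out$bw1_kg, rep(80, 200))
  expect_equal(out$d_wc, rep(0, 200))

  # planted main effect appears in d_bw exactly when noise is off
  cfg2 <- cfg; cfg2$beta_protein_sub <- 0.02
  out2 <- simulate_outcomes(latent, diet, covs, cfg2)
  s <- (diet$protein_e - diet$carbohydrate_e) / 2
  expect_equal(out2$d_bw, 0.02 * s)
})

test_that("a planted interaction is recovered by the matching fit", {
  co <- small_cohort(n = 4000, seed = 409, beta_interaction = 0.01,
                     noise_sd = 0.5)
  f <- fit_substitution(co, score_type = "complete", panel = small_panel())
  cf <- f$coefficients[f$coefficients$term == "substitution_x_score", ]
  expect_lt(abs(cf$beta - 0.01), 2 * cf$se)
})

test_that("the case-cohort preset enriches weight gainers", {
  dch <- cohort_preset("dch", panel = small_panel(), n_pool = 2500,
                       k_per_sex = 250, n_random = 470)
  co <- simulate_cohort(dch, seed = 410)
  expect_lt(nrow(co), 2500)
  expect_gt(nrow(co), 700)
  plain <- simulate_cohort(cohort_preset("dch", panel = small_panel(),
                                         emulate_gainers = FALSE, n = 1000),
                           seed = 410)
  d_sel <- (co$bw1_kg - co$bw0_kg) / co$fu_years
  d_plain <- (plain$bw1_kg - plain$bw0_kg) / plain$fu_years
  expect_gt(median(d_sel), median(d_plain))
})

test_that("the monica preset has no waist measurements", {
  co <- simulate_cohort(cohort_preset("monica", panel = small_panel(),
                                      n = 80), seed = 411)
  expect_true(all(is.na(co$wc0_cm)))
  expect_true(all(is.na(co$wc1_cm)))
  expect_false(any(is.na(co$bw1_kg)))
})

test_that("between-cohort differences in the planted interaction surface as
           heterogeneity", {
  tau_pos <- logical(12)
  for (r in seq_len(12)) {
    betas <- ses <- numeric(3)
    for (i in 1:3) {
      b_int <- c(-0.02, 0, 0.02)[i]
      co <- small_cohort(n = 500, seed = 6000 + 10 * r + i,
                         beta_interaction = b_int, noise_sd = 0.4)
      f <- fit_substitution(co, score_type = "complete",
                            panel = small_panel())
      cf <- f$coefficients[f$coefficients$term == "substitution_x_score", ]
      betas[i] <- cf$beta; ses[i] <- cf$se
    }
    tau_pos[r] <- meta_pool(betas, se = ses)$tau2 > 0
  }
  expect_gt(mean(tau_pos), 0.5)
})

test_that("simulated cohorts round-trip through the TSV writer", {
  co <- small_cohort(n = 40, seed = 412)
  path <- tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(names(back), names(co))
  expect_equal(back$individual_id, co$individual_id)
  expect_equal(back$protein_e, co$protein_e, tolerance = 1e-8)
  expect_equal(back$pa, co$pa)
  f1 <- fit_substitution(co)
  f2 <- fit_substitution(back)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  unlink(path)
})
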