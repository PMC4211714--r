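test_that("annualized changes divide by individual follow-up time", {
  a <- annualize(70, 72.5, NA, NA, 5)
  expect_equal(a$d_bw, 0.5)      # 500 g/y on the reporting scale
  expect_true(is.na(a$d_wc))
  expect_equal(annualize(80, 80, 90, 90, 3.7)$d_bw, 0)
  # waist missing at baseline: d_wc missing, d_bw still computed
  b <- annualize(70, 71, NA, 95, 2)
  expect_equal(b$d_bw, 0.5)
  expect_true(is.na(b$d_wc))
  expect_message(bad <- annualize(70, 71, NA, NA, 0), "rejected")
  expect_true(is.na(bad$d_bw))
  # linear in the follow-up measurement, scale-equivariant in time
  expect_equal(annualize(70, 74, NA, NA, 4)$d_bw,
               2 * annualize(70, 72, NA, NA, 4)$d_bw)
  expect_equal(annualize(70, 74, NA, NA, 2)$d_bw,
               2 * annualize(70, 74, NA, NA, 4)$d_bw)
})

test_that("energy-balance trichotomy partitions the line with a closed
           neutral band", {
  expect_equal(as.character(classify_energy_balance(-0.6)), "negative")
  expect_equal(as.character(classify_energy_balance(0.5)), "neutral")
  expect_equal(as.character(classify_energy_balance(-0.5)), "neutral")
  expect_equal(as.character(classify_energy_balance(0.7)), "positive")
  grid <- seq(-3, 3, by = 0.01)
  cls <- classify_energy_balance(grid)
  expect_false(any(is.na(cls)))                      # total partition
  expect_true(all(diff(as.integer(cls)) >= 0))       # monotone in d_bw
})

test_that("subgroup protein table matches a hand-computed oracle", {
  # 4-row toy cohort, statistics computed independently by hand:
  # cell (positive, low): protein_e {12, 16} -> mean 14, sem 2, CI 14 +/- 3.92
  co <- data.frame(
    individual_id = c("a", "b", "c", "d"),
    protein_e = c(12, 16, 20, 11),
    energy_mj = 8.5, bw0_kg = 85, bw1_kg = c(90, 90, 80, 85),
    fu_years = 5
  )
  sc <- data.frame(individual_id = c("a", "b", "c", "d"),
                   score = c(1, 2, 9, 9))   # mean 5.25: a,b low; c,d high
  tab <- protein_by_subgroup(co, sc)
  expect_equal(nrow(tab), 6)
  pos_low <- tab[tab$balance == "positive" & tab$score_group == "low", ]
  expect_equal(pos_low$n, 2)
  expect_equal(pos_low$protein_e_mean, 14)
  expect_equal(pos_low$protein_e_sem, 2)
  expect_equal(pos_low$protein_e_lo, 14 - qnorm(0.975) * 2)
  # g/kg/day: 14 E% of 8.5 MJ at 17 kJ/g over 85 kg -> mean by hand
  gkg <- (c(12, 16) / 100) * 8500 / 17 / 85
  expect_equal(pos_low$protein_gkg_mean, mean(gkg))
  # empty cells are reported with n = 0 and missing statistics
  neg_low <- tab[tab$balance == "negative" & tab$score_group == "low", ]
  expect_equal(neg_low$n, 0)
  expect_true(is.na(neg_low$protein_e_mean))
  # cell (negative, high): single individual, SEM 0
  neg_high <- tab[tab$balance == "negative" & tab$score_group == "high", ]
  expect_equal(neg_high$n, 1)
  expect_equal(neg_high$protein_e_sem, 0)
})

test_that("constant protein intake gives equal cell means and zero SEM", {
  co <- small_cohort(n = 150, seed = 21)
  co$protein_e <- 15; co$energy_mj <- 9; co$bw0_kg <- 80
  sc <- build_score(co, small_panel(), "BMI")
  tab <- protein_by_subgroup(co, sc)
  filled <- tab[tab$n > 0, ]
  expect_true(all(abs(filled$protein_e_mean - 15) < 1e-12))
  expect_true(all(filled$protein_e_sem == 0))
})

test_that("gainer selection ranks residuals net of baseline covariates", {
  co <- small_cohort(n = 120, seed = 22)
  # k = n returns everyone, one warning per sex group that k exceeds
  w <- capture_warnings(all_ids <- select_weight_gainers(co, nrow(co)))
  expect_length(w, 2)
  expect_match(w, "exceeds", all = TRUE)
  expect_setequal(all_ids, co$individual_id)

  # covariate-free generator: selection reduces to top-k by raw d_bw
  n <- 60
  co2 <- data.frame(
    individual_id = sprintf("i%02d", 1:n),
    bw0_kg = 80, bw1_kg = 80, height_cm = 170, age_y = 50,
    smoking = "never", sex = rep(c("female", "male"), each = n / 2),
    fu_years = 5
  )
  set.seed(1); co2$bw1_kg <- 80 + rnorm(n, 2, 3)
  got <- select_weight_gainers(co2, 5)
  raw <- (co2$bw1_kg - co2$bw0_kg) / co2$fu_years
  manual <- unlist(lapply(c("female", "male"), function(s) {
    d <- co2[co2$sex == s, ]
    d$individual_id[order(-raw[co2$sex == s], d$individual_id)][1:5]
  }))
  expect_setequal(got, manual)

  # planted covariate effect: a large gain fully explained by baseline
  # covariates is NOT selected, while a smaller unexplained gain is
  co3 <- co2
  slope <- 0.1                     # d_bw = 0.1 * (bw0 - 80) + residual
  set.seed(2)
  co3$bw0_kg <- 80 + c(30, rep(0, n - 1))          # one heavy individual
  resid_true <- c(0.2, rnorm(n - 2, 0, 0.3), 1.5)  # i60: big residual
  d_bw <- slope * (co3$bw0_kg - 80) + resid_true
  co3$bw1_kg <- co3$bw0_kg + d_bw * co3$fu_years
  got3 <- select_weight_gainers(co3, 3)
  expect_false("i01" %in% got3)    # d_bw = 3.2 kg/y but explained by bw0
  expect_true("i60" %in% got3)     # d_bw = 1.5 kg/y, all residual

  # invariance to adding any linear function of the regression covariates
  co5 <- co2
  set.seed(3)
  co5$age_y <- round(runif(n, 40, 60))
  co5$bw0_kg <- 80 + rnorm(n, 0, 5)
  base_sel <- select_weight_gainers(co5, 7)
  co6 <- co5
  co6$bw1_kg <- co5$bw1_kg + (0.05 * co5$age_y - 0.02 * co5$bw0_kg) *
    co5$fu_years
  expect_setequal(select_weight_gainers(co6, 7), base_sel)
})
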