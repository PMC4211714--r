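#' Configuration for the synthetic cohort generator
#'
#' Defines one simulated cohort: sample size, SNP panel and missingness,
#' a logistic-normal law for the four-part diet composition, covariate
#' distributions, and the outcome model. Annual weight change is generated
#' as
#' \deqn{dBW = \beta_0 + \beta_P s + \beta_G G + \beta_{int} s G +
#'   covariates + N(0, \sigma^2)}
#' where `s = (protein_e - replaced_e)/2` is the substitution variable (E%)
#' and `G` the complete predisposition score, so the generator's functional
#' form matches the analysis model. Waist change is coupled to weight change
#' (`d_wc = wc_intercept + wc_couple * d_bw + wc_sub * s + noise`), which
#' exercises the dWC-adjusted-for-dBW pathway. Follow-up weight is
#' back-computed as `bw0 + d_bw * fu_years` (waist analogously).
#'
#' @param label Cohort label.
#' @param n Individuals to simulate (ignored when `emulate_gainers` is on;
#'   the case-cohort construction sets the final size).
#' @param panel SNP panel; risk-allele frequencies drive Hardy-Weinberg
#'   genotype draws.
#' @param missing_rate Per-dosage missingness applied to the observed
#'   genotypes (the latent dosages still generate the outcomes).
#' @param diet_center Length-4 target composition (protein, carbohydrate,
#'   fat, alcohol E%); normalized to sum 100.
#' @param diet_logratio_sd SDs of the three log-ratios (carb/protein,
#'   fat/protein, alcohol/protein).
#' @param diet_logratio_cor Optional 3x3 correlation matrix for the
#'   log-ratios (default identity).
#' @param energy_median_mj,energy_sdlog Log-normal total energy intake.
#' @param replaced Macronutrient the planted substitution effect refers to.
#' @param beta0 Intercept of the weight-change model, kg/y.
#' @param beta_protein_sub Substitution main effect, kg/y per 1 E%.
#' @param beta_score Score main effect, kg/y per risk allele.
#' @param beta_interaction Substitution-by-score interaction, kg/y per 1 E%
#'   per risk allele.
#' @param covariate_effects Named vector of effects on d_bw for `bw0_kg`,
#'   `height_cm`, `sex_male`, `smoking_former`, `smoking_current`.
#' @param noise_sd Residual SD of d_bw, kg/y.
#' @param measure_wc Whether baseline/follow-up waist is measured at all
#'   (e.g. FALSE emulates a cohort without baseline waist).
#' @param wc_intercept,wc_couple,wc_sub,wc_noise_sd Waist-change model:
#'   intercept (cm/y), coupling to d_bw (cm per kg), substitution effect
#'   (cm/y per E%), residual SD (cm/y).
#' @param fu_mean,fu_sd Follow-up time distribution (years; truncated > 0.5).
#' @param age_mean,age_sd Baseline age (years).
#' @param bw0_median,bw0_sdlog Log-normal baseline body weight (kg).
#' @param height_mean_f,height_mean_m,height_sd Height by sex (cm).
#' @param sex_p_female Proportion of women.
#' @param smoking_p,pa_p Category probabilities (never/former/current; four
#'   activity groups).
#' @param education_p_high Proportion above primary schooling.
#' @param menopause_age Age (years) around which simulated women switch from
#'   pre- to postmenopausal.
#' @param emulate_gainers Emulate a case-cohort design: simulate `n_pool`
#'   eligible individuals, select the top `k_per_sex` weight gainers per sex
#'   by covariate-adjusted residuals ([select_weight_gainers()]) plus a
#'   random sample of `n_random`, and keep the union.
#' @param k_per_sex,n_random,n_pool Case-cohort construction sizes.
#' @return Object of class `gdsub_sim_config`.
#' @export
sim_config <- function(label = "cohort",
                       n = 2000,
                       panel = NULL,
                       missing_rate = 0.01,
                       diet_center = c(protein = 15, carbohydrate = 45,
                                       fat = 35, alcohol = 5),
                       diet_logratio_sd = c(0.22, 0.25, 0.9),
                       diet_logratio_cor = NULL,
                       energy_median_mj = 9.0,
                       energy_sdlog = 0.30,
                       replaced = "carbohydrate",
                       beta0 = 0.6,
                       beta_protein_sub = 0.008,
                       beta_score = 0,
                       beta_interaction = 0,
                       covariate_effects = c(bw0_kg = -0.004,
                                             height_cm = 0,
                                             sex_male = 0.05,
                                             smoking_former = 0,
                                             smoking_current = 0.08),
                       noise_sd = 0.9,
                       measure_wc = TRUE,
                       wc_intercept = 0.2,
                       wc_couple = 0.35,
                       wc_sub = 0,
                       wc_noise_sd = 0.9,
                       fu_mean = 5.2, fu_sd = 0.3,
                       age_mean = 46, age_sd = 8,
                       bw0_median = 74, bw0_sdlog = 0.18,
                       height_mean_f = 165, height_mean_m = 178,
                       height_sd = 6.5,
                       sex_p_female = 0.5,
                       smoking_p = c(never = 0.40, former = 0.30,
                                     current = 0.30),
                       pa_p = c(0.15, 0.40, 0.30, 0.15),
                       education_p_high = 0.70,
                       menopause_age = 51,
                       emulate_gainers = FALSE,
                       k_per_sex = 600, n_random = 1130, n_pool = 6000) {
  if (is.null(panel)) panel <- default_snp_panel()
  stopifnot(all(!is.na(panel$risk_allele_freq)),
            all(panel$risk_allele_freq > 0 & panel$risk_allele_freq < 1),
            noise_sd > 0, n >= 1, missing_rate >= 0, missing_rate < 1)
  check_replaced(replaced)
  diet_center <- 100 * diet_center / sum(diet_center)
  structure(as.list(environment()), class = "gdsub_sim_config")
}

#' Cohort presets emulating the three study populations
#'
#' Returns a [sim_config()] calibrated to each cohort's published profile:
#' sample size, median diet composition and energy, follow-up time, age,
#' baseline weight, covariate frequencies and genotyping missingness.
#' `"monica"` has no baseline waist measurement; `"dch"` switches on the
#' case-cohort gainer selection (600 per sex plus a random sample).
#'
#' @param cohort `"monica"`, `"dch"` or `"inter99"`.
#' @param ... Overrides passed on to [sim_config()] (e.g. `n`, `panel`).
#' @return A `gdsub_sim_config`.
#' @export
cohort_preset <- function(cohort = c("monica", "dch", "inter99"), ...) {
  cohort <- match.arg(cohort)
  args <- switch(cohort,
    monica = list(label = "MONICA", n = 1257,
                  diet_center = c(14.0, 35.9, 44.2, 4.1),
                  energy_median_mj = 9.0, fu_mean = 5.0, fu_sd = 0.15,
                  age_mean = 45, age_sd = 11, bw0_median = 69,
                  measure_wc = FALSE, missing_rate = 0.008,
                  smoking_p = c(never = 0.28, former = 0.30,
                                current = 0.42),
                  education_p_high = 0.655, sex_p_female = 0.52),
    dch = list(label = "DCH", n = 2167,
               diet_center = c(17.7, 41.6, 34.2, 4.3),
               energy_median_mj = 8.8, fu_mean = 5.3, fu_sd = 0.25,
               age_mean = 53, age_sd = 2.8, bw0_median = 77,
               missing_rate = 0.011,
               smoking_p = c(never = 0.41, former = 0.30, current = 0.29),
               education_p_high = 0.70, sex_p_female = 0.49,
               emulate_gainers = TRUE, k_per_sex = 600, n_random = 1130,
               n_pool = 6000),
    inter99 = list(label = "INTER99", n = 3630,
                   diet_center = c(14.8, 47.5, 32.4, 3.0),
                   energy_median_mj = 9.4, fu_mean = 5.4, fu_sd = 0.2,
                   age_mean = 46, age_sd = 8, bw0_median = 75,
                   missing_rate = 0.013,
                   smoking_p = c(never = 0.41, former = 0.28,
                                 current = 0.31),
                   education_p_high = 0.75, sex_p_female = 0.52))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

## latent Hardy-Weinberg dosage matrix, no missingness
sim_dosage_matrix <- function(n, panel) {
  m <- vapply(panel$risk_allele_freq,
              function(p) stats::rbinom(n, 2L, p), numeric(n))
  colnames(m) <- panel$snp_id
  m
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Risk-allele dosages are drawn Binomial(2, p) per SNP, independently across
#' SNPs and individuals; optional missingness is applied completely at
#' random.
#'
#' @param n Number of individuals.
#' @param panel SNP panel with `risk_allele_freq`.
#' @param missing_rate Probability each observed dosage is set missing.
#' @param seed Optional RNG seed.
#' @return Data frame `individual_id` + one dosage column per SNP.
#' @export
simulate_genotypes <- function(n, panel = NULL, missing_rate = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(panel)) panel <- default_snp_panel()
  m <- sim_dosage_matrix(n, panel)
  if (missing_rate > 0)
    m[stats::runif(length(m)) < missing_rate] <- NA
  out <- data.frame(individual_id = sprintf("id%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  out[colnames(m)] <- as.data.frame(m)
  out
}

#' Simulate diet compositions by a logistic-normal law
#'
#' Gaussian draws on the three log-ratios of carbohydrate, fat and alcohol to
#' protein are closed to 100 E%, so every composition sums to 100 exactly.
#' With zero log-ratio variance every individual sits at the (normalized)
#' center composition.
#'
#' @param n Number of individuals.
#' @param center Target composition (protein, carbohydrate, fat, alcohol).
#' @param logratio_sd SDs of the three log-ratios.
#' @param logratio_cor Optional correlation matrix of the log-ratios.
#' @param energy_median_mj,energy_sdlog Log-normal total energy intake.
#' @param seed Optional RNG seed.
#' @return Data frame with `protein_e`, `carbohydrate_e`, `fat_e`,
#'   `alcohol_e`, `energy_mj`.
#' @export
simulate_diet <- function(n,
                          center = c(15, 45, 35, 5),
                          logratio_sd = c(0.22, 0.25, 0.9),
                          logratio_cor = NULL,
                          energy_median_mj = 9.0, energy_sdlog = 0.30,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(center) == 4L, all(center > 0), length(logratio_sd) == 3L)
  center <- 100 * center / sum(center)
  mu <- log(center[2:4] / center[1])
  z <- matrix(stats::rnorm(3L * n), n, 3L)
  if (!is.null(logratio_cor)) z <- z %*% chol(logratio_cor)
  lr <- sweep(z %*% diag(logratio_sd), 2L, mu, `+`)
  expo <- exp(lr)
  protein <- 100 / (1 + rowSums(expo))
  data.frame(protein_e = protein,
             carbohydrate_e = protein * expo[, 1L],
             fat_e = protein * expo[, 2L],
             alcohol_e = protein * expo[, 3L],
             energy_mj = stats::rlnorm(n, log(energy_median_mj),
                                       energy_sdlog))
}

sim_covariates <- function(n, cfg) {
  sex <- ifelse(stats::runif(n) < cfg$sex_p_female, "female", "male")
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  height <- stats::rnorm(n, ifelse(sex == "female", cfg$height_mean_f,
                                   cfg$height_mean_m), cfg$height_sd)
  bw0 <- stats::rlnorm(n, log(cfg$bw0_median), cfg$bw0_sdlog)
  meno <- ifelse(sex == "male", "male",
                 ifelse(age + stats::rnorm(n, 0, 2) > cfg$menopause_age,
                        "post", "pre"))
  data.frame(
    sex = sex, age_y = age, height_cm = height, bw0_kg = bw0,
    smoking = sample(names(cfg$smoking_p), n, TRUE, cfg$smoking_p),
    pa = sample(c("1", "2", "3", "4"), n, TRUE, cfg$pa_p),
    education = ifelse(stats::runif(n) < cfg$education_p_high,
                       "high", "low"),
    menopause = meno,
    fu_years = pmax(0.5, stats::rnorm(n, cfg$fu_mean, cfg$fu_sd)),
    stringsAsFactors = FALSE
  )
}

#' Generate annualized outcomes from the planted linear model
#'
#' @param dosages Latent (complete) dosage matrix, one column per panel SNP.
#' @param diet Diet data frame from [simulate_diet()].
#' @param covariates Covariate data frame (needs `bw0_kg`, `height_cm`,
#'   `sex`, `smoking`, `fu_years`).
#' @param cfg A [sim_config()].
#' @param seed Optional RNG seed.
#' @return Data frame with `d_bw`, `d_wc`, `bw1_kg`, `wc0_cm`, `wc1_cm`.
#' @export
simulate_outcomes <- function(dosages, diet, covariates, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(diet)
  G <- rowSums(dosages)
  x <- if (cfg$replaced == "fat") diet$fat_e else diet$carbohydrate_e
  s <- (diet$protein_e - x) / 2
  ce <- cfg$covariate_effects
  cov_term <- ce[["bw0_kg"]] * covariates$bw0_kg +
    ce[["height_cm"]] * covariates$height_cm +
    ce[["sex_male"]] * (covariates$sex == "male") +
    ce[["smoking_former"]] * (covariates$smoking == "former") +
    ce[["smoking_current"]] * (covariates$smoking == "current")
  d_bw <- cfg$beta0 + cfg$beta_protein_sub * s + cfg$beta_score * G +
    cfg$beta_interaction * s * G + cov_term +
    stats::rnorm(n, 0, cfg$noise_sd)
  if (cfg$measure_wc) {
    wc0 <- 20 + 0.85 * covariates$bw0_kg + stats::rnorm(n, 0, 5)
    d_wc <- cfg$wc_intercept + cfg$wc_couple * d_bw + cfg$wc_sub * s +
      stats::rnorm(n, 0, cfg$wc_noise_sd)
    wc1 <- wc0 + d_wc * covariates$fu_years
  } else {
    wc0 <- wc1 <- d_wc <- rep(NA_real_, n)
  }
  data.frame(d_bw = d_bw, d_wc = d_wc,
             bw1_kg = covariates$bw0_kg + d_bw * covariates$fu_years,
             wc0_cm = wc0, wc1_cm = wc1)
}

#' Simulate one cohort
#'
#' Draws genotypes, diet, covariates and outcomes per the configuration;
#' under `emulate_gainers` a larger eligible pool is simulated first and the
#' case-cohort mix (top gainers per sex plus a random sample) is retained.
#' The same seed yields a bit-identical data frame.
#'
#' @param cfg A [sim_config()] or [cohort_preset()].
#' @param seed RNG seed (required, for reproducibility).
#' @return Cohort data frame with the full analysis schema: `individual_id`,
#'   one dosage column per panel SNP, diet, covariates and anthropometry
#'   (`bw0_kg`, `bw1_kg`, `wc0_cm`, `wc1_cm`, `fu_years`). The annualized
#'   `d_bw`/`d_wc` are intentionally left to [annualize_cohort()].
#' @export
simulate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "gdsub_sim_config"))
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n <- if (cfg$emulate_gainers) cfg$n_pool else cfg$n

  latent <- sim_dosage_matrix(n, cfg$panel)
  diet <- simulate_diet(n, cfg$diet_center, cfg$diet_logratio_sd,
                        cfg$diet_logratio_cor, cfg$energy_median_mj,
                        cfg$energy_sdlog)
  covs <- sim_covariates(n, cfg)
  out <- simulate_outcomes(latent, diet, covs, cfg)

  observed <- latent
  if (cfg$missing_rate > 0)
    observed[stats::runif(length(observed)) < cfg$missing_rate] <- NA

  cohort <- data.frame(
    individual_id = sprintf("%s_%05d", cfg$label, seq_len(n)),
    stringsAsFactors = FALSE)
  cohort[colnames(observed)] <- as.data.frame(observed)
  cohort <- cbind(cohort, diet, covs,
                  out[c("bw1_kg", "wc0_cm", "wc1_cm")])
  ## carry latent d_bw only for the gainer selection; recomputable exactly
  ## from bw0/bw1/fu
  if (cfg$emulate_gainers) {
    gainers <- select_weight_gainers(cohort, cfg$k_per_sex)
    random_ids <- sample(cohort$individual_id, min(cfg$n_random, n))
    keep_ids <- union(gainers, random_ids)
    cohort <- cohort[cohort$individual_id %in% keep_ids, , drop = FALSE]
    rownames(cohort) <- NULL
  }
  cohort
}

#' Simulate the three-cohort study
#'
#' @param cfgs List of `gdsub_sim_config` (default: the three presets).
#' @param seed Base seed; cohort i uses `seed + i - 1`.
#' @return Named list of cohort data frames.
#' @export
simulate_study <- function(cfgs = NULL, seed) {
  if (missing(seed)) stop("a seed is required")
  if (is.null(cfgs))
    cfgs <- list(cohort_preset("monica"), cohort_preset("dch"),
                 cohort_preset("inter99"))
  out <- lapply(seq_along(cfgs),
                function(i) simulate_cohort(cfgs[[i]], seed + i - 1L))
  names(out) <- vapply(cfgs, `[[`, character(1), "label")
  out
}
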