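# shared fixtures, all generated in code

# compact 6-SNP panel for fast tests (one dual-trait SNP, like the full panel)
small_panel <- function() {
  validate_snp_panel(data.frame(
    snp_id = paste0("rsT", 1:6),
    risk_allele = c("A", "C", "G", "T", "A", "G"),
    trait = c("BMI", "BMI", "BMI+WC", "WC", "WHR_BMI", "WHR_BMI"),
    risk_allele_freq = c(0.3, 0.5, 0.4, 0.2, 0.6, 0.5),
    stringsAsFactors = FALSE
  ))
}

small_cfg <- function(n = 200, ...) {
  sim_config(n = n, panel = small_panel(), missing_rate = 0, ...)
}

small_cohort <- function(n = 200, seed = 42, ...) {
  simulate_cohort(small_cfg(n = n, ...), seed = seed)
}

# hand-rolled diet rows with exact closure
toy_diet <- function() {
  data.frame(protein_e = 15, carbohydrate_e = 45, fat_e = 35, alcohol_e = 5,
             energy_mj = 9)
}

# Table 2 cohort-level rows (printed betas and 95% CIs), reused across tests
table2_bw_carb <- function() {
  data.frame(label = c("MONICA", "DCH", "INTER99"),
             beta = c(123.4, -11.6, 19.0),
             lo = c(30.4, -102.6, -47.6),
             hi = c(216.4, 79.5, 85.6))
}

table2_bw_fat <- function() {
  data.frame(label = c("MONICA", "DCH", "INTER99"),
             beta = c(56.3, 54.5, 15.2),
             lo = c(-31.9, -45.1, -54.1),
             hi = c(144.4, 154.1, 84.5))
}
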