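#' Per-SNP substitution-interaction scan with Bonferroni correction
#'
#' Fits one substitution-interaction model per SNP, with the SNP's risk-allele
#' dosage in place of the predisposition score, and Bonferroni-corrects the
#' interaction p-values. The correction divisor `m_tests` stays fixed at the
#' panel size even when individual SNPs are skipped (e.g. monomorphic in the
#' sample), so the family-wise guarantee refers to the full set of planned
#' tests. Correction is applied within one outcome-by-substitution
#' combination, recorded in the output attributes.
#'
#' @param cohort Cohort data frame with dosage columns for the panel SNPs.
#' @param panel SNP panel (default bundled panel).
#' @param outcome,replaced,adjust_age,adjust_fu Passed to
#'   [fit_substitution()].
#' @param m_tests Bonferroni divisor; defaults to `nrow(panel)`.
#' @return Data frame with columns `snp_id`, `beta_int` (reporting scale:
#'   g/y or mm/y per 5 E% per risk allele), `se`, `p_raw`,
#'   `p_corrected = min(1, m_tests * p_raw)`, `m_tests`, `n`; attributes
#'   `outcome` and `replaced`.
#' @export
scan_snps <- function(cohort, panel = NULL,
                      outcome = "dBW", replaced = "carbohydrate",
                      m_tests = NULL, adjust_age = FALSE, adjust_fu = FALSE) {
  if (is.null(panel)) panel <- default_snp_panel()
  if (is.null(m_tests)) m_tests <- nrow(panel)
  missing_snps <- setdiff(panel$snp_id, names(cohort))
  if (length(missing_snps) > 0L)
    stop("cohort lacks dosage column(s): ",
         paste(missing_snps, collapse = ", "))
  rows <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    snp <- panel$snp_id[i]
    dose <- cohort[[snp]]
    if (length(unique(dose[!is.na(dose)])) < 2L) {
      warning("SNP ", snp, " is monomorphic in this sample; skipped ",
              "(m_tests unchanged)")
      next
    }
    dat <- cohort
    dat$score <- dose
    fit <- tryCatch(
      fit_substitution(dat, outcome = outcome, replaced = replaced,
                       parameterization = "substitution",
                       score_type = "complete",  # label only; score supplied
                       adjust_age = adjust_age, adjust_fu = adjust_fu),
      error = function(e) {
        warning("SNP ", snp, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    rep_cf <- rescale_effect(fit)
    int <- rep_cf[rep_cf$term == "substitution_x_score", ]
    rows[[i]] <- data.frame(snp_id = snp, beta_int = int$beta, se = int$se,
                            p_raw = int$p,
                            p_corrected = bonferroni(int$p, m_tests),
                            m_tests = m_tests, n = fit$n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp_id = character(0), beta_int = numeric(0),
                      se = numeric(0), p_raw = numeric(0),
                      p_corrected = numeric(0), m_tests = integer(0),
                      n = integer(0))
  attr(out, "outcome") <- outcome
  attr(out, "replaced") <- replaced
  out
}

#' Bonferroni correction with a fixed number of tests
#'
#' @param p Raw p-value(s).
#' @param m Number of tests in the family.
#' @return `pmin(1, m * p)`.
#' @export
#' @examples
#' bonferroni(9e-4, 50)  # 0.045
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(m < 1)) stop("m must be at least 1")
  pmin(1, m * p)
}
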