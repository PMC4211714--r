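#' Ordinary least squares with classical standard errors
#'
#' QR-based OLS fit returning per-term estimates, classical (homoskedastic)
#' standard errors, normal-based (default) or t-based 95% confidence
#' intervals and two-sided p-values. Normal quantiles are the default because
#' the intended cohorts have thousands of rows.
#'
#' @param X Numeric design matrix with unique column labels (including the
#'   intercept column).
#' @param y Numeric outcome vector.
#' @param use_t Use t rather than normal quantiles for CIs and p-values.
#' @return List with `coefficients` (data.frame term/beta/se/lo/hi/p),
#'   `fitted`, `residuals`, `sigma2`, `n`, `df_residual`.
#' @export
fit_linear <- function(X, y, use_t = FALSE) {
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("design matrix must have unique column labels")
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop("need more observations (", n, ") than design columns (", p, ")")
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  pivot <- fit$qr$pivot
  xtx_inv <- xtx_inv[order(pivot), order(pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  q <- if (use_t) stats::qt(0.975, df) else Z95
  z <- beta / se
  pval <- if (use_t) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  list(coefficients = data.frame(term = colnames(X), beta = unname(beta),
                                 se = unname(se), lo = unname(beta - q * se),
                                 hi = unname(beta + q * se),
                                 p = unname(pval), row.names = NULL,
                                 stringsAsFactors = FALSE),
       fitted = fit$fitted.values, residuals = fit$residuals,
       sigma2 = sigma2, n = n, df_residual = df)
}

#' Fit a macronutrient substitution model on one cohort
#'
#' The central fitting function. Assembles the adjusted design for the
#' requested outcome, substitution parameterization and (optionally) a
#' predisposition score with its substitution interaction, and fits it by
#' ordinary least squares on the natural scale (kg/y or cm/y per 1 E%).
#' Reporting-scale effects (g/y or mm/y per 5 E%, per risk allele for
#' interactions) are available through [rescale_effect()] and shown by the
#' print method.
#'
#' @param cohort Cohort data frame: genotype dosage columns (when a score is
#'   requested), diet (`protein_e`, `carbohydrate_e`, `fat_e`, `alcohol_e`,
#'   `energy_mj`), covariates (`sex`, `height_cm`, `smoking`, `pa`,
#'   `education`, `menopause`, `age_y`) and anthropometry (`bw0_kg`,
#'   `bw1_kg`, `wc0_cm`, `wc1_cm`, `fu_years`).
#' @param panel SNP panel used to build the score (default bundled panel);
#'   ignored when `score_type` is `NULL` or the cohort already has a `score`
#'   column.
#' @inheritParams design_spec
#' @param use_t Use t instead of normal quantiles.
#' @return Object of class `gdsub_fit`.
#' @export
#' @seealso [design_spec()], [rescale_effect()], [meta_pool()]
fit_substitution <- function(cohort,
                             outcome = c("dBW", "dWC"),
                             replaced = c("carbohydrate", "fat"),
                             parameterization = c("substitution",
                                                  "leave_one_out"),
                             score_type = NULL,
                             interaction = NULL,
                             panel = NULL,
                             adjust_age = FALSE,
                             adjust_fu = FALSE,
                             use_t = FALSE) {
  spec <- design_spec(outcome, replaced, parameterization, score_type,
                      interaction, adjust_age, adjust_fu)
  if (!is.null(score_type) && !"score" %in% names(cohort)) {
    if (is.null(panel)) panel <- default_snp_panel()
    sc <- build_score(cohort, panel, score_type)
    cohort$score <- sc$score[match(cohort$individual_id, sc$individual_id)]
  }
  des <- assemble_design(cohort, spec)
  fl <- fit_linear(des$X, des$y, use_t = use_t)
  structure(list(coefficients = fl$coefficients,
                 spec = spec,
                 outcome_unit = if (spec$outcome == "dBW") "kg/y" else "cm/y",
                 term_roles = des$term_roles,
                 n = fl$n,
                 n_total = des$n_total,
                 n_dropped = des$n_dropped,
                 sigma2 = fl$sigma2,
                 df_residual = fl$df_residual,
                 fitted_values = fl$fitted,
                 residuals = fl$residuals,
                 design = des,
                 use_t = use_t),
            class = "gdsub_fit")
}

#' Rescale fitted effects to the reporting scale
#'
#' Converts natural-scale estimates (outcome units per 1 E%) to the reporting
#' scale: effects are multiplied by 5 (per 5 E% substitution) and by 1000
#' (kg/y to g/y) or 10 (cm/y to mm/y). Interaction terms are per 5 E% per
#' single risk allele (no rescaling over the score), score main effects are
#' converted in outcome units only. SE and CI endpoints scale identically, so
#' z-statistics and p-values are unchanged.
#'
#' @param fit A `gdsub_fit`, or a coefficient data.frame (term/beta/se/lo/hi)
#'   if `outcome_unit` is supplied.
#' @param per_e_pct Substitution increment on the reporting scale (default 5
#'   E%).
#' @param outcome_unit `"kg/y"` or `"cm/y"`; taken from the fit when omitted.
#' @return Coefficient data.frame restricted to the diet, score and
#'   interaction terms, on the reporting scale, with a `reporting_scale`
#'   label column.
#' @export
rescale_effect <- function(fit, per_e_pct = 5, outcome_unit = NULL) {
  if (inherits(fit, "gdsub_fit")) {
    cf <- fit$coefficients
    roles <- fit$term_roles
    outcome_unit <- fit$outcome_unit
  } else {
    cf <- fit
    roles <- stats::setNames(rep("diet", nrow(cf)), cf$term)
  }
  unit_factor <- switch(outcome_unit,
                        "kg/y" = 1000,   # -> g/y
                        "cm/y" = 10,     # -> mm/y
                        stop("unknown outcome_unit: ", outcome_unit))
  unit_label <- if (outcome_unit == "kg/y") "g/y" else "mm/y"
  keep <- cf$term %in% names(roles)[roles %in%
                                      c("diet", "score", "interaction")]
  cf <- cf[keep, , drop = FALSE]
  fac <- vapply(cf$term, function(tm) {
    switch(roles[[tm]],
           diet = per_e_pct * unit_factor,
           interaction = per_e_pct * unit_factor,
           score = unit_factor)
  }, numeric(1))
  lab <- vapply(cf$term, function(tm) {
    switch(roles[[tm]],
           diet = paste0(unit_label, " per ", per_e_pct, " E%"),
           interaction = paste0(unit_label, " per ", per_e_pct,
                                " E% per risk allele"),
           score = paste0(unit_label, " per risk allele"))
  }, character(1))
  for (cl in c("beta", "se", "lo", "hi")) cf[[cl]] <- cf[[cl]] * fac
  cf$reporting_scale <- lab
  rownames(cf) <- NULL
  cf
}

#' Project an interaction effect to a larger substitution and allele load
#'
#' Scales a reporting-scale interaction coefficient (outcome per 5 E% per
#' risk allele) to a hypothetical substitution of `extra_e_pct` E% in a
#' carrier of `n_alleles` risk alleles — a plausibility check on the
#' practical importance of an interaction estimate.
#'
#' @param beta_int Interaction coefficient, outcome units per 5 E% per risk
#'   allele.
#' @param extra_e_pct Size of the hypothetical substitution, E%.
#' @param n_alleles Number of risk alleles.
#' @return `beta_int * (extra_e_pct / 5) * n_alleles`.
#' @export
#' @examples
#' project_effect(-3.84, 5, 20)  # -76.8 g/y
project_effect <- function(beta_int, extra_e_pct, n_alleles) {
  beta_int * (extra_e_pct / 5) * n_alleles
}

#' @export
print.gdsub_fit <- function(x, digits = 3, ...) {
  s <- x$spec
  cat("Macronutrient substitution model (", s$parameterization, ")\n",
      sep = "")
  cat("  outcome: ", s$outcome, " (", x$outcome_unit, "), protein replacing ",
      s$replaced, "\n", sep = "")
  if (!is.null(s$score_type))
    cat("  score: ", s$score_type,
        if (s$interaction) " (with substitution interaction)", "\n",
        sep = "")
  cat("  n used: ", x$n, " (", x$n_dropped, " incomplete row(s) dropped)\n",
      sep = "")
  rep_cf <- rescale_effect(x)
  cat("\nEffects on the reporting scale:\n")
  print(data.frame(term = rep_cf$term,
                   beta = signif(rep_cf$beta, digits),
                   lo = signif(rep_cf$lo, digits),
                   hi = signif(rep_cf$hi, digits),
                   p = signif(rep_cf$p, digits),
                   scale = rep_cf$reporting_scale),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.gdsub_fit <- function(object, ...) {
  structure(list(fit = object,
                 natural = object$coefficients,
                 reporting = rescale_effect(object)),
            class = "summary.gdsub_fit")
}

#' @export
print.summary.gdsub_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nAll terms (natural scale, per 1 E%, ", x$fit$outcome_unit, "):\n",
      sep = "")
  nat <- x$natural
  nat[-1] <- lapply(nat[-1], signif, digits)
  print(nat, row.names = FALSE)
  cat("\nresidual variance:", signif(x$fit$sigma2, digits),
      " df:", x$fit$df_residual, "\n")
  invisible(x)
}

#' @export
coef.gdsub_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
confint.gdsub_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only 95% intervals are stored; refit with a different quantile")
  cf <- object$coefficients
  out <- cbind(`2.5 %` = cf$lo, `97.5 %` = cf$hi)
  rownames(out) <- cf$term
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
fitted.gdsub_fit <- function(object, ...) object$fitted_values

#' @export
residuals.gdsub_fit <- function(object, ...) object$residuals

#' @export
predict.gdsub_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  des <- assemble_design(newdata, object$spec)
  X <- des$X
  cf <- coef(object)
  missing_cols <- setdiff(names(cf), colnames(X))
  if (length(missing_cols) > 0L)
    stop("newdata design lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  drop(X[, names(cf), drop = FALSE] %*% cf)
}
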