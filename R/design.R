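#' Model specification for a substitution regression
#'
#' @param outcome `"dBW"` (annualized body-weight change, kg/y) or `"dWC"`
#'   (annualized waist-circumference change, cm/y; additionally adjusted for
#'   concurrent dBW).
#' @param replaced Macronutrient replaced by protein: `"carbohydrate"` or
#'   `"fat"`.
#' @param parameterization `"substitution"` (single substitution variable,
#'   supports interactions) or `"leave_one_out"`.
#' @param score_type Optional predisposition score entering the model as a
#'   main effect (`"complete"`, `"BMI"`, `"WC"`, `"WHR_BMI"`), or `NULL`.
#' @param interaction Include the substitution-by-score product term.
#'   Defaults to `TRUE` whenever a score is requested under the substitution
#'   parameterization. Requires `parameterization = "substitution"`.
#' @param adjust_age,adjust_fu Optional extra adjustment for baseline age and
#'   follow-up time (both off by default).
#' @return An object of class `gdsub_design_spec`.
#' @export
design_spec <- function(outcome = c("dBW", "dWC"),
                        replaced = c("carbohydrate", "fat"),
                        parameterization = c("substitution", "leave_one_out"),
                        score_type = NULL,
                        interaction = NULL,
                        adjust_age = FALSE,
                        adjust_fu = FALSE) {
  outcome <- match.arg(outcome)
  replaced <- match.arg(replaced)
  parameterization <- match.arg(parameterization)
  if (!is.null(score_type) &&
      (!is.character(score_type) || !score_type %in% SCORE_TYPES))
    stop("unknown score_type: must be one of ",
         paste(SCORE_TYPES, collapse = ", "))
  if (is.null(interaction))
    interaction <- !is.null(score_type) && parameterization == "substitution"
  if (interaction && is.null(score_type))
    stop("an interaction term requires a score_type")
  if (interaction && parameterization != "substitution")
    stop("true substitution interactions require the substitution ",
         "parameterization")
  structure(list(outcome = outcome, replaced = replaced,
                 parameterization = parameterization,
                 score_type = score_type, interaction = interaction,
                 adjust_age = adjust_age, adjust_fu = adjust_fu),
            class = "gdsub_design_spec")
}

## fixed factor codings; first level is the reference
FACTOR_LEVELS <- list(
  sex       = c("female", "male"),
  smoking   = c("never", "former", "current"),
  pa        = c("1", "2", "3", "4"),
  education = c("low", "high"),
  menopause = c("male", "pre", "post")
)

indicator_block <- function(x, name) {
  lev <- FACTOR_LEVELS[[name]]
  bad <- !is.na(x) & !x %in% lev
  if (any(bad))
    stop("invalid level(s) in ", name, ": ",
         paste(unique(x[bad]), collapse = ", "))
  cols <- lapply(lev[-1L], function(l) as.numeric(x == l))
  names(cols) <- paste0(name, "_", lev[-1L])
  cols
}

#' Assemble the regression design matrix for one cohort
#'
#' Builds the complete-case design matrix: intercept, diet terms for the
#' requested parameterization, optional score main effect and
#' substitution-by-score interaction, baseline level of the outcome, height,
#' and indicator blocks for sex, smoking (never/former/current), physical
#' activity (4 groups), education (low/high) and menopausal status (a single
#' postmenopausal indicator; with the sex indicator this spans the male /
#' premenopausal / postmenopausal cells). When the outcome is dWC the
#' concurrent dBW is an
#' additional covariate, so the waist effect is interpreted independently of
#' weight change. Indicator columns that are constant in the data (e.g. a
#' cohort with a single smoking level) are dropped with a warning; any
#' remaining rank deficiency is an error naming the collinear columns.
#'
#' @param cohort Cohort data frame (see [simulate_cohort()] for the schema);
#'   must contain the annualized outcome (`d_bw`/`d_wc`, else computed via
#'   [annualize_cohort()]) and, when a score is requested, a `score` column
#'   (added automatically by [fit_substitution()]).
#' @param spec A [design_spec()].
#' @return List with elements `X` (numeric matrix with labelled columns),
#'   `y`, `n_total`, `n_used`, `n_dropped`, `spec` and `term_roles` (which
#'   columns are diet / score / interaction terms), class `gdsub_design`.
#' @export
assemble_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "gdsub_design_spec"))
  cohort <- annualize_cohort(cohort)

  y_col <- if (spec$outcome == "dBW") "d_bw" else "d_wc"
  base_col <- if (spec$outcome == "dBW") "bw0_kg" else "wc0_cm"

  need <- c(y_col, base_col, DIET_COLS, "height_cm", "sex", "smoking", "pa",
            "education", "menopause")
  if (spec$outcome == "dWC") need <- c(need, "d_bw")
  if (!is.null(spec$score_type)) need <- c(need, "score")
  if (spec$adjust_age) need <- c(need, "age_y")
  if (spec$adjust_fu) need <- c(need, "fu_years")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "))

  n_total <- nrow(cohort)
  keep <- stats::complete.cases(cohort[need])
  dat <- cohort[keep, , drop = FALSE]
  if (nrow(dat) == 0L)
    stop("no complete cases for outcome ", spec$outcome,
         "; design cannot be assembled")
  dat <- check_diet(dat)

  diet_terms <- if (spec$parameterization == "substitution")
    substitution_terms(dat, spec$replaced)
  else
    leave_one_out_terms(dat, spec$replaced)

  cols <- c(list(`(Intercept)` = rep(1, nrow(dat))), as.list(diet_terms))
  roles <- c("(Intercept)" = "intercept",
             stats::setNames(rep("diet", ncol(diet_terms)),
                             names(diet_terms)))
  if (!is.null(spec$score_type)) {
    cols$score <- dat$score
    roles["score"] <- "score"
    if (spec$interaction) {
      cols$substitution_x_score <-
        interaction_column(diet_terms$substitution, dat$score)
      roles["substitution_x_score"] <- "interaction"
    }
  }
  cols[[base_col]] <- dat[[base_col]]
  cols$height_cm <- dat$height_cm
  for (f in c("sex", "smoking", "pa", "education"))
    cols <- c(cols, indicator_block(as.character(dat[[f]]), f))
  ## menopause: single postmenopausal indicator. Together with sex_male and
  ## the intercept this spans the three cells male / premenopausal /
  ## postmenopausal women; a full male/pre/post indicator block would be
  ## exactly collinear with sex.
  meno <- as.character(dat$menopause)
  bad_meno <- !meno %in% FACTOR_LEVELS$menopause
  if (any(bad_meno))
    stop("invalid level(s) in menopause: ",
         paste(unique(meno[bad_meno]), collapse = ", "))
  cols$menopause_post <- as.numeric(meno == "post")
  if (spec$outcome == "dWC") cols$d_bw <- dat$d_bw
  if (spec$adjust_age) cols$age_y <- dat$age_y
  if (spec$adjust_fu) cols$fu_years <- dat$fu_years

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  ## drop constant columns other than the intercept (degenerate factor levels
  ## or constant covariates); restores full rank in those cases
  const <- apply(X, 2L, function(v) max(v) - min(v) == 0)
  const["(Intercept)"] <- FALSE
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  roles <- roles[intersect(names(roles), colnames(X))]
  structure(list(X = X, y = dat[[y_col]],
                 individual_id = dat$individual_id,
                 n_total = n_total, n_used = nrow(dat),
                 n_dropped = n_total - nrow(dat),
                 spec = spec, term_roles = roles),
            class = "gdsub_design")
}
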