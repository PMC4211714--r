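#' Diet composition handling
#'
#' Diet is represented as the energy shares (E%) of the four macronutrients
#' protein, carbohydrate, fat and alcohol, which partition total energy and
#' must sum to 100, plus total energy intake (MJ/day). All substitution-model
#' design matrices derive from this compositional object.
#'
#' @name diet-composition
NULL

DIET_COLS <- c("protein_e", "carbohydrate_e", "fat_e", "alcohol_e")

#' Validate (and if needed renormalize) diet compositions
#'
#' Rows whose four E% components sum to 100 within `tol` are left untouched;
#' rows outside the tolerance are rescaled to sum exactly 100, with a warning
#' (real record- or FFQ-derived energy shares rarely close exactly).
#'
#' @param diet Data frame containing `protein_e`, `carbohydrate_e`, `fat_e`,
#'   `alcohol_e` (and typically `energy_mj`).
#' @param tol Closure tolerance in E%, default 0.5.
#' @return The data frame with compositions closed to 100.
#' @export
check_diet <- function(diet, tol = 0.5) {
  missing_cols <- setdiff(DIET_COLS, names(diet))
  if (length(missing_cols) > 0L)
    stop("diet table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  comp <- as.matrix(diet[DIET_COLS])
  if (any(comp < 0, na.rm = TRUE))
    stop("macronutrient energy shares must be non-negative")
  tot <- rowSums(comp)
  off <- !is.na(tot) & abs(tot - 100) > tol
  if (any(off)) {
    if (any(tot[off] <= 0))
      stop("diet composition with non-positive total E%")
    warning(sum(off), " diet row(s) off the 100 E% closure by more than ",
            tol, " E%; renormalized")
    comp[off, ] <- comp[off, ] * (100 / tot[off])
    diet[DIET_COLS] <- comp
  }
  diet
}

check_replaced <- function(replaced) {
  if (!is.character(replaced) || length(replaced) != 1L ||
      !replaced %in% c("carbohydrate", "fat"))
    stop("'replaced' must be \"carbohydrate\" or \"fat\" ",
         "(protein and alcohol cannot be the replaced macronutrient)")
  replaced
}

kept_macro <- function(replaced) {
  if (replaced == "fat") "carbohydrate_e" else "fat_e"
}

#' Leave-one-out substitution covariates
#'
#' The classic parameterization: include protein, alcohol and one of
#' carbohydrate/fat, omitting the macronutrient being replaced. With the
#' four E% summing to 100, the protein coefficient is the effect of 1 E%
#' protein replacing 1 E% of the omitted macronutrient.
#'
#' @param diet Data frame with the four `*_e` columns.
#' @param replaced `"carbohydrate"` or `"fat"` (the omitted macronutrient).
#' @return Data frame with columns `protein_e`, `alcohol_e` and the kept
#'   macronutrient.
#' @export
leave_one_out_terms <- function(diet, replaced) {
  check_replaced(replaced)
  diet[, c("protein_e", "alcohol_e", kept_macro(replaced))]
}

#' Substitution-variable covariates
#'
#' Reparameterization of the leave-one-out model: a single substitution
#' variable s = (E% protein - E% replaced)/2 carries the replacement effect
#' (its coefficient equals the leave-one-out protein coefficient), together
#' with the kept macronutrient and alcohol. Because the substitution is a
#' single column, a product with a predisposition score yields a true
#' substitution-by-score interaction specific to the replaced macronutrient.
#'
#' @inheritParams leave_one_out_terms
#' @return Data frame with columns `substitution`, `alcohol_e` and the kept
#'   macronutrient.
#' @export
substitution_terms <- function(diet, replaced) {
  check_replaced(replaced)
  x <- if (replaced == "fat") diet$fat_e else diet$carbohydrate_e
  out <- data.frame(substitution = (diet$protein_e - x) / 2)
  out$alcohol_e <- diet$alcohol_e
  out[[kept_macro(replaced)]] <- diet[[kept_macro(replaced)]]
  out
}

#' Substitution-by-score interaction column
#'
#' @param s Substitution variable values.
#' @param score Predisposition score values.
#' @return Elementwise product `s * score`; any design matrix using it must
#'   also contain both main effects (enforced by [assemble_design()]).
#' @export
interaction_column <- function(s, score) s * score
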