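#' Annualized anthropometric change
#'
#' Change between baseline and follow-up divided by the individual follow-up
#' time in years: d_bw in kg/y, d_wc in cm/y (reporting scales are g/y and
#' mm/y; see [rescale_effect()]). Waist change is missing whenever either
#' waist measurement is absent; body-weight change is still computed.
#'
#' @param bw0_kg,bw1_kg Baseline and follow-up body weight (kg).
#' @param wc0_cm,wc1_cm Baseline and follow-up waist circumference (cm),
#'   may be `NA`.
#' @param fu_years Follow-up time in years, must be positive.
#' @return Data frame with columns `d_bw` and `d_wc`; rows with
#'   non-positive follow-up time are rejected (both changes `NA`) with a
#'   message giving the count.
#' @export
#' @examples
#' annualize(70, 72.5, NA, NA, 5)$d_bw  # 0.5 kg/y
annualize <- function(bw0_kg, bw1_kg, wc0_cm = NA_real_, wc1_cm = NA_real_,
                      fu_years) {
  n <- length(bw0_kg)
  wc0_cm <- rep_len(wc0_cm, n)
  wc1_cm <- rep_len(wc1_cm, n)
  bad_fu <- !is.na(fu_years) & fu_years <= 0
  if (any(bad_fu))
    message(sum(bad_fu), " record(s) rejected: non-positive follow-up time")
  fu <- ifelse(bad_fu, NA_real_, fu_years)
  data.frame(d_bw = (bw1_kg - bw0_kg) / fu,
             d_wc = (wc1_cm - wc0_cm) / fu)
}

#' Add annualized changes to a cohort data frame
#'
#' Computes `d_bw` / `d_wc` from `bw0_kg`, `bw1_kg`, `wc0_cm`, `wc1_cm` and
#' `fu_years` unless already present.
#'
#' @param cohort Cohort data frame.
#' @return The cohort with `d_bw` and `d_wc` columns.
#' @export
annualize_cohort <- function(cohort) {
  if (all(c("d_bw", "d_wc") %in% names(cohort))) return(cohort)
  need <- c("bw0_kg", "bw1_kg", "fu_years")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cannot annualize: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  wc0 <- if ("wc0_cm" %in% names(cohort)) cohort$wc0_cm else NA_real_
  wc1 <- if ("wc1_cm" %in% names(cohort)) cohort$wc1_cm else NA_real_
  ch <- annualize(cohort$bw0_kg, cohort$bw1_kg, wc0, wc1, cohort$fu_years)
  if (!"d_bw" %in% names(cohort)) cohort$d_bw <- ch$d_bw
  if (!"d_wc" %in% names(cohort)) cohort$d_wc <- ch$d_wc
  cohort
}

#' Energy-balance trichotomy from annual weight change
#'
#' Observed weight change proxies cumulative net energy balance: loss of more
#' than 0.5 kg/y is negative, change within +/-0.5 kg/y (boundaries included)
#' neutral, gain of more than 0.5 kg/y positive.
#'
#' @param d_bw Annual weight change, kg/y.
#' @param threshold Half-width of the neutral band, kg/y (default 0.5).
#' @return Factor with levels negative/neutral/positive.
#' @export
classify_energy_balance <- function(d_bw, threshold = 0.5) {
  cls <- ifelse(d_bw < -threshold, "negative",
                ifelse(d_bw > threshold, "positive", "neutral"))
  factor(cls, levels = c("negative", "neutral", "positive"))
}

#' Protein intake in grams per kg body weight per day
#'
#' Converts the protein energy share to an absolute intake using an energy
#' density of 17 kJ per gram protein and the baseline body weight.
#'
#' @param protein_e Protein intake, E%.
#' @param energy_mj Total energy intake, MJ/day.
#' @param bw0_kg Baseline body weight, kg.
#' @param kj_per_g Energy density of protein, kJ/g (default 17).
#' @return Protein intake in g/kg/day.
#' @export
protein_g_per_kg <- function(protein_e, energy_mj, bw0_kg, kj_per_g = 17) {
  (protein_e / 100) * (energy_mj * 1000) / kj_per_g / bw0_kg
}

#' Mean protein intake by energy balance and predisposition-score level
#'
#' Cross-classifies individuals by energy-balance class (negative / neutral /
#' positive) and predisposition score above vs below the cohort mean, and
#' tabulates per cell the mean protein intake on two scales (E% and g/kg/day)
#' with SEM and normal-based 95% confidence intervals.
#'
#' @param cohort Cohort data frame (diet, anthropometry).
#' @param scores Output of [build_score()] for the score used in the split
#'   (typically the BMI score).
#' @param kj_per_g Protein energy density for the g/kg/day scale.
#' @param ties_high Tie rule passed to [split_at_mean()].
#' @return Data frame with one row per (balance x score group) cell: `n`,
#'   mean/SEM/CI for `protein_e` and for `protein_gkg`. Empty cells keep
#'   `n = 0` and missing statistics.
#' @export
protein_by_subgroup <- function(cohort, scores, kj_per_g = 17,
                                ties_high = FALSE) {
  cohort <- annualize_cohort(cohort)
  grp <- split_at_mean(scores, ties_high = ties_high)
  dat <- merge(cohort, grp, by = "individual_id")
  dat$balance <- classify_energy_balance(dat$d_bw)
  dat$protein_gkg <- protein_g_per_kg(dat$protein_e, dat$energy_mj,
                                      dat$bw0_kg, kj_per_g)
  dat <- dat[!is.na(dat$balance) & !is.na(dat$score_group) &
               !is.na(dat$protein_e) & !is.na(dat$protein_gkg), ]

  cells <- expand.grid(balance = levels(dat$balance),
                       score_group = c("low", "high"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stat <- function(x) {
    n <- length(x)
    if (n == 0L) return(c(n = 0, mean = NA, sem = NA, lo = NA, hi = NA))
    m <- mean(x)
    sem <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
    c(n = n, mean = m, sem = sem, lo = m - Z95 * sem, hi = m + Z95 * sem)
  }
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- dat$balance == cells$balance[i] &
      dat$score_group == cells$score_group[i]
    e <- stat(dat$protein_e[sel])
    g <- stat(dat$protein_gkg[sel])
    data.frame(balance = cells$balance[i],
               score_group = cells$score_group[i],
               n = e[["n"]],
               protein_e_mean = e[["mean"]], protein_e_sem = e[["sem"]],
               protein_e_lo = e[["lo"]], protein_e_hi = e[["hi"]],
               protein_gkg_mean = g[["mean"]], protein_gkg_sem = g[["sem"]],
               protein_gkg_lo = g[["lo"]], protein_gkg_hi = g[["hi"]])
  })
  do.call(rbind, out)
}

#' Select the greatest weight gainers net of baseline covariates
#'
#' Emulates a case-cohort gainer selection: within each sex, annual weight
#' change is regressed on baseline age, body weight, height, smoking status
#' and follow-up time, and the `k_per_sex` individuals with the largest
#' positive residuals are selected. Ties are broken by `individual_id` for
#' determinism.
#'
#' @param cohort Cohort data frame with `d_bw` (or the anthropometry to
#'   derive it), `sex`, `age_y`, `bw0_kg`, `height_cm`, `smoking`,
#'   `fu_years`.
#' @param k_per_sex Number selected within each sex; if it exceeds a sex
#'   group's size the whole group is returned with a warning.
#' @return Character vector of selected `individual_id`s.
#' @export
select_weight_gainers <- function(cohort, k_per_sex) {
  cohort <- annualize_cohort(cohort)
  need <- c("individual_id", "d_bw", "sex", "age_y", "bw0_kg", "height_cm",
            "smoking", "fu_years")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L)
    stop("gainer selection needs column(s): ",
         paste(missing_cols, collapse = ", "))
  dat <- cohort[stats::complete.cases(cohort[need]), need]
  selected <- character(0)
  for (s in unique(dat$sex)) {
    d <- dat[dat$sex == s, ]
    d$smoking <- factor(as.character(d$smoking))
    rhs <- c("age_y", "bw0_kg", "height_cm", "fu_years")
    if (nlevels(d$smoking) > 1L) rhs <- c(rhs, "smoking")
    fml <- stats::reformulate(rhs, response = "d_bw")
    res <- stats::residuals(stats::lm(fml, data = d))
    k <- k_per_sex
    if (k > nrow(d)) {
      warning("k_per_sex (", k_per_sex, ") exceeds group size for sex ", s,
              " (", nrow(d), "); returning whole group")
      k <- nrow(d)
    }
    ord <- order(-res, d$individual_id)
    selected <- c(selected, d$individual_id[ord[seq_len(k)]])
  }
  selected
}
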