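#' SNP panel definitions
#'
#' A panel annotates each SNP with its risk allele, the adiposity trait(s) it
#' is associated with (`BMI`, `WC`, `WHR_BMI`; a SNP associated with more than
#' one trait carries `"+"`-separated tags, e.g. `"BMI+WC"`), and a risk-allele
#' frequency used only by the synthetic-data generator. Predisposition-score
#' membership is resolved from these tags at run time, never hard-coded.
#'
#' @name snp-panel
NULL

SCORE_TYPES <- c("complete", "BMI", "WC", "WHR_BMI")
TRAIT_TAGS <- c("BMI", "WC", "WHR_BMI")

#' Read a SNP panel definition table
#'
#' @param path Path to a tab-separated file with columns `snp_id`,
#'   `risk_allele`, `trait` and `risk_allele_freq` (extra columns are kept).
#' @return A `data.frame` with one row per SNP, validated.
#' @export
read_snp_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_snp_panel(panel)
}

#' @rdname read_snp_panel
#' @param panel A data.frame to validate as a SNP panel.
#' @export
validate_snp_panel <- function(panel) {
  required <- c("snp_id", "risk_allele", "trait", "risk_allele_freq")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0L)
    stop("SNP panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(panel$snp_id))
    stop("SNP panel contains duplicated snp_id values")
  if (!all(panel$risk_allele %in% c("A", "C", "G", "T")))
    stop("risk_allele must be a single base A/C/G/T")
  tags <- strsplit(panel$trait, "+", fixed = TRUE)
  bad <- !vapply(tags, function(t) length(t) >= 1L && all(t %in% TRAIT_TAGS),
                 logical(1))
  if (any(bad))
    stop("invalid trait tag(s) for: ",
         paste(panel$snp_id[bad], collapse = ", "),
         " (allowed: ", paste(TRAIT_TAGS, collapse = ", "), ")")
  f <- panel$risk_allele_freq
  if (any(!is.na(f) & (f <= 0 | f >= 1)))
    stop("risk_allele_freq must lie strictly in (0, 1)")
  panel
}

#' Bundled synthetic 50-SNP adiposity panel
#'
#' A synthetic stand-in panel of 50 adiposity-associated SNPs (33 tagged BMI,
#' 6 tagged WC, 14 tagged WHR_BMI; three SNPs carry both BMI and WC tags).
#' Frequencies are plausible GWAS risk-allele frequencies chosen so that
#' simulated score distributions resemble population cohorts.
#'
#' @return A validated SNP panel `data.frame` (50 rows).
#' @export
default_snp_panel <- function() {
  read_snp_panel(system.file("extdata", "snp_panel_synthetic.tsv",
                             package = "gdsub", mustWork = TRUE))
}

#' Select the SNP subset that enters a predisposition score
#'
#' @param panel A SNP panel data.frame.
#' @param score_type One of `"complete"`, `"BMI"`, `"WC"`, `"WHR_BMI"`.
#' @return The panel rows whose trait tags match `score_type` (all rows for
#'   `"complete"`).
#' @export
panel_subset <- function(panel, score_type) {
  if (!is.character(score_type) || length(score_type) != 1L ||
      !score_type %in% SCORE_TYPES)
    stop("unknown score_type: must be one of ",
         paste(SCORE_TYPES, collapse = ", "))
  if (score_type == "complete") {
    out <- panel
  } else {
    tags <- strsplit(panel$trait, "+", fixed = TRUE)
    out <- panel[vapply(tags, function(t) score_type %in% t, logical(1)), ,
                 drop = FALSE]
  }
  if (nrow(out) == 0L)
    stop("empty SNP subset for score_type ", score_type)
  out
}

#' Read a genotype dosage table
#'
#' One row per individual; an `individual_id` column plus one column per SNP
#' holding risk-allele dosages 0, 1, 2 or NA.
#'
#' @param path Path to a tab-separated dosage file.
#' @param panel Optional panel; when given, dosage columns must be a subset of
#'   its `snp_id`s.
#' @return A `data.frame` of dosages.
#' @export
read_genotypes <- function(path, panel = NULL) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"individual_id" %in% names(g))
    stop("genotype table must have an individual_id column")
  snp_cols <- setdiff(names(g), "individual_id")
  if (!is.null(panel)) {
    unknown <- setdiff(snp_cols, panel$snp_id)
    if (length(unknown) > 0L)
      stop("genotype columns not in panel: ", paste(unknown, collapse = ", "))
  }
  vals <- as.matrix(g[snp_cols])
  if (!all(is.na(vals) | vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  g
}
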