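#' Build genetic predisposition scores
#'
#' Sums risk-allele dosages over the SNP subset tagged with `score_type`.
#' Scores are complete-case: an individual missing any dosage in the subset
#' receives a missing score (this reproduces the per-score sample-size pattern
#' seen when different SNP subsets have different genotyping success).
#'
#' @param genotypes Data frame with `individual_id` and one dosage column
#'   (0/1/2/NA) per SNP.
#' @param panel SNP panel data.frame (see [read_snp_panel()]).
#' @param score_type `"complete"`, `"BMI"`, `"WC"` or `"WHR_BMI"`.
#' @return Data frame with columns `individual_id`, `score` (integer or NA),
#'   `score_type` and `n_snps` (subset size).
#' @export
#' @examples
#' panel <- default_snp_panel()
#' g <- data.frame(individual_id = "i1")
#' g[panel$snp_id] <- 1L
#' build_score(g, panel, "complete")$score  # 50
build_score <- function(genotypes, panel, score_type = "complete") {
  sub <- panel_subset(panel, score_type)
  missing_snps <- setdiff(sub$snp_id, names(genotypes))
  if (length(missing_snps) > 0L)
    stop("genotype table lacks dosage column(s): ",
         paste(missing_snps, collapse = ", "))
  dos <- as.matrix(genotypes[sub$snp_id])
  storage.mode(dos) <- "double"
  score <- rowSums(dos)             # NA whenever any subset dosage is NA
  out <- data.frame(
    individual_id = genotypes$individual_id,
    score = score,
    score_type = score_type,
    n_snps = nrow(sub),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Split predisposition scores at the within-cohort mean
#'
#' Individuals with a score strictly above the mean of the non-missing scores
#' are labelled `"high"`, all others (including exact ties with the mean)
#' `"low"`. The tie rule is configurable.
#'
#' @param scores Output of [build_score()] (columns `individual_id`, `score`).
#' @param ties_high If `TRUE`, scores exactly equal to the mean go to the
#'   high group. Default `FALSE`.
#' @return Data frame with `individual_id` and `score_group` (factor
#'   low/high; NA for missing scores).
#' @export
split_at_mean <- function(scores, ties_high = FALSE) {
  ok <- !is.na(scores$score)
  if (!any(ok)) {
    warning("all scores missing; returning empty split")
    return(data.frame(individual_id = character(0),
                      score_group = factor(character(0),
                                           levels = c("low", "high"))))
  }
  m <- mean(scores$score[ok])
  high <- if (ties_high) scores$score >= m else scores$score > m
  data.frame(
    individual_id = scores$individual_id,
    score_group = factor(ifelse(high, "high", "low"),
                         levels = c("low", "high")),
    stringsAsFactors = FALSE
  )
}
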