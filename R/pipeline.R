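#' Read / write cohort tables
#'
#' Tab-separated, one row per individual, the schema produced by
#' [simulate_cohort()] and consumed by [fit_substitution()]; round-trips
#' exactly at the stored precision.
#'
#' @param path File path.
#' @param cohort Cohort data frame.
#' @return `read_cohort()` the data frame; `write_cohort()` the path,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c(individual_id = "character",
                                   pa = "character"))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

meta_row <- function(m, extra) {
  cbind(extra,
        data.frame(beta = m$beta_pooled, se = m$se_pooled,
                   lo = m$ci95[["lo"]], hi = m$ci95[["hi"]],
                   tau2 = m$tau2, Q = m$Q, p_Q = m$p_Q,
                   i2_pct = m$i2_pct, band = as.character(m$band),
                   weights_pct = paste(sprintf("%.2f", m$weights_pct),
                                       collapse = "/"),
                   labels = paste(m$labels, collapse = "/")))
}

#' Run the full gene-diet interaction analysis
#'
#' Orchestrates, for every cohort and every outcome-by-substitution
#' combination: the protein main-effect substitution model, the four
#' score-plus-interaction models, random-effects meta-analyses of each term
#' across cohorts (on the reporting scale), optional per-SNP interaction
#' scans, and the energy-balance-by-score protein-intake table. Cohorts
#' lacking an outcome entirely (e.g. no baseline waist) are skipped for that
#' outcome with a message, mirroring how such cohorts are excluded from
#' waist analyses. Per-stage complete-case attrition is logged on each
#' result row (`n_total`, `n_used`).
#'
#' @param cohorts Named list of cohort data frames (or file paths).
#' @param panel SNP panel (default bundled).
#' @param outcomes,replaced Combinations to run.
#' @param score_types Predisposition scores for interaction models.
#' @param run_scans Run the per-SNP scans (the slowest stage).
#' @param adjust_age,adjust_fu Extra adjustments.
#' @param out_dir Optional output directory; when given, writes `fits.tsv`,
#'   `meta.tsv`, `scan.tsv`, `subgroups.tsv` and `manifest.json` (config
#'   hash, seed, package version).
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List with elements `fits`, `meta`, `scan`, `subgroups`
#'   (data frames), class `gdsub_run`, invisibly when `out_dir` is set.
#' @export
run_full_analysis <- function(cohorts, panel = NULL,
                              outcomes = c("dBW", "dWC"),
                              replaced = c("carbohydrate", "fat"),
                              score_types = SCORE_TYPES,
                              run_scans = TRUE,
                              adjust_age = FALSE, adjust_fu = FALSE,
                              out_dir = NULL, seed = NULL) {
  if (is.null(panel)) panel <- default_snp_panel()
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    stop("cohorts must be a named list")
  cohorts <- lapply(cohorts, function(x) {
    if (is.character(x)) read_cohort(x) else x
  })
  cohorts <- lapply(cohorts, annualize_cohort)

  fit_rows <- list(); meta_rows <- list(); scan_rows <- list()

  one_fit <- function(cohort_name, cohort, outcome, repl, score_type) {
    fit <- tryCatch(
      fit_substitution(cohort, outcome = outcome, replaced = repl,
                       score_type = score_type, panel = panel,
                       adjust_age = adjust_age, adjust_fu = adjust_fu),
      error = function(e) {
        message("skipping ", cohort_name, " / ", outcome, " / ", repl,
                if (!is.null(score_type)) paste0(" / ", score_type),
                ": ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) return(NULL)
    rep_cf <- rescale_effect(fit)
    keep <- if (is.null(score_type)) "substitution"
            else c("substitution", "score", "substitution_x_score")
    rep_cf <- rep_cf[rep_cf$term %in% keep, , drop = FALSE]
    cbind(data.frame(cohort = cohort_name, outcome = outcome,
                     replaced = repl,
                     score_type = if (is.null(score_type)) "" else score_type,
                     n_total = fit$n_total, n_used = fit$n),
          rep_cf)
  }

  for (outcome in outcomes) {
    for (repl in replaced) {
      for (st in c(list(NULL), as.list(score_types))) {
        per_cohort <- list()
        for (cn in names(cohorts))
          per_cohort[[cn]] <- one_fit(cn, cohorts[[cn]], outcome, repl, st)
        per_cohort <- per_cohort[!vapply(per_cohort, is.null, logical(1))]
        if (length(per_cohort) == 0L) next
        fit_rows[[length(fit_rows) + 1L]] <- do.call(rbind, per_cohort)
        tab <- do.call(rbind, per_cohort)
        for (tm in unique(tab$term)) {
          sub <- tab[tab$term == tm, ]
          if (nrow(sub) < 1L) next
          m <- meta_pool(sub$beta, se = sub$se, labels = sub$cohort,
                         method = "random")
          meta_rows[[length(meta_rows) + 1L]] <- meta_row(
            m, data.frame(outcome = outcome, replaced = repl,
                          score_type = if (is.null(st)) "" else st,
                          term = tm))
        }
      }
      if (run_scans) {
        for (cn in names(cohorts)) {
          if (outcome == "dWC" && all(is.na(cohorts[[cn]]$d_wc))) {
            message("scan skipped for ", cn, ": no waist measurements")
            next
          }
          sc <- tryCatch(
            scan_snps(cohorts[[cn]], panel, outcome = outcome,
                      replaced = repl, adjust_age = adjust_age,
                      adjust_fu = adjust_fu),
            error = function(e) {
              message("scan skipped for ", cn, " / ", outcome, " / ", repl,
                      ": ", conditionMessage(e))
              NULL
            })
          if (!is.null(sc) && nrow(sc) > 0L)
            scan_rows[[length(scan_rows) + 1L]] <-
              cbind(data.frame(cohort = cn, outcome = outcome,
                               replaced = repl), sc)
        }
      }
    }
  }

  subgroup_rows <- list()
  for (cn in names(cohorts)) {
    sc <- build_score(cohorts[[cn]], panel, "BMI")
    sg <- protein_by_subgroup(cohorts[[cn]], sc)
    subgroup_rows[[cn]] <- cbind(data.frame(cohort = cn), sg)
  }

  bundle <- structure(list(
    fits = do.call(rbind, fit_rows),
    meta = do.call(rbind, meta_rows),
    scan = if (length(scan_rows)) do.call(rbind, scan_rows) else NULL,
    subgroups = do.call(rbind, subgroup_rows)
  ), class = "gdsub_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(bundle$fits, file.path(out_dir, "fits.tsv"))
    write_tsv(bundle$meta, file.path(out_dir, "meta.tsv"))
    if (!is.null(bundle$scan))
      write_tsv(bundle$scan, file.path(out_dir, "scan.tsv"))
    write_tsv(bundle$subgroups, file.path(out_dir, "subgroups.tsv"))
    cfg <- list(cohorts = names(cohorts), outcomes = outcomes,
                replaced = replaced, score_types = score_types,
                adjust_age = adjust_age, adjust_fu = adjust_fu,
                n_panel_snps = nrow(panel))
    cfg_file <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, pretty = TRUE)
    manifest <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                     seed = seed,
                     package_version =
                       as.character(utils::packageVersion("gdsub")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}

#' @export
print.gdsub_run <- function(x, ...) {
  cat("gdsub analysis bundle:\n")
  cat("  fit rows:      ", nrow(x$fits), "\n")
  cat("  meta rows:     ", nrow(x$meta), "\n")
  cat("  scan rows:     ", if (is.null(x$scan)) 0L else nrow(x$scan), "\n")
  cat("  subgroup rows: ", nrow(x$subgroups), "\n")
  invisible(x)
}
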