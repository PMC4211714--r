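#' Standard error from a confidence interval
#'
#' @param lo,hi Interval endpoints (`hi > lo`).
#' @param level Coverage of the interval (default 0.95, i.e. quantile
#'   1.959964).
#' @return `(hi - lo) / (2 * qnorm((1 + level) / 2))`.
#' @export
#' @examples
#' se_from_ci(30.4, 216.4)  # 47.45
se_from_ci <- function(lo, hi, level = 0.95) {
  if (any(hi <= lo)) stop("need hi > lo to derive a standard error")
  (hi - lo) / (2 * stats::qnorm((1 + level) / 2))
}

#' Heterogeneity band from I-squared
#'
#' Bins: \code{[0, 25)} no, \code{[25, 50)} moderate, \code{[50, 75)}
#' significant, \code{[75, 100]} extreme heterogeneity. Boundary values are
#' assigned to the higher band.
#'
#' @param i2_pct I-squared in percent, within \code{[0, 100]}.
#' @return Factor level among no/moderate/significant/extreme.
#' @export
heterogeneity_band <- function(i2_pct) {
  if (any(is.na(i2_pct)) || any(i2_pct < 0 | i2_pct > 100))
    stop("I-squared must lie in [0, 100]")
  bands <- c("no", "moderate", "significant", "extreme")
  idx <- findInterval(i2_pct, c(0, 25, 50, 75), rightmost.closed = FALSE)
  factor(bands[idx], levels = bands)
}

#' Inverse-variance meta-analysis of cohort estimates
#'
#' Pools study-level estimates by inverse variance: fixed-effect weights
#' `1/se^2`, or DerSimonian-Laird random effects where the moment estimator
#' `tau^2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`
#' (fixed-effect weights, not iterated) is added to each sampling variance.
#' Reports the pooled estimate with a normal-based 95% CI, percentage
#' weights, Cochran's Q with its p-value, tau-squared, I-squared and the
#' heterogeneity band of [heterogeneity_band()]. With a single study the
#' input is passed through (Q = 0, tau^2 = 0).
#'
#' @param beta Study estimates.
#' @param se Study standard errors; alternatively give `lo`/`hi` and SEs are
#'   derived via [se_from_ci()].
#' @param lo,hi Optional 95% CI endpoints used when `se` is missing.
#' @param labels Study labels.
#' @param method `"random"` (DerSimonian-Laird) or `"fixed"`.
#' @return Object of class `gdsub_meta`.
#' @export
#' @examples
#' m <- meta_pool(beta = c(123.4, -11.6, 19.0),
#'                lo = c(30.4, -102.6, -47.6), hi = c(216.4, 79.5, 85.6),
#'                labels = c("MONICA", "DCH", "INTER99"))
#' round(m$beta_pooled, 1)  # 41.0
meta_pool <- function(beta, se = NULL, lo = NULL, hi = NULL, labels = NULL,
                      method = c("random", "fixed")) {
  method <- match.arg(method)
  k <- length(beta)
  if (k < 1L) stop("need at least one study")
  if (is.null(se)) {
    if (is.null(lo) || is.null(hi))
      stop("supply either se or both lo and hi")
    se <- se_from_ci(lo, hi)
  }
  if (length(se) != k) stop("beta and se lengths differ")
  if (any(is.na(beta)) || any(is.na(se)) || any(se <= 0))
    stop("study estimates must be non-missing with positive SEs")
  if (is.null(labels)) labels <- paste0("study", seq_len(k))

  w <- 1 / se^2
  beta_fixed <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - beta_fixed)^2)
  df <- k - 1L
  p_Q <- if (df > 0L) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (df > 0L && C > 0) max(0, (Q - df) / C) else 0
  i2 <- if (Q > 0 && df > 0L) max(0, (Q - df) / Q) * 100 else 0

  w_used <- if (method == "random") 1 / (se^2 + tau2) else w
  beta_pooled <- sum(w_used * beta) / sum(w_used)
  se_pooled <- 1 / sqrt(sum(w_used))

  structure(list(model = method, k = k, labels = labels,
                 beta = beta, se = se,
                 beta_pooled = beta_pooled, se_pooled = se_pooled,
                 ci95 = c(lo = beta_pooled - Z95 * se_pooled,
                          hi = beta_pooled + Z95 * se_pooled),
                 weights_pct = 100 * w_used / sum(w_used),
                 Q = Q, df = df, p_Q = p_Q, tau2 = tau2, i2_pct = i2,
                 band = heterogeneity_band(i2)),
            class = "gdsub_meta")
}

#' Pool a table of cohort-level estimates
#'
#' Consumes a data frame with columns `label`, `beta` and either `se` or
#' `lo`/`hi` (95% CI endpoints), e.g. read from a results TSV or transcribed
#' from a published table.
#'
#' @param estimates The estimates data frame.
#' @param method Passed to [meta_pool()].
#' @return A `gdsub_meta` object.
#' @export
meta_from_estimates <- function(estimates, method = "random") {
  if (!"beta" %in% names(estimates)) stop("estimates need a beta column")
  labels <- if ("label" %in% names(estimates)) estimates$label else NULL
  if ("se" %in% names(estimates) && !all(is.na(estimates$se)))
    meta_pool(estimates$beta, se = estimates$se, labels = labels,
              method = method)
  else
    meta_pool(estimates$beta, lo = estimates$lo, hi = estimates$hi,
              labels = labels, method = method)
}

#' @export
print.gdsub_meta <- function(x, digits = 4, ...) {
  cat(if (x$model == "random") "Random-effects (DerSimonian-Laird)"
      else "Fixed-effect",
      "meta-analysis of", x$k, "studies\n")
  cat("  pooled: ", signif(x$beta_pooled, digits), " (95% CI ",
      signif(x$ci95[["lo"]], digits), "; ", signif(x$ci95[["hi"]], digits),
      ")\n", sep = "")
  cat("  tau^2 = ", signif(x$tau2, digits), ", Q = ", signif(x$Q, digits),
      " (df ", x$df, ", p = ", signif(x$p_Q, 3), "), I^2 = ",
      round(x$i2_pct, 1), "% (", as.character(x$band),
      " heterogeneity)\n", sep = "")
  invisible(x)
}

#' @export
summary.gdsub_meta <- function(object, ...) {
  print(object, ...)
  cat("\n")
  cat(forest_text(object), sep = "\n")
  invisible(object)
}

#' Plain-text forest table of a meta-analysis
#'
#' @param x A `gdsub_meta` object.
#' @param digits Significant digits.
#' @return Character vector of table lines (one per study plus the pooled
#'   row).
#' @export
forest_text <- function(x, digits = 4) {
  stopifnot(inherits(x, "gdsub_meta"))
  rows <- sprintf("%-10s %10s (%s; %s)  %6.2f%%",
                  x$labels,
                  signif(x$beta, digits),
                  signif(x$beta - Z95 * x$se, digits),
                  signif(x$beta + Z95 * x$se, digits),
                  x$weights_pct)
  pooled <- sprintf("%-10s %10s (%s; %s)  100.00%%",
                    "Overall",
                    signif(x$beta_pooled, digits),
                    signif(x$ci95[["lo"]], digits),
                    signif(x$ci95[["hi"]], digits))
  c(rows, pooled)
}
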