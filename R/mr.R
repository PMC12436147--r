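mr_result_row <- function(exposure_id = NA_character_, outcome_id = NA_character_,
                          method, nsnp, b, se, p,
                          Q = NA_real_, Q_df = NA_integer_, Q_p = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_p = NA_real_) {
  data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
             method = method, nsnp = as.integer(nsnp), b = b, se = se, p = p,
             Q = Q, Q_df = Q_df, Q_p = Q_p,
             egger_intercept = egger_intercept,
             egger_intercept_se = egger_intercept_se,
             egger_intercept_p = egger_intercept_p,
             stringsAsFactors = FALSE)
}

#' Wald ratio causal estimate for a single instrument
#'
#' The causal effect of exposure on outcome instrumented by one variant is
#' `by / bx`. Its standard error uses the two-term Taylor (delta-method)
#' expansion `sqrt(sy^2/bx^2 + by^2 * sx^2 / bx^4)`, which accounts for
#' sampling error in both the numerator and the denominator. The p-value is
#' two-sided normal.
#'
#' @param bx,sx Variant-exposure effect and standard error (`bx != 0`,
#'   `sx > 0`).
#' @param by,sy Variant-outcome effect and standard error (`sy > 0`).
#' @param exposure_id,outcome_id Optional identifiers carried into the result.
#' @return One-row `data.frame` with columns `exposure_id, outcome_id, method,
#'   nsnp, b, se, p` (diagnostic columns `NA`).
#' @export
wald_ratio <- function(bx, sx, by, sy,
                       exposure_id = NA_character_, outcome_id = NA_character_) {
  stopifnot(length(bx) == 1L, sx > 0, sy > 0)
  if (bx == 0) stop("Wald ratio undefined for a null exposure effect (bx = 0)")
  b <- by / bx
  se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  p <- 2 * stats::pnorm(-abs(b / se))
  mr_result_row(exposure_id, outcome_id, "wald", 1L, b, se, p)
}

#' Inverse-variance-weighted causal estimate
#'
#' Zero-intercept weighted regression of outcome effects on exposure effects
#' with weights `1/sy^2`: `b = sum(w by bx) / sum(w bx^2)`. Heterogeneity is
#' summarised by Cochran's Q with `k - 1` degrees of freedom, and the
#' fixed-effect standard error `1/sqrt(sum(w bx^2))` is inflated by
#' `max(1, sqrt(Q/(k-1)))` (multiplicative random-effects model), so that
#' over-dispersed instrument sets yield wider intervals while homogeneous
#' ones reduce to the fixed-effect analysis. P-values are two-sided normal.
#'
#' @param bx,sx,by,sy Vectors of harmonised per-variant effects and standard
#'   errors (`k >= 2`).
#' @param random_effects Apply the multiplicative SE inflation (default
#'   `TRUE`); `FALSE` gives the fixed-effect IVW.
#' @param exposure_id,outcome_id Optional identifiers.
#' @return One-row `data.frame` as in [wald_ratio()], with `Q`, `Q_df`, `Q_p`
#'   filled.
#' @export
ivw <- function(bx, sx, by, sy, random_effects = TRUE,
                exposure_id = NA_character_, outcome_id = NA_character_) {
  k <- length(bx)
  stopifnot(k >= 2L, length(by) == k, length(sy) == k, all(sy > 0))
  w <- 1 / sy^2
  b <- sum(w * by * bx) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - b * bx)^2)
  q_df <- k - 1L
  q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  se <- if (random_effects) se_fixed * max(1, sqrt(q / q_df)) else se_fixed
  p <- 2 * stats::pnorm(-abs(b / se))
  mr_result_row(exposure_id, outcome_id, "ivw", k, b, se, p,
                Q = q, Q_df = q_df, Q_p = q_p)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, weights `1/sy^2`. Pairs are first oriented so all
#' exposure effects are non-negative (negating both members where needed),
#' which makes the intercept interpretable as the average directional
#' pleiotropic effect. Slope and intercept inference uses the t distribution
#' with `k - 2` degrees of freedom.
#'
#' @param bx,sx,by,sy Vectors of harmonised per-variant effects and standard
#'   errors (`k >= 3`).
#' @param exposure_id,outcome_id Optional identifiers.
#' @return One-row `data.frame` as in [wald_ratio()], with the intercept
#'   columns filled; `b` is the Egger slope.
#' @export
egger <- function(bx, sx, by, sy,
                  exposure_id = NA_character_, outcome_id = NA_character_) {
  k <- length(bx)
  if (k < 3L) stop("MR-Egger requires at least 3 instruments")
  stopifnot(length(by) == k, length(sy) == k, all(sy > 0))
  flip <- bx < 0
  bx <- ifelse(flip, -bx, bx)
  by <- ifelse(flip, -by, by)
  fit <- stats::lm(by ~ bx, weights = 1 / sy^2)
  sm <- summary(fit)$coefficients
  b <- sm["bx", "Estimate"]
  se <- sm["bx", "Std. Error"]
  a <- sm["(Intercept)", "Estimate"]
  a_se <- sm["(Intercept)", "Std. Error"]
  p <- 2 * stats::pt(-abs(b / se), df = k - 2)
  a_p <- 2 * stats::pt(-abs(a / a_se), df = k - 2)
  mr_result_row(exposure_id, outcome_id, "egger", k, b, se, p,
                egger_intercept = a, egger_intercept_se = a_se,
                egger_intercept_p = a_p)
}

#' Multiple-testing control: BH step-up and Bonferroni
#'
#' Benjamini-Hochberg q-values control the false discovery rate across the
#' supplied tests; the Bonferroni gate uses the exact ratio
#' `alpha / n_tests_bonferroni` (rounding of the threshold is
#' presentation-only). `n_tests_bonferroni` may exceed `length(pvals)` when
#' the analysis is one slice of a larger family of tests.
#'
#' @param pvals P-values in `(0, 1]`.
#' @param alpha Family-wise error rate for the Bonferroni gate (default 0.05).
#' @param n_tests_bonferroni Bonferroni denominator; defaults to
#'   `length(pvals)`.
#' @param fdr_level FDR level for `fdr_pass` (default 0.05).
#' @return List with `pvals`, `q_values`, `fdr_pass`, `bonferroni_threshold`,
#'   `bonferroni_pass`.
#' @export
adjust_pvalues <- function(pvals, alpha = 0.05,
                           n_tests_bonferroni = length(pvals),
                           fdr_level = 0.05) {
  if (length(pvals) == 0L) {
    return(list(pvals = numeric(0), q_values = numeric(0),
                fdr_pass = logical(0),
                bonferroni_threshold = if (n_tests_bonferroni > 0)
                  alpha / n_tests_bonferroni else NA_real_,
                bonferroni_pass = logical(0)))
  }
  stopifnot(all(pvals > 0 & pvals <= 1), n_tests_bonferroni >= length(pvals))
  q <- stats::p.adjust(pvals, method = "BH")
  thr <- alpha / n_tests_bonferroni
  list(pvals = pvals, q_values = q, fdr_pass = q <= fdr_level,
       bonferroni_threshold = thr, bonferroni_pass = pvals <= thr)
}
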