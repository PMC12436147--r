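#' Variance in a trait explained by one variant
#'
#' Two estimators of the per-variant r-squared. `eaf_beta` assumes a
#' unit-variance quantitative phenotype and uses the allele frequency:
#' `r^2 = 2 f (1 - f) beta^2`. `p_n` recovers r-squared from the association
#' p-value and sample size via the z statistic: `r^2 = z^2 / (z^2 + n - 2)`;
#' it needs no frequency and applies to any trait, including case-control
#' traits on the observed scale. When `eaf_beta` is requested but the
#' frequency is missing, the function falls back to `p_n` with a warning.
#'
#' @param beta,eaf,pval,n Per-variant summary fields (vectorised; `eaf` may
#'   be `NA`).
#' @param method `"eaf_beta"` or `"p_n"`.
#' @return Numeric vector of r-squared values, clamped to `[0, 1]`.
#' @export
variance_explained <- function(beta, eaf, pval, n,
                               method = c("eaf_beta", "p_n")) {
  method <- match.arg(method)
  r2_pn <- function(pval, n) {
    z <- stats::qnorm(pmin(pval, 1) / 2, lower.tail = FALSE)
    # p-values at the double-precision floor: fall back to a very large z
    z[!is.finite(z)] <- 40
    z[pval >= 1] <- 0
    z^2 / (z^2 + n - 2)
  }
  if (method == "p_n") {
    stopifnot(all(n >= 3))
    r2 <- r2_pn(pval, n)
  } else {
    r2 <- 2 * eaf * (1 - eaf) * beta^2
    if (anyNA(r2)) {
      warning("eaf missing for some variants; using the p/n method for those")
      miss <- is.na(r2)
      r2[miss] <- r2_pn(pval[miss], n[miss])
    }
  }
  pmin(pmax(r2, 0), 1)
}

# r2 summed over an instrument table for one trait, with trait-appropriate
# method: eaf_beta for quantitative traits with frequencies, p_n otherwise.
trait_r2 <- function(variants, trait) {
  method <- if (trait$trait_type == "quantitative") "eaf_beta" else "p_n"
  r2 <- variance_explained(variants$beta, variants$eaf, variants$p,
                           variants$n, method = method)
  total <- sum(r2)
  if (total > 1) {
    warning("summed variance explained exceeds 1; capped")
    total <- 1
  }
  total
}

#' Steiger directionality test for an instrument set
#'
#' Sums the variance explained by the instruments in the exposure and in the
#' outcome. If the instruments explain more variance in the outcome than in
#' the exposure, the primary phenotype influenced by the variants is likely
#' the outcome — evidence of reverse causation — and the pair fails the
#' direction gate. The p-value compares the two (dependent) correlations via
#' Fisher's z transform using the smaller of the two sample sizes.
#'
#' @param exposure_variants,outcome_variants Harmonised per-variant records
#'   for the same instruments (identical order) in each trait, as
#'   `data.frame`s with columns `beta, eaf, p, n`.
#' @param exposure_trait,outcome_trait [trait_meta()] objects; quantitative
#'   traits with frequencies use the `eaf_beta` method, case-control traits
#'   the `p_n` method.
#' @return List of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `correct_direction` (`r2_exposure > r2_outcome`), `steiger_pval`.
#' @export
steiger_direction <- function(exposure_variants, outcome_variants,
                              exposure_trait, outcome_trait) {
  stopifnot(nrow(exposure_variants) >= 1L,
            nrow(exposure_variants) == nrow(outcome_variants))
  r2_exp <- trait_r2(exposure_variants, exposure_trait)
  r2_out <- trait_r2(outcome_variants, outcome_trait)
  n <- min(min(exposure_variants$n), min(outcome_variants$n))
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) / sqrt(2 / max(n - 3, 1))
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(r2_exposure = r2_exp, r2_outcome = r2_out,
         correct_direction = r2_exp > r2_out, steiger_pval = p),
    class = "steiger_result"
  )
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf(
    "<steiger_result> r2_exp=%.4g r2_out=%.4g direction=%s p=%.3g\n",
    x$r2_exposure, x$r2_outcome, x$correct_direction, x$steiger_pval))
  invisible(x)
}
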