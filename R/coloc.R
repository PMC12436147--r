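#' Log approximate Bayes factor for a single association
#'
#' Wakefield's approximate Bayes factor compares the model in which a variant
#' has a normally distributed effect with prior variance `w` against the null,
#' using only the z statistic and its sampling variance `v`:
#' `log ABF = 0.5 * (log(v/(v+w)) + z^2 * w/(v+w))`.
#'
#' @param z Association z statistic (vectorised).
#' @param v Sampling variance of the effect estimate, `se^2` (`> 0`).
#' @param w Prior variance of the true effect (`> 0`).
#' @return Log Bayes factor(s) in favour of association.
#' @export
log_abf <- function(z, v, w) {
  stopifnot(all(v > 0), all(w > 0))
  0.5 * (log(v / (v + w)) + z^2 * w / (v + w))
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Default colocalisation priors
#'
#' Per-variant prior probabilities: `p1`/`p2` for association with a single
#' trait, `p12` for association with both.
#'
#' @return Named list `p1 = 1e-4, p2 = 1e-4, p12 = 1e-5`.
#' @export
coloc_priors <- function() list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)

# Prior effect s.d. for the Wakefield ABF by trait type (log-odds scale for
# case-control traits).
prior_effect_sd <- function(trait) {
  if (trait$trait_type == "case_control") 0.2 else 0.15
}

#' Colocalisation posteriors under a single-causal-variant model
#'
#' Enumerates the single-causal-variant configurations for two traits over
#' the shared variants of a region and returns posterior probabilities of the
#' five hypotheses: H0 no association, H1/H2 association with one trait only,
#' H3 two distinct causal variants, H4 one shared causal variant. Per-variant
#' evidence is the Wakefield [log_abf()]; configuration sums use log-sum-exp.
#'
#' @param d1,d2 [region_dataset()]s for the two traits over the same region;
#'   variants are intersected on id (an error if no overlap). Datasets must
#'   already be allele-harmonised.
#' @param priors List with `p1`, `p2`, `p12` (see [coloc_priors()]).
#' @param sd1,sd2 Prior effect standard deviations; default 0.15 for
#'   quantitative and 0.2 for case-control traits.
#' @param keep_per_snp Attach the per-variant log-ABF table (default `FALSE`).
#' @return List of class `coloc_result`: `pp_h0` .. `pp_h4` (summing to 1),
#'   `n_snps`, `priors`, and optionally `per_snp_log_abf`.
#' @export
coloc_posteriors <- function(d1, d2, priors = coloc_priors(),
                             sd1 = NULL, sd2 = NULL, keep_per_snp = FALSE) {
  stopifnot(inherits(d1, "region_dataset"), inherits(d2, "region_dataset"))
  shared <- intersect(d1$variants$snp, d2$variants$snp)
  if (!length(shared)) stop("no shared variants for colocalisation")
  v1 <- d1$variants[match(shared, d1$variants$snp), , drop = FALSE]
  v2 <- d2$variants[match(shared, d2$variants$snp), , drop = FALSE]
  if (is.null(sd1)) sd1 <- prior_effect_sd(d1$trait)
  if (is.null(sd2)) sd2 <- prior_effect_sd(d2$trait)
  l1 <- log_abf(v1$beta / v1$se, v1$se^2, sd1^2)
  l2 <- log_abf(v2$beta / v2$se, v2$se^2, sd2^2)

  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh0 <- 0
  lh1 <- log(priors$p1) + lsum1
  lh2 <- log(priors$p2) + lsum2
  # sum over ordered pairs i != j of exp(l1_i + l2_j)
  lh3 <- log(priors$p1) + log(priors$p2) + logdiffexp(lsum1 + lsum2, lsum12)
  lh4 <- log(priors$p12) + lsum12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - logsumexp(lh))
  out <- list(pp_h0 = pp[1], pp_h1 = pp[2], pp_h2 = pp[3],
              pp_h3 = pp[4], pp_h4 = pp[5],
              n_snps = length(shared), priors = priors)
  if (keep_per_snp) {
    out$per_snp_log_abf <- data.frame(snp = shared, log_abf_1 = l1,
                                      log_abf_2 = l2, stringsAsFactors = FALSE)
  }
  structure(out, class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %d SNPs  PP: H0=%.3f H1=%.3f H2=%.3f H3=%.3f H4=%.3f\n",
    x$n_snps, x$pp_h0, x$pp_h1, x$pp_h2, x$pp_h3, x$pp_h4))
  invisible(x)
}
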