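#' Default conditional-analysis thresholds
#'
#' @return Named list: `p_select` stepwise selection threshold (5e-8),
#'   `collinearity_r2` (0.9) above which a variant is flagged rather than
#'   conditioned, `freq_mismatch` (0.2) maximum allowed |GWAS eaf - reference
#'   eaf|.
#' @export
conditional_thresholds <- function() {
  list(p_select = 5e-8, collinearity_r2 = 0.9, freq_mismatch = 0.2)
}

# Standardised effects and an estimate of the phenotypic variance implied by
# the summary statistics (median across variants of the var(y) each variant's
# se/beta/eaf/n imply under simple regression on a unit-variance genotype).
standardise_region <- function(variants, ld) {
  idx <- match(variants$snp, ld$variants$snp)
  keep <- !is.na(idx)
  if (!all(keep)) {
    warning(sprintf("%d variant(s) absent from LD reference dropped from conditional analysis",
                    sum(!keep)))
    variants <- variants[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  f <- ifelse(is.na(variants$eaf), ld$variants$eaf[idx], variants$eaf)
  scale <- sqrt(2 * f * (1 - f))
  bs <- variants$beta * scale
  ses <- variants$se * scale
  n <- variants$n
  vary <- stats::median((n * ses^2 * (n - 2) + n * bs^2) / (n - 1))
  list(variants = variants, f = f, scale = scale, bs = bs, ses = ses,
       n = n, vary = vary)
}

solve_psd <- function(A, b) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) out <- solve(A + diag(1e-8, nrow(A)), b)
  out
}

#' Conditional summary statistics given a set of index variants
#'
#' Approximates, from marginal summary statistics plus reference LD, the
#' association each remaining variant would show in a regression that also
#' includes the `condition_on` variants (joint/conditional estimation in the
#' COJO style). Effects are standardised via allele frequencies, the
#' conditioning model's joint coefficients come from LD-derived normal
#' equations, and each remaining variant's conditional effect and standard
#' error derive from its residual association after projecting out the
#' conditioning set. Variants whose LD with the conditioning set exceeds the
#' collinearity cutoff are omitted from the output (no stable conditional
#' estimate exists for them), as are the conditioning variants themselves.
#'
#' @param ds A [region_dataset()] of marginal associations.
#' @param ld An [ld_reference()] covering the region.
#' @param condition_on Character vector of variant ids to condition on
#'   (non-empty, all present in `ds` and `ld`).
#' @param collinearity_r2 Cutoff on the LD r-squared between a variant and the
#'   conditioning set (default 0.9).
#' @return A [region_dataset()] of conditional betas, ses and p-values for
#'   the non-conditioned variants.
#' @export
conditional_stats <- function(ds, ld, condition_on,
                              collinearity_r2 = conditional_thresholds()$collinearity_r2) {
  stopifnot(inherits(ds, "region_dataset"), inherits(ld, "ld_reference"),
            length(condition_on) >= 1L)
  if (!all(condition_on %in% ds$variants$snp)) {
    stop("conditioning variant(s) absent from dataset")
  }
  std <- standardise_region(ds$variants, ld)
  v <- std$variants
  if (!all(condition_on %in% v$snp)) {
    stop("conditioning variant(s) absent from LD reference")
  }
  R <- ld_cor(ld, v$snp)
  ci <- match(condition_on, v$snp)
  ti <- setdiff(seq_len(nrow(v)), ci)
  n_model <- stats::median(std$n)

  RCC <- R[ci, ci, drop = FALSE]
  bC <- std$bs[ci]
  bJ <- solve_psd(RCC, bC)                      # joint standardised effects
  explained <- sum(bJ * bC)
  p <- length(ci)
  sigma2 <- (n_model * std$vary - n_model * explained) /
    (n_model - p - 1)
  sigma2 <- max(sigma2, std$vary * 1e-6)

  QC <- solve_psd(RCC, t(R[ti, ci, drop = FALSE]))   # RCC^-1 R[C, t]
  # r^2 between each target and the conditioning set in the joint model
  r2_model <- rowSums(R[ti, ci, drop = FALSE] * t(QC))
  denom <- pmax(1 - r2_model, 0)
  ok <- r2_model <= collinearity_r2 & denom > 0

  b_cond_std <- (std$bs[ti] - as.vector(R[ti, ci, drop = FALSE] %*% bJ)) / denom
  se_cond_std <- sqrt(sigma2 / (n_model * denom))
  out <- v[ti, , drop = FALSE][ok, , drop = FALSE]
  if (nrow(out)) {
    scale <- std$scale[ti][ok]
    out$beta <- (b_cond_std[ok]) / scale
    out$se <- (se_cond_std[ok]) / scale
    z <- out$beta / out$se
    out$p <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
  }
  region_dataset(out, trait = ds$trait, window = ds$window, validate = FALSE)
}

#' Stepwise selection of conditionally independent signals
#'
#' Forward selection of index variants in a region: start from the marginal
#' statistics, repeatedly add the variant with the smallest (conditional)
#' p-value at or below `p_select`, recompute conditional statistics given the
#' selected set, and stop when no variant qualifies. Variants whose GWAS and
#' reference allele frequencies disagree by more than `freq_mismatch` are
#' excluded up front.
#'
#' @param ds A [region_dataset()] for one region.
#' @param ld An [ld_reference()].
#' @param p_select Selection threshold (default 5e-8).
#' @param collinearity_r2 Collinearity cutoff passed to [conditional_stats()].
#' @param freq_mismatch Maximum |GWAS eaf - reference eaf| (default 0.2).
#' @param max_signals Safety cap on the number of selected signals.
#' @return List of `conditional_signal` objects, each with `lead_variant_id`
#'   and `conditional_dataset` — the region's statistics conditioned on all
#'   *other* selected leads (the marginal data when only one signal exists).
#'   Empty list when nothing reaches `p_select`.
#' @export
stepwise_select <- function(ds, ld,
                            p_select = conditional_thresholds()$p_select,
                            collinearity_r2 = conditional_thresholds()$collinearity_r2,
                            freq_mismatch = conditional_thresholds()$freq_mismatch,
                            max_signals = 10L) {
  stopifnot(inherits(ds, "region_dataset"), inherits(ld, "ld_reference"))
  v <- ds$variants[ds$variants$snp %in% ld$variants$snp, , drop = FALSE]
  if (!nrow(v)) return(list())
  idx <- match(v$snp, ld$variants$snp)
  mism <- !is.na(v$eaf) &
    abs(v$eaf - ld$variants$eaf[idx]) > freq_mismatch
  v <- v[!mism, , drop = FALSE]
  if (!nrow(v)) return(list())
  base <- region_dataset(v, trait = ds$trait, window = ds$window,
                         validate = FALSE)

  selected <- character(0)
  current <- base
  repeat {
    cand <- current$variants[!current$variants$snp %in% selected, , drop = FALSE]
    if (!nrow(cand) || min(cand$p) > p_select ||
        length(selected) >= max_signals) break
    lead <- cand$snp[which.min(cand$p)]
    selected <- c(selected, lead)
    remaining <- base$variants[!base$variants$snp %in% selected, , drop = FALSE]
    if (!nrow(remaining)) break
    current <- conditional_stats(base, ld, condition_on = selected,
                                 collinearity_r2 = collinearity_r2)
  }
  if (!length(selected)) return(list())
  lapply(selected, function(lead) {
    others <- setdiff(selected, lead)
    cond_ds <- if (length(others)) {
      conditional_stats(base, ld, condition_on = others,
                        collinearity_r2 = collinearity_r2)
    } else {
      base
    }
    structure(list(lead_variant_id = lead, conditional_dataset = cond_ds),
              class = "conditional_signal")
  })
}

#' Pairwise conditional colocalisation (PWCoCo)
#'
#' Single-causal-variant colocalisation can miss a shared signal when a
#' region carries several independent associations. PWCoCo decomposes each
#' trait's region into conditionally independent signals via
#' [stepwise_select()] and runs [coloc_posteriors()] for the
#' marginal-marginal pair and every conditional-exposure x conditional-outcome
#' pair, reporting all pairs and the maximum H4.
#'
#' @param d1,d2 Allele-harmonised [region_dataset()]s over a shared region.
#' @param ld An [ld_reference()] covering the region.
#' @param priors Colocalisation priors (see [coloc_priors()]).
#' @param thresholds Conditional-analysis thresholds
#'   (see [conditional_thresholds()]).
#' @return List of class `pwcoco_result`: `pair_results` (data.frame with
#'   `exposure_signal`, `outcome_signal` — `"marginal"` or the lead variant
#'   id — and `PP.H0` .. `PP.H4`, `n_snps`), `colocs` (the underlying
#'   `coloc_result` objects), `n_signals_1`, `n_signals_2`, `max_h4`.
#' @export
pwcoco <- function(d1, d2, ld, priors = coloc_priors(),
                   thresholds = conditional_thresholds()) {
  stopifnot(inherits(d1, "region_dataset"), inherits(d2, "region_dataset"))
  shared <- intersect(d1$variants$snp, d2$variants$snp)
  if (!length(shared)) stop("no shared variants in the region")
  restrict <- function(ds) {
    region_dataset(ds$variants[ds$variants$snp %in% shared, , drop = FALSE],
                   trait = ds$trait, window = ds$window, validate = FALSE)
  }
  d1 <- restrict(d1)
  d2 <- restrict(d2)

  sig1 <- stepwise_select(d1, ld, p_select = thresholds$p_select,
                          collinearity_r2 = thresholds$collinearity_r2,
                          freq_mismatch = thresholds$freq_mismatch)
  sig2 <- stepwise_select(d2, ld, p_select = thresholds$p_select,
                          collinearity_r2 = thresholds$collinearity_r2,
                          freq_mismatch = thresholds$freq_mismatch)

  reps1 <- if (length(sig1) >= 2L) {
    stats::setNames(lapply(sig1, `[[`, "conditional_dataset"),
                    vapply(sig1, `[[`, "", "lead_variant_id"))
  } else list(marginal = d1)
  reps2 <- if (length(sig2) >= 2L) {
    stats::setNames(lapply(sig2, `[[`, "conditional_dataset"),
                    vapply(sig2, `[[`, "", "lead_variant_id"))
  } else list(marginal = d2)

  pairs <- expand.grid(e = names(reps1), o = names(reps2),
                       stringsAsFactors = FALSE)
  if (!("marginal" %in% pairs$e && "marginal" %in% pairs$o)) {
    pairs <- rbind(data.frame(e = "marginal", o = "marginal",
                              stringsAsFactors = FALSE), pairs)
  }
  colocs <- vector("list", nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    de <- if (pairs$e[i] == "marginal") d1 else reps1[[pairs$e[i]]]
    do <- if (pairs$o[i] == "marginal") d2 else reps2[[pairs$o[i]]]
    cl <- coloc_posteriors(de, do, priors = priors)
    colocs[[i]] <- cl
    rows[[i]] <- data.frame(
      exposure_signal = pairs$e[i], outcome_signal = pairs$o[i],
      PP.H0 = cl$pp_h0, PP.H1 = cl$pp_h1, PP.H2 = cl$pp_h2,
      PP.H3 = cl$pp_h3, PP.H4 = cl$pp_h4, n_snps = cl$n_snps,
      stringsAsFactors = FALSE)
  }
  pair_results <- do.call(rbind, rows)
  structure(
    list(pair_results = pair_results, colocs = colocs,
         n_signals_1 = length(sig1), n_signals_2 = length(sig2),
         max_h4 = max(pair_results$PP.H4)),
    class = "pwcoco_result"
  )
}

#' @export
print.pwcoco_result <- function(x, ...) {
  cat(sprintf("<pwcoco_result> %d x %d signal(s), %d pair(s), max H4 = %.3f\n",
              x$n_signals_1, x$n_signals_2, nrow(x$pair_results), x$max_h4))
  invisible(x)
}
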