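#' Default tiering thresholds
#'
#' @return Named list: `tier_a_p` Bonferroni gate for Tier A (1.8e-06;
#'   `0.05/24598 = 2.03e-06` is the config alternative used in some analyses
#'   — the two differ slightly and both are supported), `h4_min` (0.8),
#'   `fdr_level` (0.05), `het_alpha`/`pleio_alpha` (0.05) for the
#'   heterogeneity and pleiotropy "no evidence" gates.
#' @export
tiering_thresholds <- function() {
  list(tier_a_p = 1.8e-06, h4_min = 0.8, fdr_level = 0.05,
       het_alpha = 0.05, pleio_alpha = 0.05)
}

#' Choose the variant whose region is tested for colocalisation
#'
#' When an instrument set contains at least one cis variant, colocalisation
#' is anchored on the cis variant with the smallest p-value; a purely trans
#' set uses the trans variant with the smallest p-value; a single-variant set
#' uses that variant regardless of locality.
#'
#' @param iset An `instrument_set` from [build_instrument_set()] (non-empty).
#' @return One-row variant `data.frame` (the selected instrument row).
#' @export
select_coloc_variant <- function(iset) {
  stopifnot(inherits(iset, "instrument_set"))
  ins <- iset$instruments
  if (!nrow(ins)) stop("cannot select a colocalisation variant: empty instrument set")
  if (nrow(ins) == 1L) return(ins)
  cis <- ins[ins$locality == "cis", , drop = FALSE]
  pool <- if (nrow(cis)) cis else ins
  pool[which.min(pool$p), , drop = FALSE]
}

#' Map gate booleans to an evidence tier
#'
#' Pure function from the seven evidence gates to the tier label:
#' \describe{
#'   \item{A}{Bonferroni, Steiger, colocalisation, cis-only instruments, and
#'     no evidence of heterogeneity or pleiotropy.}
#'   \item{B}{as A with the FDR gate in place of Bonferroni.}
#'   \item{C}{as B but the instrument set includes trans variants.}
#'   \item{fdr_only}{passes FDR but fails at least one other gate.}
#'   \item{none}{fails FDR (and, for tier A, Bonferroni).}
#' }
#'
#' @param bonferroni_pass,fdr_pass,steiger_pass,coloc_pass,cis_only_instruments,het_pass,pleio_pass
#'   Logical scalars (vectorised).
#' @return Character vector of tiers in `{"A","B","C","fdr_only","none"}`.
#' @export
tier_from_gates <- function(bonferroni_pass, fdr_pass, steiger_pass,
                            coloc_pass, cis_only_instruments, het_pass,
                            pleio_pass) {
  core <- steiger_pass & coloc_pass & het_pass & pleio_pass
  ifelse(bonferroni_pass & core & cis_only_instruments, "A",
    ifelse(fdr_pass & core & cis_only_instruments, "B",
      ifelse(fdr_pass & core & !cis_only_instruments, "C",
        ifelse(fdr_pass, "fdr_only", "none"))))
}

#' Assign the evidence tier for one exposure-outcome pair
#'
#' Computes the seven evidence gates from the stage outputs and maps them to
#' a tier via [tier_from_gates()]. Heterogeneity is only an exclusion with
#' more than 2 instruments (Cochran's Q p <= `het_alpha`), pleiotropy only
#' with more than 3 (Egger intercept p <= `pleio_alpha`); smaller sets pass
#' those gates vacuously.
#'
#' @param mr One-row MR result `data.frame` (from [wald_ratio()], [ivw()]).
#' @param q_value BH q-value of the MR p-value within the analysis family.
#' @param steiger A `steiger_result` from [steiger_direction()].
#' @param max_h4 Maximum colocalisation H4 for the pair (from [pwcoco()]).
#' @param iset The `instrument_set` used.
#' @param egger_intercept_p Egger intercept p-value, or `NA` when not
#'   estimated.
#' @param thresholds See [tiering_thresholds()].
#' @param steiger_p_max Optional Steiger p-value requirement (default `NULL`:
#'   the gate is direction-only).
#' @return One-row `data.frame` of class `tier_assignment` with the gate
#'   booleans, `mhc_flag`, `coloc_variant_id` and `tier`.
#' @export
assign_tier <- function(mr, q_value, steiger, max_h4, iset,
                        egger_intercept_p = NA_real_,
                        thresholds = tiering_thresholds(),
                        steiger_p_max = NULL) {
  for (nm in c("mr", "q_value", "steiger", "max_h4", "iset")) {
    if (is.null(get(nm)) || (is.atomic(get(nm)) && all(is.na(get(nm))))) {
      stop("incomplete evidence: missing stage output '", nm, "'")
    }
  }
  stopifnot(inherits(steiger, "steiger_result"), inherits(iset, "instrument_set"))
  gates <- list(
    bonferroni_pass = mr$p <= thresholds$tier_a_p,
    fdr_pass = q_value <= thresholds$fdr_level,
    steiger_pass = steiger$correct_direction &&
      (is.null(steiger_p_max) || steiger$steiger_pval <= steiger_p_max),
    coloc_pass = max_h4 >= thresholds$h4_min,
    cis_only_instruments = all(iset$instruments$locality == "cis"),
    het_pass = mr$nsnp <= 2 || is.na(mr$Q_p) || mr$Q_p > thresholds$het_alpha,
    pleio_pass = mr$nsnp <= 3 || is.na(egger_intercept_p) ||
      egger_intercept_p > thresholds$pleio_alpha
  )
  tier <- tier_from_gates(gates$bonferroni_pass, gates$fdr_pass,
                          gates$steiger_pass, gates$coloc_pass,
                          gates$cis_only_instruments, gates$het_pass,
                          gates$pleio_pass)
  cv <- select_coloc_variant(iset)
  out <- data.frame(
    exposure_id = mr$exposure_id, outcome_id = mr$outcome_id, tier = tier,
    bonferroni_pass = gates$bonferroni_pass, fdr_pass = gates$fdr_pass,
    steiger_pass = gates$steiger_pass, coloc_pass = gates$coloc_pass,
    cis_only_instruments = gates$cis_only_instruments,
    het_pass = gates$het_pass, pleio_pass = gates$pleio_pass,
    mhc_flag = any(iset$instruments$mhc_flag),
    coloc_variant_id = cv$snp, stringsAsFactors = FALSE)
  class(out) <- c("tier_assignment", class(out))
  out
}

#' Cross-QTL colocalisation for a biomarker with tiered evidence
#'
#' When a biomarker reaches Tier A/B/C through more than one QTL source
#' (e.g. blood pQTL and brain eQTL), colocalising the QTL datasets against
#' each other tests whether the same underlying variant drives the molecular
#' signals, strengthening the biomarker's link to the outcome. Pairs where
#' either QTL lies in the MHC are skipped — the region's LD makes the
#' result unreliable.
#'
#' @param qtl_datasets Named list of [region_dataset()]s, one per tiered QTL
#'   source for the biomarker (>= 2 for any pairs to be tested).
#' @param mhc_flags Named logical vector parallel to `qtl_datasets`.
#' @param ld An [ld_reference()] covering the shared region.
#' @param priors,thresholds Passed to [pwcoco()].
#' @return `data.frame` with one row per unordered pair: `qtl_1`, `qtl_2`,
#'   `skipped`, `skip_reason`, `PP.H4_max` (`NA` when skipped). Zero rows
#'   when fewer than two datasets are supplied.
#' @export
cross_qtl_coloc <- function(qtl_datasets, mhc_flags, ld,
                            priors = coloc_priors(),
                            thresholds = conditional_thresholds()) {
  k <- length(qtl_datasets)
  empty <- data.frame(qtl_1 = character(), qtl_2 = character(),
                      skipped = logical(), skip_reason = character(),
                      PP.H4_max = numeric(), stringsAsFactors = FALSE)
  if (k < 2L) return(empty)
  nms <- names(qtl_datasets)
  stopifnot(!is.null(nms), all(nms %in% names(mhc_flags)))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (mhc_flags[[nms[i]]] || mhc_flags[[nms[j]]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          qtl_1 = nms[i], qtl_2 = nms[j], skipped = TRUE,
          skip_reason = "MHC", PP.H4_max = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        pw <- pwcoco(qtl_datasets[[i]], qtl_datasets[[j]], ld,
                     priors = priors, thresholds = thresholds)
        rows[[length(rows) + 1L]] <- data.frame(
          qtl_1 = nms[i], qtl_2 = nms[j], skipped = FALSE,
          skip_reason = NA_character_, PP.H4_max = pw$max_h4,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
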