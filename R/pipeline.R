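#' Run the forward drug-target prioritisation analysis
#'
#' For every exposure x outcome x selection mode: build instruments, estimate
#' the causal effect (Wald ratio for a single instrument, IVW with Cochran's
#' Q otherwise, plus MR-Egger when at least three instruments are available),
#' run Steiger directionality filtering, anchor a +/-500 kb region on the
#' colocalisation variant, run pairwise conditional colocalisation, control
#' multiple testing across the pooled results, and assign evidence tiers.
#'
#' @param exposures Named list; each element is `list(dataset =, gene =)`
#'   with a [region_dataset()] and a [gene_region()].
#' @param outcomes Named list of [region_dataset()]s.
#' @param ld An [ld_reference()] covering the exposure variants.
#' @param modes Selection modes to run (subset of
#'   `c("cis_only", "cis_and_trans")`).
#' @param instrument_cfg,tier_cfg,priors,cond_cfg Stage configurations; see
#'   [instrument_thresholds()], [tiering_thresholds()], [coloc_priors()],
#'   [conditional_thresholds()].
#' @param coloc_half_width Half-width of the colocalisation window around the
#'   anchored variant (default 500 kb).
#' @param n_tests_bonferroni Denominator for the pooled Bonferroni threshold
#'   reported alongside the results; defaults to the number of tests run.
#' @param fdr_scope `"pooled"` (default: BH across all results of the run) or
#'   `"per_outcome"`.
#' @return List of class `forward_result`: `results` (one row per analysed
#'   pair: MR estimates, diagnostics, Steiger and coloc columns, q-values,
#'   gates, tier), `skipped` (pair, mode, reason), `details` (per-row list of
#'   stage objects), `bonferroni_threshold`.
#' @export
run_forward <- function(exposures, outcomes, ld,
                        modes = "cis_only",
                        instrument_cfg = instrument_thresholds(),
                        tier_cfg = tiering_thresholds(),
                        priors = coloc_priors(),
                        cond_cfg = conditional_thresholds(),
                        coloc_half_width = 5e5,
                        n_tests_bonferroni = NULL,
                        fdr_scope = c("pooled", "per_outcome")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(length(modes) >= 1, all(modes %in% c("cis_only", "cis_and_trans")))
  rows <- list()
  details <- list()
  skipped <- list()
  skip <- function(e, o, m, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      exposure_id = e, outcome_id = o, mode = m, reason = reason,
      stringsAsFactors = FALSE)
  }

  for (ename in names(exposures)) {
    exp_ds <- exposures[[ename]]$dataset
    gene <- exposures[[ename]]$gene
    for (mode in modes) {
      iset <- build_instrument_set(exp_ds, gene, ld, mode = mode,
                                   thresholds = instrument_cfg)
      for (oname in names(outcomes)) {
        out_ds <- outcomes[[oname]]
        if (iset$empty) {
          skip(ename, oname, mode, "empty instrument set")
          next
        }
        ins_ds <- region_dataset(iset$instruments[variant_columns],
                                 trait = exp_ds$trait, validate = FALSE)
        out_sub <- region_dataset(
          out_ds$variants[out_ds$variants$snp %in% ins_ds$variants$snp, ,
                          drop = FALSE],
          trait = out_ds$trait, validate = FALSE)
        if (!nrow(out_sub$variants)) {
          skip(ename, oname, mode, "no instruments present in outcome")
          next
        }
        hp <- harmonise_pair(ins_ds, out_sub)
        hx <- hp$exposure$variants
        hy <- hp$outcome$variants
        k <- nrow(hx)
        if (!k) {
          skip(ename, oname, mode, "no harmonisable instruments")
          next
        }

        mr <- if (k == 1L) {
          wald_ratio(hx$beta, hx$se, hy$beta, hy$se, ename, oname)
        } else {
          ivw(hx$beta, hx$se, hy$beta, hy$se,
              exposure_id = ename, outcome_id = oname)
        }
        eg <- if (k >= 3L) {
          egger(hx$beta, hx$se, hy$beta, hy$se, ename, oname)
        } else NULL

        st <- steiger_direction(hx, hy, exp_ds$trait, out_ds$trait)

        # keep only instruments that survived harmonisation for coloc anchoring
        iset_h <- iset
        iset_h$instruments <- iset$instruments[
          iset$instruments$snp %in% hx$snp, , drop = FALSE]
        cv <- select_coloc_variant(iset_h)
        reg_e <- extract_region(exp_ds, cv$chr, cv$pos, coloc_half_width)
        reg_o <- extract_region(out_ds, cv$chr, cv$pos, coloc_half_width)
        pw <- tryCatch({
          hp_reg <- harmonise_pair(reg_e, reg_o)
          pwcoco(hp_reg$exposure, hp_reg$outcome, ld,
                 priors = priors, thresholds = cond_cfg)
        }, error = function(e) NULL)
        if (is.null(pw)) {
          skip(ename, oname, mode, "no overlapping colocalisation region")
          next
        }

        i <- length(rows) + 1L
        rows[[i]] <- data.frame(
          exposure_id = ename, outcome_id = oname, mode = mode,
          qtl_type = exp_ds$trait$qtl_type, tissue = exp_ds$trait$tissue,
          method = mr$method, nsnp = mr$nsnp, b = mr$b, se = mr$se, p = mr$p,
          Q = mr$Q, Q_df = mr$Q_df, Q_p = mr$Q_p,
          egger_intercept = if (is.null(eg)) NA_real_ else eg$egger_intercept,
          egger_intercept_p = if (is.null(eg)) NA_real_ else eg$egger_intercept_p,
          r2_exp = st$r2_exposure, r2_out = st$r2_outcome,
          steiger_dir = st$correct_direction, steiger_p = st$steiger_pval,
          PP.H4_max = pw$max_h4, PP.H3_marginal = pw$pair_results$PP.H3[1],
          PP.H4_marginal = pw$pair_results$PP.H4[1],
          coloc_variant_id = cv$snp,
          stringsAsFactors = FALSE)
        details[[i]] <- list(iset = iset_h, mr = mr, egger = eg, steiger = st,
                             pwcoco = pw)
      }
    }
  }

  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(exposure_id = character(), outcome_id = character(),
               mode = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (!length(rows)) {
    return(structure(list(results = NULL, skipped = skipped,
                          details = list(), bonferroni_threshold = NA_real_),
                     class = "forward_result"))
  }
  res <- do.call(rbind, rows)
  if (is.null(n_tests_bonferroni)) n_tests_bonferroni <- nrow(res)

  if (fdr_scope == "pooled") {
    adj <- adjust_pvalues(res$p, alpha = 0.05,
                          n_tests_bonferroni = n_tests_bonferroni,
                          fdr_level = tier_cfg$fdr_level)
    res$q_value <- adj$q_values
    bonf_thr <- adj$bonferroni_threshold
  } else {
    res$q_value <- NA_real_
    for (oname in unique(res$outcome_id)) {
      ix <- res$outcome_id == oname
      res$q_value[ix] <- stats::p.adjust(res$p[ix], method = "BH")
    }
    bonf_thr <- 0.05 / n_tests_bonferroni
  }

  tiers <- lapply(seq_len(nrow(res)), function(i) {
    assign_tier(details[[i]]$mr, res$q_value[i], details[[i]]$steiger,
                res$PP.H4_max[i], details[[i]]$iset,
                egger_intercept_p = res$egger_intercept_p[i],
                thresholds = tier_cfg)
  })
  tier_tab <- do.call(rbind, tiers)
  res <- cbind(res, tier_tab[!(names(tier_tab) %in%
                                 c("exposure_id", "outcome_id"))])
  structure(list(results = res, skipped = skipped, details = details,
                 bonferroni_threshold = bonf_thr),
            class = "forward_result")
}

#' @export
print.forward_result <- function(x, ...) {
  n <- if (is.null(x$results)) 0L else nrow(x$results)
  cat(sprintf("<forward_result> %d pair(s) analysed, %d skipped\n",
              n, nrow(x$skipped)))
  if (n) print(table(x$results$tier))
  invisible(x)
}

#' Run the reverse (bidirectional) MR pass
#'
#' Tests the causal effect of genetic liability to each condition on each
#' biomarker. Instruments are clumped at genome-wide significance; when
#' fewer than `fallback_min` survive, selection is repeated at the relaxed
#' `fallback_p` threshold and the fallback is recorded. Effects are estimated
#' by IVW (Wald ratio for a single instrument) and gated at the Bonferroni
#' threshold `0.05 / (n_conditions * n_biomarkers)`.
#'
#' @param conditions Named list of condition [region_dataset()]s (exposures
#'   of this pass).
#' @param biomarkers Named list of biomarker [region_dataset()]s (outcomes).
#' @param ld An [ld_reference()].
#' @param p_threshold Primary instrument threshold (default 5e-8).
#' @param fallback_p Relaxed threshold (default 5e-7).
#' @param fallback_min Minimum instrument count below which the fallback
#'   engages (default 3).
#' @param clump_r2,clump_window_kb Clumping parameters.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List of class `reverse_result`: `results` (condition, biomarker,
#'   MR columns, `instrument_p_threshold_used`, `bonferroni_pass`),
#'   `skipped`, `bonferroni_threshold`.
#' @export
run_reverse <- function(conditions, biomarkers, ld,
                        p_threshold = 5e-8, fallback_p = 5e-7,
                        fallback_min = 3L, clump_r2 = 0.001,
                        clump_window_kb = 10000, alpha = 0.05) {
  thr <- alpha / (length(conditions) * length(biomarkers))
  rows <- list()
  skipped <- list()
  for (cname in names(conditions)) {
    cds <- conditions[[cname]]
    sel <- clump(cds, ld, p_threshold = p_threshold,
                 r2_threshold = clump_r2, window_kb = clump_window_kb)
    used <- p_threshold
    if (nrow(sel) < fallback_min) {
      sel <- clump(cds, ld, p_threshold = fallback_p,
                   r2_threshold = clump_r2, window_kb = clump_window_kb)
      used <- fallback_p
    }
    for (bname in names(biomarkers)) {
      bds <- biomarkers[[bname]]
      if (!nrow(sel)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          condition = cname, biomarker = bname,
          reason = "no instruments after fallback", stringsAsFactors = FALSE)
        next
      }
      ins_ds <- region_dataset(sel[variant_columns], trait = cds$trait,
                               validate = FALSE)
      bsub <- region_dataset(
        bds$variants[bds$variants$snp %in% sel$snp, , drop = FALSE],
        trait = bds$trait, validate = FALSE)
      if (!nrow(bsub$variants)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          condition = cname, biomarker = bname,
          reason = "no instruments present in biomarker GWAS",
          stringsAsFactors = FALSE)
        next
      }
      hp <- harmonise_pair(ins_ds, bsub)
      hx <- hp$exposure$variants
      hy <- hp$outcome$variants
      mr <- if (nrow(hx) == 1L) {
        wald_ratio(hx$beta, hx$se, hy$beta, hy$se, cname, bname)
      } else {
        ivw(hx$beta, hx$se, hy$beta, hy$se,
            exposure_id = cname, outcome_id = bname)
      }
      mr$instrument_p_threshold_used <- used
      mr$bonferroni_pass <- mr$p <= thr
      rows[[length(rows) + 1L]] <- mr
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(condition = character(), biomarker = character(),
               reason = character(), stringsAsFactors = FALSE)
  structure(list(results = results, skipped = skipped,
                 bonferroni_threshold = thr),
            class = "reverse_result")
}

#' @export
print.reverse_result <- function(x, ...) {
  n <- if (is.null(x$results)) 0L else nrow(x$results)
  cat(sprintf(
    "<reverse_result> %d pair(s), %d skipped, Bonferroni threshold %.3g\n",
    n, nrow(x$skipped), x$bonferroni_threshold))
  invisible(x)
}

#' Run the forward pipeline on one simulated scenario and check expectations
#'
#' Convenience wrapper used throughout validation: runs [run_forward()] on a
#' [scenario_suite()] bundle in the scenario's selection mode and evaluates
#' its expectation record (tier membership, individual gates, H3 vs H4).
#'
#' @param bundle One element of [scenario_suite()].
#' @return List: `met` (logical: every expectation satisfied), `row` (the
#'   pipeline result row, or `NULL` if the pair was skipped), `checks`
#'   (named logical vector of individual expectations).
#' @export
check_scenario <- function(bundle) {
  fw <- run_forward(
    exposures = list(biomarker = list(dataset = bundle$exposure,
                                      gene = bundle$gene)),
    outcomes = list(condition = bundle$outcome),
    ld = bundle$ld, modes = bundle$scenario$mode)
  exp_rec <- bundle$scenario$expectation
  if (is.null(fw$results)) {
    return(list(met = FALSE, row = NULL,
                checks = c(pair_analysed = FALSE)))
  }
  row <- fw$results[1, ]
  checks <- c(pair_analysed = TRUE)
  if (!is.null(exp_rec$tier_in)) {
    checks["tier"] <- row$tier %in% exp_rec$tier_in
  }
  for (g in names(exp_rec$gates)) {
    checks[g] <- row[[g]] == exp_rec$gates[[g]]
  }
  if (isTRUE(exp_rec$h3_gt_h4)) {
    checks["h3_gt_h4"] <- row$PP.H3_marginal > row$PP.H4_marginal
  }
  list(met = all(checks), row = row, checks = checks)
}
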