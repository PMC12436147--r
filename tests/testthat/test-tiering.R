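make_iset <- function(localities, pvals = NULL, mhc = NULL) {
  k <- length(localities)
  v <- if (k == 0) toy_variants(1)[0, ] else toy_variants(k)
  if (!is.null(pvals)) v$p <- pvals
  v$f_stat <- rep(50, k)
  v$locality <- localities
  v$mhc_flag <- if (is.null(mhc)) rep(FALSE, k) else mhc
  structure(list(exposure_id = "exp", gene = gene_region("G", "1", 1, 2),
                 instruments = v, selection_mode = "cis_and_trans",
                 empty = k == 0),
            class = "instrument_set")
}

test_that("coloc variant selection prefers cis, then the smallest p-value", {
  # cis beats a stronger trans variant
  iset <- make_iset(c("cis", "trans"), pvals = c(1e-8, 1e-20))
  expect_equal(select_coloc_variant(iset)$locality, "cis")
  # all-trans: smallest p wins
  iset2 <- make_iset(c("trans", "trans"), pvals = c(1e-9, 1e-12))
  expect_equal(select_coloc_variant(iset2)$p, 1e-12)
  # single variant: itself, regardless of locality
  iset3 <- make_iset("trans")
  expect_equal(select_coloc_variant(iset3)$snp, "v1")
  # several cis: smallest cis p
  iset4 <- make_iset(c("cis", "cis", "trans"), pvals = c(1e-9, 1e-11, 1e-30))
  expect_equal(select_coloc_variant(iset4)$p, 1e-11)
  expect_error(select_coloc_variant(make_iset(character(0))), "empty")
})

test_that("the full gate truth table maps to tiers exactly as defined", {
  gates <- expand.grid(bonf = c(TRUE, FALSE), fdr = c(TRUE, FALSE),
                       steiger = c(TRUE, FALSE), coloc = c(TRUE, FALSE),
                       cis = c(TRUE, FALSE), het = c(TRUE, FALSE),
                       pleio = c(TRUE, FALSE))
  got <- tier_from_gates(gates$bonf, gates$fdr, gates$steiger, gates$coloc,
                         gates$cis, gates$het, gates$pleio)
  # independent restatement of the tier definitions
  want <- character(nrow(gates))
  for (i in seq_len(nrow(gates))) {
    g <- gates[i, ]
    core <- g$steiger && g$coloc && g$het && g$pleio
    want[i] <-
      if (g$bonf && core && g$cis) "A"
      else if (g$fdr && core && g$cis) "B"
      else if (g$fdr && core && !g$cis) "C"
      else if (g$fdr) "fdr_only"
      else "none"
  }
  expect_identical(got, want)
  # tiers are mutually exclusive by construction (one label per combination)
  expect_true(all(got %in% c("A", "B", "C", "fdr_only", "none")))
})

test_that("tightening the tier-A threshold can only demote A to B", {
  st <- structure(list(r2_exposure = 0.01, r2_outcome = 0.001,
                       correct_direction = TRUE, steiger_pval = 1e-5),
                  class = "steiger_result")
  iset <- make_iset("cis")
  mr <- mrtier:::mr_result_row("exp", "out", "wald", 1, 0.5, 0.1,
                               p = 1e-7)
  loose <- assign_tier(mr, 0.001, st, 0.9, iset,
                       thresholds = modifyList(tiering_thresholds(),
                                               list(tier_a_p = 2.03e-7)))
  strict <- assign_tier(mr, 0.001, st, 0.9, iset,
                        thresholds = modifyList(tiering_thresholds(),
                                                list(tier_a_p = 1e-8)))
  expect_equal(loose$tier, "A")
  expect_equal(strict$tier, "B")
})

test_that("assign_tier reproduces the worked gate examples", {
  st_pass <- structure(list(r2_exposure = 0.01, r2_outcome = 0.001,
                            correct_direction = TRUE, steiger_pval = 1e-5),
                       class = "steiger_result")
  cis1 <- make_iset("cis")
  mr_strong <- mrtier:::mr_result_row("exp", "out", "wald", 1, 0.5, 0.08,
                                      p = 1e-8)
  # Bonferroni + cis + direction + coloc: Tier A
  expect_equal(assign_tier(mr_strong, 0.001, st_pass, 0.9, cis1)$tier, "A")
  # FDR-level significance only: Tier B
  mr_mid <- mrtier:::mr_result_row("exp", "out", "wald", 1, 0.3, 0.08,
                                   p = 1e-4)
  expect_equal(assign_tier(mr_mid, 0.01, st_pass, 0.95, cis1)$tier, "B")
  # same gates with a trans instrument in the set: Tier C
  mixed <- make_iset(c("cis", "trans"))
  mr_ivw <- mrtier:::mr_result_row("exp", "out", "ivw", 2, 0.3, 0.08,
                                   p = 1e-4, Q = 0.5, Q_df = 1L, Q_p = 0.5)
  expect_equal(assign_tier(mr_ivw, 0.01, st_pass, 0.95, mixed)$tier, "C")
  # colocalisation below 0.8 drops to fdr_only
  expect_equal(assign_tier(mr_mid, 0.01, st_pass, 0.79, cis1)$tier,
               "fdr_only")
  # heterogeneity gate only binds with more than 2 instruments
  mr_het2 <- mrtier:::mr_result_row("exp", "out", "ivw", 2, 0.3, 0.08,
                                    p = 1e-4, Q = 20, Q_df = 1L,
                                    Q_p = 1e-5)
  expect_equal(assign_tier(mr_het2, 0.01, st_pass, 0.9, cis1)$tier, "B")
  mr_het3 <- mrtier:::mr_result_row("exp", "out", "ivw", 3, 0.3, 0.08,
                                    p = 1e-4, Q = 30, Q_df = 2L,
                                    Q_p = 1e-6)
  cis3 <- make_iset(rep("cis", 3))
  expect_equal(assign_tier(mr_het3, 0.01, st_pass, 0.9, cis3)$tier,
               "fdr_only")
  # pleiotropy gate only binds with more than 3 instruments
  cis4 <- make_iset(rep("cis", 4))
  mr_p4 <- mrtier:::mr_result_row("exp", "out", "ivw", 4, 0.3, 0.08,
                                  p = 1e-4, Q = 1, Q_df = 3L, Q_p = 0.8)
  expect_equal(assign_tier(mr_p4, 0.01, st_pass, 0.9, cis4,
                           egger_intercept_p = 0.01)$tier, "fdr_only")
  mr_p3 <- mrtier:::mr_result_row("exp", "out", "ivw", 3, 0.3, 0.08,
                                  p = 1e-4, Q = 1, Q_df = 2L, Q_p = 0.8)
  expect_equal(assign_tier(mr_p3, 0.01, st_pass, 0.9, cis3,
                           egger_intercept_p = 0.01)$tier, "B")
})

test_that("cross-QTL colocalisation skips MHC pairs and reports H4 otherwise", {
  ld <- simulate_ld_reference(3000, 100, block_size = 25, rho = 0.9,
                              seed = 31)
  R <- ld_cor(ld, ld$variants$snp)
  f <- ld$variants$eaf
  b <- 12 / sqrt(30000) / sqrt(2 * f[50] * (1 - f[50]))
  mk <- function(seed, tissue) {
    tr <- trait_meta(paste0("bm_", tissue), "quantitative", tissue = tissue,
                     qtl_type = if (tissue == "blood") "pqtl" else "eqtl")
    simulate_gwas(ld, data.frame(index = 50, beta = b), tr, 30000,
                  seed = seed, R = R)
  }
  ds <- list(blood_pqtl = mk(1, "blood"), brain_eqtl = mk(2, "brain"))
  tab <- cross_qtl_coloc(ds, c(blood_pqtl = FALSE, brain_eqtl = FALSE), ld)
  expect_equal(nrow(tab), 1L)
  expect_false(tab$skipped)
  expect_gte(tab$PP.H4_max, 0.8)
  # an MHC-resident QTL skips the pair with a reason
  tab2 <- cross_qtl_coloc(ds, c(blood_pqtl = TRUE, brain_eqtl = FALSE), ld)
  expect_true(tab2$skipped)
  expect_equal(tab2$skip_reason, "MHC")
  # fewer than two datasets: empty table
  expect_equal(nrow(cross_qtl_coloc(ds[1], c(blood_pqtl = FALSE), ld)), 0L)
})
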