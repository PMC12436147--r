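test_that("summary-stat files round-trip through the TSV dialect", {
  ds <- toy_dataset(4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ds, path)
  back <- read_summary_stats(path, trait = ds$trait)
  expect_equal(back$variants, ds$variants, tolerance = 1e-12)
  expect_equal(nrow(back$drop_log), 0L)
})

test_that("invalid rows are dropped and counted, not fatal", {
  v <- toy_variants(5)
  v$se[2] <- 0                       # non-positive se
  v$p[4] <- 2 * pnorm(-20)           # p wildly inconsistent with beta/se
  ds <- region_dataset(v, trait = quant_trait())
  expect_equal(nrow(ds$variants), 3L)
  expect_setequal(ds$drop_log$variant_id, c("v2", "v4"))
  expect_true("non-positive se" %in% ds$drop_log$reason)
  expect_true("p inconsistent with beta/se" %in% ds$drop_log$reason)
})

test_that("a dialect without an eaf column yields absent frequencies", {
  ds <- toy_dataset(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ds, path)
  dia <- mrtier:::default_dialect()
  dia <- dia[names(dia) != "eaf"]
  back <- read_summary_stats(path, trait = ds$trait, dialect = dia)
  expect_true(all(is.na(back$variants$eaf)))
  # variance explained then falls back to the p/n method
  expect_warning(
    r2 <- variance_explained(back$variants$beta, back$variants$eaf,
                             back$variants$p, back$variants$n,
                             method = "eaf_beta"),
    "p/n")
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("a missing required column is a named format error", {
  ds <- toy_dataset(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- ds$variants
  tab$se <- NULL
  names(tab) <- mrtier:::default_dialect()[names(tab)]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path, trait = ds$trait), "SE")
})

test_that("extract_region keeps closed-interval boundaries and is idempotent", {
  v <- toy_variants(3)
  v$pos <- c(500000L, 1500000L, 1500001L)
  ds <- region_dataset(v, trait = quant_trait())
  win <- extract_region(ds, "1", 1000000, 500000)
  expect_setequal(win$variants$pos, c(500000L, 1500000L))
  again <- extract_region(win, "1", 1000000, 500000)
  expect_equal(again$variants, win$variants)
  # half_width 0 keeps only the exact centre
  only <- extract_region(ds, "1", 500000, 0)
  expect_equal(only$variants$pos, 500000L)
  # a chromosome with no data is an empty flagged region, not an error
  none <- extract_region(ds, "17", 1000000, 500000)
  expect_true(none$empty_region)
  expect_equal(nrow(none$variants), 0L)
})

test_that("harmonisation flips swapped alleles and drops ambiguous palindromes", {
  ex <- toy_variants(3)
  ex$ea <- c("A", "A", "C"); ex$oa <- c("G", "T", "G")
  ex$eaf <- c(0.3, 0.50, 0.2)
  ou <- ex
  # v1 has swapped alleles in the outcome
  ou$ea[1] <- "G"; ou$oa[1] <- "A"
  ou$beta[1] <- 0.05; ou$p[1] <- 2 * pnorm(-0.05 / ou$se[1]); ou$eaf[1] <- 0.7
  dse <- region_dataset(ex, trait = quant_trait())
  dso <- region_dataset(ou, trait = cc_trait())
  hp <- harmonise_pair(dse, dso)
  # flipped onto the exposure allele
  v1 <- hp$outcome$variants[hp$outcome$variants$snp == "v1", ]
  expect_equal(v1$beta, -0.05)
  expect_equal(v1$eaf, 0.3)
  expect_equal(v1$ea, "A")
  # the A/T palindrome at eaf 0.5 is unresolvable
  expect_true("v2" %in% hp$dropped$variant_id)
  expect_match(hp$dropped$reason[hp$dropped$variant_id == "v2"], "palindrome")
  # untouched variant passes through unchanged
  v3 <- hp$outcome$variants[hp$outcome$variants$snp == "v3", ]
  expect_equal(v3$beta, ou$beta[3])
})

test_that("harmonisation is idempotent and invariant to double allele flips", {
  set.seed(11)
  ex <- toy_variants(6)
  ou <- toy_variants(6)
  flip <- c(2, 5)
  ou$ea[flip] <- ex$oa[flip]; ou$oa[flip] <- ex$ea[flip]
  ou$beta[flip] <- -ou$beta[flip]
  ou$eaf[flip] <- 1 - ou$eaf[flip]
  dse <- region_dataset(ex, trait = quant_trait())
  dso <- region_dataset(ou, trait = cc_trait())
  hp <- harmonise_pair(dse, dso)
  expect_identical(hp$exposure$variants$snp, hp$outcome$variants$snp)
  expect_identical(hp$exposure$variants$ea, hp$outcome$variants$ea)
  # idempotent
  hp2 <- harmonise_pair(hp$exposure, hp$outcome)
  expect_equal(hp2$exposure$variants, hp$exposure$variants)
  expect_equal(hp2$outcome$variants, hp$outcome$variants)
  expect_equal(nrow(hp2$dropped), 0L)
  # flipping both alleles and negating beta before harmonisation: no change
  ou3 <- toy_variants(6)
  tmp <- ou3$ea; ou3$ea <- ou3$oa; ou3$oa <- tmp
  ou3$beta <- -ou3$beta
  ou3$eaf <- 1 - ou3$eaf
  hp3 <- harmonise_pair(dse, region_dataset(ou3, trait = cc_trait()))
  base <- harmonise_pair(dse, region_dataset(toy_variants(6),
                                             trait = cc_trait()))
  expect_equal(hp3$outcome$variants, base$outcome$variants, tolerance = 1e-12)
})

test_that("disjoint variant sets raise an empty-overlap error", {
  a <- toy_dataset(3)
  b <- toy_variants(3)
  b$snp <- paste0("w", 1:3)
  expect_error(
    harmonise_pair(a, region_dataset(b, trait = cc_trait())),
    "no shared variants")
})
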