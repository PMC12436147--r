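test_that("conditioning on an unlinked variant leaves other estimates unchanged", {
  fx <- make_individual_fixture(301, n_ind = 3000)
  ds <- fx$ds
  # variant 45 is in the last block, unlinked to block-1 variants
  cond <- conditional_stats(ds, fx$ld, condition_on = "rs00045")
  pick <- cond$variants$snp %in% paste0("rs0000", 1:5)
  orig <- ds$variants[match(cond$variants$snp[pick], ds$variants$snp), ]
  expect_equal(cond$variants$beta[pick], orig$beta, tolerance = 0.02)
  expect_equal(cond$variants$se[pick], orig$se, tolerance = 0.02)
})

test_that("conditional estimates match individual-level multiple regression within 2%", {
  for (seed in c(11, 23)) {
    k <- sample(2:5, 1)
    causal_ix <- seq(5, 45, length.out = k)
    fx <- make_individual_fixture(seed, causal_ix = round(causal_ix))
    cond_set <- fx$ld$variants$snp[round(causal_ix)[-1]]
    cond <- conditional_stats(fx$ds, fx$ld, condition_on = cond_set)
    # targets with a real signal: the remaining causal variant
    target <- fx$ld$variants$snp[round(causal_ix)[1]]
    got <- cond$variants[cond$variants$snp == target, ]
    oracle <- lm(fx$y ~ fx$X[, c(round(causal_ix)[1], round(causal_ix)[-1])])
    want <- coef(oracle)[2]
    expect_equal(got$beta, unname(want), tolerance = 0.02)
  }
})

test_that("conditioning on the causal variant collapses its tags", {
  fx <- make_individual_fixture(77, causal_ix = 25, causal_beta = 0.15)
  causal <- fx$ld$variants$snp[25]
  tags <- fx$ld$variants$snp[c(23, 24, 26, 27)]
  marg_z <- abs(fx$ds$variants$beta / fx$ds$variants$se)[
    match(tags, fx$ds$variants$snp)]
  expect_true(all(marg_z > 4))  # tags carry the signal marginally
  cond <- conditional_stats(fx$ds, fx$ld, condition_on = causal)
  cz <- abs(cond$variants$beta / cond$variants$se)[
    match(tags, cond$variants$snp)]
  expect_true(all(cz < 3))
  expect_lt(mean(cz), mean(marg_z) / 3)
})

test_that("stepwise selection finds one signal per causal variant", {
  # single causal: exactly one signal led by the top marginal variant
  fx1 <- make_individual_fixture(401, causal_ix = 25, causal_beta = 0.12)
  sig1 <- stepwise_select(fx1$ds, fx1$ld, p_select = 5e-8)
  expect_length(sig1, 1)
  expect_equal(sig1[[1]]$lead_variant_id,
               fx1$ds$variants$snp[which.min(fx1$ds$variants$p)])
  # the single-signal conditional dataset is the marginal data
  expect_equal(sig1[[1]]$conditional_dataset$variants, fx1$ds$variants)
  # no qualifying variant: empty list
  expect_length(stepwise_select(fx1$ds, fx1$ld, p_select = 1e-300), 0)
})

test_that("two unlinked strong causal variants yield two signals in most replicates", {
  hits <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    fx <- make_individual_fixture(800 + r, n_ind = 4000,
                                  causal_ix = c(15, 35),
                                  causal_beta = c(0.25, 0.22))
    sig <- stepwise_select(fx$ds, fx$ld, p_select = 5e-8)
    hits <- hits + (length(sig) == 2)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("pwcoco reduces to plain colocalisation for single-signal regions", {
  ld <- simulate_ld_reference(5000, 100, block_size = 25, rho = 0.9,
                              seed = 55)
  R <- ld_cor(ld, ld$variants$snp)
  f <- ld$variants$eaf
  b <- 14 / sqrt(30000) / sqrt(2 * f[50] * (1 - f[50]))
  d1 <- simulate_gwas(ld, data.frame(index = 50, beta = b), quant_trait(),
                      30000, seed = 9, R = R)
  b2 <- 9 / sqrt(8000) / sqrt(2 * f[50] * (1 - f[50]))
  d2 <- simulate_gwas(ld, data.frame(index = 50, beta = b2), cc_trait(),
                      50000, seed = 10, R = R)
  pw <- pwcoco(d1, d2, ld)
  plain <- coloc_posteriors(d1, d2)
  expect_equal(pw$max_h4, plain$pp_h4, tolerance = 1e-6)
  expect_equal(nrow(pw$pair_results), 1L)
  expect_equal(pw$pair_results$exposure_signal, "marginal")
})

test_that("pwcoco errors on disjoint regions", {
  d1 <- toy_dataset(3)
  v <- toy_variants(3)
  v$snp <- paste0("w", 1:3)
  d2 <- region_dataset(v, trait = cc_trait())
  ld <- simulate_ld_reference(100, 10, seed = 1)
  expect_error(pwcoco(d1, d2, ld), "no shared variants")
})

test_that("conditional decomposition rescues a second shared signal", {
  # exposure has two signals; the outcome shares only the weaker one, so
  # marginal colocalisation fails but the conditional pair succeeds
  ld <- simulate_ld_reference(5000, 200, block_size = 25, rho = 0.9,
                              seed = 66)
  R <- ld_cor(ld, ld$variants$snp)
  f <- ld$variants$eaf
  i_big <- 88; i_shared <- 113
  rescued <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    bx <- c(18, 12) / sqrt(30000) /
      sqrt(2 * f[c(i_big, i_shared)] * (1 - f[c(i_big, i_shared)]))
    d1 <- simulate_gwas(ld, data.frame(index = c(i_big, i_shared), beta = bx),
                        quant_trait(), 30000, seed = 4000 + 2 * r, R = R)
    by <- 9 / sqrt(8000) / sqrt(2 * f[i_shared] * (1 - f[i_shared]))
    d2 <- simulate_gwas(ld, data.frame(index = i_shared, beta = by),
                        cc_trait(), 50000, seed = 4001 + 2 * r, R = R)
    pw <- pwcoco(d1, d2, ld)
    marginal_h4 <- pw$pair_results$PP.H4[
      pw$pair_results$exposure_signal == "marginal"]
    rescued <- rescued + (marginal_h4 < 0.8 && pw$max_h4 >= 0.8)
  }
  expect_gte(rescued / reps, 0.8)
})
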