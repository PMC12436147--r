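#' Simulate a block-LD genotype reference panel
#'
#' Generates dosages for `n_ind` individuals at `n_var` variants arranged in
#' LD blocks. Within a block, haplotypes are thresholded first-order
#' autoregressive latent Gaussians with correlation `rho` between adjacent
#' variants (so LD decays with distance inside a block); blocks are mutually
#' independent. Allele frequencies are drawn uniformly from `maf_range`.
#' Variant alleles are drawn from non-palindromic pairs so harmonisation of
#' simulated data is never frequency-ambiguous.
#'
#' @param n_ind Number of individuals (`>= 50`).
#' @param n_var Number of variants.
#' @param block_size Variants per LD block (default 25).
#' @param rho Adjacent-variant latent correlation in `[0, 1)` (default 0.9).
#' @param maf_range Frequency range, within `(0, 0.5]` (default `c(0.1, 0.5)`).
#' @param seed Integer seed; same seed, same panel.
#' @param chrom Chromosome label (default `"1"`).
#' @param region_start,region_bp Region origin and length in bp; variants are
#'   evenly spaced (defaults 9.5 Mb and 1 Mb).
#' @return An [ld_reference()] whose variant table also carries an `oa`
#'   column.
#' @export
simulate_ld_reference <- function(n_ind, n_var, block_size = 25, rho = 0.9,
                                  maf_range = c(0.1, 0.5), seed = 1,
                                  chrom = "1", region_start = 9.5e6,
                                  region_bp = 1e6) {
  stopifnot(n_ind >= 50, n_var >= 1, block_size >= 1, rho >= 0, rho < 1)
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be (lo, hi) with 0 < lo < hi <= 0.5")
  }
  set.seed(seed)
  f <- stats::runif(n_var, maf_range[1], maf_range[2])
  allele_pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                        c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
  pick <- sample(nrow(allele_pairs), n_var, replace = TRUE)

  latent_block <- function(m) {
    z <- matrix(stats::rnorm(n_ind * m), n_ind, m)
    if (m > 1 && rho > 0) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    z
  }
  haplotype <- function() {
    blocks <- split(seq_len(n_var), ceiling(seq_len(n_var) / block_size))
    z <- do.call(cbind, lapply(blocks, function(ix) latent_block(length(ix))))
    thr <- stats::qnorm(1 - f)
    t(t(z) > thr) * 1
  }
  dosages <- haplotype() + haplotype()

  variants <- data.frame(
    snp = sprintf("rs%05d", seq_len(n_var)),
    chr = chrom,
    pos = as.integer(round(seq(region_start, region_start + region_bp,
                               length.out = n_var))),
    ea = allele_pairs[pick, 1], oa = allele_pairs[pick, 2],
    eaf = colMeans(dosages) / 2,  # empirical frequency is the stated one
    stringsAsFactors = FALSE)
  ld_reference(variants, dosages, check = FALSE)
}

#' Effective sample size for association standard errors
#'
#' For quantitative traits this is `n`; for case-control traits the log-odds
#' standard error scales with `n * case_fraction * (1 - case_fraction)`.
#'
#' @param trait A [trait_meta()].
#' @param n GWAS sample size.
#' @return Effective n.
#' @export
effective_n <- function(trait, n) {
  if (trait$trait_type == "case_control") {
    n * trait$case_fraction * (1 - trait$case_fraction)
  } else n
}

#' Simulate GWAS summary statistics over an LD reference
#'
#' Draws marginal effect estimates directly from their sampling distribution:
#' true standardised marginal effects are the LD-propagated causal effects
#' `R %*% beta_std`, observed effects are multivariate normal around the
#' truth with covariance `resid_var * R / n_eff`, and standard errors are
#' `sqrt(resid_var / n_eff)` on the standardised scale — equivalently
#' `1/sqrt(2 f (1-f) n_eff)` per allele at unit residual variance. For
#' case-control traits effects are on the log-odds scale and `n_eff`
#' includes the `case_fraction * (1 - case_fraction)` scaling.
#'
#' @param ld An [ld_reference()] from [simulate_ld_reference()].
#' @param causal `data.frame` with columns `index` (variant column index) and
#'   `beta` (true per-allele effect); zero rows for a null trait.
#' @param trait A [trait_meta()].
#' @param n GWAS sample size (reported in the output `n` column).
#' @param resid_var Residual phenotypic variance (default 1).
#' @param seed Integer seed.
#' @param R Optional precomputed LD correlation matrix over all panel
#'   variants (saves recomputation in replicate loops).
#' @return A [region_dataset()] with one row per panel variant.
#' @export
simulate_gwas <- function(ld, causal, trait, n, resid_var = 1, seed = 1,
                          R = NULL) {
  stopifnot(inherits(ld, "ld_reference"), inherits(trait, "trait_meta"))
  m <- nrow(ld$variants)
  if (nrow(causal) && (any(causal$index < 1) || any(causal$index > m))) {
    stop("causal index out of range")
  }
  if (is.null(R)) R <- ld_cor(ld, ld$variants$snp)
  set.seed(seed)
  f <- ld$variants$eaf
  scale <- sqrt(2 * f * (1 - f))
  b_std <- numeric(m)
  if (nrow(causal)) {
    b_std[causal$index] <- b_std[causal$index] + causal$beta * scale[causal$index]
  }
  truth <- as.vector(R %*% b_std)
  n_eff <- effective_n(trait, n)
  se_std <- sqrt(resid_var / n_eff)
  ch <- chol(R + diag(1e-6, m))
  noise <- as.vector(t(ch) %*% stats::rnorm(m)) * se_std
  bhat_std <- truth + noise

  v <- data.frame(
    snp = ld$variants$snp, chr = ld$variants$chr, pos = ld$variants$pos,
    ea = ld$variants$ea,
    oa = if ("oa" %in% names(ld$variants)) ld$variants$oa else "X",
    eaf = f, beta = bhat_std / scale, se = se_std / scale,
    p = pmax(2 * stats::pnorm(-abs(bhat_std / se_std)), 1e-300),
    n = n, stringsAsFactors = FALSE)
  region_dataset(v, trait = trait, validate = FALSE)
}

scenario_labels <- c("tierA_shared", "tierB_shared", "tierC_trans",
                     "distinct_variants", "reverse_causation",
                     "heterogeneous", "pleiotropic", "null")

# Study-condition defaults for the scenario suite: 1 Mb region, 300 variants
# in 25-variant blocks, exposure GWAS n = 30,000 (quantitative), outcome GWAS
# n = 50,000 with 20% cases.
suite_defaults <- function() {
  list(n_ind = 5000, n_var = 300L, block_size = 25L, rho = 0.9,
       maf_range = c(0.1, 0.5), n_exp = 30000, n_out = 50000,
       case_fraction = 0.2)
}

#' Generate the labelled ground-truth scenario suite
#'
#' Produces one dataset bundle per scenario the pipeline must distinguish,
#' each with an expectation record describing which gates the end-to-end
#' analysis should pass or fail:
#' \describe{
#'   \item{tierA_shared}{strong cis instrument, shared causal variant, strong
#'     forward causal effect: expect Tier A.}
#'   \item{tierB_shared}{same architecture with a moderate causal effect
#'     (MR z-score around 5): expect Tier A or B — sampling noise on a z
#'     statistic spans the Bonferroni line, so the record separates the
#'     scenario from C/none rather than between A and B.}
#'   \item{tierC_trans}{the encoding gene sits on another chromosome, so the
#'     (strong, shared) instrument is trans: expect Tier C under
#'     cis-and-trans selection.}
#'   \item{distinct_variants}{exposure and outcome causal variants in
#'     different LD blocks (r^2 < 0.3), no causal effect: expect the
#'     colocalisation gate to fail with H3 > H4.}
#'   \item{reverse_causation}{the outcome's causal variant drives the
#'     exposure signal, so instruments explain more outcome variance:
#'     expect Steiger failure.}
#'   \item{heterogeneous}{six instruments with instrument-specific effects:
#'     expect the Cochran's Q gate to fail.}
#'   \item{pleiotropic}{eight instruments with a constant directional
#'     pleiotropic effect on the outcome: expect the Egger-intercept gate to
#'     fail.}
#'   \item{null}{instrumented exposure, no effect anywhere on the outcome:
#'     expect no tier and a failed FDR gate.}
#' }
#'
#' @param base_seed Integer seed; scenario `i` uses `base_seed * 100 + i`
#'   offsets for its panel, exposure and outcome draws.
#' @param conditions Study-condition list as from `suite_defaults()`
#'   (sample sizes, region geometry, LD structure).
#' @return Named list of scenario bundles; each bundle has `scenario` (label,
#'   `true_causal_effect`, `shared_variant`, `mode`, `seed`, `expectation`),
#'   `exposure`, `outcome` ([region_dataset()]s), `ld`, `gene`.
#' @export
scenario_suite <- function(base_seed = 1, conditions = suite_defaults()) {
  cf <- conditions
  exposure_trait <- trait_meta("biomarker", "quantitative", tissue = "blood",
                               qtl_type = "pqtl")
  outcome_trait <- trait_meta("condition", "case_control",
                              case_fraction = cf$case_fraction,
                              tissue = "other", qtl_type = "none")
  n_eff_exp <- cf$n_exp
  n_eff_out <- effective_n(outcome_trait, cf$n_out)

  # per-allele effect giving expected standardised z at the causal variant
  beta_for_z <- function(z, f, n_eff) z / sqrt(n_eff) / sqrt(2 * f * (1 - f))

  cis_gene <- function(ld) {
    center <- round(stats::median(ld$variants$pos))
    gene_region("GENE1", ld$variants$chr[1], center - 5000, center + 5000)
  }
  trans_gene <- gene_region("GENE2", "2", 5e6, 5.01e6)

  build <- function(i, label, make) {
    seed_ld <- base_seed * 100 + i
    ld <- simulate_ld_reference(cf$n_ind, cf$n_var, cf$block_size, cf$rho,
                                cf$maf_range, seed = seed_ld)
    R <- ld_cor(ld, ld$variants$snp)
    bundle <- make(ld, R, seed_ld)
    bundle$scenario$label <- label
    bundle$scenario$seed <- seed_ld
    bundle$ld <- ld
    bundle
  }

  # indices inside distinct LD blocks
  mid <- as.integer(round(cf$n_var / 2))
  blocks <- function(k) as.integer(round(seq(13, cf$n_var - 12,
                                             length.out = k)))

  shared_scenario <- function(z_exp, alpha, gene_fun, mode, expectation,
                              shared = TRUE) {
    function(ld, R, s) {
      f <- ld$variants$eaf
      bx <- beta_for_z(z_exp, f[mid], n_eff_exp)
      exposure <- simulate_gwas(ld, data.frame(index = mid, beta = bx),
                                exposure_trait, cf$n_exp, seed = s + 1, R = R)
      outcome <- simulate_gwas(ld, data.frame(index = mid, beta = alpha * bx),
                               outcome_trait, cf$n_out, seed = s + 2, R = R)
      gene <- if (identical(gene_fun, "trans")) trans_gene else cis_gene(ld)
      list(scenario = list(true_causal_effect = alpha, shared_variant = shared,
                           mode = mode, expectation = expectation),
           exposure = exposure, outcome = outcome, gene = gene)
    }
  }

  # Instrument strengths spread over a range of z-scores: the Egger
  # intercept is identified only when bx varies across instruments (the
  # ratio by/bx = alpha + c/bx must vary), so a constant-z design would
  # load any directional pleiotropy onto the slope instead.
  multi_instrument_scenario <- function(alphas, pleio_c, expectation,
                                        z_targets = NULL) {
    function(ld, R, s) {
      k <- length(alphas)
      if (is.null(z_targets)) z_targets <- rep(12, k)
      ix <- blocks(k)
      f <- ld$variants$eaf
      bx <- beta_for_z(z_targets, f[ix], n_eff_exp)
      exposure <- simulate_gwas(ld, data.frame(index = ix, beta = bx),
                                exposure_trait, cf$n_exp, seed = s + 1, R = R)
      outcome <- simulate_gwas(ld, data.frame(index = ix,
                                              beta = alphas * bx + pleio_c),
                               outcome_trait, cf$n_out, seed = s + 2, R = R)
      list(scenario = list(true_causal_effect = mean(alphas),
                           shared_variant = TRUE, mode = "cis_only",
                           expectation = expectation),
           exposure = exposure, outcome = outcome, gene = cis_gene(ld))
    }
  }

  # z_exp = 15 gives an essentially certain genome-wide cis instrument;
  # alpha is scaled so the expected MR z-score hits the stated target.
  alpha_for_mr_z <- function(z_target, z_exp = 15) {
    # MR z ~ outcome z at the shared variant: alpha * b_std * sqrt(n_eff_out)
    b_std <- z_exp / sqrt(n_eff_exp)
    z_target / (b_std * sqrt(n_eff_out))
  }

  suite <- list(
    tierA_shared = function(ld, R, s) shared_scenario(
      15, alpha_for_mr_z(8), "cis", "cis_only",
      list(tier_in = "A"))(ld, R, s),
    tierB_shared = function(ld, R, s) shared_scenario(
      15, alpha_for_mr_z(5), "cis", "cis_only",
      list(tier_in = c("A", "B")))(ld, R, s),
    tierC_trans = function(ld, R, s) shared_scenario(
      15, alpha_for_mr_z(8), "trans", "cis_and_trans",
      list(tier_in = "C"))(ld, R, s),
    distinct_variants = function(ld, R, s) {
      f <- ld$variants$eaf
      # adjacent LD blocks: mutually unlinked but both inside the +/-500 kb
      # colocalisation window anchored on the exposure's instrument
      ix <- blocks(6)
      i1 <- ix[3]; i2 <- ix[4]
      exposure <- simulate_gwas(
        ld, data.frame(index = i1, beta = beta_for_z(15, f[i1], n_eff_exp)),
        exposure_trait, cf$n_exp, seed = s + 1, R = R)
      outcome <- simulate_gwas(
        ld, data.frame(index = i2, beta = beta_for_z(10, f[i2], n_eff_out)),
        outcome_trait, cf$n_out, seed = s + 2, R = R)
      list(scenario = list(true_causal_effect = 0, shared_variant = FALSE,
                           mode = "cis_only",
                           expectation = list(gates = list(coloc_pass = FALSE),
                                              h3_gt_h4 = TRUE)),
           exposure = exposure, outcome = outcome, gene = cis_gene(ld))
    },
    reverse_causation = function(ld, R, s) {
      f <- ld$variants$eaf
      exposure <- simulate_gwas(
        ld, data.frame(index = mid, beta = beta_for_z(7.5, f[mid], n_eff_exp)),
        exposure_trait, cf$n_exp, seed = s + 1, R = R)
      outcome <- simulate_gwas(
        ld, data.frame(index = mid, beta = beta_for_z(15, f[mid], n_eff_out)),
        outcome_trait, cf$n_out, seed = s + 2, R = R)
      list(scenario = list(true_causal_effect = 0, shared_variant = TRUE,
                           mode = "cis_only",
                           expectation = list(gates = list(steiger_pass = FALSE))),
           exposure = exposure, outcome = outcome, gene = cis_gene(ld))
    },
    heterogeneous = function(ld, R, s) multi_instrument_scenario(
      c(1.5, -0.5, 1.0, 0.2, -1.2, 0.8) * alpha_for_mr_z(8), 0,
      list(gates = list(het_pass = FALSE)))(ld, R, s),
    # pleiotropy sized at ~6x the empirical Egger-intercept SE for this
    # architecture (~0.05 per allele: the instruments cluster away from
    # bx = 0, so the intercept is an extrapolation), giving the gate near
    # certain power without distorting the slope fit
    pleiotropic = function(ld, R, s) multi_instrument_scenario(
      rep(alpha_for_mr_z(4), 8), 0.30,
      list(gates = list(pleio_pass = FALSE)),
      z_targets = seq(10, 22, length.out = 8))(ld, R, s),
    null = function(ld, R, s) {
      f <- ld$variants$eaf
      exposure <- simulate_gwas(
        ld, data.frame(index = mid, beta = beta_for_z(15, f[mid], n_eff_exp)),
        exposure_trait, cf$n_exp, seed = s + 1, R = R)
      outcome <- simulate_gwas(ld, data.frame(index = integer(0),
                                              beta = numeric(0)),
                               outcome_trait, cf$n_out, seed = s + 2, R = R)
      list(scenario = list(true_causal_effect = 0, shared_variant = FALSE,
                           mode = "cis_only",
                           expectation = list(tier_in = "none",
                                              gates = list(fdr_pass = FALSE))),
           exposure = exposure, outcome = outcome, gene = cis_gene(ld))
    }
  )
  out <- vector("list", length(scenario_labels))
  names(out) <- scenario_labels
  for (i in seq_along(scenario_labels)) {
    lab <- scenario_labels[i]
    out[[lab]] <- build(i, lab, suite[[lab]])
  }
  out
}

#' Write a scenario bundle to disk
#'
#' Writes the exposure and outcome summary statistics in the standard TSV
#' dialect, the LD reference, the gene annotation, and the expectation record
#' as plain text.
#'
#' @param bundle One element of [scenario_suite()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(bundle$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(bundle$outcome, file.path(dir, "outcome.tsv"))
  write_ld_reference(bundle$ld, file.path(dir, "ld"))
  g <- bundle$gene
  utils::write.table(
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(
    utils::capture.output(utils::str(bundle$scenario)),
    file.path(dir, "expectation.txt"))
  invisible(dir)
}
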