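# Small in-code fixtures and independent oracles shared across test files.

quant_trait <- function(id = "exp") {
  trait_meta(id, "quantitative", tissue = "blood", qtl_type = "pqtl")
}

cc_trait <- function(id = "out", cf = 0.2) {
  trait_meta(id, "case_control", case_fraction = cf, tissue = "other",
             qtl_type = "none")
}

# A hand-built variant table; all rows valid unless perturbed by the caller.
toy_variants <- function(n = 5, chr = "1", pos0 = 1000L) {
  z <- seq(2, 6, length.out = n)
  se <- rep(0.02, n)
  data.frame(
    snp = paste0("v", seq_len(n)), chr = chr,
    pos = pos0 + seq_len(n) * 100L,
    ea = rep(c("A", "C"), length.out = n), oa = rep(c("G", "T"), length.out = n),
    eaf = seq(0.15, 0.45, length.out = n),
    beta = z * se, se = se, p = 2 * pnorm(-z), n = 10000L,
    stringsAsFactors = FALSE)
}

toy_dataset <- function(n = 5, trait = quant_trait(), ...) {
  region_dataset(toy_variants(n, ...), trait = trait)
}

# Brute-force enumeration oracle for single-causal-variant colocalisation:
# sums Bayes factors over every configuration explicitly, in plain
# arithmetic, independent of the log-sum-exp path under test.
coloc_bruteforce <- function(d1, d2, priors, sd1, sd2) {
  shared <- intersect(d1$variants$snp, d2$variants$snp)
  v1 <- d1$variants[match(shared, d1$variants$snp), ]
  v2 <- d2$variants[match(shared, d2$variants$snp), ]
  abf <- function(beta, se, sd) {
    z <- beta / se; v <- se^2; w <- sd^2
    sqrt(v / (v + w)) * exp(z^2 / 2 * w / (v + w))
  }
  bf1 <- abf(v1$beta, v1$se, sd1)
  bf2 <- abf(v2$beta, v2$se, sd2)
  m <- length(shared)
  h0 <- 1
  h1 <- priors$p1 * sum(bf1)
  h2 <- priors$p2 * sum(bf2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) h3 <- h3 + bf1[i] * bf2[j]
  }
  h3 <- priors$p1 * priors$p2 * h3
  h4 <- priors$p12 * sum(bf1 * bf2)
  tot <- h0 + h1 + h2 + h3 + h4
  c(h0, h1, h2, h3, h4) / tot
}

# Individual-level oracle: marginal summary statistics computed by per-variant
# simple regression on real (simulated) genotypes, for comparing the
# summary-statistic conditional analysis against multiple regression.
marginal_stats_from_genotypes <- function(X, y, ld_variants, trait) {
  n <- length(y)
  beta <- se <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm.fit(cbind(1, X[, j]), y)
    beta[j] <- fit$coefficients[2]
    s2 <- sum(fit$residuals^2) / (n - 2)
    beta_se <- sqrt(s2 / sum((X[, j] - mean(X[, j]))^2))
    se[j] <- beta_se
  }
  v <- data.frame(
    snp = ld_variants$snp, chr = ld_variants$chr, pos = ld_variants$pos,
    ea = ld_variants$ea, oa = ld_variants$oa, eaf = ld_variants$eaf,
    beta = beta, se = se, p = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
    n = n, stringsAsFactors = FALSE)
  region_dataset(v, trait = trait, validate = FALSE)
}

# Individual-level fixture: phenotype simulated on the panel's own genotypes,
# marginal statistics from per-variant regressions, so the summary-level
# conditional machinery can be compared against full multiple regression.
make_individual_fixture <- function(seed, n_ind = 10000, n_var = 50,
                                    causal_ix = c(10, 30), causal_beta = NULL) {
  ld <- simulate_ld_reference(n_ind, n_var, block_size = 10, rho = 0.9,
                              seed = seed)
  X <- ld$dosages
  set.seed(seed + 1)
  if (is.null(causal_beta)) causal_beta <- rep(0.08, length(causal_ix))
  g <- as.vector(X[, causal_ix, drop = FALSE] %*% causal_beta)
  y <- g + rnorm(n_ind, 0, sqrt(max(1 - var(g), 0.5)))
  ds <- marginal_stats_from_genotypes(X, y, ld$variants, quant_trait())
  list(ld = ld, X = X, y = y, ds = ds)
}

# Summary-level simulator for independent (unlinked) instruments: observed
# exposure/outcome effects for k valid instruments of a true causal effect.
sim_independent_instruments <- function(k, alpha, n_exp, n_out, seed,
                                        z_range = c(8, 15),
                                        pleio = rep(0, k)) {
  set.seed(seed)
  sx <- rep(1 / sqrt(n_exp), k)
  sy <- rep(1 / sqrt(n_out), k)
  bx_true <- runif(k, z_range[1], z_range[2]) * sx
  bx <- bx_true + rnorm(k, 0, sx)
  by <- alpha * bx_true + pleio + rnorm(k, 0, sy)
  list(bx = bx, sx = sx, by = by, sy = sy, bx_true = bx_true)
}
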