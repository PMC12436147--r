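---
title: "Methods: tiered drug-target prioritisation with MR and conditional colocalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered drug-target prioritisation with MR and conditional colocalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtier)
```

## The question and the model

A molecular biomarker (a circulating protein, or the expression of its
encoding gene) is a plausible drug target for a disease when genetic
variation that shifts the biomarker also shifts disease risk, through the
biomarker. `mrtier` operationalises that judgement as a pipeline of
falsifiable gates rather than a single statistic, because each individual
line of evidence has a characteristic failure mode:

* **Two-sample MR** estimates the causal effect of exposure on outcome from
  per-variant summary effects in two separate GWAS. It assumes the variants
  affect the outcome only through the exposure — violated by pleiotropy —
  and that effects are homogeneous across instruments.
* **Steiger filtering** guards against reverse causation: a variant whose
  primary phenotype is the *outcome* will explain more outcome than
  exposure variance, and the MR estimate built on it is not evidence for
  the forward direction.
* **Colocalisation** guards against LD confounding: a biomarker association
  and a disease association can sit in the same region under two distinct
  causal variants, in which case MR evidence is spurious at the
  variant level even if both signals are genuine.
* **Multiple-testing control** calibrates the scan across hundreds of
  biomarkers × several outcomes.

The tier classifier composes these into three grades of evidence. Tier A:
Bonferroni-significant (p ≤ 1.8×10⁻⁶), Steiger-pass, colocalising
(H4 ≥ 0.8), cis-only instruments, and no heterogeneity/pleiotropy evidence.
Tier B: the same with the FDR < 5% gate in place of Bonferroni. Tier C: as
B but the instrument set may include trans variants. Everything else that
passes FDR is recorded as `fdr_only`, the rest as `none`. The gate-to-tier
map is a pure function (`tier_from_gates()`), exhaustively tested over all
2⁷ gate combinations.

Two Bonferroni denominators appear in the defaults: the Tier-A gate uses
1.8×10⁻⁶ directly, while `adjust_pvalues()` computes thresholds from any
supplied test count (0.05/24,598 ≈ 2×10⁻⁶ for a full four-source ×
seven-outcome scan; 0.05/(7×736) ≈ 9.7×10⁻⁶ for the reverse pass). The two
close-but-different Tier-A values are both supported via
`tiering_thresholds()`; the tier definition's own number is the default and
the alternative is a documented config choice, since nothing in the
definitions forces them to coincide.

## Estimators and their numerical choices

**Wald ratio.** For one instrument, `b = by/bx` with the two-term
delta-method standard error `sqrt(sy²/bx² + by²·sx²/bx⁴)`. The ratio
distribution has heavier tails than the delta approximation (a parametric
bootstrap at typical instrument strength gives an SE about 2% larger); with
F ≥ 10 enforced upstream the approximation is standard practice. `bx = 0`
is an error by contract, not a silent `Inf`.

**IVW.** Zero-intercept weighted regression of outcome on exposure effects
with weights `1/sy²`. We report Cochran's Q with k−1 df and inflate the
fixed-effect SE by `max(1, sqrt(Q/(k−1)))` — a multiplicative
random-effects model. This choice (rather than strict fixed effects or an
additive random effect) mirrors the common default in two-sample MR
software: homogeneous sets reduce exactly to fixed-effect IVW, while
over-dispersed sets get proportionally wider intervals. A
`random_effects = FALSE` switch gives the fixed-effect variant. Wald and
IVW p-values use the normal; Egger uses t with k−2 df, where the small-k
penalty matters.

**MR-Egger.** Weighted least squares with a free intercept, after
orienting all pairs to non-negative exposure effects (negating both
members), which the intercept's interpretation as average directional
pleiotropy requires. Two facts drove the simulator design here and are
worth knowing when interpreting real data: the intercept is an
extrapolation to `bx = 0`, so its SE grows sharply when instruments
cluster in strength; and pleiotropy that is *proportional* to the
instrument effect loads on the slope, not the intercept — Egger can only
see pleiotropy to the extent that `by/bx` varies with `1/bx` across
instruments.

**Steiger.** Per-variant variance explained uses `2f(1−f)β²` for
quantitative traits (unit-variance phenotype) and `z²/(z² + n − 2)` from
the p-value and sample size otherwise. Case-control traits always use the
p/n form on the observed scale: liability-scale conversion would add
assumptions (prevalence) the gate does not need, since only the
*comparison* of the two r² matters. The comparison p-value is a Fisher-z
test using the smaller of the two sample sizes — conservative, and
immaterial by default because the gate is direction-only (an optional
p-threshold exists but is off; the tier definitions require a directional
pass, not a significance level on it).

**Colocalisation.** Wakefield log-ABFs per variant,
`0.5·[log(v/(v+w)) + z²·w/(v+w)]`, with prior effect SD 0.15 for
quantitative and 0.2 for case-control traits (the published defaults of
the underlying method), and configuration priors p1 = p2 = 1e−4,
p12 = 1e−5. Hypothesis sums use log-sum-exp throughout; H3's
"sum over ordered pairs i ≠ j" is computed as a log-difference
`logdiff(lse(l1)+lse(l2), lse(l1+l2))`, exact to working precision and
verified against brute-force enumeration at M ≤ 20 to 1e−10. Posteriors
are invariant to a common shift of all log-ABFs, so overflow never enters.

**Conditional analysis (PWCoCo).** Regions with several independent
signals defeat single-causal-variant colocalisation: the marginal signal
is dominated by the strongest association on each side, and a shared
secondary signal is invisible. `stepwise_select()` forward-selects index
variants at p ≤ 5e−8, recomputing conditional statistics from marginal
effects plus reference LD after each addition (effects are standardised
via allele frequencies; joint coefficients solve the LD normal equations;
the residual variance comes from the phenotypic variance implied by the
median per-variant `se`, `eaf`, `n`). Each signal is then represented by
the region conditioned on all *other* leads, and every exposure-signal ×
outcome-signal pair is colocalised along with the marginal–marginal pair;
the evidence gate uses the maximum H4. Numerical guards: variants with
r² > 0.9 to the conditioning set are omitted (no stable estimate exists),
|GWAS − reference| allele-frequency gaps over 0.2 drop the variant, and
near-singular LD systems fall back to a ridge-jittered solve. Conditional
estimates agree with individual-level multiple regression to well under 2%
when the reference panel is drawn from the GWAS population — the
regime the tests exercise; panel mismatch in real data degrades this.

**Harmonisation.** Variants are matched by id; swapped alleles flip
`beta` and `eaf`. Palindromic variants are retained only when both
frequencies are informative (outside [0.42, 0.58]) and agree on which
allele is minor; otherwise they are dropped with a logged reason. The
operation is idempotent and invariant to double allele flips — both
property-tested.

**Clumping** is greedy on ascending p (ties broken by genomic position for
determinism), removing candidates within the window at r² ≥ the threshold.
Variants absent from the LD panel are dropped rather than assumed
independent: assuming independence is exactly the error clumping exists to
prevent.

## What the simulator emulates — and what it does not

`simulate_ld_reference()` builds genotype panels as thresholded AR(1)
latent Gaussians in blocks: LD decays with distance within a block
(adjacent latent correlation 0.9 by default) and is zero between blocks.
`simulate_gwas()` draws marginal effect estimates directly from their
sampling distribution: truth is the LD-propagated causal vector `R·β_std`,
noise is MVN with covariance `R/n_eff`, and case-control traits scale the
effective sample size by `case_fraction·(1 − case_fraction)` on the
log-odds scale. Sampling summary statistics directly (rather than
regressing simulated phenotypes) is orders of magnitude faster and exact
for the quantities the pipeline consumes; the slower individual-level
route exists in the test suite as the independent oracle for the
conditional analysis and variance-explained formulas.

The default study conditions: 1 Mb regions of 300 variants in 25-variant
blocks, MAF uniform on [0.1, 0.5], exposure GWAS n = 30,000 (quantitative),
outcome GWAS n = 50,000 with 20% cases, and a reference panel of 5,000
individuals. The panel size is not cosmetic: clumping at r² < 0.001 needs
the panel's null-LD noise floor (E[r²] = 1/n) below the threshold, which
5,000 individuals satisfy and a few hundred do not — with a small panel,
genuinely independent instruments are spuriously clumped away. The same
consideration applies to real analyses with small reference panels.

`scenario_suite()` generates eight labelled architectures — strong and
moderate shared-variant causal effects (cis), a trans-instrumented
version, distinct causal variants, reverse causation, instrument
heterogeneity, directional pleiotropy, and a null — each with an
expectation record that `check_scenario()` evaluates after a full pipeline
run. Three design notes:

* The moderate scenario's expectation is "Tier A or B". Its MR z-score is
  targeted at 5, and a z statistic has sampling SD 1; no fixed effect size
  can land between the FDR and Bonferroni cutoffs in nearly all seeds, so
  the expectation separates the scenario from C/`none` (cis instruments,
  colocalisation, direction) rather than drawing an unstable line between
  A and B.
* The pleiotropic scenario spreads instrument z-scores over 10–22 (the
  Egger identifiability point above) and sizes the per-allele direct
  effect at ~6× the intercept SE computed for that architecture with the
  effect set to zero.
* The null scenario's FDR gate passes by chance in ~5% of seeds — that is
  what a 5% FDR means — so its expectation-met rate hovers near 95%, not
  100%.

What the simulator does **not** emulate: realistic human LD maps (block
AR(1) is a caricature), imputation error, sample overlap between exposure
and outcome GWAS, population stratification, allele-frequency drift
between GWAS and panel, or strand ambiguity resolved by anything other
than frequency. Passing tests therefore demonstrate the *machinery* is
correct under its stated assumptions, not that those assumptions hold in
any particular real dataset.

## Pipeline conventions

`run_forward()` analyses every exposure × outcome × selection-mode triple:
instruments → MR (+ diagnostics) → Steiger → colocalisation region of
±500 kb anchored on the colocalisation variant → PWCoCo → pooled FDR →
tier. The colocalisation variant is the best cis instrument when any cis
instrument exists, else the best trans instrument — cis anchoring keeps
the tested region biologically tied to the gene. FDR is pooled across the
whole run by default (a per-outcome option exists) because the tier
definitions speak of one FDR across the analyses; the Bonferroni
denominator defaults to the run's own test count and is configurable for
embedding a run in a larger family. Every input pair lands in exactly one
of the results table or the skip log, and rerunning with the same seeds
reproduces outputs exactly.

`run_reverse()` instruments the outcomes at 5×10⁻⁸ and relaxes to 5×10⁻⁷
for conditions with fewer than three surviving instruments — the fallback
exists because liability GWAS for some conditions are under-powered, and
two instruments leave no room for any consistency check. Cross-QTL
colocalisation (`cross_qtl_coloc()`) runs PWCoCo between the QTL sources
of a biomarker that reached a tier through more than one source, except
when a QTL lies in the MHC, whose LD structure makes colocalisation
unreliable; those pairs are skipped with an explicit reason.

The package exposes this surface as plain R functions over data frames
(the convention of the two-sample MR software family it belongs to) rather
than a shell tool; scripted use goes through `Rscript`, as
`scripts/acceptance.R` demonstrates.

## Problem sizes used in validation

The shipped validation uses: 500 IVW replicates (10 instruments,
n = 20,000/50,000); 2,000 Egger calibration replicates; 100 seeds each for
colocalisation discrimination and the PWCoCo rescue scenario (200-variant
regions, 5,000-individual panel); individual-level conditional oracles at
n = 10,000; 200 Steiger seeds per direction; and 20 suite seeds × 8
scenarios end to end. These sizes give Monte-Carlo error comfortably
inside the asserted bands while keeping a full run in minutes on one core.

## Known limitations

Single-causal-variant colocalisation per signal (no SuSiE-style
fine-mapping); no proxy-variant lookup for instruments missing from an
outcome GWAS; no multivariable MR, weighted-median/mode estimators, or
MR-PRESSO; variant matching is by id only (synthetic data controls ids;
real data would want a chrom:pos fallback); no liability-scale r²
conversion; and the MHC is flagged rather than modelled.
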