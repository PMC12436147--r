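#' Trait metadata
#'
#' Describes one GWAS trait: its identifier, measurement scale, and (for
#' molecular exposures) which QTL class and tissue it comes from. Case-control
#' traits must carry the case fraction so that effective sample sizes can be
#' computed downstream; quantitative traits must not.
#'
#' @param trait_id Character scalar identifying the trait.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param case_fraction Proportion of cases in `(0, 1)`; required exactly when
#'   `trait_type = "case_control"`.
#' @param tissue `"blood"`, `"brain"` or `"other"`.
#' @param qtl_type `"pqtl"`, `"eqtl"` or `"none"` (disease outcomes).
#' @return An object of class `trait_meta`.
#' @export
trait_meta <- function(trait_id,
                       trait_type = c("quantitative", "case_control"),
                       case_fraction = NULL,
                       tissue = c("blood", "brain", "other"),
                       qtl_type = c("pqtl", "eqtl", "none")) {
  trait_type <- match.arg(trait_type)
  tissue <- match.arg(tissue)
  qtl_type <- match.arg(qtl_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L, nzchar(trait_id))
  if (trait_type == "case_control") {
    if (is.null(case_fraction) || !is.finite(case_fraction) ||
        case_fraction <= 0 || case_fraction >= 1) {
      stop("case_fraction in (0,1) is required for case_control traits")
    }
  } else if (!is.null(case_fraction)) {
    stop("case_fraction must be absent for quantitative traits")
  }
  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         case_fraction = case_fraction, tissue = tissue, qtl_type = qtl_type),
    class = "trait_meta"
  )
}

#' @export
print.trait_meta <- function(x, ...) {
  cat(sprintf("<trait_meta> %s [%s, %s, %s]\n",
              x$trait_id, x$trait_type, x$tissue, x$qtl_type))
  invisible(x)
}

variant_columns <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

# Default header names for the on-disk summary-statistic dialect.
default_dialect <- function() {
  c(snp = "SNP", chr = "CHR", pos = "POS", ea = "EA", oa = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N")
}

#' Construct a region dataset
#'
#' A `region_dataset` holds all per-variant summary associations for one trait
#' in one (optionally windowed) genomic stretch, sorted by chromosome and
#' position. Rows violating the per-variant validity rules are dropped and
#' logged rather than raising an error, matching how GWAS files are cleaned in
#' practice.
#'
#' Validity per variant: `se > 0`; `p` in `(0, 1]`; `n >= 1`; alleles present
#' and different; `eaf` in `(0, 1)` when present (invalid frequencies are set
#' to missing rather than dropping the row); and `p` consistent with
#' `2 * pnorm(-|beta/se|)` within 10% relative tolerance on the z scale.
#'
#' @param variants `data.frame` with columns `snp, chr, pos, ea, oa, eaf,
#'   beta, se, p, n` (`eaf` may be `NA`).
#' @param trait A [trait_meta()] object.
#' @param window Optional `list(chr =, start =, end =)` recording the region
#'   the variants were extracted from (1-based, closed).
#' @param validate Drop invalid rows (default `TRUE`).
#' @return `region_dataset`: list with elements `trait`, `variants`, `window`,
#'   `drop_log` (data.frame of `variant_id`, `reason`), `empty_region` flag.
#' @export
region_dataset <- function(variants, trait, window = NULL, validate = TRUE) {
  stopifnot(inherits(trait, "trait_meta"), is.data.frame(variants))
  missing_cols <- setdiff(variant_columns, names(variants))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  v <- variants[variant_columns]
  v$snp <- as.character(v$snp)
  v$chr <- as.character(v$chr)
  v$pos <- as.integer(v$pos)
  v$ea <- toupper(as.character(v$ea))
  v$oa <- toupper(as.character(v$oa))
  for (col in c("eaf", "beta", "se", "p")) v[[col]] <- as.numeric(v[[col]])
  v$n <- as.numeric(v$n)

  drop_log <- data.frame(variant_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (validate && nrow(v)) {
    bad_eaf <- !is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1)
    v$eaf[bad_eaf] <- NA_real_
    reason <- rep(NA_character_, nrow(v))
    ok_num <- is.finite(v$beta) & is.finite(v$se) & is.finite(v$p) &
      is.finite(v$n) & is.finite(v$pos)
    reason[!ok_num] <- "non-finite required field"
    reason[is.na(reason) & v$se <= 0] <- "non-positive se"
    reason[is.na(reason) & (v$p <= 0 | v$p > 1)] <- "p outside (0,1]"
    reason[is.na(reason) & v$n < 1] <- "n < 1"
    reason[is.na(reason) & (!nzchar(v$ea) | !nzchar(v$oa) | v$ea == v$oa)] <-
      "invalid alleles"
    # z implied by p vs z from beta/se, 10% relative tolerance; only testable
    # away from the double-precision floor of pnorm.
    idx <- which(is.na(reason))
    if (length(idx)) {
      z_obs <- abs(v$beta[idx] / v$se[idx])
      z_p <- stats::qnorm(pmin(v$p[idx], 1) / 2, lower.tail = FALSE)
      testable <- is.finite(z_p) & z_p > 0.1 & z_obs > 0.1 & v$p[idx] > 1e-300
      mismatch <- testable & abs(z_obs - z_p) > 0.1 * pmax(z_obs, z_p)
      reason[idx[mismatch]] <- "p inconsistent with beta/se"
    }
    bad <- !is.na(reason)
    if (any(bad)) {
      drop_log <- data.frame(variant_id = v$snp[bad], reason = reason[bad],
                             stringsAsFactors = FALSE)
      v <- v[!bad, , drop = FALSE]
    }
  }
  v <- v[order(v$chr, v$pos, v$snp), , drop = FALSE]
  if (anyDuplicated(v$snp)) {
    dup <- duplicated(v$snp)
    drop_log <- rbind(drop_log,
                      data.frame(variant_id = v$snp[dup],
                                 reason = "duplicate variant_id",
                                 stringsAsFactors = FALSE))
    v <- v[!dup, , drop = FALSE]
  }
  rownames(v) <- NULL
  structure(
    list(trait = trait, variants = v, window = window,
         drop_log = drop_log, empty_region = nrow(v) == 0L),
    class = "region_dataset"
  )
}

#' @export
print.region_dataset <- function(x, ...) {
  w <- if (is.null(x$window)) "unwindowed" else
    sprintf("%s:%d-%d", x$window$chr, x$window$start, x$window$end)
  cat(sprintf("<region_dataset> %s: %d variants (%s), %d dropped\n",
              x$trait$trait_id, nrow(x$variants), w, nrow(x$drop_log)))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated summary-statistic table (gzip-transparent), renames
#' columns according to `dialect`, validates each row, and returns a
#' [region_dataset()]. A dialect that does not map an `eaf` column yields a
#' dataset with all frequencies missing; variance-explained computations then
#' fall back to the p-value/sample-size method.
#'
#' @param path Path to a TSV (optionally gzipped) with a header row.
#' @param trait A [trait_meta()] object.
#' @param dialect Named character vector mapping internal names
#'   (`snp, chr, pos, ea, oa, eaf, beta, se, p, n`) to file column names;
#'   defaults to `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`. `eaf` is the
#'   only optional mapping.
#' @return A [region_dataset()].
#' @export
read_summary_stats <- function(path, trait, dialect = default_dialect()) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty summary-statistic file: ", path)
  required <- setdiff(variant_columns, "eaf")
  missing_map <- setdiff(required, names(dialect))
  if (length(missing_map)) {
    stop("dialect does not map required field(s): ",
         paste(missing_map, collapse = ", "))
  }
  for (field in required) {
    if (!dialect[[field]] %in% names(tab)) {
      stop("missing required column in file: ", dialect[[field]])
    }
  }
  out <- data.frame(row.names = seq_len(nrow(tab)))
  for (field in variant_columns) {
    out[[field]] <- if (field %in% names(dialect) &&
                        dialect[[field]] %in% names(tab)) {
      tab[[dialect[[field]]]]
    } else if (field == "eaf") NA_real_ else
      stop("unreachable")  # required fields checked above
  }
  region_dataset(out, trait = trait)
}

#' Write a region dataset back to the summary-statistic dialect
#'
#' @param ds A [region_dataset()].
#' @param path Output TSV path.
#' @param dialect Column-name mapping as in [read_summary_stats()].
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ds, path, dialect = default_dialect()) {
  stopifnot(inherits(ds, "region_dataset"))
  out <- ds$variants
  names(out) <- unname(dialect[names(out)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the drop log of a dataset or harmonised pair
#'
#' @param x A [region_dataset()] or [harmonise_pair()] result.
#' @param path Output TSV path with columns `variant_id`, `reason`.
#' @return `path`, invisibly.
#' @export
write_drop_log <- function(x, path) {
  log <- if (inherits(x, "region_dataset")) x$drop_log else x$dropped
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a window of variants around a position
#'
#' Returns the variants whose position lies in the closed interval
#' `[center - half_width, center + half_width]` on `chrom`. An empty window is
#' not an error: the result carries `empty_region = TRUE`.
#'
#' @param ds A [region_dataset()].
#' @param chrom Chromosome (character).
#' @param center Centre position (bp, 1-based).
#' @param half_width Half-width in bp (`>= 0`).
#' @return A windowed [region_dataset()].
#' @export
extract_region <- function(ds, chrom, center, half_width) {
  stopifnot(inherits(ds, "region_dataset"), half_width >= 0)
  chrom <- as.character(chrom)
  lo <- center - half_width
  hi <- center + half_width
  keep <- ds$variants$chr == chrom & ds$variants$pos >= lo & ds$variants$pos <= hi
  region_dataset(ds$variants[keep, , drop = FALSE], trait = ds$trait,
                 window = list(chr = chrom, start = lo, end = hi),
                 validate = FALSE)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonise two summary-statistic datasets onto shared effect alleles
#'
#' Matches variants by id, flips outcome effects (`beta -> -beta`,
#' `eaf -> 1 - eaf`) where the outcome's alleles are recorded in the opposite
#' order to the exposure's, and drops variants whose alleles cannot be
#' reconciled. Palindromic variants (A/T, C/G) are strand-ambiguous;
#' following standard two-sample-MR practice they are kept only when both
#' allele frequencies are informative — outside
#' `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]` — and fall on the same
#' side of 0.5 after alignment.
#'
#' @param exposure,outcome [region_dataset()]s for the two traits.
#' @param palindrome_eaf_limit Frequency band half-limit; default `0.42`.
#' @return `harmonised_pair`: list with `exposure` and `outcome` datasets
#'   restricted to the shared, allele-aligned variants (identically ordered)
#'   and `dropped`, a data.frame of `variant_id`, `reason`.
#' @export
harmonise_pair <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "region_dataset"),
            inherits(outcome, "region_dataset"))
  ex <- exposure$variants
  ou <- outcome$variants
  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  add_drop <- function(ids, reason) {
    if (length(ids)) {
      dropped <<- rbind(dropped, data.frame(variant_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }
  add_drop(setdiff(ex$snp, ou$snp), "absent from outcome")
  add_drop(setdiff(ou$snp, ex$snp), "absent from exposure")
  shared <- intersect(ex$snp, ou$snp)
  if (!length(shared)) stop("no shared variants between exposure and outcome")
  ex <- ex[match(shared, ex$snp), , drop = FALSE]
  ou <- ou[match(shared, ou$snp), , drop = FALSE]

  same <- ex$ea == ou$ea & ex$oa == ou$oa
  swapped <- ex$ea == ou$oa & ex$oa == ou$ea & !same
  incompatible <- !(same | swapped)
  add_drop(shared[incompatible], "incompatible alleles")

  ou$beta[swapped] <- -ou$beta[swapped]
  ou$eaf[swapped] <- 1 - ou$eaf[swapped]
  ou$ea[swapped] <- ex$ea[swapped]
  ou$oa[swapped] <- ex$oa[swapped]

  pal <- is_palindromic(ex$ea, ex$oa) & !incompatible
  if (any(pal)) {
    lo <- palindrome_eaf_limit
    hi <- 1 - palindrome_eaf_limit
    informative <- function(f) !is.na(f) & (f < lo | f > hi)
    ok <- informative(ex$eaf) & informative(ou$eaf) &
      (ex$eaf - 0.5) * (ou$eaf - 0.5) > 0
    add_drop(shared[pal & !ok], "ambiguous palindrome")
    incompatible <- incompatible | (pal & !ok)
  }

  keep <- !incompatible
  if (!any(keep)) stop("no shared variants survive allele harmonisation")
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  structure(
    list(
      exposure = region_dataset(ex, trait = exposure$trait,
                                window = exposure$window, validate = FALSE),
      outcome = region_dataset(ou, trait = outcome$trait,
                               window = outcome$window, validate = FALSE),
      dropped = dropped
    ),
    class = "harmonised_pair"
  )
}

#' @export
print.harmonised_pair <- function(x, ...) {
  cat(sprintf("<harmonised_pair> %s ~ %s: %d shared variants, %d dropped\n",
              x$exposure$trait$trait_id, x$outcome$trait$trait_id,
              nrow(x$exposure$variants), nrow(x$dropped)))
  invisible(x)
}
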