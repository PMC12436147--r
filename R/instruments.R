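#' Gene region annotation
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome.
#' @param start,end 1-based inclusive gene-body coordinates, `start <= end`.
#' @return An object of class `gene_region`.
#' @export
gene_region <- function(gene_id, chrom, start, end) {
  stopifnot(start <= end)
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end)),
            class = "gene_region")
}

#' Read gene annotations from TSV
#'
#' Expects columns `gene_id, chrom, start, end` (1-based, inclusive).
#'
#' @param path Path to the annotation TSV.
#' @return Named list of [gene_region()] objects keyed by `gene_id`.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("gene annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    gene_region(tab$gene_id[i], tab$chrom[i], tab$start[i], tab$end[i])
  })
  names(out) <- tab$gene_id
  out
}

#' Default instrument-selection thresholds
#'
#' Genome-wide significance `p <= 5e-8`, clumping at `r^2 < 0.001` within a
#' 10,000 kb window, instrument strength `F >= 10`, cis defined as within
#' 1 Mb of the gene body, and the extended MHC interval chr6:25-34 Mb.
#'
#' @return Named list of thresholds.
#' @export
instrument_thresholds <- function() {
  list(p_threshold = 5e-8, clump_r2 = 0.001, clump_window_kb = 10000,
       f_min = 10, cis_half_width_bp = 1e6,
       mhc_interval = list(chr = "6", start = 25e6, end = 34e6))
}

#' Single-variant instrument strength
#'
#' F-statistic approximated per variant as `(beta/se)^2`; `F >= 10` is the
#' conventional weak-instrument gate.
#'
#' @param beta,se Marginal effect and standard error (`se > 0`). Vectorised.
#' @return Numeric F-statistic(s).
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Greedy LD clumping of associated variants
#'
#' Candidates with `p <= p_threshold` are sorted by ascending p-value (ties by
#' chromosome then position); the best is retained and all remaining
#' candidates within `window_kb` of it with `r^2 >= r2_threshold` are removed,
#' iterating until none remain. Variants on different chromosomes are treated
#' as unlinked. Candidates absent from the LD reference are dropped with a
#' warning rather than assumed independent.
#'
#' @param ds A [region_dataset()].
#' @param ld An [ld_reference()].
#' @param p_threshold Significance threshold (default `5e-8`).
#' @param r2_threshold LD pruning threshold (default `0.001`).
#' @param window_kb Clumping window in kb (default `10000`).
#' @return `data.frame` of retained variants (subset of `ds$variants` rows).
#' @export
clump <- function(ds, ld, p_threshold = 5e-8, r2_threshold = 0.001,
                  window_kb = 10000) {
  stopifnot(inherits(ds, "region_dataset"), inherits(ld, "ld_reference"))
  v <- ds$variants[ds$variants$p <= p_threshold, , drop = FALSE]
  if (!nrow(v)) return(v)
  in_ld <- v$snp %in% ld$variants$snp
  if (!all(in_ld)) {
    warning(sprintf("%d candidate(s) absent from LD reference dropped",
                    sum(!in_ld)))
    v <- v[in_ld, , drop = FALSE]
    if (!nrow(v)) return(v)
  }
  v <- v[order(v$p, v$chr, v$pos), , drop = FALSE]
  r2 <- ld_cor(ld, v$snp)^2
  window_bp <- window_kb * 1000
  keep <- logical(nrow(v))
  active <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))) {
    if (!active[i]) next
    keep[i] <- TRUE
    linked <- active & v$chr == v$chr[i] &
      abs(v$pos - v$pos[i]) <= window_bp & r2[i, ] >= r2_threshold
    active[linked] <- FALSE
    active[i] <- FALSE
  }
  out <- v[keep, , drop = FALSE]
  out[order(out$chr, out$pos), , drop = FALSE]
}

#' Classify a variant as cis or trans and flag the MHC
#'
#' A variant is cis when it lies on the gene's chromosome within
#' `cis_half_width` of the gene body (closed interval
#' `[start - cis_half_width, end + cis_half_width]`), trans otherwise. The
#' MHC flag marks variants in the extended major histocompatibility complex,
#' whose complex LD makes colocalisation unreliable.
#'
#' @param chr,pos Variant coordinates (vectorised).
#' @param gene A [gene_region()].
#' @param cis_half_width Cis window half-width in bp (default 1 Mb).
#' @param mhc_interval `list(chr =, start =, end =)`; default chr6:25-34 Mb.
#' @return `data.frame` with columns `locality` (`"cis"`/`"trans"`) and
#'   `mhc_flag`.
#' @export
classify_locality <- function(chr, pos, gene, cis_half_width = 1e6,
                              mhc_interval = instrument_thresholds()$mhc_interval) {
  stopifnot(inherits(gene, "gene_region"))
  chr <- as.character(chr)
  cis <- chr == gene$chrom &
    pos >= gene$start - cis_half_width & pos <= gene$end + cis_half_width
  mhc <- chr == mhc_interval$chr &
    pos >= mhc_interval$start & pos <= mhc_interval$end
  data.frame(locality = ifelse(cis, "cis", "trans"), mhc_flag = mhc,
             stringsAsFactors = FALSE)
}

#' Build the instrument set for one exposure
#'
#' Composes the selection rules: (optionally restrict to cis variants),
#' greedy LD [clump()], exclude weak instruments (`F < f_min`), and annotate
#' locality and MHC membership. In `cis_only` mode trans variants are removed
#' before clumping, mirroring the biologically informed selection approach;
#' `cis_and_trans` clumps all candidates jointly.
#'
#' @param ds A [region_dataset()] of genome- or region-wide associations for
#'   the exposure.
#' @param gene The exposure's [gene_region()].
#' @param ld An [ld_reference()].
#' @param mode `"cis_only"` or `"cis_and_trans"`.
#' @param thresholds Threshold list as from [instrument_thresholds()].
#' @return `instrument_set`: list with `exposure_id`, `gene`, `instruments`
#'   (variant data.frame with `f_stat`, `locality`, `mhc_flag` columns),
#'   `selection_mode`, and an `empty` flag.
#' @export
build_instrument_set <- function(ds, gene, ld,
                                 mode = c("cis_only", "cis_and_trans"),
                                 thresholds = instrument_thresholds()) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "region_dataset"), inherits(gene, "gene_region"))
  v <- ds$variants
  loc <- classify_locality(v$chr, v$pos, gene,
                           cis_half_width = thresholds$cis_half_width_bp,
                           mhc_interval = thresholds$mhc_interval)
  if (mode == "cis_only") {
    v <- v[loc$locality == "cis", , drop = FALSE]
  }
  cand <- region_dataset(v, trait = ds$trait, validate = FALSE)
  sel <- clump(cand, ld, p_threshold = thresholds$p_threshold,
               r2_threshold = thresholds$clump_r2,
               window_kb = thresholds$clump_window_kb)
  if (nrow(sel)) {
    sel$f_stat <- f_statistic(sel$beta, sel$se)
    sel <- sel[sel$f_stat >= thresholds$f_min, , drop = FALSE]
  }
  if (nrow(sel)) {
    ann <- classify_locality(sel$chr, sel$pos, gene,
                             cis_half_width = thresholds$cis_half_width_bp,
                             mhc_interval = thresholds$mhc_interval)
    sel$locality <- ann$locality
    sel$mhc_flag <- ann$mhc_flag
  } else {
    sel$f_stat <- numeric(0)
    sel$locality <- character(0)
    sel$mhc_flag <- logical(0)
  }
  rownames(sel) <- NULL
  structure(
    list(exposure_id = ds$trait$trait_id, gene = gene, instruments = sel,
         selection_mode = mode, empty = nrow(sel) == 0L),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s [%s]: %d instrument(s) (%d cis, %d trans)\n",
              x$exposure_id, x$selection_mode, nrow(x$instruments),
              sum(x$instruments$locality == "cis"),
              sum(x$instruments$locality == "trans")))
  invisible(x)
}
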