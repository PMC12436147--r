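#' LD reference panel
#'
#' A reference panel of genotype dosages from which pairwise variant
#' correlations are computed, standing in for an external cohort panel.
#'
#' @param variants `data.frame` with columns `snp, chr, pos, ea, eaf`
#'   (the stated allele frequency of the effect allele).
#' @param dosages Numeric matrix, individuals x variants, entries in `[0, 2]`,
#'   column order matching `variants`.
#' @param check Verify that empirical frequencies agree with the stated `eaf`
#'   within 0.05 (default `TRUE`).
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(variants, dosages, check = TRUE) {
  stopifnot(is.data.frame(variants), is.matrix(dosages),
            ncol(dosages) == nrow(variants))
  need <- c("snp", "chr", "pos", "ea", "eaf")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols)) {
    stop("LD reference variant table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  variants$snp <- as.character(variants$snp)
  variants$chr <- as.character(variants$chr)
  if (anyDuplicated(variants$snp)) stop("duplicate variant ids in LD reference")
  if (min(dosages) < 0 || max(dosages) > 2) stop("dosages must lie in [0, 2]")
  if (check) {
    emp <- colMeans(dosages) / 2
    off <- abs(emp - variants$eaf)
    if (any(off > 0.05, na.rm = TRUE)) {
      warning(sprintf(
        "%d variant(s) with empirical frequency > 0.05 from stated eaf",
        sum(off > 0.05, na.rm = TRUE)))
    }
  }
  colnames(dosages) <- variants$snp
  structure(list(variants = variants, dosages = dosages,
                 .cache = new.env(parent = emptyenv())),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d individuals x %d variants\n",
              nrow(x$dosages), nrow(x$variants)))
  invisible(x)
}

#' Pairwise LD correlations from a reference panel
#'
#' @param ld An [ld_reference()].
#' @param snps Variant ids to include (must all be present).
#' @return Correlation matrix (signed r) with `snps` as dimnames. Monomorphic
#'   columns get zero correlation with everything (and 1 on the diagonal).
#' @export
ld_cor <- function(ld, snps) {
  stopifnot(inherits(ld, "ld_reference"))
  idx <- match(snps, ld$variants$snp)
  if (anyNA(idx)) {
    stop("variant(s) absent from LD reference: ",
         paste(utils::head(snps[is.na(idx)], 5), collapse = ", "))
  }
  # the panel-wide matrix is computed once and subset thereafter
  if (is.null(ld$.cache$R)) {
    R <- suppressWarnings(stats::cor(ld$dosages))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    ld$.cache$R <- R
  }
  r <- ld$.cache$R[idx, idx, drop = FALSE]
  dimnames(r) <- list(snps, snps)
  r
}

#' Write an LD reference to disk as plain text
#'
#' Layout: `<stem>.variants.tsv` (columns `snp, chr, pos, ea, eaf`) and
#' `<stem>.dosages.tsv` (one row per individual, tab-separated dosages in
#' variant order, no header).
#'
#' @param ld An [ld_reference()].
#' @param stem Path stem for the two files.
#' @return `stem`, invisibly.
#' @export
write_ld_reference <- function(ld, stem) {
  utils::write.table(ld$variants, paste0(stem, ".variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ld$dosages, paste0(stem, ".dosages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' Read an LD reference written by [write_ld_reference()]
#'
#' @param stem Path stem used when writing.
#' @return An [ld_reference()].
#' @export
read_ld_reference <- function(stem) {
  variants <- utils::read.delim(paste0(stem, ".variants.tsv"),
                                stringsAsFactors = FALSE)
  dosages <- as.matrix(utils::read.delim(paste0(stem, ".dosages.tsv"),
                                         header = FALSE))
  dimnames(dosages) <- NULL
  ld_reference(variants, dosages)
}
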