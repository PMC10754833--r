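#' Phased haplotype panel
#'
#' Container for a phased biallelic panel: a binary allele matrix with one
#' row per haplotype (two consecutive rows per sample) and one column per
#' variant, plus per-variant metadata.
#'
#' @param alleles integer/numeric matrix of 0/1 alleles,
#'   `n_haplotypes x n_variants`.
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `maf` (recomputed from `alleles` when absent), one row per
#'   variant, sorted by `(chrom, pos)`.
#' @param sample_ids character vector, length `n_haplotypes / 2`; haplotype
#'   rows `2k - 1` and `2k` belong to sample `k`.
#' @return object of class `haplotype_panel` with elements `alleles`,
#'   `sites`, `sample_ids`.
#' @export
haplotype_panel <- function(alleles, sites, sample_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("n_haplotypes must be even (two phased haplotypes per sample)")
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L)))
    stop("allele matrix entries must be 0 or 1 with no missing values")
  stopifnot(is.data.frame(sites), nrow(sites) == ncol(alleles),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate positions per chromosome are not allowed")
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample%03d", seq_len(nrow(alleles) / 2L))
  stopifnot(length(sample_ids) == nrow(alleles) / 2L)
  sites$maf <- compute_maf(alleles)
  rownames(sites) <- NULL
  structure(list(alleles = alleles, sites = sites,
                 sample_ids = as.character(sample_ids)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d samples) x %d variants\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles)))
  cat(sprintf("  chrom %s, pos %d..%d; MAF %.4f..%.4f\n",
              paste(unique(x$sites$chrom), collapse = ","),
              min(x$sites$pos), max(x$sites$pos),
              min(x$sites$maf), max(x$sites$maf)))
  invisible(x)
}

#' Minor allele frequency per variant
#'
#' `maf_i = min(c_i, H - c_i) / H` where `c_i` is the alternate allele count
#' over the `H` haplotypes of the panel. The MAF used for loss weighting and
#' binning is always computed from the training panel.
#'
#' @param panel a [haplotype_panel()] or a 0/1 haplotype matrix.
#' @return numeric vector in `[0, 0.5]`, one entry per variant.
#' @export
compute_maf <- function(panel) {
  m <- if (inherits(panel, "haplotype_panel")) panel$alleles else as.matrix(panel)
  if (!nrow(m)) stop("empty panel")
  ac <- colSums(m)
  pmin(ac, nrow(m) - ac) / nrow(m)
}

#' Drop rare variants
#'
#' Restricts the panel to sites with `maf >= min_maf`, preserving order.
#' The published protocol removes sites with MAF below 0.005 before
#' training and evaluation.
#'
#' @param panel a [haplotype_panel()].
#' @param min_maf threshold in `[0, 0.5]`; boundary sites are kept.
#' @return filtered [haplotype_panel()].
#' @export
filter_rare <- function(panel, min_maf = 0.005) {
  stopifnot(inherits(panel, "haplotype_panel"), min_maf >= 0, min_maf <= 0.5)
  keep <- which(panel$sites$maf >= min_maf)
  subset_panel(panel, keep)
}

# restrict a panel to site indices (order preserved as given)
subset_panel <- function(panel, idx) {
  out <- panel
  out$alleles <- panel$alleles[, idx, drop = FALSE]
  out$sites <- panel$sites[idx, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

# canonical site key used for manifest/panel matching
site_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
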