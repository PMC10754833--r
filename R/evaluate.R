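#' Dosage R-squared
#'
#' Squared Pearson correlation between imputed dosages and true genotype
#' counts, computed from explicit covariance sums:
#' `R^2 = (sum (x - mean(x)) (y - mean(y)))^2 / (sum (x - mean(x))^2 sum (y - mean(y))^2)`.
#' If either vector has zero variance the correlation is undefined and
#' `NA` is returned; callers exclude (and report) such sites rather than
#' scoring them 0.
#'
#' @param x imputed dosage vector.
#' @param y true genotype count vector, same length (>= 2).
#' @return value in `[0, 1]`, or `NA` for degenerate input.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least two observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sum(dx * dy)^2 / (sxx * syy)
}

#' Overall dosage R-squared
#'
#' One [r_squared()] over all (sample, variant) pairs flattened, without
#' separating variants into MAF bins.
#'
#' @param dosages matrix `n_samples x n_variants` of imputed dosages.
#' @param truth matrix of true genotype counts, same shape.
#' @return value in `[0, 1]`, or `NA` if the flattened truth is constant.
#' @export
overall_r2 <- function(dosages, truth) {
  stopifnot(identical(dim(dosages), dim(truth)))
  r_squared(as.numeric(dosages), as.numeric(truth))
}

#' Average per-variant dosage R-squared
#'
#' [r_squared()] of each variant's dosage column against its truth column,
#' averaged over variants. Columns where the correlation is undefined
#' (typically monomorphic truth) are excluded from the mean; their count is
#' attached as attribute `n_excluded`.
#'
#' @inheritParams overall_r2
#' @return mean per-variant value in `[0, 1]` with attribute `n_excluded`.
#' @export
average_r2_per_variant <- function(dosages, truth) {
  stopifnot(identical(dim(dosages), dim(truth)), nrow(dosages) >= 2L)
  per <- vapply(seq_len(ncol(truth)), function(j)
    r_squared(dosages[, j], truth[, j]), numeric(1))
  excluded <- sum(is.na(per))
  if (excluded == ncol(truth)) stop("all variants degenerate: no R2 defined")
  structure(mean(per, na.rm = TRUE), n_excluded = excluded)
}

#' MAF-binned dosage R-squared
#'
#' Pools all (sample, variant) entries of the variants falling in each MAF
#' bin and computes one [r_squared()] per bin. Bins are keyed by the
#' training-panel MAF and are left-open, right-closed:
#' `(e_1, e_2], (e_2, e_3], ...`.
#'
#' @inheritParams overall_r2
#' @param panel_maf per-variant MAF from the training panel.
#' @param bin_edges increasing numeric vector of bin boundaries. The exact
#'   bin layout of published accuracy figures is not reproducible from the
#'   figures, so the default edges are a conventional spread over
#'   `(0.005, 0.5]`.
#' @return data frame with `maf_lo`, `maf_hi`, `r2`, `n_variants`; empty
#'   bins carry `NA` for `r2`.
#' @export
maf_binned_r2 <- function(dosages, truth, panel_maf,
                          bin_edges = c(0.005, 0.01, 0.02, 0.05, 0.1,
                                        0.2, 0.3, 0.4, 0.5)) {
  stopifnot(identical(dim(dosages), dim(truth)),
            ncol(dosages) == length(panel_maf),
            !is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1L
  out <- data.frame(maf_lo = bin_edges[-length(bin_edges)],
                    maf_hi = bin_edges[-1],
                    r2 = NA_real_, n_variants = 0L)
  bin <- findInterval(panel_maf, bin_edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  bin[panel_maf <= bin_edges[1] | panel_maf > bin_edges[length(bin_edges)]] <- NA
  for (b in seq_len(nb)) {
    j <- which(!is.na(bin) & bin == b)
    out$n_variants[b] <- length(j)
    if (length(j))
      out$r2[b] <- r_squared(as.numeric(dosages[, j, drop = FALSE]),
                             as.numeric(truth[, j, drop = FALSE]))
  }
  out
}

#' Evaluate an imputation result against a truth panel
#'
#' Convenience wrapper producing the full report: overall R-squared,
#' average per-variant R-squared (with exclusion count) and the MAF-binned
#' curve, plus an optional TSV report file.
#'
#' @param imputation a `grud_imputation` from [impute()], or a dosage
#'   matrix.
#' @param truth_panel a [haplotype_panel()] carrying the true genotypes of
#'   the same samples, or a genotype-count matrix aligned to the imputed
#'   variants.
#' @param panel_maf training-panel MAF per imputed variant (taken from the
#'   imputation's site metadata when available).
#' @param bin_edges passed to [maf_binned_r2()].
#' @param report_path optional TSV output path.
#' @return list with `overall_r2`, `average_r2_per_variant`, `n_excluded`,
#'   `per_bin`.
#' @export
evaluate_imputation <- function(imputation, truth_panel, panel_maf = NULL,
                                bin_edges = c(0.005, 0.01, 0.02, 0.05, 0.1,
                                              0.2, 0.3, 0.4, 0.5),
                                report_path = NULL) {
  if (inherits(imputation, "grud_imputation")) {
    dos <- imputation$dosages
    if (is.null(panel_maf)) panel_maf <- imputation$sites$maf
  } else dos <- as.matrix(imputation)
  truth <- if (inherits(truth_panel, "haplotype_panel")) {
    keys <- site_key(imputation$sites)
    hit <- match(keys, site_key(truth_panel$sites))
    if (anyNA(hit)) stop("truth panel is missing imputed variants")
    h <- truth_panel$alleles[, hit, drop = FALSE]
    odd <- seq(1L, nrow(h), by = 2L)
    h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  } else as.matrix(truth_panel)
  if (!identical(dim(dos), dim(truth)))
    stop("imputation and truth shapes differ")
  avg <- average_r2_per_variant(dos, truth)
  res <- list(overall_r2 = overall_r2(dos, truth),
              average_r2_per_variant = as.numeric(avg),
              n_excluded = attr(avg, "n_excluded"),
              per_bin = if (!is.null(panel_maf))
                maf_binned_r2(dos, truth, panel_maf, bin_edges) else NULL)
  if (!is.null(report_path)) {
    rows <- data.frame(metric = c("overall_r2", "average_r2_per_variant"),
                       maf_lo = NA, maf_hi = NA,
                       value = c(res$overall_r2, res$average_r2_per_variant),
                       n = c(length(panel_maf),
                             length(panel_maf) - res$n_excluded))
    if (!is.null(res$per_bin))
      rows <- rbind(rows, data.frame(metric = "maf_bin_r2",
                                     maf_lo = res$per_bin$maf_lo,
                                     maf_hi = res$per_bin$maf_hi,
                                     value = res$per_bin$r2,
                                     n = res$per_bin$n_variants))
    write.table(rows, report_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  res
}
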