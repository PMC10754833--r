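#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF (plain or bgzipped) with `VariantAnnotation`, keeps
#' biallelic records, and transcribes the phased GT field into a binary
#' haplotype matrix (two rows per sample). Multiallelic records are removed
#' with a warning giving the count; input must be pre-split upstream if they
#' are wanted.
#'
#' @param vcf_path path to a VCF file.
#' @param require_phased error on unphased ("/"-separated) genotypes. When
#'   `FALSE`, unphased heterozygotes are transcribed in file order, which is
#'   only acceptable for evaluation truth sets, not training panels.
#' @param missing_policy what to do with missing genotypes (`.`):
#'   `"error"` (default; a training panel must be complete) or
#'   `"drop_site"` (remove the affected variants, with a warning).
#' @return a [haplotype_panel()].
#' @export
read_panel <- function(vcf_path, require_phased = TRUE,
                       missing_policy = c("error", "drop_site")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  if (!("GT" %in% names(VariantAnnotation::geno(vcf))))
    stop("malformed VCF: no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1L
  if (any(multi))
    warning(sum(multi), " multiallelic record(s) removed")
  keep <- which(!multi)
  if (!length(keep)) stop("no biallelic records in ", vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  sites <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = as.character(VariantAnnotation::ref(vcf))[keep],
    alt = vapply(seq_along(keep), function(i)
      as.character(alt[[keep[i]]][1]), character(1)),
    stringsAsFactors = FALSE)

  has_missing <- apply(gt, 1, function(r) any(grepl(".", r, fixed = TRUE)))
  if (any(has_missing)) {
    if (missing_policy == "error")
      stop(sum(has_missing), " record(s) with missing genotypes; ",
           "set missing_policy = \"drop_site\" to remove them")
    warning(sum(has_missing), " record(s) with missing genotypes dropped")
    gt <- gt[!has_missing, , drop = FALSE]
    sites <- sites[!has_missing, , drop = FALSE]
  }
  if (!nrow(gt)) stop("no usable records after filtering")
  if (require_phased && any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes present; phase the input or set ",
         "require_phased = FALSE")

  a1 <- suppressWarnings(as.integer(sub("[/|].*$", "", gt)))
  a2 <- suppressWarnings(as.integer(sub("^[^/|]*[/|]", "", gt)))
  if (anyNA(a1) || anyNA(a2) || any(a1 > 1) || any(a2 > 1))
    stop("malformed GT field (expected 0|0 / 0|1 / 1|0 / 1|1)")
  nv <- nrow(gt); ns <- ncol(gt)
  hap <- matrix(0L, 2L * ns, nv)
  hap[seq(1L, 2L * ns, by = 2L), ] <- t(matrix(a1, nv, ns))
  hap[seq(2L, 2L * ns, by = 2L), ] <- t(matrix(a2, nv, ns))

  ord <- order(sites$chrom, sites$pos)
  haplotype_panel(hap[, ord, drop = FALSE], sites[ord, , drop = FALSE],
                  colnames(gt))
}

#' Write a haplotype panel as a phased VCF
#'
#' Deterministic serialiser for panels: VCF 4.2 with a single GT FORMAT
#' field, phased separators. Used for round-tripping panels and producing
#' truth/target files; the writer is plain-text (use `Rsamtools::bgzip` for
#' a compressed copy).
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (a trailing `.gz`/`.bgz` triggers bgzip
#'   compression of the written text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  gt_mat <- hap_to_gt_strings(panel$alleles)
  write_vcf_lines(panel$sites, panel$sample_ids,
                  format = "GT", body = gt_mat, path = path)
}

# alleles (2n x V) -> character matrix (V x n) of "a|b"
hap_to_gt_strings <- function(alleles) {
  ns <- nrow(alleles) / 2L
  h1 <- alleles[seq(1L, 2L * ns, by = 2L), , drop = FALSE]
  h2 <- alleles[seq(2L, 2L * ns, by = 2L), , drop = FALSE]
  matrix(paste0(t(h1), "|", t(h2)), ncol = ns)
}

write_vcf_lines <- function(sites, sample_ids, format, body, path,
                            extra_header = character(0)) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grud",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  fixed <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                 ".", "PASS", ".", format, sep = "\t")
  lines <- c(header, paste(fixed, apply(body, 1, paste, collapse = "\t"),
                           sep = "\t"))
  gz <- grepl("\\.(gz|bgz)$", path)
  plain <- if (gz) sub("\\.(gz|bgz)$", "", path) else path
  writeLines(lines, plain)
  if (gz) {
    Rsamtools::bgzip(plain, dest = path, overwrite = TRUE)
    unlink(plain)
  }
  invisible(path)
}

#' Write imputed genotypes to VCF
#'
#' Emits one record per imputed variant with FORMAT fields `GT` (phased
#' argmax alleles; a tie at probability 0.5 resolves to the reference
#' allele), `DS` (alternate allele dosage, three decimals) and `GP`
#' (genotype probabilities for 0/0, 0/1, 1/1, three decimals, computed from
#' the two haplotype probabilities assuming independence).
#'
#' @param sites data frame with `chrom`, `pos`, `ref`, `alt` for the imputed
#'   variants (rows ordered by position).
#' @param probabilities array `n_haplotypes x n_variants x 2` of allele
#'   probabilities (as returned by [impute()]).
#' @param dosages matrix `n_samples x n_variants` of alternate-allele
#'   dosages in `[0, 2]`.
#' @param out_path output VCF path.
#' @param sample_ids sample names, length `n_haplotypes / 2`.
#' @return `out_path`, invisibly.
#' @export
write_imputed_vcf <- function(sites, probabilities, dosages, out_path,
                              sample_ids = NULL) {
  stopifnot(length(dim(probabilities)) == 3L, dim(probabilities)[3] == 2L)
  nh <- dim(probabilities)[1]; nv <- dim(probabilities)[2]
  ns <- nh / 2L
  if (nv != nrow(sites) || !all(dim(dosages) == c(ns, nv)))
    stop("shape mismatch between sites, probabilities and dosages")
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%03d", seq_len(ns))
  p1 <- probabilities[seq(1L, nh, by = 2L), , 2, drop = FALSE][, , 1]
  p2 <- probabilities[seq(2L, nh, by = 2L), , 2, drop = FALSE][, , 1]
  p1 <- matrix(p1, ns, nv); p2 <- matrix(p2, ns, nv)
  a1 <- ifelse(p1 > 0.5, 1L, 0L)   # tie -> ref
  a2 <- ifelse(p2 > 0.5, 1L, 0L)
  gp00 <- (1 - p1) * (1 - p2)
  gp11 <- p1 * p2
  gp01 <- 1 - gp00 - gp11
  cell <- sprintf("%d|%d:%.3f:%.3f,%.3f,%.3f",
                  t(a1), t(a2), t(dosages), t(gp00), t(gp01), t(gp11))
  body <- matrix(cell, nrow = nv)
  write_vcf_lines(sites, sample_ids, format = "GT:DS:GP", body = body,
                  path = out_path, extra_header = c(
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype probabilities">',
    paste0("##grud_model_version=", GRUD_CHECKPOINT_VERSION)))
}

#' Read dosages back from an imputed VCF
#'
#' Companion reader for [write_imputed_vcf()]: extracts the `DS` field into
#' a samples-by-variants matrix, plus the site table.
#'
#' @param vcf_path path to a VCF with a DS FORMAT field.
#' @return list with `dosages` (matrix `n_samples x n_variants`), `sites`
#'   data frame and `sample_ids`.
#' @export
read_dosage_vcf <- function(vcf_path) {
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  ds <- VariantAnnotation::geno(vcf)$DS
  if (is.null(ds)) stop("no DS field in ", vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  sites <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_len(nrow(ds)), function(i)
      as.character(alt[[i]][1]), character(1)),
    stringsAsFactors = FALSE)
  m <- t(matrix(as.numeric(ds), nrow(ds), ncol(ds)))
  rownames(m) <- colnames(ds)
  list(dosages = m, sites = sites, sample_ids = colnames(ds))
}

#' Marker manifests
#'
#' A marker manifest designates the observed variants (the array or low-pass
#' call set) by exact `(chrom, pos, ref, alt)` key. On disk it is a headered
#' tab-separated file with those four columns.
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param path file path.
#' @param manifest a `marker_manifest`.
#' @return `marker_manifest()` and `read_manifest()` return a
#'   `marker_manifest` (a data frame); `write_manifest()` returns `path`
#'   invisibly.
#' @export
marker_manifest <- function(df) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  df <- df[order(df$chrom, df$pos), c("chrom", "pos", "ref", "alt")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (anyDuplicated(site_key(df))) stop("duplicate manifest entries")
  rownames(df) <- NULL
  class(df) <- c("marker_manifest", "data.frame")
  df
}

#' @rdname marker_manifest
#' @export
read_manifest <- function(path) {
  marker_manifest(read.table(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "integer",
                                            "character", "character")))
}

#' @rdname marker_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
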