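#' Impute unobserved genotypes with a trained checkpoint
#'
#' Runs the trained generator (evaluation mode, deterministic) on new
#' samples' observed genotypes, region by region, and concatenates the
#' regional outputs in genomic order. The checkpoint is self-describing:
#' no reference panel is needed. The target's variant keys must match the
#' checkpoint's observed-site keys exactly (`chrom:pos:ref:alt`).
#'
#' @param checkpoint a `grud_checkpoint` from [train_grud()] or
#'   [load_checkpoint()].
#' @param target a [haplotype_panel()] of the samples to impute (typically
#'   from [read_panel()] on the array/low-pass VCF), or a path to such a
#'   VCF. Extra target sites not used by the model are ignored.
#' @param missing_policy what to do when an observed marker required by the
#'   model is absent from the target: `"error"` (default) or
#'   `"panel_af"` (feed the training panel's alternate-allele frequency as
#'   a soft allele, with a warning).
#' @param unphased_het if `TRUE`, treat the target as unphased: at
#'   heterozygous sites both pseudo-haplotypes carry the averaged soft
#'   allele 0.5. Approximate; off by default.
#' @return object of class `grud_imputation`: list with `probabilities`
#'   (array `n_haplotypes x n_unobserved x 2`), `dosages` (matrix
#'   `n_samples x n_unobserved` in `[0, 2]`), `sites` (metadata of the
#'   imputed variants, position order) and `sample_ids`.
#' @export
impute <- function(checkpoint, target,
                   missing_policy = c("error", "panel_af"),
                   unphased_het = FALSE) {
  stopifnot(inherits(checkpoint, "grud_checkpoint"))
  missing_policy <- match.arg(missing_policy)
  if (is.character(target)) target <- read_panel(target)
  stopifnot(inherits(target, "haplotype_panel"))

  obs_sites <- checkpoint$sites[checkpoint$observed_idx, , drop = FALSE]
  need <- site_key(obs_sites)
  have <- site_key(target$sites)
  hit <- match(need, have)
  if (anyNA(hit)) {
    miss <- need[is.na(hit)]
    if (missing_policy == "error")
      stop(length(miss), " observed marker(s) required by the model are ",
           "missing from the target, e.g. ",
           paste(head(miss, 5), collapse = ", "),
           "; use missing_policy = \"panel_af\" to fill from panel ",
           "frequencies")
    warning(length(miss), " missing observed marker(s) filled with ",
            "training-panel allele frequencies")
  }
  nh <- nrow(target$alleles)
  X <- matrix(NA_real_, nh, length(need))
  ok <- !is.na(hit)
  X[, ok] <- target$alleles[, hit[ok], drop = FALSE]
  if (any(!ok)) X[, !ok] <- rep(checkpoint$obs_af[!ok], each = nh)
  if (unphased_het) {
    odd <- seq(1L, nh, by = 2L)
    het <- X[odd, , drop = FALSE] + X[odd + 1L, , drop = FALSE] == 1
    for (j in seq_len(ncol(X))) {
      rows <- which(het[, j])
      if (length(rows)) {
        X[2L * rows - 1L, j] <- 0.5
        X[2L * rows, j] <- 0.5
      }
    }
  }

  res <- impute_alleles(checkpoint, X)
  p_alt <- res$p_alt
  probs <- array(NA_real_, c(nh, ncol(p_alt), 2))
  probs[, , 1] <- 1 - p_alt
  probs[, , 2] <- p_alt
  odd <- seq(1L, nh, by = 2L)
  dos <- p_alt[odd, , drop = FALSE] + p_alt[odd + 1L, , drop = FALSE]
  dos <- pmin(pmax(dos, 0), 2)
  structure(list(probabilities = probs, dosages = dos,
                 sites = checkpoint$sites[res$target_idx, , drop = FALSE],
                 sample_ids = target$sample_ids),
            class = "grud_imputation")
}

# core eval-mode forward over all regions; X: haplotypes x n_observed
# (columns in checkpoint observed order), values in [0, 1].
# Haplotypes are processed in chunks to bound peak memory.
impute_alleles <- function(checkpoint, X, chunk = 128L) {
  parts <- list()
  gc_ <- checkpoint$gen_config
  nh <- nrow(X)
  starts <- seq(1L, nh, by = chunk)
  for (m in checkpoint$region_models) {
    if (is.null(m)) next
    net <- grud_net_create(m$n_input, gc_$feature_size, gc_$hidden_units,
                           gc_$num_layers, m$n_targets,
                           m$left - 1L, m$right - 1L, gc_$leaky_slope)
    grud_net_set_theta(net, m$theta)
    grud_net_set_bn(net, m$bn$mean, m$bn$var, m$bn$batches)
    Xr <- X[, m$input_obs_pos, drop = FALSE]
    p <- matrix(NA_real_, nh, m$n_targets)
    for (s0 in starts) {
      rows <- s0:min(s0 + chunk - 1L, nh)
      p[rows, ] <- grud_net_forward(net, Xr[rows, , drop = FALSE],
                                    FALSE)$p_alt
    }
    parts[[length(parts) + 1L]] <- list(p_alt = p, target_idx = m$target_idx)
  }
  if (!length(parts)) stop("checkpoint contains no trained regions")
  concat <- concat_regions(lapply(parts, `[[`, "p_alt"),
                           lapply(parts, `[[`, "target_idx"))
  concat
}

#' Concatenate per-region allele probabilities
#'
#' Joins regional outputs into one chromosome-wide matrix ordered by
#' genomic position (site index). Regions must cover disjoint target sets;
#' the result is independent of the order in which regions are supplied.
#'
#' @param prob_list list of matrices (haplotypes x region targets) of
#'   alternate-allele probabilities, or of `B x U x 2` arrays.
#' @param index_list list of integer site-index vectors aligning each
#'   matrix's columns to the genome.
#' @return list with `p_alt` (haplotypes x total targets, columns in
#'   increasing site order) and `target_idx` (the sorted indices).
#' @export
concat_regions <- function(prob_list, index_list) {
  stopifnot(length(prob_list) == length(index_list), length(prob_list) >= 1L)
  prob_list <- lapply(prob_list, function(p) {
    if (length(dim(p)) == 3L) p[, , 2, drop = TRUE] else p
  })
  idx <- unlist(index_list)
  if (anyDuplicated(idx))
    stop("regions overlap: duplicated unobserved indices")
  nh <- unique(vapply(prob_list, nrow, integer(1)))
  if (length(nh) != 1L) stop("regions disagree on haplotype count")
  all_p <- do.call(cbind, prob_list)
  ord <- order(idx)
  list(p_alt = all_p[, ord, drop = FALSE], target_idx = idx[ord])
}

#' @export
print.grud_imputation <- function(x, ...) {
  cat(sprintf("grud_imputation: %d samples x %d imputed variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}
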