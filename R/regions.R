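#' Split panel sites into observed and unobserved sets
#'
#' A panel site is observed iff its exact `(chrom, pos, ref, alt)` key
#' appears in the manifest; there is no allele flipping or position-only
#' matching, since a silent strand or allele swap would corrupt the dosage
#' evaluation. Manifest entries absent from the panel (chip markers the
#' panel does not carry) are ignored with a warning.
#'
#' @param panel a [haplotype_panel()].
#' @param manifest a [marker_manifest()].
#' @return list with integer site-index vectors `observed` and `unobserved`
#'   (1-based, strictly increasing, disjoint, jointly covering all sites).
#' @export
split_observed_unobserved <- function(panel, manifest) {
  pk <- site_key(panel$sites)
  mk <- site_key(manifest)
  missing <- setdiff(mk, pk)
  if (length(missing))
    warning(length(missing), " manifest marker(s) not present in the panel")
  observed <- which(pk %in% mk)
  unobserved <- setdiff(seq_along(pk), observed)
  if (!length(observed))
    stop("no observed variants: nothing to condition on")
  if (!length(unobserved))
    stop("no unobserved variants: nothing to impute")
  list(observed = observed, unobserved = as.integer(unobserved))
}

#' Partition a chromosome into imputation regions
#'
#' Consecutive windows of about `region_size` observed variants each (the
#' observed variants drive the recurrent sequence length, so they define the
#' window). Each region also receives up to `flank_size` observed variants
#' on each side as upstream/downstream extensions: they feed the recurrent
#' input for boundary context but contribute no loss terms and no targets.
#' Terminal regions have truncated flanks.
#'
#' Target ownership: region boundaries are drawn at the first core observed
#' variant of each region; a region owns every unobserved site whose index
#' lies after its own first core observed variant (region 1: from the start
#' of the chromosome) and before the next region's first core observed
#' variant (last region: to the end). Every unobserved site therefore
#' belongs to exactly one region.
#'
#' @param observed_idx,unobserved_idx strictly increasing site-index vectors
#'   from [split_observed_unobserved()].
#' @param region_size target number of core observed variants per region.
#' @param flank_size observed variants included on each side beyond the
#'   core.
#' @return list of `region_spec` objects: lists with `observed_idx` (core),
#'   `flank_left_idx`, `flank_right_idx`, `unobserved_idx` (all panel site
#'   indices).
#' @export
make_regions <- function(observed_idx, unobserved_idx, region_size = 1000L,
                         flank_size = 100L) {
  stopifnot(region_size >= 1L, flank_size >= 0L)
  observed_idx <- as.integer(observed_idx)
  unobserved_idx <- as.integer(unobserved_idx)
  if (is.unsorted(observed_idx, strictly = TRUE) ||
      is.unsorted(unobserved_idx, strictly = TRUE))
    stop("index lists must be strictly increasing")
  if (length(intersect(observed_idx, unobserved_idx)))
    stop("observed and unobserved indices overlap")
  n_obs <- length(observed_idx)
  n_regions <- max(1L, ceiling(n_obs / region_size))
  starts <- (seq_len(n_regions) - 1L) * region_size + 1L  # into observed_idx
  ends <- pmin(starts + region_size - 1L, n_obs)
  # ownership cut points: panel index of each region's first core observed
  cuts <- observed_idx[starts]
  owner <- findInterval(unobserved_idx, cuts)   # 0 -> before region 1
  owner[owner == 0L] <- 1L
  regions <- vector("list", n_regions)
  for (k in seq_len(n_regions)) {
    core <- observed_idx[starts[k]:ends[k]]
    lo <- max(1L, starts[k] - flank_size)
    hi <- min(n_obs, ends[k] + flank_size)
    fl <- if (starts[k] > 1L) observed_idx[lo:(starts[k] - 1L)] else integer(0)
    fr <- if (ends[k] < n_obs) observed_idx[(ends[k] + 1L):hi] else integer(0)
    regions[[k]] <- structure(
      list(observed_idx = core,
           flank_left_idx = as.integer(fl),
           flank_right_idx = as.integer(fr),
           unobserved_idx = unobserved_idx[owner == k]),
      class = "region_spec")
  }
  regions
}

# all observed input indices of a region, in genomic order
region_input_idx <- function(region) {
  c(region$flank_left_idx, region$observed_idx, region$flank_right_idx)
}
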