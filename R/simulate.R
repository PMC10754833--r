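#' Simulation configuration
#'
#' Parameters of the founder-mosaic panel generator. Each simulated
#' haplotype copies a random founder haplotype, switching to a new random
#' founder with probability `switch_rate` at every site (geometric block
#' lengths, emulating recombination against a small effective founder pool)
#' and then flipping each allele with probability `mutation_rate`
#' (emulating mutation/genotyping noise). Founder allele frequencies are
#' drawn uniformly on `(maf_floor, 0.5)`, covering the evaluation MAF bins.
#'
#' @param n_founders number of founder haplotypes (>= 2).
#' @param n_haplotypes number of panel haplotypes (even).
#' @param n_sites number of variant sites.
#' @param switch_rate per-site probability of changing the copied founder.
#' @param mutation_rate per-site allele flip probability; 0.5 destroys all
#'   linkage (no-signal control), 0 gives exact founder mosaics.
#' @param maf_floor lower bound for realised panel MAFs (sites below it are
#'   redrawn).
#' @param seed optional integer seed applied by [simulate_panel()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 16L, n_haplotypes = 200L,
                       n_sites = 1000L, switch_rate = 0.02,
                       mutation_rate = 0.001, maf_floor = 0.005,
                       seed = NULL) {
  stopifnot(n_founders >= 2L, n_haplotypes >= 2L, n_haplotypes %% 2L == 0L,
            n_sites >= 1L,
            switch_rate >= 0, switch_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            maf_floor >= 0, maf_floor < 0.5)
  structure(list(n_founders = as.integer(n_founders),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_sites = as.integer(n_sites),
                 switch_rate = switch_rate,
                 mutation_rate = mutation_rate,
                 maf_floor = maf_floor,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a phased haplotype panel
#'
#' Founder-mosaic model: founders are drawn i.i.d. per site from a uniform
#' allele-frequency spectrum, each panel haplotype is a mosaic copy of
#' founders with per-site switch probability, and alleles are flipped with
#' the mutation rate. Positions are strictly increasing with random gaps.
#' Sites whose realised panel MAF falls below `maf_floor` are redrawn (new
#' founder alleles at that site, same copying paths) up to 25 rounds, after
#' which the generator errors; monomorphic output is thereby excluded.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()].
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- config$n_founders; nh <- config$n_haplotypes; nv <- config$n_sites

  freq <- runif(nv, config$maf_floor, 0.5)
  founders <- matrix(rbinom(nf * nv, 1L, rep(freq, each = nf)), nf, nv)

  # copying paths: founder id per (haplotype, site)
  path <- matrix(0L, nh, nv)
  path[, 1] <- sample.int(nf, nh, replace = TRUE)
  if (nv > 1L) {
    switch <- matrix(rbinom(nh * (nv - 1L), 1L, config$switch_rate) == 1L,
                     nh, nv - 1L)
    new_f <- matrix(sample.int(nf, nh * (nv - 1L), replace = TRUE),
                    nh, nv - 1L)
    for (j in 2:nv)
      path[, j] <- ifelse(switch[, j - 1L], new_f[, j - 1L], path[, j - 1L])
  }
  flip <- matrix(rbinom(nh * nv, 1L, config$mutation_rate), nh, nv)
  alleles <- matrix(founders[cbind(as.vector(path),
                                   rep(seq_len(nv), each = nh))], nh, nv)
  alleles <- (alleles + flip) %% 2L

  # redraw sites with MAF below the floor
  round <- 0L
  repeat {
    maf <- compute_maf(alleles)
    bad <- which(maf < config$maf_floor)
    if (!length(bad)) break
    round <- round + 1L
    if (round > 25L)
      stop("could not reach maf_floor after 25 resampling rounds")
    for (j in bad) {
      fj <- runif(1, config$maf_floor, 0.5)
      founders[, j] <- rbinom(nf, 1L, fj)
      aj <- founders[path[, j], j]
      alleles[, j] <- (aj + rbinom(nh, 1L, config$mutation_rate)) %% 2L
    }
  }

  pos <- cumsum(sample.int(200L, nv, replace = TRUE))
  sites <- data.frame(chrom = "1", pos = as.integer(pos),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  haplotype_panel(alleles, sites)
}

#' Select array-style observed markers
#'
#' Chooses `floor(fraction_observed * n_sites)` panel sites as the observed
#' set. The `maf_biased` strategy weights selection by panel MAF, emulating
#' the common-variant bias of genotyping chips; `uniform` samples sites
#' equiprobably.
#'
#' @param panel a [haplotype_panel()].
#' @param fraction_observed fraction of sites on the "chip", in (0, 1).
#' @param strategy `"maf_biased"` or `"uniform"`.
#' @param seed optional integer seed.
#' @return a [marker_manifest()].
#' @export
make_chip_manifest <- function(panel, fraction_observed,
                               strategy = c("maf_biased", "uniform"),
                               seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(fraction_observed > 0, fraction_observed < 1)
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(panel$sites)
  k <- floor(fraction_observed * nv)
  if (k < 1L) stop("selection empty: fraction too small for ", nv, " sites")
  w <- if (strategy == "maf_biased") panel$sites$maf else rep(1, nv)
  sel <- sort(sample.int(nv, k, prob = w))
  marker_manifest(panel$sites[sel, c("chrom", "pos", "ref", "alt")])
}

#' Perfect-linkage fixture
#'
#' Builds a panel of `n_blocks` blocks, each holding one observed variant
#' followed by `k_unobserved` unobserved variants that are exact copies or
#' exact complements of it (alternating). The unobserved alleles of any
#' haplotype are a deterministic function of its observed alleles, so an
#' ideal imputer reaches per-variant dosage R-squared 1, while a predictor
#' ignoring the observed alleles carries no per-variant signal.
#'
#' @param n_haplotypes number of haplotypes (even).
#' @param n_blocks number of independent blocks (>= 1).
#' @param k_unobserved unobserved variants per block.
#' @param seed optional integer seed.
#' @return list with `panel` ([haplotype_panel()]) and `manifest`
#'   ([marker_manifest()]).
#' @export
make_perfect_ld_fixture <- function(n_haplotypes = 200L, n_blocks = 50L,
                                    k_unobserved = 5L, seed = NULL) {
  stopifnot(n_blocks >= 1L, k_unobserved >= 1L, n_haplotypes %% 2L == 0L)
  if (!is.null(seed)) set.seed(seed)
  nh <- n_haplotypes
  per <- 1L + k_unobserved
  nv <- n_blocks * per
  alleles <- matrix(0L, nh, nv)
  obs_cols <- integer(n_blocks)
  for (b in seq_len(n_blocks)) {
    f <- runif(1, 0.2, 0.5)
    x <- rbinom(nh, 1L, f)
    while (length(unique(x)) < 2L) x <- rbinom(nh, 1L, f)  # keep polymorphic
    j0 <- (b - 1L) * per + 1L
    obs_cols[b] <- j0
    alleles[, j0] <- x
    for (k in seq_len(k_unobserved))
      alleles[, j0 + k] <- if (k %% 2L == 0L) 1L - x else x
  }
  pos <- seq_len(nv) * 10L
  sites <- data.frame(chrom = "1", pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  panel <- haplotype_panel(alleles, sites)
  manifest <- marker_manifest(sites[obs_cols, ])
  list(panel = panel, manifest = manifest)
}
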