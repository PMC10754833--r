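# Small in-code fixtures shared across test files.

# hand-written phased VCF text: 4 samples, 3 biallelic records (+ optional
# extra lines), written to a temp file
write_tiny_vcf <- function(path, extra_records = character(0),
                           gt_override = NULL) {
  gts <- if (is.null(gt_override))
    c("0|1\t1|1\t0|0\t0|1", "0|0\t0|1\t1|0\t0|0", "1|1\t0|0\t0|1\t1|0")
  else gt_override
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "101", ".", "A", "G", ".", "PASS", ".", "GT", gts[1], sep = "\t"),
    paste("1", "205", ".", "C", "T", ".", "PASS", ".", "GT", gts[2], sep = "\t"),
    paste("1", "309", ".", "G", "A", ".", "PASS", ".", "GT", gts[3], sep = "\t"),
    extra_records)
  writeLines(lines, path)
  path
}

# small mosaic panel + manifest for pipeline tests
tiny_mosaic <- function(seed = 99, n_hap = 60L, n_sites = 120L,
                        fraction = 0.25) {
  panel <- simulate_panel(sim_config(n_founders = 6, n_haplotypes = n_hap,
                                     n_sites = n_sites, switch_rate = 0.05,
                                     mutation_rate = 0.002, seed = seed))
  manifest <- make_chip_manifest(panel, fraction, "uniform", seed = seed + 1)
  list(panel = panel, manifest = manifest)
}

# genotype-count matrix (samples x variants) from a haplotype matrix
hap_to_counts <- function(h) {
  odd <- seq(1L, nrow(h), by = 2L)
  h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
}

# quick training setup used by several suites: small generator on the
# perfect-LD fixture
quick_train <- function(n_hap = 80, n_blocks = 12, k = 3, epochs = 12,
                        seed = 5, gen_config = generator_config(
                          hidden_units = 12, num_layers = 2,
                          feature_size = 8),
                        config = NULL) {
  fx <- make_perfect_ld_fixture(n_hap, n_blocks, k, seed = seed)
  if (is.null(config))
    config <- train_config(batch_size = 16, max_epochs = epochs,
                           early_stop_patience = epochs, seed = seed)
  ck <- train_grud(fx$panel, fx$manifest, gen_config = gen_config,
                   config = config)
  list(fx = fx, ck = ck)
}
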