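test_that("read_panel transcribes a phased VCF into a haplotype matrix", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(f)
  p <- read_panel(f)
  expect_s3_class(p, "haplotype_panel")
  expect_identical(dim(p$alleles), c(8L, 3L))
  # hand transcription: site 1 GTs 0|1 1|1 0|0 0|1 -> haps 0,1,1,1,0,0,0,1
  expect_identical(p$alleles[, 1], c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L))
  expect_identical(p$alleles[, 2], c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(p$sites$pos, c(101L, 205L, 309L))
  expect_identical(p$sample_ids, c("s1", "s2", "s3", "s4"))
  # MAF from panel counts: ac = 4, 2, 4 over 8 haplotypes
  expect_equal(p$sites$maf, c(0.5, 0.25, 0.5))
})

test_that("read_panel missing-genotype policies", {
  f <- withr::local_tempfile(fileext = ".vcf")
  rec <- paste("1", "400", ".", "T", "C", ".", "PASS", ".", "GT",
               ".|.\t0|1\t1|1\t0|0", sep = "\t")
  write_tiny_vcf(f, extra_records = rec)
  expect_error(read_panel(f), "missing")
  expect_warning(p <- read_panel(f, missing_policy = "drop_site"), "missing")
  expect_identical(ncol(p$alleles), 3L)
  expect_false(400L %in% p$sites$pos)
})

test_that("read_panel drops multiallelic records with a warning", {
  f <- withr::local_tempfile(fileext = ".vcf")
  rec <- paste("1", "500", ".", "T", "C,G", ".", "PASS", ".", "GT",
               "0|1\t0|2\t1|1\t0|0", sep = "\t")
  write_tiny_vcf(f, extra_records = rec)
  expect_warning(p <- read_panel(f), "multiallelic")
  expect_identical(ncol(p$alleles), 3L)
  expect_false(500L %in% p$sites$pos)
})

test_that("read_panel enforces phasing when asked", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(f, gt_override = c("0/1\t1|1\t0|0\t0|1",
                                    "0|0\t0|1\t1|0\t0|0",
                                    "1|1\t0|0\t0|1\t1|0"))
  expect_error(read_panel(f), "unphased")
  expect_s3_class(read_panel(f, require_phased = FALSE), "haplotype_panel")
})

test_that("write_panel_vcf / read_panel round-trip is the identity", {
  set.seed(31)
  panel <- simulate_panel(sim_config(n_haplotypes = 20, n_sites = 40,
                                     seed = 31))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(panel, f)
  back <- read_panel(f)
  expect_identical(back$alleles, panel$alleles)
  expect_equal(back$sites$pos, panel$sites$pos)
  expect_equal(back$sites$maf, panel$sites$maf)
})

test_that("compute_maf matches a brute-force count", {
  set.seed(7)
  m <- matrix(rbinom(50 * 20, 1, 0.3), 50, 20)
  brute <- sapply(seq_len(20), function(j) {
    ac <- 0
    for (i in 1:50) ac <- ac + m[i, j]
    min(ac, 50 - ac) / 50
  })
  expect_equal(compute_maf(m), brute)
  expect_identical(compute_maf(matrix(0L, 4, 1)), 0)
  expect_identical(compute_maf(matrix(c(0L, 1L, 0L, 1L), 4, 1)), 0.5)
})

test_that("filter_rare threshold semantics and composition", {
  # construct exact MAFs {0, 0.004, 0.005, 0.3} over 1000 haplotypes
  mk <- function(ac) c(rep(1L, ac), rep(0L, 1000 - ac))
  alleles <- cbind(mk(0), mk(4), mk(5), mk(300))
  sites <- data.frame(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                      ref = "A", alt = "G")
  p <- haplotype_panel(alleles, sites)
  expect_equal(p$sites$maf, c(0, 0.004, 0.005, 0.3))
  kept <- filter_rare(p, 0.005)
  expect_identical(kept$sites$pos, c(30L, 40L))   # boundary kept
  expect_identical(filter_rare(p, 0)$sites$pos, p$sites$pos)

  # filter_rare(filter_rare(p, a), b) == filter_rare(p, max(a, b))
  for (ab in list(c(0.004, 0.1), c(0.1, 0.004), c(0.005, 0.005))) {
    lhs <- filter_rare(filter_rare(p, ab[1]), ab[2])
    rhs <- filter_rare(p, max(ab))
    expect_identical(lhs$alleles, rhs$alleles)
  }
})

test_that("split_observed_unobserved partitions panel sites", {
  set.seed(11)
  panel <- simulate_panel(sim_config(n_haplotypes = 10, n_sites = 10, seed = 11))
  man <- marker_manifest(panel$sites[c(2, 5, 8), c("chrom", "pos", "ref", "alt")])
  sp <- split_observed_unobserved(panel, man)
  expect_identical(sp$observed, c(2L, 5L, 8L))
  expect_identical(sp$unobserved, setdiff(1:10, c(2L, 5L, 8L)))

  # manifest key absent from panel -> warning, still usable
  man2 <- marker_manifest(rbind(as.data.frame(man),
                                data.frame(chrom = "1", pos = 999999L,
                                           ref = "A", alt = "G")))
  expect_warning(sp2 <- split_observed_unobserved(panel, man2), "not present")
  expect_identical(sp2$observed, sp$observed)

  # degenerate manifests
  empty <- marker_manifest(data.frame(chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0)))
  expect_error(split_observed_unobserved(panel, empty), "observed")
  full <- marker_manifest(panel$sites[, c("chrom", "pos", "ref", "alt")])
  expect_error(split_observed_unobserved(panel, full), "unobserved")
})

test_that("make_regions window boundaries on the 2500-observed instance", {
  observed <- seq(1L, 4999L, by = 2L)    # 2500 observed site indices
  unobserved <- seq(2L, 5000L, by = 2L)
  regs <- make_regions(observed, unobserved, region_size = 1000L,
                       flank_size = 100L)
  expect_length(regs, 3L)
  expect_equal(lengths(lapply(regs, `[[`, "observed_idx")), c(1000L, 1000L, 500L))
  # interior flanks are exactly 100; terminal flanks truncate to zero
  expect_length(regs[[1]]$flank_left_idx, 0L)
  expect_identical(regs[[1]]$flank_right_idx, observed[1001:1100])
  expect_identical(regs[[2]]$flank_left_idx, observed[901:1000])
  expect_identical(regs[[2]]$flank_right_idx, observed[2001:2100])
  expect_identical(regs[[3]]$flank_left_idx, observed[1901:2000])
  expect_length(regs[[3]]$flank_right_idx, 0L)
  # ownership: region k holds unobserved sites up to the next region's cut
  expect_identical(regs[[1]]$unobserved_idx, unobserved[unobserved < observed[1001]])

  one <- make_regions(observed, unobserved, region_size = 5000L)
  expect_length(one, 1L)
  expect_length(one[[1]]$flank_left_idx, 0L)
  expect_length(one[[1]]$flank_right_idx, 0L)
})

test_that("make_regions covers every unobserved index exactly once", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    obs <- sort(sample(n, sample(5:(n %/% 2), 1)))
    unobs <- setdiff(seq_len(n), obs)
    rs <- sample(c(3L, 7L, 10L, 1000L), 1)
    fs <- sample(0:5, 1)
    regs <- make_regions(obs, unobs, rs, fs)
    got <- sort(unlist(lapply(regs, `[[`, "unobserved_idx")))
    expect_identical(got, as.integer(unobs))
    # brute-force: no index in two regions
    all_lists <- lapply(regs, `[[`, "unobserved_idx")
    for (i in seq_along(all_lists))
      for (j in seq_len(i - 1L))
        expect_length(intersect(all_lists[[i]], all_lists[[j]]), 0L)
    # strictly increasing index lists
    for (r in regs) {
      expect_false(is.unsorted(r$observed_idx, strictly = TRUE))
      expect_false(is.unsorted(r$unobserved_idx, strictly = TRUE))
    }
  }
})

test_that("write_imputed_vcf encodes GT/DS/GP and round-trips dosages", {
  sites <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G")
  # one sample; site 1 hap probs (0.9, 0.95), site 2 (1.0, 0.0)
  probs <- array(NA_real_, c(2, 2, 2))
  probs[, 1, 2] <- c(0.9, 0.95); probs[, 2, 2] <- c(1.0, 0.0)
  probs[, , 1] <- 1 - probs[, , 2]
  dos <- matrix(c(0.9 + 0.95, 1.0), 1, 2)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_imputed_vcf(sites, probs, dos, f, sample_ids = "s1")
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_match(body[1], "1\\|1:1\\.850:")
  expect_match(body[2], "1\\|0:1\\.000:")
  back <- read_dosage_vcf(f)
  expect_equal(back$dosages[1, ], c(1.850, 1.000), ignore_attr = TRUE)
  expect_identical(back$sites$pos, c(10L, 20L))
  # round-trip preserves DS to three decimals for arbitrary dosages
  dos2 <- matrix(c(0.1234, 1.9876), 1, 2)
  write_imputed_vcf(sites, probs, dos2, f, sample_ids = "s1")
  expect_equal(as.numeric(read_dosage_vcf(f)$dosages),
               round(as.numeric(dos2), 3))
  expect_error(write_imputed_vcf(sites, probs, matrix(1, 2, 2), f),
               "shape")
})

test_that("bgzipped VCF round-trips through the reader", {
  set.seed(83)
  panel <- simulate_panel(sim_config(n_haplotypes = 12, n_sites = 25,
                                     seed = 83))
  f <- withr::local_tempfile(fileext = ".vcf.gz")
  write_panel_vcf(panel, f)
  back <- read_panel(f)
  expect_identical(back$alleles, panel$alleles)
})
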