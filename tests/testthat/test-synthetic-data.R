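# The generator is first-class code: planted truths must be recoverable and
# the emitted files must round-trip through the package readers.

test_that("the worked example matches its hand-enumerable truths", {
  b <- worked_example()
  expect_equal(length(b$sites), 20L)
  expect_equal(length(b$peaks), 10L)
  expect_equal(nrow(b$variants), 40L)
  ins <- variants_to_granges(b$variants, b$layout)
  expect_equal(count_overlaps(ins, b$sites), 30L)
  expect_equal(count_overlaps(ins, b$peaks), 30L)
  # all records are AC=1 / AN=150,000 -> all classify as singletons
  cls <- classify_variants(b$variants)
  expect_true(all(cls$rarity == "singleton"))
  expect_true(all(cls$size_class == "5-20bp"))
  # 3 planted SVs -> 6 breakpoints
  bp <- extract_breakpoints(b$svs, b$layout, "singleton_per_sv")
  expect_equal(length(bp), 6L)
  # enhancer activity labels are recovered from the geometry
  cls_e <- classify_enhancer_activity(b$enhancers, b$peaks, b$layout)
  expect_equal(length(cls_e$active), sum(b$enhancers$intended_active))
})

test_that("bundles are deterministic for a fixed config", {
  cfg <- sim_config(n_peaks = 60L, chromosome_length = 2e5,
                    n_enhancers = 40L, n_common_sv_groups = 5L, seed = 33L)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$svs, b2$svs)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(IRanges::ranges(b1$sites), IRanges::ranges(b2$sites))
  b3 <- simulate_bundle(sim_config(n_peaks = 60L, chromosome_length = 2e5,
                                   n_enhancers = 40L,
                                   n_common_sv_groups = 5L, seed = 34L))
  expect_false(identical(b1$variants, b3$variants))
})

test_that("generated files round-trip through the package readers", {
  cfg <- sim_config(n_peaks = 40L, chromosome_length = 2e5,
                    n_enhancers = 20L, n_common_sv_groups = 4L, seed = 12L)
  b <- simulate_bundle(cfg)
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  g <- read_chrom_sizes(paths$chrom_sizes, sex_chromosomes = "chrX")
  expect_equal(g$chromosomes, b$layout$chromosomes)
  # VCF round-trips positions, alleles and AC/AN bit-exactly
  v <- read_variant_vcf(paths$vcf)
  expect_equal(nrow(v), nrow(b$variants))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, d$ac, d$an)
  expect_setequal(key(v), key(b$variants))
  # BED and SV TSV round-trips
  peaks <- read_bed(paths$peaks, g)
  expect_equal(IRanges::ranges(peaks), IRanges::ranges(b$peaks))
  svs <- read_sv_tsv(paths$svs)
  expect_equal(svs$start, b$svs$start)
  expect_equal(svs$end, b$svs$end)
  # genome FASTA matches site instances: sequence at site == instance
  genome <- Biostrings::readDNAStringSet(paths$fasta)
  i <- 1L
  ch <- as.character(GenomeInfoDb::seqnames(b$sites))[i]
  s <- GenomicRanges::start(b$sites)[i]
  e <- GenomicRanges::end(b$sites)[i]
  expect_equal(as.character(Biostrings::subseq(genome[[ch]], s, e)),
               b$sites$instance[i])
})

test_that("a null configuration plants no at-site excess", {
  cfg <- sim_config(insertion_fold = 1, n_peaks = 400L,
                    chromosome_length = 5e5, seed = 61L,
                    sv_rate = 0, n_common_sv_groups = 0L)
  b <- simulate_bundle(cfg)
  n_at <- sum(b$variants$stratum == "singleton_insertion_at_site")
  n_bg <- sum(b$variants$stratum == "singleton_insertion_bg")
  rate_at <- n_at / b$truth$site_bp
  rate_bg <- n_bg / b$truth$background_bp
  # Poisson SE on the at-site density
  se <- sqrt(n_at) / b$truth$site_bp
  expect_lt(abs(rate_at - rate_bg), 3 * se + sqrt(n_bg) / b$truth$background_bp)
})

test_that("tandem-duplicating insertions carry the site motif", {
  cfg <- sim_config(tandem_duplication_probability = 1, n_peaks = 100L,
                    chromosome_length = 3e5, seed = 71L,
                    sv_rate = 0, n_common_sv_groups = 0L)
  b <- simulate_bundle(cfg)
  at <- b$variants[b$variants$stratum == "singleton_insertion_at_site", ]
  expect_gt(nrow(at), 20)
  inserted <- substring(at$alt, 2L)
  # every at-site insertion under probability 1 contains a family motif
  fams <- vapply(seq_len(nrow(at)), function(i) {
    hit <- GenomicRanges::findOverlaps(
      variants_to_granges(at[i, , drop = FALSE], b$layout), b$sites)
    b$sites$family_id[S4Vectors::subjectHits(hit)[1]]
  }, integer(1))
  res1 <- vapply(unique(fams), function(f) {
    insertion_motif_content(inserted[fams == f], b$family_pwms[[f]])$fraction
  }, numeric(1))
  expect_true(all(res1 == 1))
  # and with probability 0 the match fraction collapses to ~0
  cfg0 <- sim_config(tandem_duplication_probability = 0, n_peaks = 100L,
                     chromosome_length = 3e5, seed = 72L,
                     sv_rate = 0, n_common_sv_groups = 0L)
  b0 <- simulate_bundle(cfg0)
  at0 <- b0$variants[b0$variants$stratum == "singleton_insertion_at_site", ]
  r0 <- insertion_motif_content(substring(at0$alt, 2L),
                                b0$family_pwms[[1]])$fraction
  expect_lt(r0, 0.2)
})

test_that("common variants are depleted at sites by the planted factor", {
  cfg <- sim_config(common_rate = 4e-3, common_depletion = 0.2,
                    insertion_rate = 1e-4, seed = 81L,
                    sv_rate = 0, n_common_sv_groups = 0L)
  b <- simulate_bundle(cfg)
  com <- b$variants[b$variants$stratum == "common_insertion", ]
  gr_com <- variants_to_granges(com, b$layout)
  site_bp <- b$truth$site_bp
  n_at <- count_overlaps(gr_com, b$sites)
  n_tot <- nrow(com)
  genome_bp <- sum(b$layout$lengths)
  rate_at <- n_at / site_bp
  rate_gw <- n_tot / genome_bp
  ratio <- rate_at / rate_gw
  # planted retention 0.2; Poisson noise on a ~25-count stratum
  expect_lt(abs(ratio - 0.2), 3 * sqrt(max(n_at, 1)) / site_bp / rate_gw)
  expect_lt(ratio, 1)
})

test_that("generated AC/AN fields reproduce the intended rarity classes", {
  b <- simulate_bundle(sim_config(n_peaks = 60L, chromosome_length = 2e5,
                                  seed = 91L))
  cls <- classify_variants(b$variants)
  singleton_strata <- c("singleton_insertion_bg", "singleton_insertion_at_site",
                        "singleton_insertion_1_2bp", "singleton_snp")
  expect_true(all(cls$rarity[cls$stratum %in% singleton_strata] == "singleton"))
  expect_true(all(cls$rarity[cls$stratum == "common_insertion"] == "common"))
  expect_true(all(cls$rarity[cls$stratum == "other_insertion"] == "other"))
  expect_true(all(cls$size_class[cls$stratum == "singleton_insertion_1_2bp"]
                  == "1-2bp"))
})
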