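# Rarity/size classification, indel gap normalization, reciprocal-overlap
# grouping, breakpoint extraction, and downsampling.

test_that("rarity classes follow the AC/AN rules", {
  v <- classify_variants(rbind(
    variant_df(100, ac = 1L, an = 120000L),          # singleton
    variant_df(200, ac = 1L, an = 50000L),           # AN below threshold
    variant_df(300, ac = 6000L, an = 100000L),       # 6% -> common
    variant_df(400, ac = 5L, an = 150000L)))         # neither
  expect_equal(v$rarity, c("singleton", "other", "common", "other"))
  # pure function: same records, same classes
  expect_identical(classify_variants(v[, 1:9]), classify_variants(v[, 1:9]))
})

test_that("indel size classes are 1-2bp, 5-20bp, or excluded", {
  v <- classify_variants(rbind(
    variant_df(100, alt = "AT"),                     # 1 bp insertion
    variant_df(200, alt = "ATTT"),                   # 3 bp -> excluded
    variant_df(300, alt = paste0("A", strrep("T", 5))),
    variant_df(400, alt = paste0("A", strrep("T", 20))),
    variant_df(500, alt = paste0("A", strrep("T", 21))),
    variant_df(600, alt = "C")))                     # SNP
  expect_equal(v$size_class,
               c("1-2bp", "excluded", "5-20bp", "5-20bp", "excluded", "SNP"))
})

test_that("classification rejects AN = 0 and malformed counts", {
  expect_error(classify_variants(variant_df(1, an = 0L)), "AN")
  expect_error(classify_variants(variant_df(1, ac = 10L, an = 5L)), "AC")
})

test_that("normalize_indels removes both members of close pairs", {
  both <- normalize_indels(variant_df(c(100, 101)), min_gap = 2)
  expect_equal(nrow(both), 0L)
  kept <- normalize_indels(variant_df(c(100, 102)), min_gap = 2)
  expect_equal(kept$pos, c(100, 102))
  single <- normalize_indels(variant_df(100), min_gap = 2)
  expect_equal(nrow(single), 1L)
  # SNPs are not part of the gap rule
  mix <- rbind(variant_df(100), variant_df(101, alt = "C"))
  expect_equal(nrow(normalize_indels(mix, min_gap = 2)), 2L)
  # chromosomes are independent
  two <- rbind(variant_df(100, chrom = "chr1"), variant_df(101, chrom = "chr2"))
  expect_equal(nrow(normalize_indels(two, min_gap = 2)), 2L)
})

test_that("reciprocal overlap links at the exact boundary fraction", {
  # BED [100,200) and [120,220): overlap 80 of length 100 each
  expect_equal(length(unique(reciprocal_overlap_group(
    sv_df(c(101, 121), c(200, 220))))), 1L)
  # BED [100,200) and [130,230): overlap 70 -> separate
  expect_equal(length(unique(reciprocal_overlap_group(
    sv_df(c(101, 131), c(200, 230))))), 2L)
  expect_error(reciprocal_overlap_group(
    sv_df(c(1, 1), c(10, 10), type = c("deletion", "duplication"))),
    "mixed")
})

test_that("grouping is transitive and order-independent", {
  # chain: a~b and b~c but a!~c
  chain <- sv_df(c(101, 121, 141), c(200, 220, 240))
  expect_equal(length(unique(reciprocal_overlap_group(chain))), 1L)
  set.seed(11)
  svs <- sv_df(start = sort(sample(1:5000, 60)), end = 0)
  svs$end <- svs$start + sample(50:400, 60, replace = TRUE)
  grp <- reciprocal_overlap_group(svs)
  perm <- sample(nrow(svs))
  grp_perm <- reciprocal_overlap_group(svs[perm, , drop = FALSE])
  expect_true(same_partition(grp[perm], grp_perm))
})

test_that("grouping matches the brute-force connected-components oracle", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 80
    svs <- sv_df(start = sample(1:20000, n),
                 end = 0, chrom = sample(c("chr1", "chr2"), n, TRUE))
    svs$end <- svs$start + sample(100:3000, n, replace = TRUE)
    got <- reciprocal_overlap_group(svs, 0.8)
    want <- brute_reciprocal_groups(svs, 0.8)
    expect_true(same_partition(got, want))
  }
})

test_that("singleton breakpoints are the 5' and 3' coordinates, two per SV", {
  g <- tiny_layout(1e5)
  # one deletion BED [1000,5000) -> breakpoints at BED 1000 and 4999
  bp <- extract_breakpoints(sv_df(1001, 5000), g, "singleton_per_sv")
  expect_equal(GenomicRanges::start(bp), c(1001, 5000))
  expect_true(all(GenomicRanges::width(bp) == 1L))
  # 2 x n invariant, no dedup even for identical SVs
  twin <- sv_df(c(1001, 1001), c(5000, 5000))
  expect_equal(length(extract_breakpoints(twin, g, "singleton_per_sv")), 4L)
})

test_that("common breakpoints are outermost per group and deduplicated", {
  g <- tiny_layout(1e5)
  # group {[100,200),[110,210)}: 90/100 reciprocal -> outermost BED 100, 209
  bp <- extract_breakpoints(sv_df(c(101, 111), c(200, 210)), g,
                            "common_grouped")
  expect_equal(GenomicRanges::start(bp), c(101, 210))
  # two groups sharing breakpoint coordinate 500 emit it once:
  # group A = [101,500] (3' bp 500), group B = [500,900] (5' bp 500);
  # their 1-bp overlap is far below the reciprocal fraction
  shared <- rbind(sv_df(101, 500), sv_df(500, 900))
  bp <- extract_breakpoints(shared, g, "common_grouped")
  expect_equal(sum(GenomicRanges::start(bp) == 500), 1L)
  expect_equal(length(bp), 3L)
})

test_that("SV TSVs round-trip the half-open file convention", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000\t5000\tdeletion\t2e-05",
               "chr1\t7000\t9000\tdeletion\t0.06"), path)
  svs <- read_sv_tsv(path)
  expect_equal(svs$start, c(1001, 7001))
  expect_equal(svs$end, c(5000, 9000))
  expect_equal(svs$freq, c(2e-5, 0.06))
})

test_that("downsampling is uniform-without-replacement and deterministic", {
  v <- variant_df(1:10 * 100)
  expect_equal(downsample_records(v, 10, seed = 3)$pos, v$pos)
  d1 <- downsample_records(v, 4, seed = 9)
  d2 <- downsample_records(v, 4, seed = 9)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 4L)
  expect_false(identical(d1$pos, downsample_records(v, 4, seed = 10)$pos))
  expect_error(downsample_records(v, 11, seed = 1), "exceeds")
  # GRanges input comes back sorted
  x <- gr("chr1", c(500, 100, 300), c(510, 110, 310))
  d <- downsample_records(x, 2, seed = 4)
  expect_true(!is.unsorted(GenomicRanges::start(d)))
})

test_that("novelty screening flags SVs absent from a reference catalog", {
  cand <- sv_df(c(101, 5001), c(200, 6000))
  ref <- sv_df(121, 220)          # 80/100 reciprocal with the first record
  expect_equal(novel_svs(cand, ref), c(FALSE, TRUE))
  # an overlap below the reciprocal fraction does not mask novelty
  ref2 <- sv_df(171, 270)         # 30/100 overlap
  expect_equal(novel_svs(cand, ref2), c(TRUE, TRUE))
  expect_equal(novel_svs(cand, ref[0, ]), c(TRUE, TRUE))
})

test_that("the singleton carrier-frequency bound is one over total cohort", {
  expect_equal(carrier_frequency_bound(c(100)), 1)
  expect_equal(carrier_frequency_bound(c(9625, 10738, 29084)),
               100 / 49447)
})
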