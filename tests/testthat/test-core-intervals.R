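# Interval arithmetic primitives. Internal coordinates are 1-based closed
# (GRanges); BED-convention examples from the interface contract are
# translated accordingly, e.g. BED [10,20) == 11-20.

test_that("merge_intervals joins overlapping and book-ended records", {
  g <- tiny_layout(1000)
  # BED {[10,20),[15,30)} -> {[10,30)}
  m <- merge_intervals(gr("chr1", c(11, 16), c(20, 30)), g)
  expect_equal(GenomicRanges::start(m), 11)
  expect_equal(GenomicRanges::end(m), 30)
  # book-ended half-open intervals touch: {[10,20),[20,30)} -> {[10,30)}
  m <- merge_intervals(gr("chr1", c(11, 21), c(20, 30)), g)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::end(m), 30)
  # disjoint unchanged
  m <- merge_intervals(gr("chr1", c(11, 26), c(20, 30)), g)
  expect_equal(length(m), 2L)
  # covered bases preserved at max_gap = 0
  x <- gr("chr1", c(5, 12, 40), c(15, 30, 45))
  expect_equal(sum(GenomicRanges::width(merge_intervals(x, g))),
               sum(GenomicRanges::width(GenomicRanges::reduce(x))))
})

test_that("merge_intervals is idempotent and honours max_gap", {
  g <- tiny_layout(1000)
  x <- gr("chr1", c(1, 30, 32, 100), c(10, 31, 60, 120))
  m1 <- merge_intervals(x, g, max_gap = 5)
  m2 <- merge_intervals(m1, g, max_gap = 5)
  expect_identical(GenomicRanges::granges(m1), GenomicRanges::granges(m2))
  # gap of exactly max_gap merges; one more base does not
  near <- gr("chr1", c(1, 16), c(10, 20))       # gap = 5 bases (11..15)
  expect_equal(length(merge_intervals(near, g, max_gap = 5)), 1L)
  expect_equal(length(merge_intervals(near, g, max_gap = 4)), 2L)
})

test_that("layout validation rejects unknown chromosomes and out-of-bounds", {
  g <- tiny_layout(1000)
  expect_error(merge_intervals(gr("chrUn", 1, 10), g), "chrUn")
  expect_error(check_intervals(gr("chr1", 990, 1500), g), "bounds")
})

test_that("count_overlaps counts each query record once", {
  # BED a=[0,10), b=[9,20): 1-bp intersection
  expect_equal(count_overlaps(gr("chr1", 1, 10), gr("chr1", 10, 20)), 1L)
  # half-open touching intervals do not intersect
  expect_equal(count_overlaps(gr("chr1", 1, 10), gr("chr1", 11, 20)), 0L)
  # identity on 5 disjoint records
  five <- gr("chr1", seq(1, 401, by = 100), seq(50, 450, by = 100))
  expect_equal(count_overlaps(five, five), 5L)
  # multi-hit fixture: count is bounded by |query| and not symmetric
  a <- gr("chr1", 1, 100)                         # one record, many partners
  b <- gr("chr1", c(10, 40, 70), c(20, 50, 80))
  expect_equal(count_overlaps(a, b), 1L)
  expect_equal(count_overlaps(b, a), 3L)
  expect_lte(count_overlaps(a, b), length(a))
})

test_that("nearest_distance excludes self-matches and flags undefined", {
  # query [100,110) in BED; target contains itself plus [200,210) -> 90
  q <- gr("chr1", 101, 110)
  t <- gr("chr1", c(101, 201), c(110, 210))
  expect_equal(nearest_distance(q, t), 90L)
  # overlap with a distinct record -> 0
  expect_equal(nearest_distance(gr("chr1", 105, 115), t), 0L)
  # no candidate on the chromosome -> NA
  lv <- c("chr1", "chr2")
  expect_true(is.na(nearest_distance(gr("chr2", 1, 10, seqlevels = lv),
                                     gr("chr1", c(101, 201), c(110, 210),
                                        seqlevels = lv))))
  # vectorized over queries, self-excluded for every element
  d <- nearest_distance(t, t)
  expect_equal(d, c(90L, 90L))
})

test_that("filter_by_mappability applies the window fraction rule", {
  g <- tiny_layout(10000)
  site <- gr("chr1", 1001, 1001)
  # window is mid +/- 50 = 100 bp: 951..1050
  keep96 <- gr("chr1", 951, 1046)   # 96 mappable bases
  keep94 <- gr("chr1", 951, 1044)   # 94 mappable bases
  expect_equal(length(filter_by_mappability(site, keep96, g, flank = 50,
                                            min_fraction = 0.95)), 1L)
  expect_equal(length(filter_by_mappability(site, keep94, g, flank = 50,
                                            min_fraction = 0.95)), 0L)
  # fully mappable genome -> identity; min_fraction 0 -> identity
  full <- gr("chr1", 1, 10000)
  sites <- gr("chr1", c(101, 5001), c(120, 5050))
  expect_equal(length(filter_by_mappability(sites, full, g, flank = 500,
                                            min_fraction = 0.95)), 2L)
  expect_equal(length(filter_by_mappability(sites, keep94, g, flank = 500,
                                            min_fraction = 0)), 2L)
  expect_error(filter_by_mappability(site, full, g, flank = 0), "flank")
})

test_that("mappability windows truncated at chromosome ends use the
           truncated denominator", {
  g <- tiny_layout(1000)
  site <- gr("chr1", 3, 4)                # window clips at position 1
  full <- gr("chr1", 1, 1000)
  expect_equal(length(filter_by_mappability(site, full, g, flank = 100,
                                            min_fraction = 1)), 1L)
})

test_that("midpoint_windows recenters, clips, and reproduces records", {
  g <- tiny_layout(1e5)
  # BED [1000,2000), flank 500 -> [1000,2000): mid0 = 1500
  w <- midpoint_windows(gr("chr1", 1001, 2000), g, flank = 500)
  expect_equal(GenomicRanges::start(w), 1001)
  expect_equal(GenomicRanges::end(w), 2000)
  # BED [0,10) flank 500 -> clipped [0,505)
  w <- midpoint_windows(gr("chr1", 1, 10), g, flank = 500)
  expect_equal(GenomicRanges::start(w), 1)
  expect_equal(GenomicRanges::end(w), 505)
  # flank equal to half the record length reproduces the record
  rec <- gr("chr1", 4001, 4800)
  w <- midpoint_windows(rec, g, flank = 400)
  expect_identical(IRanges::ranges(w), IRanges::ranges(rec))
})

test_that("BED files round-trip through read_bed/write_bed", {
  g <- tiny_layout(1e5)
  x <- gr("chr1", c(101, 501, 901), c(200, 650, 1000),
          strand = c("+", "-", "*"))
  x$name <- c("a", "b", "c")
  x$score <- c(1, 2, 3)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path, g)
  expect_equal(GenomicRanges::start(y), GenomicRanges::start(x))
  expect_equal(GenomicRanges::end(y), GenomicRanges::end(x))
  expect_equal(as.character(GenomicRanges::strand(y)),
               as.character(GenomicRanges::strand(x)))
  expect_equal(y$name, x$name)
  # file-level coordinates are half-open 0-based
  raw <- utils::read.table(path, sep = "\t")
  expect_equal(raw$V2, GenomicRanges::start(x) - 1L)
  expect_equal(raw$V3, GenomicRanges::end(x))
})

test_that("chrom.sizes files load into a validated layout", {
  path <- withr::local_tempfile(fileext = ".chrom.sizes")
  writeLines(c("chr1\t1000000", "chrX\t500000"), path)
  g <- read_chrom_sizes(path, sex_chromosomes = "chrX")
  expect_equal(unname(g$lengths["chrX"]), 500000)
  expect_equal(g$sex_chromosomes, "chrX")
  expect_error(genome_layout(c("a", "a"), c(1, 2)), "unique")
})
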