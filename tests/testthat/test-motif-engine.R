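# PWM construction, similarity clustering, the p-value -> score threshold
# dynamic program, and sequence scanning.

test_that("consensus columns follow the epsilon rule", {
  p <- consensus_to_pwm("A")
  expect_equal(as.vector(unclass(p)), c(0.97, 0.01, 0.01, 0.01))
  expect_equal(as.vector(unclass(consensus_to_pwm("N"))), rep(0.25, 4))
  # degenerate two-base code splits the remaining mass
  expect_equal(as.vector(unclass(consensus_to_pwm("R"))),
               c(0.49, 0.01, 0.49, 0.01))
  expect_equal(ncol(consensus_to_pwm("CCNCCNTNNCCNC")), 13L)
  expect_error(consensus_to_pwm("ACGQ"), "invalid")
})

test_that("PWM correlation distance handles identity, orientation, and
           anti-correlation", {
  p <- consensus_to_pwm("CCACCATTGCCAC")
  expect_equal(pwm_distance(p, p), 0)
  expect_equal(pwm_distance(p, pwm_reverse_complement(p)), 0)
  a <- pwm(matrix(c(1, 0, 0, 0), 4), "a")
  b <- pwm(matrix(c(0, 1, 0, 0), 4), "b")
  expect_equal(pwm_distance(a, b), 4 / 3)
  expect_equal(pwm_distance(a, b), pwm_distance(b, a))
  # bounded in [0, 2]
  set.seed(5)
  for (i in 1:5) {
    x <- pwm(matrix(runif(4 * 8), 4), "x")
    y <- pwm(matrix(runif(4 * 6), 4), "y")
    d <- pwm_distance(x, y)
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("family clustering partitions by average linkage at the cut", {
  p1 <- consensus_to_pwm("ACGTACGT", name = "m1")
  p2 <- consensus_to_pwm("ACGTACGT", name = "m2")
  p3 <- consensus_to_pwm("GGGGCCCC", name = "m3")
  fam <- cluster_families(list(p1, p2, p3), threshold = 0.5)
  expect_equal(fam$family_id[fam$name == "m1"], fam$family_id[fam$name == "m2"])
  expect_false(fam$family_id[fam$name == "m3"] == fam$family_id[fam$name == "m1"])
  # threshold 0: distinct PWMs get their own family
  fam0 <- cluster_families(list(p1, p3), threshold = 0)
  expect_equal(length(unique(fam0$family_id)), 2L)
  # representative is the longest member, ties lexicographic
  long <- consensus_to_pwm("ACGTACGTAA", name = "zz_long")
  fam2 <- cluster_families(list(p1, long, p2), threshold = 0.5)
  expect_true(all(fam2$representative == "zz_long"))
})

test_that("family partition is invariant under input permutation", {
  set.seed(8)
  pwms <- lapply(1:6, function(i)
    consensus_to_pwm(paste(sample(c("A", "C", "G", "T"), 8, TRUE),
                           collapse = ""), name = paste0("m", i)))
  f1 <- cluster_families(pwms, threshold = 0.4)
  perm <- c(4, 1, 6, 2, 5, 3)
  f2 <- cluster_families(pwms[perm], threshold = 0.4)
  merged <- merge(f1, f2, by = "name")
  expect_true(same_partition(merged$family_id.x, merged$family_id.y))
})

test_that("score thresholds match exhaustive enumeration up to length 6", {
  set.seed(13)
  for (L in 1:6) {
    m <- matrix(stats::runif(4 * L, 0.05, 1), 4)
    p <- pwm(sweep(m, 2, colSums(m), "/"), paste0("r", L))
    for (pv in c(0.5, 0.05, 0.002)) {
      want <- enum_threshold(p, pv)
      if (is.na(want)) {
        expect_true(attr(suppressWarnings(score_threshold(p, pv)),
                         "unattainable"))
      } else {
        expect_equal(as.numeric(score_threshold(p, pv)), want,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("score threshold handles the trivial and unattainable edges", {
  p <- pwm(matrix(c(.5, .25, .125, .125), 4), "t")
  # L=1, uniform bg: log-odds {1, 0, -1, -1}; P(>=1) = 0.25
  expect_equal(as.numeric(score_threshold(p, 0.25)), 1)
  # pvalue 1 returns the minimum achievable score
  expect_equal(as.numeric(score_threshold(p, 1)), -1)
  # just below 1, the all-pass score no longer qualifies
  expect_equal(as.numeric(score_threshold(p, 0.9999)), 0)
  expect_warning(thr <- score_threshold(p, 1e-9), "achievable")
  expect_true(attr(thr, "unattainable"))
})

test_that("scanning finds planted sites and respects N windows", {
  cons <- "CCACCATTGCCAC"
  p <- consensus_to_pwm(cons)
  thr <- score_threshold(p, 1e-4)
  set.seed(2)
  seqc <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  substr(seqc, 51, 63) <- cons
  hits <- scan_sequences(c(chr1 = seqc), p, thr)
  expect_true(any(GenomicRanges::start(hits) == 51 &
                  GenomicRanges::end(hits) == 63))
  # all-N sequence yields nothing
  expect_equal(length(scan_sequences(c(chr1 = strrep("N", 100)), p, thr)), 0L)
})

test_that("scanning a reverse-complemented sequence mirrors coordinates", {
  cons <- "CCACCATTGCCAC"
  p <- consensus_to_pwm(cons)
  thr <- score_threshold(p, 1e-4)
  set.seed(4)
  fwd <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  substr(fwd, 101, 113) <- cons
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  h_f <- scan_sequences(c(chr1 = fwd), p, thr)
  h_r <- scan_sequences(c(chr1 = rev), p, thr)
  n <- nchar(fwd)
  # a hit [s, e] on fwd appears at [n - e + 1, n - s + 1] on rev
  mirrored <- sort(n - GenomicRanges::end(h_f) + 1)
  expect_equal(sort(GenomicRanges::start(h_r)), mirrored)
  expect_equal(length(h_f), length(h_r))
})

test_that("palindromic matches merge to a single family site", {
  g <- tiny_layout(200)
  pal <- "GAATTC"                       # EcoRI site, reverse complement of itself
  p <- consensus_to_pwm(pal)
  thr <- score_threshold(p, 1e-3)
  seqc <- paste0(strrep("A", 50), pal, strrep("A", 144))
  hits <- scan_sequences(c(chr1 = seqc), p, thr)
  expect_equal(length(hits), 2L)        # both strands, same coordinates
  merged <- build_family_sites(hits, g, family_id = 7L)
  expect_equal(length(merged), 1L)
  expect_equal(merged$family_id, 7L)
  expect_equal(GenomicRanges::start(merged), 51)
})

test_that("family sites merge overlapping member hits and keep best score", {
  g <- tiny_layout(1000)
  hits <- gr("chr1", c(11, 16, 101), c(23, 28, 113), strand = "+")
  hits$score <- c(5, 9, 3)
  hits$motif <- c("A", "B", "A")
  m <- build_family_sites(hits, g)
  expect_equal(length(m), 2L)
  expect_equal(GenomicRanges::start(m), c(11, 101))
  expect_equal(GenomicRanges::end(m), c(28, 113))
  expect_equal(m$score, c(9, 3))
})

test_that("JASPAR PFM files parse in bracketed and bare layouts", {
  path <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(
    ">MA0001.1 TEST1",
    "A  [ 4 19  0 ]",
    "C  [16  0  0 ]",
    "G  [ 0  1 20 ]",
    "T  [ 0  0  0 ]",
    ">TEST2",
    "1 0",
    "0 1",
    "0 0",
    "0 0"), path)
  pwms <- read_jaspar_pfm(path)
  expect_equal(names(pwms), c("MA0001.1", "TEST2"))
  expect_equal(ncol(pwms$MA0001.1), 3L)
  expect_true(all(abs(colSums(unclass(pwms$MA0001.1)) - 1) < 1e-9))
  # count 19 of 20 (+pseudocount) dominates column 2
  expect_gt(unclass(pwms$MA0001.1)["A", 2], 0.9)
})
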