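#' Fold enrichment of observed over expected counts
#'
#' The ratio `observed / expected`, where the expected count is typically
#' the mean of the permutation distribution from [perm_test()]. For 5-20 bp
#' singleton insertions at binding sites this ratio is the insertion fold
#' enrichment (IFE). Reports round it to one decimal; the raw ratio is
#' returned here.
#'
#' @param observed Observed count.
#' @param expected Expected count (`> 0` for a defined ratio).
#' @return Numeric fold; `NA` when `expected <= 0`.
#' @examples
#' fold_enrichment(108, 10)  # 10.8
#' @export
fold_enrichment <- function(observed, expected) {
  ifelse(is.na(expected) | expected <= 0, NA_real_, observed / expected)
}

#' Summarize a permutation test as an enrichment result
#'
#' @param pt A [perm_test()] object.
#' @param label Track or family label.
#' @param n_sites Optional number of sites tested.
#' @return One-row data.frame: `label`, `n_sites`, `observed`, `expected`,
#'   `fold`, `fold_1dp` (reporting convention), `z`, `p_empirical`.
#' @export
enrichment_result <- function(pt, label = "track", n_sites = NA_integer_) {
  data.frame(
    label = label,
    n_sites = n_sites,
    observed = pt$observed,
    expected = pt$mean_exp,
    fold = fold_enrichment(pt$observed, pt$mean_exp),
    fold_1dp = round(fold_enrichment(pt$observed, pt$mean_exp), 1),
    z = pt$z,
    p_empirical = pt$p_empirical,
    stringsAsFactors = FALSE
  )
}

#' Binned count profile of variants around site midpoints
#'
#' For each site midpoint, variants within `window` bp are assigned to bins
#' of `bin` bp by their signed offset (variant position minus midpoint,
#' half-open bins `[k*bin, (k+1)*bin)`), and counts are summed over sites.
#' A variant in the window of several sites contributes to each (the
#' profile is site-centric). `normalize = "per_site"` divides by the number
#' of sites, giving the average count per site.
#'
#' @param variants Width-1 `GRanges` of variant positions (or a data.frame
#'   with `chrom`/`pos`).
#' @param sites `GRanges` of anchor sites.
#' @param g A [genome_layout()] object.
#' @param window Half-window in bp; must be divisible by `bin`.
#' @param bin Bin width in bp (5 bp for binding-site profiles; 100 bp or
#'   5 kb for enhancer-scale profiles).
#' @param normalize `"raw"` or `"per_site"`.
#' @return data.frame with `bin_start`, `bin_end` (signed offsets, half-open)
#'   and `count`; attribute `n_sites`.
#' @export
profile_counts <- function(variants, sites, g, window = 1000L, bin = 5L,
                           normalize = c("raw", "per_site")) {
  normalize <- match.arg(normalize)
  if (window %% bin != 0) stop("'window' must be divisible by 'bin'")
  if (is.data.frame(variants)) variants <- variants_to_granges(variants, g)
  check_intervals(variants, g)
  check_intervals(sites, g)
  edges <- seq(-window, window, by = bin)
  counts <- numeric(length(edges) - 1L)
  if (length(sites) && length(variants)) {
    s0 <- GenomicRanges::start(sites) - 1L
    e0 <- GenomicRanges::end(sites)
    mid0 <- (s0 + e0) %/% 2L
    win <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(sites),
      IRanges::IRanges(start = pmax(mid0 - window + 1L, 1L),
                       end = pmin(mid0 + window,
                                  g$lengths[as.character(
                                    GenomeInfoDb::seqnames(sites))])))
    ov <- GenomicRanges::findOverlaps(variants, win, ignore.strand = TRUE)
    if (length(ov)) {
      vpos0 <- GenomicRanges::start(variants)[S4Vectors::queryHits(ov)] - 1L
      off <- vpos0 - mid0[S4Vectors::subjectHits(ov)]
      off <- off[off >= -window & off < window]
      if (length(off)) {
        idx <- (off + window) %/% bin + 1L
        tab <- tabulate(idx, nbins = length(counts))
        counts <- counts + tab
      }
    }
  }
  if (normalize == "per_site" && length(sites))
    counts <- counts / length(sites)
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_end = edges[-1L],
                    count = counts)
  attr(out, "n_sites") <- length(sites)
  out
}

#' Exact-position coincidence test between two 1-bp feature sets
#'
#' Tests whether two sets of single-base features (e.g. singleton insertion
#' positions and singleton SV deletion breakpoints) fall on the exact same
#' nucleotide more often than the permutation null expects. Both inputs
#' must already be width-1; the evaluation is ordinary overlap counting,
#' which for 1-bp features is exact-coordinate coincidence.
#'
#' @inheritParams perm_test
#' @param a Width-1 `GRanges`; the set randomized.
#' @param b Width-1 `GRanges`; held fixed.
#' @return A [perm_test()] object.
#' @export
coincidence_test <- function(a, b, g, n_perm = 1000L,
                             null = c("circular", "shuffle"), seed = 1L) {
  if (any(GenomicRanges::width(a) != 1L) || any(GenomicRanges::width(b) != 1L))
    stop("coincidence_test requires width-1 features; reduce to breakpoints ",
         "or positions first")
  perm_test(a, b, g, n_perm = n_perm, null = match.arg(null), seed = seed)
}

#' X-to-autosome variant density ratio
#'
#' Variants per uniquely mappable base on the sex chromosome(s) divided by
#' the same density on the autosomes. Ratios below one indicate relative
#' depletion on X, the signature of a male-biased mutational process (the X
#' spends one third of its time in males).
#'
#' @param variants Width-1 `GRanges` of variant positions (or data.frame
#'   with `chrom`/`pos`).
#' @param mappable `GRanges` of uniquely mappable bases.
#' @param g A [genome_layout()] with `sex_chromosomes` declared.
#' @return Numeric ratio; `NA` when either side has zero mappable bases.
#' @export
x_autosome_ratio <- function(variants, mappable, g) {
  if (!length(g$sex_chromosomes))
    stop("the genome layout declares no sex chromosomes")
  if (is.data.frame(variants)) variants <- variants_to_granges(variants, g)
  check_intervals(variants, g)
  check_intervals(mappable, g)
  mapred <- GenomicRanges::reduce(mappable, ignore.strand = TRUE)
  on_x <- as.character(GenomeInfoDb::seqnames(variants)) %in% g$sex_chromosomes
  map_x <- as.character(GenomeInfoDb::seqnames(mapred)) %in% g$sex_chromosomes
  bp_x <- sum(GenomicRanges::width(mapred)[map_x])
  bp_a <- sum(GenomicRanges::width(mapred)[!map_x])
  if (bp_x == 0 || bp_a == 0) return(NA_real_)
  (sum(on_x) / bp_x) / (sum(!on_x) / bp_a)
}

#' Quartile labels by the empirical (type-1) quantile rule
#'
#' Assigns each score to quartile 1-4 using left-open cuts at the type-1
#' empirical quartiles, so scores `1..8` label as `1,1,2,2,3,3,4,4`.
#'
#' @param scores Numeric vector.
#' @return Integer vector of quartile labels in `1:4`.
#' @export
quartile_labels <- function(scores) {
  q <- stats::quantile(scores, probs = c(0.25, 0.5, 0.75), type = 1,
                       names = FALSE)
  1L + findInterval(scores, q, left.open = TRUE)
}

#' Per-group enrichment of variants at stratified sites
#'
#' Runs one permutation test per site stratum (for instance accessibility
#' quartile crossed with bound-factor count): the group's sites are the
#' randomized features and the variant set stays fixed. Empty groups are
#' skipped with a message.
#'
#' @param variants Width-1 `GRanges` (or data.frame with `chrom`/`pos`),
#'   held fixed.
#' @param sites `GRanges` of sites.
#' @param groups Vector of group labels, one per site.
#' @param g A [genome_layout()] object.
#' @param n_perm,null,seed Passed to [perm_test()].
#' @return data.frame of [enrichment_result()] rows, one per non-empty
#'   group, ordered by group label.
#' @export
grouped_enrichment <- function(variants, sites, groups, g, n_perm = 1000L,
                               null = c("circular", "shuffle"), seed = 1L) {
  null <- match.arg(null)
  if (length(groups) != length(sites))
    stop("'groups' must label every site")
  if (is.data.frame(variants)) variants <- variants_to_granges(variants, g)
  out <- list()
  for (grp in sort(unique(groups))) {
    sel <- sites[groups == grp]
    if (length(sel) == 0L) {
      message("skipping empty group ", grp)
      next
    }
    pt <- perm_test(sel, variants, g, n_perm = n_perm, null = null,
                    seed = seed)
    out[[length(out) + 1L]] <-
      enrichment_result(pt, label = as.character(grp), n_sites = length(sel))
  }
  do.call(rbind, out)
}
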