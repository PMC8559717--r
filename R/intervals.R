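#' Merge overlapping or nearby intervals
#'
#' Collapses records of one interval set so that no two output records
#' overlap or lie within `max_gap` bp of each other on the same chromosome.
#' With `max_gap = 0`, book-ended records (zero bases between them) are
#' joined but the set of covered bases is unchanged. Used to merge binding
#' sites of the same motif family so each footprint is called once.
#'
#' @param x A [GenomicRanges::GRanges].
#' @param g A [genome_layout()] object; `x` is validated against it.
#' @param max_gap Maximum gap in bp between records that are still merged
#'   (`>= 0`). A gap of 0 means touching records merge.
#' @param ignore_strand Merge across strands (default `TRUE`, matching
#'   family-wise site merging where palindromic calls collapse).
#' @return A merged `GRanges`.
#' @export
merge_intervals <- function(x, g, max_gap = 0L, ignore_strand = TRUE) {
  check_intervals(x, g)
  if (max_gap < 0) stop("'max_gap' must be >= 0")
  GenomicRanges::reduce(x, min.gapwidth = max_gap + 1L,
                        ignore.strand = ignore_strand)
}

#' Count query records overlapping a subject set
#'
#' Number of records in `query` with at least one shared base with any
#' record of `subject`; each query record counts at most once, however many
#' partners it has. This is the evaluation statistic of the permutation
#' tests.
#'
#' @param query,subject [GenomicRanges::GRanges] on the same genome.
#' @return A single integer.
#' @export
count_overlaps <- function(query, subject) {
  sum(GenomicRanges::countOverlaps(query, subject, ignore.strand = TRUE) > 0L)
}

#' Edge-to-edge distance to the nearest non-identical neighbour
#'
#' For each query record, the distance in bp to the nearest target record,
#' excluding targets with exactly the query's coordinates (self-matches when
#' the query is drawn from the target set). Overlap with any distinct target
#' gives 0. Records with no candidate target on their chromosome get `NA`.
#'
#' Used for homotypic clustering: the median distance from a motif inside an
#' active region to the nearest genome-wide motif of the same family.
#'
#' @param query,target [GenomicRanges::GRanges].
#' @return Integer vector of distances, one per query record; `NA` where
#'   undefined.
#' @export
nearest_distance <- function(query, target) {
  if (length(query) == 0L) return(integer())
  out <- rep(NA_integer_, length(query))

  ov <- GenomicRanges::findOverlaps(query, target, ignore.strand = TRUE)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    ti <- S4Vectors::subjectHits(ov)
    identical_pair <-
      as.character(GenomeInfoDb::seqnames(query))[qi] ==
        as.character(GenomeInfoDb::seqnames(target))[ti] &
      GenomicRanges::start(query)[qi] == GenomicRanges::start(target)[ti] &
      GenomicRanges::end(query)[qi] == GenomicRanges::end(target)[ti]
    out[unique(qi[!identical_pair])] <- 0L
  }

  todo <- which(is.na(out))
  if (length(todo)) {
    q2 <- query[todo]
    # a coordinate-identical target overlaps the query, so precede/follow
    # (strictly non-overlapping neighbours) exclude self-matches by nature
    nxt <- GenomicRanges::precede(q2, target, ignore.strand = TRUE)
    prv <- GenomicRanges::follow(q2, target, ignore.strand = TRUE)
    d_nxt <- rep(NA_integer_, length(q2))
    d_prv <- rep(NA_integer_, length(q2))
    has_n <- !is.na(nxt)
    has_p <- !is.na(prv)
    if (any(has_n))
      d_nxt[has_n] <- GenomicRanges::distance(q2[has_n], target[nxt[has_n]],
                                              ignore.strand = TRUE)
    if (any(has_p))
      d_prv[has_p] <- GenomicRanges::distance(q2[has_p], target[prv[has_p]],
                                              ignore.strand = TRUE)
    out[todo] <- pmin(d_nxt, d_prv, na.rm = TRUE)
    out[todo][!has_n & !has_p] <- NA_integer_
  }
  out
}

#' Keep sites whose flanking window is uniquely mappable
#'
#' A site passes when the fraction of mappable bases in the window of
#' `flank` bp either side of its midpoint is at least `min_fraction`.
#' Windows truncated at chromosome ends use the truncated window length as
#' the denominator. The standard use is requiring >= 95% unique mappability
#' in the 10-kb region around each binding site.
#'
#' @param sites [GenomicRanges::GRanges] of candidate sites.
#' @param mappable `GRanges` track of uniquely mappable bases (merged).
#' @param g A [genome_layout()] object.
#' @param flank Half-window in bp (`> 0`); the full window is `2 * flank`.
#' @param min_fraction Minimum mappable fraction in `[0, 1]`.
#' @return The subset of `sites` passing the filter.
#' @export
filter_by_mappability <- function(sites, mappable, g, flank = 5000L,
                                  min_fraction = 0.95) {
  check_intervals(sites, g)
  check_intervals(mappable, g)
  if (flank <= 0) stop("'flank' must be > 0")
  if (min_fraction < 0 || min_fraction > 1)
    stop("'min_fraction' must be in [0, 1]")
  if (length(sites) == 0L) return(sites)
  win <- GenomicRanges::granges(midpoint_windows(sites, g, flank = flank))
  GenomicRanges::strand(win) <- "*"
  mapred <- GenomicRanges::reduce(mappable, ignore.strand = TRUE)
  GenomicRanges::strand(mapred) <- "*"
  ov <- GenomicRanges::findOverlaps(win, mapred)
  inter <- GenomicRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                     mapred[S4Vectors::subjectHits(ov)])
  mapp_bp <- rep(0, length(win))
  got <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
  mapp_bp[as.integer(names(got))] <- got
  frac <- mapp_bp / GenomicRanges::width(win)
  sites[frac >= min_fraction]
}

#' Replace intervals by fixed windows around their midpoints
#'
#' Each record becomes the window of `flank` bp either side of its midpoint,
#' clipped to chromosome bounds. Midpoints follow the half-open convention
#' of BED files: for a record covering 0-based `[s, e)` the midpoint base is
#' `floor((s + e) / 2)` and the window is `[mid - flank, mid + flank)`.
#' Enhancer activity classification uses midpoint +/- 500 bp windows.
#'
#' @inheritParams filter_by_mappability
#' @param x [GenomicRanges::GRanges].
#' @return A `GRanges` of clipped midpoint windows, metadata preserved.
#' @export
midpoint_windows <- function(x, g, flank = 500L) {
  check_intervals(x, g)
  if (flank <= 0) stop("'flank' must be > 0")
  if (length(x) == 0L) return(x)
  s0 <- GenomicRanges::start(x) - 1L          # 0-based start
  e0 <- GenomicRanges::end(x)                 # half-open end
  mid0 <- (s0 + e0) %/% 2L
  L <- g$lengths[as.character(GenomeInfoDb::seqnames(x))]
  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(x),
    IRanges::IRanges(start = pmax(mid0 - flank + 1L, 1L),
                     end = pmin(mid0 + flank, L)),
    strand = GenomicRanges::strand(x),
    seqinfo = as_seqinfo(g))
  S4Vectors::mcols(out) <- S4Vectors::mcols(x)
  out
}

#' Read a BED3/BED6 file into a GRanges
#'
#' Tab-delimited, no header; name/score/strand columns optional. BED's
#' 0-based half-open coordinates are converted to the 1-based closed
#' convention of `GRanges` on read (and back on write), so files round-trip
#' bit-exactly.
#'
#' @param path File path.
#' @param g Optional [genome_layout()]; when given, intervals are validated
#'   and the seqinfo applied.
#' @return A `GRanges` (with `name`/`score` metadata when present).
#' @export
read_bed <- function(path, g = NULL) {
  x <- rtracklayer::import(path, format = "BED")
  x <- methods::as(x, "GRanges")
  if (!is.null(g)) check_intervals(x, g)
  x
}

#' Write a GRanges as BED
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
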