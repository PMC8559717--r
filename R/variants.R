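#' Read short variants from a VCF
#'
#' Reads SNPs and indels with their `AC`/`AN` INFO fields, splitting
#' multiallelic records into biallelic ones and keeping only records whose
#' FILTER column is `PASS` or `.`. Positions are reported 1-based (VCF
#' convention), which matches the package's internal GRanges convention.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param cohort_tag Label recorded on every returned record.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `vclass`
#'   (`SNP`/`insertion`/`deletion`), `size` (0 for SNPs, net length change
#'   for indels), `ac`, `an`, `cohort`.
#' @export
read_variant_vcf <- function(path, cohort_tag = "cohort") {
  vcf <- VariantAnnotation::readVcf(path)
  filt <- VariantAnnotation::filt(vcf)
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  vcf <- vcf[keep]
  vcf <- VariantAnnotation::expand(vcf)   # biallelic split; AC is per-alt
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  vclass <- ifelse(nchar(ref) == nchar(alt), "SNP",
            ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref,
    alt = alt,
    vclass = vclass,
    size = abs(nchar(alt) - nchar(ref)),
    ac = as.integer(unlist(info$AC)),
    an = as.integer(info$AN),
    cohort = cohort_tag,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Classify short variants by rarity and size
#'
#' Rarity rules: a variant is a `singleton` when its allele count is exactly
#' one and its allele number is at least `min_an` (cohorts of 100,000+
#' alleles make a singleton's frequency <= 0.001%); `common` when
#' `AC/AN >= common_min_af` (default 5%); anything else is `other`.
#' Size classes for indels: `1-2bp`, `5-20bp`, or `excluded` for lengths
#' outside both windows; substitutions are `SNP`.
#'
#' @param variants data.frame as returned by [read_variant_vcf()].
#' @param min_an Minimum allele number for the singleton call (default
#'   100,000).
#' @param common_min_af Minimum allele frequency for the common call
#'   (default 0.05).
#' @return `variants` with added columns `rarity` and `size_class`. Records
#'   with `an == 0` are rejected with an error.
#' @export
classify_variants <- function(variants, min_an = 100000L,
                              common_min_af = 0.05) {
  if (any(is.na(variants$an)) || any(variants$an == 0))
    stop("records with missing or zero allele number (AN) cannot be classified")
  if (any(variants$ac < 1))
    stop("allele count (AC) must be >= 1")
  if (any(variants$ac > variants$an))
    stop("AC must not exceed AN")
  af <- variants$ac / variants$an
  rarity <- ifelse(variants$ac == 1L & variants$an >= min_an, "singleton",
            ifelse(af >= common_min_af, "common", "other"))
  size_class <- ifelse(variants$vclass == "SNP", "SNP",
                ifelse(variants$size >= 1 & variants$size <= 2, "1-2bp",
                ifelse(variants$size >= 5 & variants$size <= 20, "5-20bp",
                       "excluded")))
  variants$rarity <- rarity
  variants$size_class <- size_class
  variants
}

#' Remove indels closer together than a minimum gap
#'
#' Mirrors an indel-gap normalization step: any indel whose position lies
#' within `min_gap` bp of another indel's position on the same chromosome is
#' dropped, and both members of a violating pair are removed (symmetric,
#' conservative reading of the gap filter). SNPs pass through untouched.
#'
#' @param variants data.frame of variants (see [read_variant_vcf()]).
#' @param min_gap Minimum separation in bp (default 2: positions 100 and 101
#'   conflict, 100 and 102 do not).
#' @return The filtered data.frame.
#' @export
normalize_indels <- function(variants, min_gap = 2L) {
  is_indel <- variants$vclass %in% c("insertion", "deletion")
  idx <- which(is_indel)
  if (length(idx) < 2L) return(variants)
  ind <- variants[idx, , drop = FALSE]
  ord <- order(ind$chrom, ind$pos)
  pos <- ind$pos[ord]
  chr <- ind$chrom[ord]
  n <- length(pos)
  close_next <- c(chr[-n] == chr[-1] & (pos[-1] - pos[-n]) < min_gap, FALSE)
  bad <- close_next | c(FALSE, close_next[-n])
  drop <- idx[ord][bad]
  if (length(drop)) variants <- variants[-drop, , drop = FALSE]
  variants
}

#' Read structural variants from a BED-like TSV
#'
#' Columns (tab-separated, header optional via `header`): chrom, start, end,
#' type (`deletion`/`duplication`), and optionally a frequency annotation.
#' Start/end follow the BED half-open 0-based convention and are converted
#' to 1-based closed positions internally.
#'
#' @param path File path.
#' @param header Does the file carry a header line (default `FALSE`)?
#' @param cohort_tag Label recorded on every record.
#' @return data.frame with `chrom`, `start`, `end` (1-based closed), `type`,
#'   `freq` (`NA` when absent), `cohort`.
#' @export
read_sv_tsv <- function(path, header = FALSE, cohort_tag = "cohort") {
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("SV file needs at least chrom, start, end, type")
  names(tab)[1:4] <- c("chrom", "start", "end", "type")
  out <- data.frame(
    chrom = as.character(tab$chrom),
    start = as.integer(tab$start) + 1L,
    end = as.integer(tab$end),
    type = as.character(tab$type),
    freq = if (ncol(tab) >= 5) suppressWarnings(as.numeric(tab[[5]])) else NA_real_,
    cohort = cohort_tag,
    stringsAsFactors = FALSE
  )
  if (any(out$end < out$start)) stop("SV with end <= start")
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Group structural variants by reciprocal overlap
#'
#' Two SVs of the same type are considered the same variant when their
#' intersection covers at least `min_fraction` of EACH of them (the 80%
#' reciprocal overlap criterion). Groups are the connected components of
#' this link graph, so chains are merged transitively.
#'
#' @param svs data.frame of SVs of a single type (`chrom`, `start`, `end`,
#'   1-based closed).
#' @param min_fraction Reciprocal overlap fraction in `(0, 1]`, default 0.8.
#' @return Integer vector of group ids (1-based, arbitrary but stable
#'   labels), one per row of `svs`.
#' @export
reciprocal_overlap_group <- function(svs, min_fraction = 0.8) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must be in (0, 1]")
  if (length(unique(svs$type)) > 1)
    stop("mixed SV types; group deletions and duplications separately")
  n <- nrow(svs)
  if (n == 0L) return(integer())
  gr <- GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(svs$start, svs$end))
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- qi < si
  qi <- qi[keep]; si <- si[keep]
  if (length(qi)) {
    inter <- pmin(svs$end[qi], svs$end[si]) - pmax(svs$start[qi], svs$start[si]) + 1L
    w_q <- svs$end[qi] - svs$start[qi] + 1L
    w_s <- svs$end[si] - svs$start[si] + 1L
    linked <- inter >= min_fraction * w_q & inter >= min_fraction * w_s
    qi <- qi[linked]; si <- si[linked]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = qi, to = si),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  as.integer(comp[as.character(seq_len(n))])
}

#' Extract breakpoints from structural variants
#'
#' Breakpoints are the 5' and 3' coordinates of an SV, represented as 1-bp
#' features. In `singleton_per_sv` mode every SV contributes its own two
#' breakpoints (never deduplicated). In `common_grouped` mode SVs are first
#' grouped by reciprocal overlap; each group contributes the outermost start
#' and outermost end of its members, and identical breakpoint coordinates
#' across groups are counted once.
#'
#' Under the half-open file convention the 3' breakpoint is the last base
#' inside the SV footprint: a deletion written as BED `[1000, 5000)` yields
#' breakpoints at 0-based positions 1000 and 4999.
#'
#' @param svs data.frame of SVs of a single type (see [read_sv_tsv()]).
#' @param g A [genome_layout()] object.
#' @param mode `"singleton_per_sv"` or `"common_grouped"`.
#' @param min_fraction Reciprocal overlap fraction used in grouped mode.
#' @return A width-1 `GRanges`; metadata column `sv_id` (singleton mode) or
#'   `group_id` (grouped mode, first contributing group per coordinate).
#' @export
extract_breakpoints <- function(svs, g,
                                mode = c("singleton_per_sv", "common_grouped"),
                                min_fraction = 0.8) {
  mode <- match.arg(mode)
  if (nrow(svs) == 0L)
    return(check_intervals(GenomicRanges::GRanges(seqinfo = as_seqinfo(g)), g))
  if (mode == "singleton_per_sv") {
    bp <- GenomicRanges::GRanges(
      rep(svs$chrom, 2L),
      IRanges::IRanges(start = c(svs$start, svs$end), width = 1L))
    bp$sv_id <- rep(seq_len(nrow(svs)), 2L)
  } else {
    grp <- reciprocal_overlap_group(svs, min_fraction = min_fraction)
    starts <- tapply(svs$start, grp, min)
    ends <- tapply(svs$end, grp, max)
    chroms <- tapply(svs$chrom, grp, function(x) x[1])
    ids <- as.integer(names(starts))
    bp <- GenomicRanges::GRanges(
      rep(as.character(chroms), 2L),
      IRanges::IRanges(start = c(as.integer(starts), as.integer(ends)),
                       width = 1L))
    bp$group_id <- rep(ids, 2L)
    key <- paste(as.character(GenomeInfoDb::seqnames(bp)),
                 GenomicRanges::start(bp))
    bp <- bp[!duplicated(key)]
  }
  bp <- GenomicRanges::sort(bp, ignore.strand = TRUE)
  check_intervals(bp, g)
  bp
}

#' Flag SVs absent from a reference catalog
#'
#' Novelty screening: an SV is novel when it does not satisfy the
#' reciprocal-overlap criterion with any record of a supplied reference SV
#' set of the same type (the reference catalog is an input file, e.g. a
#' population SV database export).
#'
#' @param svs data.frame of candidate SVs (single type).
#' @param reference data.frame of reference SVs of the same type.
#' @param min_fraction Reciprocal overlap fraction, default 0.8.
#' @return Logical vector: `TRUE` where the SV is novel.
#' @export
novel_svs <- function(svs, reference, min_fraction = 0.8) {
  if (nrow(svs) == 0L) return(logical())
  if (nrow(reference) == 0L) return(rep(TRUE, nrow(svs)))
  if (length(unique(c(svs$type, reference$type))) > 1)
    stop("mixed SV types; screen deletions and duplications separately")
  a <- GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(svs$start, svs$end))
  b <- GenomicRanges::GRanges(reference$chrom,
                              IRanges::IRanges(reference$start, reference$end))
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  inter <- pmin(svs$end[qi], reference$end[si]) -
    pmax(svs$start[qi], reference$start[si]) + 1L
  wa <- svs$end[qi] - svs$start[qi] + 1L
  wb <- reference$end[si] - reference$start[si] + 1L
  known <- unique(qi[inter >= min_fraction * wa & inter >= min_fraction * wb])
  out <- rep(TRUE, nrow(svs))
  out[known] <- FALSE
  out
}

#' Downsample records without replacement
#'
#' Uniform sample of `n` records, deterministic for a fixed seed, returned
#' in coordinate order. Works on data.frames carrying `chrom`/`pos` (or
#' `chrom`/`start`) columns and on `GRanges`. Used to bring variant classes
#' to a common size (e.g. 650,000 short variants per class; 10,000 control
#' motif sites per family).
#'
#' @param x data.frame or `GRanges`.
#' @param n Number of records to keep (`n <= nrow/length(x)`).
#' @param seed Integer seed.
#' @return Object of the same type as `x` with `n` records.
#' @export
downsample_records <- function(x, n, seed = 1L) {
  size <- if (methods::is(x, "GRanges")) length(x) else nrow(x)
  if (n > size) stop("'n' exceeds the number of records (", size, ")")
  idx <- with_seed(seed, sample.int(size, n))
  if (methods::is(x, "GRanges")) {
    GenomicRanges::sort(x[idx], ignore.strand = TRUE)
  } else {
    out <- x[idx, , drop = FALSE]
    poscol <- if ("pos" %in% names(out)) "pos" else "start"
    out[order(out$chrom, out[[poscol]]), , drop = FALSE]
  }
}

#' Upper bound on the carrier frequency of a singleton variant
#'
#' A variant seen exactly once across several cohorts has carrier frequency
#' at most one over the total number of screened individuals.
#'
#' @param cohort_sizes Integer vector of individuals per cohort.
#' @return Percentage (e.g. `0.002` means 0.002%).
#' @examples
#' carrier_frequency_bound(c(9625, 10738, 29084))  # ~0.002
#' @export
carrier_frequency_bound <- function(cohort_sizes) {
  total <- sum(as.numeric(cohort_sizes))
  if (total <= 0) stop("cohort sizes must sum to a positive count")
  100 / total
}

#' Convert 1-bp variant records to a GRanges
#'
#' @param variants data.frame with `chrom` and `pos` columns.
#' @param g Optional [genome_layout()] for validation.
#' @return A width-1 `GRanges` in input row order.
#' @export
variants_to_granges <- function(variants, g = NULL) {
  gr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1L))
  if (!is.null(g)) check_intervals(gr, g)
  gr
}
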