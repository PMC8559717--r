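#' Define the chromosome universe for an analysis
#'
#' A `GenomeLayout` fixes the set of chromosome names, their lengths, and
#' which of them are sex chromosomes. Every interval set used downstream is
#' validated against it, and the circular permutation null rotates features
#' around these chromosome lengths.
#'
#' @param chromosomes Character vector of chromosome names (unique).
#' @param lengths Integer vector of chromosome lengths in bp (`> 0`), parallel
#'   to `chromosomes`.
#' @param sex_chromosomes Character vector naming the subset of `chromosomes`
#'   treated as sex chromosomes (e.g. `"chrX"`); may be empty.
#'
#' @return An object of class `GenomeLayout`.
#' @examples
#' genome_layout(c("chr1", "chrX"), c(1e6, 5e5), sex_chromosomes = "chrX")
#' @export
genome_layout <- function(chromosomes, lengths, sex_chromosomes = character()) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("'chromosomes' and 'lengths' must have the same length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  bad <- setdiff(sex_chromosomes, chromosomes)
  if (length(bad))
    stop("sex chromosome(s) not in layout: ", paste(bad, collapse = ", "))
  structure(
    list(
      chromosomes = chromosomes,
      lengths = stats::setNames(lengths, chromosomes),
      sex_chromosomes = as.character(sex_chromosomes)
    ),
    class = "GenomeLayout"
  )
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout with", length(x$chromosomes), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  if (length(x$sex_chromosomes))
    cat("  sex chromosomes:", paste(x$sex_chromosomes, collapse = ", "), "\n")
  invisible(x)
}

#' Read a chrom.sizes file into a GenomeLayout
#'
#' Two tab-separated columns, no header: chromosome name and length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @inheritParams genome_layout
#' @return A [genome_layout()] object.
#' @export
read_chrom_sizes <- function(path, sex_chromosomes = character()) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_layout(tab$chrom, tab$length, sex_chromosomes = sex_chromosomes)
}

#' Convert a GenomeLayout to a Seqinfo
#'
#' @param g A [genome_layout()] object.
#' @return A [GenomeInfoDb::Seqinfo] carrying the layout's names and lengths.
#' @export
as_seqinfo <- function(g) {
  stopifnot(inherits(g, "GenomeLayout"))
  GenomeInfoDb::Seqinfo(seqnames = g$chromosomes,
                        seqlengths = as.integer(g$lengths))
}

#' Validate a GRanges against a GenomeLayout
#'
#' Checks that every range sits on a known chromosome and within
#' `[1, length]`. Called by all layout-aware operations; exported because the
#' same check is useful when assembling inputs by hand.
#'
#' @param x A [GenomicRanges::GRanges].
#' @param g A [genome_layout()] object.
#' @return `x`, invisibly, with the layout's seqinfo applied.
#' @export
check_intervals <- function(x, g) {
  stopifnot(inherits(g, "GenomeLayout"))
  if (!methods::is(x, "GRanges"))
    stop("'x' must be a GRanges")
  chroms <- as.character(GenomeInfoDb::seqnames(x))
  unknown <- setdiff(unique(chroms), g$chromosomes)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (length(x)) {
    lens <- g$lengths[chroms]
    if (any(GenomicRanges::start(x) < 1) || any(GenomicRanges::end(x) > lens))
      stop("interval(s) outside chromosome bounds")
  }
  GenomeInfoDb::seqlevels(x) <- g$chromosomes
  GenomeInfoDb::seqinfo(x) <- as_seqinfo(g)
  invisible(x)
}

# run code under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed on exit so library calls do not perturb user RNG
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
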