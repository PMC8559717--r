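#' Construct a position weight matrix
#'
#' A PWM is a 4 x L matrix of per-position base probabilities in A, C, G, T
#' order. Counts (e.g. from a JASPAR PFM) are converted to probabilities
#' with a pseudocount added to every cell; probability matrices are
#' renormalized so columns sum to one.
#'
#' @param mat Numeric 4 x L matrix of counts or probabilities, rows A,C,G,T.
#' @param name Motif name.
#' @param pseudocount Added to every cell before column normalization when
#'   `mat` contains counts (default 0.1, the usual scanning default).
#' @return An object of class `pwm`: the probability matrix with attributes
#'   `name` and `pseudocount`.
#' @export
pwm <- function(mat, name = "motif", pseudocount = 0.1) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1L) stop("PWM must have at least one column")
  if (any(mat < 0) || any(!is.finite(mat))) stop("PWM entries must be finite and >= 0")
  is_prob <- all(abs(colSums(mat) - 1) < 1e-6)
  if (!is_prob) mat <- mat + pseudocount
  mat <- sweep(mat, 2L, colSums(mat), "/")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(mat, name = name, pseudocount = pseudocount, class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", sQuote(attr(x, "name")), "of length", ncol(x), "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

pwm_name <- function(p) attr(p, "name")
pwm_length <- function(p) ncol(p)

#' Read motifs from a JASPAR-format PFM flat file
#'
#' Parses the classic JASPAR text layout: a `>name` header line followed by
#' four rows of counts, either bare numbers or the bracketed
#' `A  [ 4 19 0 ]` form. Multiple motifs per file are supported.
#'
#' @param path File path.
#' @param pseudocount Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) < 4L) stop("motif block with fewer than 4 rows in ", path)
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("ragged count rows for motif ", name)
    out[[name]] <- pwm(do.call(rbind, rows), name = name,
                       pseudocount = pseudocount)
  }
  out
}

# IUPAC code -> member bases, used for consensus conversion
.iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Convert an IUPAC consensus string to a PWM
#'
#' A specified base receives probability `1 - 3 * epsilon` and the other
#' bases `epsilon` each; `N` gives 0.25 everywhere. Degenerate codes with k
#' member bases split `1 - (4 - k) * epsilon` equally among members. The
#' standard use is the 13-mer PRDM9 consensus `"CCNCCNTNNCCNC"`.
#'
#' @param consensus Character string over the IUPAC alphabet.
#' @param epsilon Leak probability for unspecified bases (default 0.01).
#' @param name Motif name (defaults to the consensus itself).
#' @return A [pwm()] object of length `nchar(consensus)`.
#' @examples
#' consensus_to_pwm("CCNCCNTNNCCNC")
#' @export
consensus_to_pwm <- function(consensus, epsilon = 0.01, name = consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (!length(chars)) stop("empty consensus")
  bad <- setdiff(chars, names(.iupac))
  if (length(bad))
    stop("invalid consensus character(s): ", paste(unique(bad), collapse = ", "))
  bases <- c("A", "C", "G", "T")
  mat <- vapply(chars, function(ch) {
    members <- .iupac[[ch]]
    k <- length(members)
    col <- rep(epsilon, 4L)
    col[match(members, bases)] <- (1 - (4 - k) * epsilon) / k
    col
  }, numeric(4))
  pwm(matrix(mat, nrow = 4L), name = name)
}

#' Reverse complement of a PWM
#'
#' @param p A [pwm()] object.
#' @return A `pwm` for the opposite strand (columns reversed, A/T and C/G
#'   rows swapped).
#' @export
pwm_reverse_complement <- function(p) {
  m <- unclass(p)[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(p))), drop = FALSE]
  pwm(m, name = paste0(pwm_name(p), "_rc"),
      pseudocount = attr(p, "pseudocount"))
}

#' Correlation distance between two PWMs
#'
#' `1 -` the maximum Pearson correlation between flattened probability
#' columns over all ungapped offsets of `q` (and its reverse complement)
#' against `p`, requiring at least `min(4, L)` aligned columns per offset.
#' Identical motifs, or a motif against its own reverse complement, give 0;
#' the distance lies in `[0, 2]`.
#'
#' @param p,q [pwm()] objects.
#' @return A single numeric distance.
#' @export
pwm_distance <- function(p, q) {
  best <- -1
  for (qq in list(unclass(q), unclass(pwm_reverse_complement(q)))) {
    r <- .best_offset_cor(unclass(p), qq)
    if (r > best) best <- r
  }
  1 - best
}

.best_offset_cor <- function(a, b) {
  la <- ncol(a); lb <- ncol(b)
  min_ov <- min(4L, la, lb)
  best <- -1
  for (off in (-(lb - min_ov)):(la - min_ov)) {
    ia <- max(1L, 1L + off):min(la, lb + off)
    ib <- ia - off
    va <- as.vector(a[, ia, drop = FALSE])
    vb <- as.vector(b[, ib, drop = FALSE])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    r <- stats::cor(va, vb)
    if (r > best) best <- r
  }
  best
}

#' Distance matrix over a set of PWMs
#'
#' @param pwms List of [pwm()] objects.
#' @return A symmetric `dist`-convertible matrix of [pwm_distance()] values.
#' @export
pwm_distance_matrix <- function(pwms) {
  n <- length(pwms)
  nm <- vapply(pwms, pwm_name, character(1))
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- pwm_distance(pwms[[i]], pwms[[j]])
      }
    }
  }
  d
}

#' Cluster PWMs into motif families
#'
#' Average-linkage hierarchical clustering on the PWM correlation distance,
#' with the tree cut at `threshold`. Similar motifs bound by different
#' proteins collapse into one family so that a footprint matched by several
#' of them is only counted once. Each family records its members and a
#' representative (the longest member; ties broken lexicographically).
#'
#' @param pwms List of [pwm()] objects.
#' @param threshold Tree cut height (default 0.25; see the package vignette
#'   for how the default was chosen).
#' @return data.frame with one row per PWM: `name`, `family_id`,
#'   `representative`.
#' @export
cluster_families <- function(pwms, threshold = 0.25) {
  if (!length(pwms)) stop("need at least one PWM")
  nm <- vapply(pwms, pwm_name, character(1))
  if (length(pwms) == 1L) {
    fam <- 1L
  } else {
    d <- pwm_distance_matrix(pwms)
    # clamp tiny negative rounding noise; hclust needs a true dist
    d[d < 0] <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    fam <- stats::cutree(hc, h = threshold)
  }
  lens <- vapply(pwms, pwm_length, integer(1))
  rep_of <- vapply(split(seq_along(pwms), fam), function(ix) {
    ix <- ix[order(-lens[ix], nm[ix])]
    nm[ix[1]]
  }, character(1))
  # renumber families deterministically by representative name
  ord <- order(rep_of)
  relabel <- stats::setNames(seq_along(ord), names(rep_of)[ord])
  data.frame(
    name = nm,
    family_id = as.integer(relabel[as.character(fam)]),
    representative = rep_of[as.character(fam)],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Log-odds score matrix of a PWM
#'
#' @param p A [pwm()] object.
#' @param background Background base probabilities (A,C,G,T), default
#'   uniform.
#' @return 4 x L matrix of log2 odds scores.
#' @export
pwm_log_odds <- function(p, background = rep(0.25, 4)) {
  if (length(background) != 4L || any(background <= 0))
    stop("'background' must be 4 positive probabilities")
  background <- background / sum(background)
  log2(unclass(p) / background)
}

#' Map a scan p-value to a log-odds score threshold
#'
#' Computes the exact null distribution of the PWM log-odds score under the
#' background model by dynamic programming: per-position score
#' distributions, discretized at `granularity` bits, are convolved across
#' positions. Returns the smallest score `s` with `P(score >= s) <= pvalue`
#' (the FIMO-style score cutoff; FIMO's default scan p-value is 1e-4).
#'
#' @param p A [pwm()] object.
#' @param pvalue Target p-value in `(0, 1]`; 1 returns the minimum
#'   achievable score.
#' @param background Background base probabilities (A,C,G,T).
#' @param granularity Score discretization in bits (default 1e-3).
#' @return Numeric score threshold with attribute `attained_p` (the actual
#'   tail probability at the threshold). If `pvalue` is below the best
#'   achievable tail, the maximum score is returned with attribute
#'   `unattainable = TRUE` and a warning.
#' @export
score_threshold <- function(p, pvalue = 1e-4, background = rep(0.25, 4),
                            granularity = 1e-3) {
  if (pvalue <= 0 || pvalue > 1) stop("'pvalue' must be in (0, 1]")
  background <- background / sum(background)
  lo <- pwm_log_odds(p, background)
  q <- round(lo / granularity)               # integer score units
  L <- ncol(q)
  offset <- sum(apply(q, 2L, min))           # smallest achievable total
  span <- sum(apply(q, 2L, max)) - offset + 1L
  dist <- numeric(span)                      # dist[i] = P(total = offset + i - 1)
  dist[1L] <- 1
  reach <- 1L                                # current support size
  minsofar <- 0L
  for (j in seq_len(L)) {
    qj <- q[, j] - min(q[, j])
    new <- numeric(min(span, reach + max(qj)))
    for (b in 1:4) {
      sh <- qj[b]
      idx <- seq_len(reach) + sh
      new[idx] <- new[idx] + background[b] * dist[seq_len(reach)]
    }
    reach <- length(new)
    dist <- new
    minsofar <- minsofar + min(q[, j])
  }
  # survival function over the discrete support
  surv <- rev(cumsum(rev(dist)))
  scores <- (offset + seq_len(reach) - 1L) * granularity
  ok <- which(surv <= pvalue & dist > 0)   # smallest achievable score
  if (!length(ok)) {
    warning("requested p-value below the best achievable tail; ",
            "returning the maximum score")
    out <- scores[reach]
    attr(out, "attained_p") <- surv[reach]
    attr(out, "unattainable") <- TRUE
    return(out)
  }
  i <- ok[1L]
  out <- scores[i]
  attr(out, "attained_p") <- surv[i]
  attr(out, "unattainable") <- FALSE
  out
}

#' Scan sequences for PWM matches above a score threshold
#'
#' Slides the PWM log-odds matrix over both strands of each input sequence
#' and emits every window scoring at least `threshold`. Windows containing
#' `N` are skipped. Coordinates are reported on the forward strand
#' (1-based, closed, per the package convention); minus-strand hits cover
#' the same forward-strand window with strand `-`.
#'
#' @param seqs Named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.
#' @param p A [pwm()] object.
#' @param threshold Log-odds score cutoff (see [score_threshold()]).
#' @param background Background probabilities used for the log-odds matrix.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return `GRanges` of hits with metadata `score` (best log2 odds) and
#'   `motif`.
#' @export
scan_sequences <- function(seqs, p, threshold, background = rep(0.25, 4),
                           both_strands = TRUE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("'seqs' must be named by chromosome")
  lo_f <- pwm_log_odds(p, background)
  mats <- list(`+` = lo_f)
  if (both_strands)
    mats$`-` <- pwm_log_odds(pwm_reverse_complement(p), background)
  L <- ncol(lo_f)
  hits <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(as.character(seqs[[chrom]]), "")[[1]]
    code <- match(chars, c("A", "C", "G", "T"))
    n <- length(code)
    if (n < L) next
    nwin <- n - L + 1L
    for (str in names(mats)) {
      m <- mats[[str]]
      sc <- numeric(nwin)
      for (j in seq_len(L)) {
        v <- m[code[j:(j + nwin - 1L)], j]
        sc <- sc + v                      # NA codes (N) propagate
      }
      pass <- which(!is.na(sc) & sc >= threshold)
      if (length(pass)) {
        hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(start = pass, width = L),
          strand = str, score = sc[pass], motif = pwm_name(p))
      }
    }
  }
  if (!length(hits)) {
    out <- GenomicRanges::GRanges()
    out$score <- numeric()
    out$motif <- character()
    return(out)
  }
  GenomicRanges::sort(do.call(c, hits), ignore.strand = TRUE)
}

#' Merge member-motif hits into family-level binding sites
#'
#' Overlapping hits from PWMs of the same family are merged into one site
#' (gap 0), and palindromic duplicates -- identical coordinates called on
#' both strands -- collapse to a single record. The merged record keeps the
#' best (maximum) hit score.
#'
#' @param hits `GRanges` of hits (e.g. concatenated [scan_sequences()]
#'   output for all member PWMs), with a `score` metadata column optional.
#' @param g A [genome_layout()] object.
#' @param family_id Integer label stored on the output.
#' @return Merged `GRanges` with metadata `family_id` (and `score` when the
#'   input carried scores).
#' @export
build_family_sites <- function(hits, g, family_id = 1L) {
  check_intervals(hits, g)
  merged <- GenomicRanges::reduce(hits, min.gapwidth = 1L,
                                  ignore.strand = TRUE)
  if (length(merged) && !is.null(hits$score)) {
    ov <- GenomicRanges::findOverlaps(merged, hits, ignore.strand = TRUE)
    best <- tapply(hits$score[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), max)
    merged$score <- as.numeric(best[as.character(seq_along(merged))])
  }
  merged$family_id <- family_id
  merged
}
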