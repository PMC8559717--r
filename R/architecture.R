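#' Classify enhancers as germline active or inactive
#'
#' An enhancer counts as active in the germline when the window of
#' `flank` bp either side of its midpoint intersects at least one
#' accessibility peak; the midpoint window corrects for variable enhancer
#' size. The partition is exhaustive and exclusive.
#'
#' @param enhancers `GRanges` of enhancers.
#' @param peaks `GRanges` of accessibility peaks.
#' @param g A [genome_layout()] object.
#' @param flank Half-window in bp (default 500).
#' @return List with elements `active` and `inactive` (`GRanges`).
#' @export
classify_enhancer_activity <- function(enhancers, peaks, g, flank = 500L) {
  check_intervals(enhancers, g)
  check_intervals(peaks, g)
  win <- midpoint_windows(enhancers, g, flank = flank)
  hit <- GenomicRanges::countOverlaps(win, peaks, ignore.strand = TRUE) > 0L
  list(active = enhancers[hit], inactive = enhancers[!hit])
}

#' Odds ratio of disruption for shared versus tissue-specific enhancers
#'
#' Given `A` disrupted among `B` germline-active enhancers and `C` disrupted
#' among `D` germline-inactive enhancers, computes
#' `OR = (A / (B - A)) / (C / (D - C))` with the 95% log-scale confidence
#' interval `exp(log(OR) +/- 1.96 * sqrt(1/A + 1/(B-A) + 1/C + 1/(D-C)))`.
#'
#' @param A Disrupted, active count (`0 < A < B`).
#' @param B All active count.
#' @param C Disrupted, inactive count (`0 < C < D`).
#' @param D All inactive count.
#' @return Object of class `odds_ratio`: list with `or`, `ci_low`,
#'   `ci_high`, `counts`, `degenerate`. Degenerate tables (`A = 0`, `C = 0`,
#'   `A = B`, or `C = D`) return `NA` values with `degenerate = TRUE`.
#' @examples
#' odds_ratio(20, 100, 10, 200)  # OR = (20/80)/(10/190) = 4.75
#' @export
odds_ratio <- function(A, B, C, D) {
  counts <- c(A = A, B = B, C = C, D = D)
  if (A < 0 || C < 0 || B < A || D < C)
    stop("need 0 <= A <= B and 0 <= C <= D")
  if (A == 0 || C == 0 || A == B || C == D) {
    return(structure(list(or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, counts = counts,
                          degenerate = TRUE),
                     class = "odds_ratio"))
  }
  or <- (A / (B - A)) / (C / (D - C))
  se <- sqrt(1 / A + 1 / (B - A) + 1 / C + 1 / (D - C))
  structure(list(or = or,
                 ci_low = exp(log(or) - 1.96 * se),
                 ci_high = exp(log(or) + 1.96 * se),
                 counts = counts,
                 degenerate = FALSE),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  if (x$degenerate) {
    cat("Odds ratio undefined (degenerate 2x2 table)\n")
  } else {
    cat(sprintf("OR = %.2f (95%% CI [%.2f, %.2f])\n",
                x$or, x$ci_low, x$ci_high))
  }
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Count enhancers disrupted by a variant set
#'
#' An enhancer is "disrupted" when at least one variant (e.g. a singleton
#' breakpoint or insertion position) intersects it. `mode = "window"`
#' (default) tests the midpoint +/- `flank` window used for the activity
#' classification; `mode = "body"` tests the full enhancer extent.
#'
#' @param enhancers `GRanges`.
#' @param variants Width-1 `GRanges` of variant positions.
#' @param g A [genome_layout()] object.
#' @param flank Half-window in bp for `"window"` mode.
#' @param mode `"window"` or `"body"`.
#' @return Integer count of disrupted enhancers.
#' @export
count_disrupted <- function(enhancers, variants, g, flank = 500L,
                            mode = c("window", "body")) {
  mode <- match.arg(mode)
  check_intervals(enhancers, g)
  check_intervals(variants, g)
  region <- if (mode == "window") midpoint_windows(enhancers, g, flank)
            else enhancers
  sum(GenomicRanges::countOverlaps(region, variants, ignore.strand = TRUE) > 0L)
}

#' Odds ratio of enhancer disruption by germline activity
#'
#' Convenience wrapper: classifies enhancers by germline activity, counts
#' disrupted enhancers in each class, and evaluates [odds_ratio()].
#'
#' @inheritParams classify_enhancer_activity
#' @param variants Width-1 `GRanges` of disrupting variant positions.
#' @param mode Disruption mode, see [count_disrupted()].
#' @return An [odds_ratio()] object.
#' @export
enhancer_disruption_or <- function(enhancers, peaks, variants, g,
                                   flank = 500L,
                                   mode = c("window", "body")) {
  mode <- match.arg(mode)
  cls <- classify_enhancer_activity(enhancers, peaks, g, flank = flank)
  A <- count_disrupted(cls$active, variants, g, flank = flank, mode = mode)
  C <- count_disrupted(cls$inactive, variants, g, flank = flank, mode = mode)
  odds_ratio(A, length(cls$active), C, length(cls$inactive))
}

#' Homotypic motif clustering ratio
#'
#' For one motif family, measures how much closer together motifs are near
#' target regulatory sites than near reference sites. For motifs inside the
#' target regions, compute the median distance to the nearest genome-wide
#' motif of the same family (self-matches excluded, see
#' [nearest_distance()]); likewise for the reference regions. The ratio
#' `reference_median / target_median` exceeds one when target-region motifs
#' sit in tighter clusters.
#'
#' @param target_sites `GRanges`: family motifs within the target regions
#'   (e.g. germline-active sites).
#' @param reference_sites `GRanges`: family motifs within the reference
#'   regions (e.g. sites active in somatic tissues).
#' @param all_family_motifs `GRanges`: genome-wide motif scan for the
#'   family.
#' @return List of class `clustering_ratio`: `median_target`,
#'   `median_reference`, `ratio` (`NA` when either median is undefined).
#' @export
clustering_ratio <- function(target_sites, reference_sites,
                             all_family_motifs) {
  if (!length(target_sites) || !length(reference_sites) ||
      !length(all_family_motifs))
    stop("all three site sets must be non-empty")
  d_t <- nearest_distance(target_sites, all_family_motifs)
  d_r <- nearest_distance(reference_sites, all_family_motifs)
  med_t <- stats::median(d_t[!is.na(d_t)])
  med_r <- stats::median(d_r[!is.na(d_r)])
  ratio <- if (is.na(med_t) || is.na(med_r) || med_t == 0) NA_real_
           else med_r / med_t
  structure(list(median_target = med_t, median_reference = med_r,
                 ratio = ratio),
            class = "clustering_ratio")
}

#' @export
print.clustering_ratio <- function(x, ...) {
  cat(sprintf(
    "Motif clustering ratio: %.3g (reference median %s bp / target median %s bp)\n",
    x$ratio, format(x$median_reference), format(x$median_target)))
  invisible(x)
}

#' Fraction of inserted sequences containing the disrupted motif
#'
#' Scans each inserted sequence (the ALT allele minus the shared leading
#' REF base) on both strands with the family's representative PWM at the
#' score threshold for `pvalue`. Insertions shorter than the motif count as
#' non-matches. A high fraction indicates that insertions at a family's
#' binding sites are tandem duplications of the motif itself -- the
#' mechanism that grows homotypic site clusters.
#'
#' @param inserted_seqs Character vector of inserted sequences.
#' @param p Representative [pwm()] of the family.
#' @param pvalue Scan p-value for [score_threshold()] (default 1e-4).
#' @param background Background base probabilities.
#' @return List: `fraction` (matching insertions / all insertions), `match`
#'   (logical per insertion), `threshold` (the score cutoff used).
#' @export
insertion_motif_content <- function(inserted_seqs, p, pvalue = 1e-4,
                                    background = rep(0.25, 4)) {
  if (!length(inserted_seqs)) stop("no inserted sequences supplied")
  thr <- score_threshold(p, pvalue = pvalue, background = background)
  L <- pwm_length(p)
  match <- vapply(seq_along(inserted_seqs), function(i) {
    s <- toupper(inserted_seqs[i])
    if (is.na(s) || nchar(s) < L) return(FALSE)
    hits <- scan_sequences(stats::setNames(s, "ins"), p, threshold = thr,
                           background = background)
    length(hits) > 0L
  }, logical(1))
  list(fraction = mean(match), match = match, threshold = as.numeric(thr))
}

#' Variant load at peaks cobound by two motif families
#'
#' Selects the peaks containing at least one site of EACH family, restricts
#' each family's sites to those peaks, and runs one permutation test per
#' family with the restricted sites held fixed and the variant set
#' randomized. Motifs co-occurring with a second factor often carry higher
#' loads than the family-wide rate.
#'
#' @param peaks `GRanges` of accessibility peaks.
#' @param fam1_sites,fam2_sites `GRanges` of the two families' binding
#'   sites.
#' @param variants Width-1 `GRanges` of variant positions.
#' @param g A [genome_layout()] object.
#' @param n_perm,null,seed Passed to [perm_test()].
#' @param labels Character vector of length 2 naming the families in the
#'   output.
#' @return data.frame of [enrichment_result()] rows (one per family) with
#'   attribute `n_cobound_peaks`; zero-row with a message when no peak is
#'   cobound.
#' @export
cobound_load <- function(peaks, fam1_sites, fam2_sites, variants, g,
                         n_perm = 1000L, null = c("circular", "shuffle"),
                         seed = 1L, labels = c("family1", "family2")) {
  null <- match.arg(null)
  check_intervals(peaks, g)
  has1 <- GenomicRanges::countOverlaps(peaks, fam1_sites,
                                       ignore.strand = TRUE) > 0L
  has2 <- GenomicRanges::countOverlaps(peaks, fam2_sites,
                                       ignore.strand = TRUE) > 0L
  cobound <- peaks[has1 & has2]
  if (length(cobound) == 0L) {
    message("no cobound peaks for the two families")
    out <- enrichment_result(list(observed = NA, mean_exp = NA, z = NA,
                                  p_empirical = NA))[0, ]
    attr(out, "n_cobound_peaks") <- 0L
    return(out)
  }
  rows <- lapply(seq_along(labels), function(i) {
    sites <- if (i == 1L) fam1_sites else fam2_sites
    keep <- GenomicRanges::countOverlaps(sites, cobound,
                                         ignore.strand = TRUE) > 0L
    restricted <- sites[keep]
    pt <- perm_test(variants, restricted, g, n_perm = n_perm, null = null,
                    seed = seed)
    enrichment_result(pt, label = labels[i], n_sites = length(restricted))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_cobound_peaks") <- length(cobound)
  out
}
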