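#' Configuration for the synthetic regulatory-genome generator
#'
#' Collects the planted parameters of a simulation: a small multi-chromosome
#' genome with accessibility peaks, motif-family binding sites written into
#' the sequence, a mappability track, and variant catalogs in which singleton
#' short insertions and SV breakpoints are enriched at binding sites at a
#' configurable fold while common variants are depleted. Defaults are chosen
#' so that each planted stratum yields enough events for stable fold
#' recovery on a desk-scale genome (see the package vignette).
#'
#' @param n_chromosomes Number of chromosomes; the last one is named `chrX`
#'   and declared a sex chromosome.
#' @param chromosome_length Length of every chromosome in bp.
#' @param n_peaks Total number of accessibility peaks across the genome.
#' @param peak_length Length range `c(min, max)` in bp for peaks.
#' @param n_families Number of motif families.
#' @param motif_length Motif length in bp (recycled over families).
#' @param sites_per_peak Integer range `c(min, max)` of binding sites per
#'   peak.
#' @param insertion_rate Background rate of singleton 5-20 bp insertions
#'   per mappable bp (outside site footprints).
#' @param insertion_fold Fold enrichment of singleton insertions inside site
#'   footprints.
#' @param sv_rate Background rate of singleton SV 5' breakpoints per bp.
#' @param sv_fold Fold enrichment of SV 5' breakpoints inside site
#'   footprints.
#' @param sv_length Length range `c(min, max)` in bp of SV deletions.
#' @param common_rate Rate of common 5-20 bp insertions per bp.
#' @param common_depletion Retention probability of a common insertion that
#'   falls inside a site footprint (values `< 1` plant depletion).
#' @param n_common_sv_groups Number of common-SV groups; each group is
#'   written as several near-identical records that satisfy the reciprocal
#'   overlap criterion.
#' @param tandem_duplication_probability Probability that an at-site
#'   insertion's inserted sequence is a copy of the overlapped motif
#'   instance.
#' @param snp_rate Rate of singleton SNPs per bp.
#' @param small_insertion_rate Rate of singleton 1-2 bp insertions per bp.
#' @param other_rate Rate of intermediate-frequency (`AC = 5`) insertions
#'   per bp, exercising the `other` rarity class.
#' @param mappability_gap_fraction Fraction of each chromosome masked as
#'   unmappable (gaps are drawn outside peaks).
#' @param n_enhancers Number of enhancers (half are centered on peaks and
#'   hence germline active).
#' @param enhancer_length Length range `c(min, max)` in bp of enhancers.
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3L,
                       chromosome_length = 1e6,
                       n_peaks = 750L,
                       peak_length = c(200L, 500L),
                       n_families = 2L,
                       motif_length = 13L,
                       sites_per_peak = c(2L, 4L),
                       insertion_rate = 4e-3,
                       insertion_fold = 5,
                       sv_rate = 4e-4,
                       sv_fold = 5,
                       sv_length = c(1000L, 10000L),
                       common_rate = 1e-3,
                       common_depletion = 0.2,
                       n_common_sv_groups = 30L,
                       tandem_duplication_probability = 0.5,
                       snp_rate = 5e-4,
                       small_insertion_rate = 5e-4,
                       other_rate = 2e-4,
                       mappability_gap_fraction = 0.05,
                       n_enhancers = 300L,
                       enhancer_length = c(500L, 1500L),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_chromosomes >= 1, chromosome_length > 0, n_peaks >= 1,
            n_families >= 1)
  rates <- c(insertion_rate, sv_rate, common_rate, snp_rate,
             small_insertion_rate, other_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (insertion_fold < 0 || sv_fold < 0) stop("folds must be >= 0")
  if (common_depletion < 0 || common_depletion > 1 ||
      tandem_duplication_probability < 0 ||
      tandem_duplication_probability > 1 ||
      mappability_gap_fraction < 0 || mappability_gap_fraction >= 1)
    stop("probabilities must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# uniformly sample n base positions (1-based) from a GRanges region set
.sample_positions <- function(regions, n) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      region = integer()))
  }
  w <- GenomicRanges::width(regions)
  total <- sum(w)
  if (total == 0L) stop("cannot sample positions from an empty region set")
  ridx <- sample.int(length(regions), n, replace = TRUE, prob = w)
  off <- floor(stats::runif(n) * w[ridx])
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(regions))[ridx],
    pos = GenomicRanges::start(regions)[ridx] + as.integer(off),
    region = ridx)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# place k non-overlapping intervals of widths w inside [lo, hi] by slotting
.place_in_segments <- function(lo, hi, widths) {
  k <- length(widths)
  span <- hi - lo + 1
  seg <- span %/% k
  if (seg < max(widths) + 1) stop("region too small for requested features")
  starts <- vapply(seq_len(k), function(i) {
    s_lo <- lo + (i - 1) * seg
    s_hi <- s_lo + seg - widths[i]
    s_lo + sample.int(s_hi - s_lo + 1L, 1L) - 1L
  }, numeric(1))
  starts
}

#' Generate a synthetic bundle with planted effects
#'
#' Builds, deterministically for a given config, the full input surface of
#' the analysis: genome layout and sequence (motif instances written at the
#' binding sites), peaks, family site sets, mappability track, enhancers,
#' a short-variant catalog with AC/AN fields chosen so the rarity
#' classifier reproduces the intended classes, and an SV table. Background
#' singleton insertions are placed uniformly on mappable bases outside site
#' footprints at `insertion_rate`; at-site insertions inside footprints at
#' `insertion_rate * insertion_fold`, so `insertion_fold` is the planted
#' truth the fold-enrichment analysis should recover. Common insertions are
#' thinned inside footprints by `common_depletion`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle`: `config`, `layout`, `genome`
#'   ([Biostrings::DNAStringSet]), `peaks`, `sites` (with `family_id`,
#'   `instance` sequence), `mappable`, `enhancers` (with `intended_active`),
#'   `variants` (data.frame), `svs` (data.frame, 1-based closed),
#'   `family_pwms`, `family_consensus`, `truth` (stratum bookkeeping).
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_bundle_impl(config))
}

.simulate_bundle_impl <- function(cfg) {
  chroms <- c(if (cfg$n_chromosomes > 1)
                paste0("chr", seq_len(cfg$n_chromosomes - 1L)), "chrX")
  layout <- genome_layout(chroms, rep(cfg$chromosome_length, length(chroms)),
                          sex_chromosomes = "chrX")
  si <- as_seqinfo(layout)

  ## peaks: slotted placement per chromosome keeps them disjoint
  per_chrom <- diff(round(seq(0, cfg$n_peaks, length.out = length(chroms) + 1)))
  peak_list <- list()
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    w <- sample(cfg$peak_length[1]:cfg$peak_length[2], k, replace = TRUE)
    starts <- .place_in_segments(1, cfg$chromosome_length, w)
    peak_list[[ci]] <- GenomicRanges::GRanges(
      chroms[ci], IRanges::IRanges(start = starts, width = w), seqinfo = si)
  }
  peaks <- GenomicRanges::sort(do.call(c, peak_list), ignore.strand = TRUE)
  peaks$score <- round(stats::rlnorm(length(peaks), meanlog = 4, sdlog = 0.5), 2)

  ## family motifs: fixed random consensus per family, sharp PWMs
  motif_len <- rep_len(cfg$motif_length, cfg$n_families)
  family_consensus <- vapply(motif_len, .random_dna, character(1))
  names(family_consensus) <- paste0("FAM", seq_len(cfg$n_families))
  family_pwms <- lapply(seq_len(cfg$n_families), function(i)
    consensus_to_pwm(family_consensus[i], name = names(family_consensus)[i]))
  names(family_pwms) <- names(family_consensus)

  ## binding sites inside peaks
  site_rows <- list()
  for (pi in seq_along(peaks)) {
    k <- sample(cfg$sites_per_peak[1]:cfg$sites_per_peak[2], 1L)
    if (k == 0L) next
    fams <- sample.int(cfg$n_families, k, replace = TRUE)
    widths <- motif_len[fams]
    starts <- .place_in_segments(GenomicRanges::start(peaks)[pi],
                                 GenomicRanges::end(peaks)[pi], widths)
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(peaks))[pi],
      start = starts, width = widths, family_id = fams,
      strand = sample(c("+", "-"), k, replace = TRUE))
  }
  sdf <- do.call(rbind, site_rows)
  sites <- GenomicRanges::GRanges(
    sdf$chrom, IRanges::IRanges(start = sdf$start, width = sdf$width),
    strand = sdf$strand, seqinfo = si)
  sites$family_id <- sdf$family_id
  sites <- GenomicRanges::sort(sites, ignore.strand = TRUE)

  ## genome sequence: iid uniform bases, motif instances written at sites
  seqs <- lapply(chroms, function(ch)
    strsplit(.random_dna(cfg$chromosome_length), "")[[1]])
  names(seqs) <- chroms
  instance <- character(length(sites))
  for (i in seq_along(sites)) {
    ch <- as.character(GenomeInfoDb::seqnames(sites))[i]
    fam <- sites$family_id[i]
    inst <- family_consensus[fam]
    if (as.character(GenomicRanges::strand(sites))[i] == "-")
      inst <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(inst)))
    pos <- GenomicRanges::start(sites)[i]
    seqs[[ch]][pos:(pos + nchar(inst) - 1L)] <- strsplit(inst, "")[[1]]
    instance[i] <- inst
  }
  sites$instance <- instance
  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))

  ## mappability: whole genome minus random gaps outside peaks
  gap_list <- list()
  for (ch in chroms) {
    target <- cfg$mappability_gap_fraction * cfg$chromosome_length
    placed <- 0
    tries <- 0
    gaps <- GenomicRanges::GRanges(seqinfo = si)
    while (placed < target && tries < 10000L) {
      tries <- tries + 1L
      gw <- sample(500:2000, 1L)
      gs <- sample.int(cfg$chromosome_length - gw, 1L)
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(gs, width = gw),
                                     seqinfo = si)
      if (count_overlaps(cand, peaks) == 0L &&
          count_overlaps(cand, gaps) == 0L) {
        gaps <- c(gaps, cand)
        placed <- placed + gw
      }
    }
    gap_list[[ch]] <- gaps
  }
  gaps <- do.call(c, unname(gap_list))
  full <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(1L, cfg$chromosome_length), seqinfo = si)
  mappable <- GenomicRanges::sort(
    GenomicRanges::setdiff(full, gaps, ignore.strand = TRUE),
    ignore.strand = TRUE)

  ## sampling universes
  site_bp <- GenomicRanges::reduce(sites, ignore.strand = TRUE)
  bg_universe <- GenomicRanges::setdiff(mappable, site_bp,
                                        ignore.strand = TRUE)
  bg_bp <- sum(GenomicRanges::width(bg_universe))
  at_bp <- sum(GenomicRanges::width(site_bp))

  base_at <- function(ch, pos) seqs[[ch]][pos]
  rand_base_not <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

  draw_stratum <- function(n_expected, universe, label) {
    n <- stats::rpois(1L, n_expected)
    if (n_expected < 1) warning("expected count < 1 for stratum ", label)
    .sample_positions(universe, n)
  }

  make_insertions <- function(pos_df, ac, an, stratum, at_site = FALSE) {
    if (!nrow(pos_df)) return(NULL)
    n <- nrow(pos_df)
    ref <- vapply(seq_len(n), function(i)
      base_at(pos_df$chrom[i], pos_df$pos[i]), character(1))
    inserted <- character(n)
    for (i in seq_len(n)) {
      dup <- at_site &&
        stats::runif(1) < cfg$tandem_duplication_probability
      if (dup) {
        # copy the motif instance overlapped by this position
        hit <- GenomicRanges::findOverlaps(
          GenomicRanges::GRanges(pos_df$chrom[i],
                                 IRanges::IRanges(pos_df$pos[i], width = 1L)),
          sites, ignore.strand = TRUE)
        j <- S4Vectors::subjectHits(hit)[1]
        inserted[i] <- sites$instance[j]
      } else {
        inserted[i] <- .random_dna(sample(5:20, 1L))
      }
    }
    data.frame(chrom = pos_df$chrom, pos = pos_df$pos, ref = ref,
               alt = paste0(ref, inserted), vclass = "insertion",
               size = nchar(inserted), ac = ac, an = an,
               cohort = "synthetic", stratum = stratum,
               at_site = at_site, stringsAsFactors = FALSE)
  }

  v <- list()
  v$bg_singleton <- make_insertions(
    draw_stratum(cfg$insertion_rate * bg_bp, bg_universe, "bg_singleton"),
    ac = 1L, an = 150000L, stratum = "singleton_insertion_bg")
  v$at_singleton <- make_insertions(
    draw_stratum(cfg$insertion_rate * cfg$insertion_fold * at_bp, site_bp,
                 "at_singleton"),
    ac = 1L, an = 150000L, stratum = "singleton_insertion_at_site",
    at_site = TRUE)

  ## common insertions: uniform on mappable bases, thinned inside sites
  com <- draw_stratum(cfg$common_rate * sum(GenomicRanges::width(mappable)),
                      mappable, "common")
  if (nrow(com)) {
    in_site <- GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(com$chrom, IRanges::IRanges(com$pos, width = 1L)),
      site_bp, ignore.strand = TRUE) > 0L
    keep <- !in_site | stats::runif(nrow(com)) < cfg$common_depletion
    com <- com[keep, , drop = FALSE]
  }
  v$common <- make_insertions(com, ac = 9000L, an = 150000L,
                              stratum = "common_insertion")

  v$other <- make_insertions(
    draw_stratum(cfg$other_rate * bg_bp, bg_universe, "other"),
    ac = 5L, an = 150000L, stratum = "other_insertion")

  small <- draw_stratum(cfg$small_insertion_rate * bg_bp, bg_universe,
                        "small_insertion")
  if (nrow(small)) {
    n <- nrow(small)
    ref <- vapply(seq_len(n), function(i)
      base_at(small$chrom[i], small$pos[i]), character(1))
    ins <- vapply(sample(1:2, n, replace = TRUE), .random_dna, character(1))
    v$small <- data.frame(chrom = small$chrom, pos = small$pos, ref = ref,
                          alt = paste0(ref, ins), vclass = "insertion",
                          size = nchar(ins), ac = 1L, an = 150000L,
                          cohort = "synthetic",
                          stratum = "singleton_insertion_1_2bp",
                          at_site = FALSE, stringsAsFactors = FALSE)
  }

  snp <- draw_stratum(cfg$snp_rate * bg_bp, bg_universe, "snp")
  if (nrow(snp)) {
    n <- nrow(snp)
    ref <- vapply(seq_len(n), function(i)
      base_at(snp$chrom[i], snp$pos[i]), character(1))
    alt <- vapply(ref, rand_base_not, character(1))
    v$snp <- data.frame(chrom = snp$chrom, pos = snp$pos, ref = ref,
                        alt = alt, vclass = "SNP", size = 0L,
                        ac = 1L, an = 150000L, cohort = "synthetic",
                        stratum = "singleton_snp", at_site = FALSE,
                        stringsAsFactors = FALSE)
  }

  variants <- do.call(rbind, v[!vapply(v, is.null, logical(1))])
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  ## singleton SVs: 5' breakpoints drawn like insertions, length uniform
  n_sv_bg <- stats::rpois(1L, cfg$sv_rate * bg_bp)
  n_sv_at <- stats::rpois(1L, cfg$sv_rate * cfg$sv_fold * at_bp)
  sv_start <- rbind(.sample_positions(bg_universe, n_sv_bg),
                    .sample_positions(site_bp, n_sv_at))
  if (nrow(sv_start)) {
    sv_len <- sample(cfg$sv_length[1]:cfg$sv_length[2],
                     nrow(sv_start), replace = TRUE)
    sv_end <- pmin(sv_start$pos + sv_len - 1L, cfg$chromosome_length)
    svs <- data.frame(chrom = sv_start$chrom, start = sv_start$pos,
                      end = sv_end, type = "deletion", freq = 2e-5,
                      cohort = "synthetic", stringsAsFactors = FALSE)
  } else {
    svs <- data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(), freq = numeric(),
                      cohort = character(), stringsAsFactors = FALSE)
  }

  ## common SV groups: jittered copies satisfying reciprocal overlap
  if (cfg$n_common_sv_groups > 0L) {
    rows <- list()
    for (gi in seq_len(cfg$n_common_sv_groups)) {
      ch <- sample(chroms, 1L)
      len <- sample(cfg$sv_length[1]:cfg$sv_length[2], 1L)
      st <- sample.int(cfg$chromosome_length - 2L * len, 1L)
      k <- sample(2:4, 1L)
      jit <- sample(0:floor(0.05 * len), k, replace = TRUE)
      rows[[gi]] <- data.frame(
        chrom = ch, start = st + jit, end = st + len - 1L + jit,
        type = "deletion", freq = 0.06, cohort = "synthetic",
        stringsAsFactors = FALSE)
    }
    svs <- rbind(svs, do.call(rbind, rows))
  }
  svs <- svs[order(svs$chrom, svs$start, svs$end), , drop = FALSE]
  rownames(svs) <- NULL

  ## enhancers: half centered on peaks (active), half on background
  n_act <- cfg$n_enhancers %/% 2L
  n_inact <- cfg$n_enhancers - n_act
  ew <- sample(cfg$enhancer_length[1]:cfg$enhancer_length[2],
               cfg$n_enhancers, replace = TRUE)
  anchor_peaks <- sample.int(length(peaks), n_act, replace = TRUE)
  act_mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks))[anchor_peaks] %/% 2L
  clamp_start <- function(s, w) pmax(1, pmin(s, cfg$chromosome_length - w + 1))
  act_w <- ew[seq_len(n_act)]
  act <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(peaks))[anchor_peaks],
    IRanges::IRanges(start = clamp_start(act_mid - act_w %/% 2L, act_w),
                     width = act_w))
  bg_pos <- .sample_positions(bg_universe, n_inact)
  inact_w <- ew[n_act + seq_len(n_inact)]
  inact <- GenomicRanges::GRanges(
    bg_pos$chrom,
    IRanges::IRanges(start = clamp_start(bg_pos$pos, inact_w),
                     width = inact_w))
  enhancers <- c(act, inact)
  GenomeInfoDb::seqlevels(enhancers) <- chroms
  GenomeInfoDb::seqinfo(enhancers) <- si
  enhancers$intended_active <- rep(c(TRUE, FALSE), c(n_act, n_inact))
  enhancers <- GenomicRanges::sort(enhancers, ignore.strand = TRUE)

  truth <- list(
    site_bp = at_bp,
    background_bp = bg_bp,
    n_sites = length(sites),
    n_peaks = length(peaks),
    planted_insertion_fold = cfg$insertion_fold,
    planted_sv_fold = cfg$sv_fold,
    planted_common_depletion = cfg$common_depletion,
    stratum_counts = table(variants$stratum),
    n_singleton_sv = sum(svs$freq < 0.01),
    n_common_sv_records = sum(svs$freq >= 0.01),
    n_common_sv_groups = cfg$n_common_sv_groups)

  structure(
    list(config = cfg, layout = layout, genome = genome, peaks = peaks,
         sites = sites, mappable = mappable, enhancers = enhancers,
         variants = variants, svs = svs, family_pwms = family_pwms,
         family_consensus = family_consensus, truth = truth),
    class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic bundle:", length(x$layout$chromosomes), "chromosomes,",
      length(x$peaks), "peaks,", length(x$sites), "sites,",
      nrow(x$variants), "short variants,", nrow(x$svs), "SV records\n")
  invisible(x)
}

#' Write a synthetic bundle to standard file formats
#'
#' Emits FASTA (genome), BED (peaks, per-family sites, mappability,
#' enhancers), VCF (short variants, minimal header with AC/AN INFO fields),
#' TSV (SVs, BED-convention half-open coordinates), chrom.sizes, and a JSON
#' manifest recording the config and planted truth.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  paths$chrom_sizes <- file.path(dir, "genome.chrom.sizes")
  utils::write.table(
    data.frame(bundle$layout$chromosomes, as.integer(bundle$layout$lengths)),
    paths$chrom_sizes, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  paths$fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(bundle$genome, paths$fasta)

  paths$peaks <- file.path(dir, "peaks.bed")
  write_bed(bundle$peaks, paths$peaks)

  for (fam in unique(bundle$sites$family_id)) {
    p <- file.path(dir, sprintf("sites_family%d.bed", fam))
    fs <- bundle$sites[bundle$sites$family_id == fam]
    fs$name <- paste0("family", fam)
    write_bed(fs, p)
    paths[[sprintf("sites_family%d", fam)]] <- p
  }

  paths$mappable <- file.path(dir, "mappable.bed")
  write_bed(bundle$mappable, paths$mappable)

  paths$enhancers <- file.path(dir, "enhancers.bed")
  enh <- bundle$enhancers
  enh$name <- ifelse(enh$intended_active, "active", "inactive")
  write_bed(enh, paths$enhancers)

  paths$vcf <- file.path(dir, "variants.vcf")
  .write_minimal_vcf(bundle$variants, bundle$layout, paths$vcf)

  paths$svs <- file.path(dir, "svs.tsv")
  sv <- bundle$svs
  utils::write.table(
    data.frame(sv$chrom, sv$start - 1L, sv$end, sv$type, sv$freq),
    paths$svs, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  paths$manifest <- file.path(dir, "manifest.json")
  manifest <- list(
    config = unclass(bundle$config),
    truth = lapply(bundle$truth, function(x)
      if (inherits(x, "table")) as.list(x) else x),
    family_consensus = as.list(bundle$family_consensus))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

.write_minimal_vcf <- function(variants, layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=germload-simulator",
    paste0("##contig=<ID=", layout$chromosomes, ",length=",
           as.integer(layout$lengths), ">"),
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Allele count">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Allele number">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  v <- variants[order(match(variants$chrom, layout$chromosomes),
                      variants$pos), , drop = FALSE]
  if (nrow(v)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAC=%d;AN=%d",
                       v$chrom, v$pos, v$ref, v$alt, v$ac, v$an), con)
  }
  invisible(path)
}

#' A tiny fully hand-checkable synthetic bundle
#'
#' One 100-kb chromosome, 10 peaks of 1 kb, one motif family with 20 sites
#' (two per peak), 40 planted singleton insertions of which exactly 30 fall
#' inside site footprints and 10 in background, and 3 SV deletions (hence 6
#' breakpoints). All coordinates are fixed constants so every overlap can
#' be enumerated by hand; the `truth` element records the planted counts.
#'
#' @return A `sim_bundle` (without `family_pwms` scan-quality sequence
#'   randomness: the sequence is deterministic).
#' @export
worked_example <- function() {
  cfg <- sim_config(n_chromosomes = 1L, chromosome_length = 1e5,
                    n_peaks = 10L, n_families = 1L, seed = 424242L)
  layout <- genome_layout("chrX", 1e5, sex_chromosomes = "chrX")
  si <- as_seqinfo(layout)
  consensus <- "CCACCATTGCCAC"        # sharp 13-mer, N-free
  fam_pwm <- consensus_to_pwm(consensus, name = "FAM1")

  peaks <- GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(start = seq(5001, 95001, by = 10000),
                             width = 1000L), seqinfo = si)
  peaks$score <- 100

  # two sites per peak at fixed offsets 200 and 600 into the peak
  site_start <- as.vector(outer(c(200L, 600L),
                                GenomicRanges::start(peaks), `+`))
  sites <- GenomicRanges::sort(GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(start = site_start, width = 13L),
    strand = "+", seqinfo = si))
  sites$family_id <- 1L
  sites$instance <- consensus

  base <- rep(c("A", "C", "G", "T"), length.out = 1e5)
  for (s in GenomicRanges::start(sites))
    base[s:(s + 12L)] <- strsplit(consensus, "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- "chrX"

  mappable <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1L, 1e5),
                                     seqinfo = si)

  # 30 at-site insertions: sites 1..15 get two each (offsets +2 and +8);
  # 10 background insertions at fixed positions between peaks
  at_pos <- as.vector(outer(c(2L, 8L), GenomicRanges::start(sites)[1:15], `+`))
  bg_pos <- seq(2500L, 92500L, by = 10000L)
  pos <- c(at_pos, bg_pos)
  ref <- base[pos]
  variants <- data.frame(
    chrom = "chrX", pos = pos, ref = ref,
    alt = paste0(ref, strrep("ACGTA", 2L)),   # 10-bp insertion
    vclass = "insertion", size = 10L, ac = 1L, an = 150000L,
    cohort = "worked", stratum = rep(c("at_site", "background"), c(30, 10)),
    at_site = rep(c(TRUE, FALSE), c(30, 10)), stringsAsFactors = FALSE)
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  svs <- data.frame(
    chrom = "chrX",
    start = c(20001L, 50001L, 70001L),
    end = c(30000L, 52000L, 80000L),
    type = "deletion", freq = 2e-5, cohort = "worked",
    stringsAsFactors = FALSE)

  enhancers <- GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(start = c(5201L, 45201L, 2001L, 62001L),
                             width = 600L), seqinfo = si)
  enhancers$intended_active <- c(TRUE, TRUE, FALSE, FALSE)

  truth <- list(
    n_sites = 20L, n_peaks = 10L,
    n_insertions = 40L, n_at_site_insertions = 30L,
    n_background_insertions = 10L,
    n_svs = 3L, n_breakpoints = 6L)

  structure(
    list(config = cfg, layout = layout, genome = genome, peaks = peaks,
         sites = sites, mappable = mappable, enhancers = enhancers,
         variants = variants, svs = svs,
         family_pwms = list(FAM1 = fam_pwm),
         family_consensus = c(FAM1 = consensus), truth = truth),
    class = "sim_bundle")
}
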