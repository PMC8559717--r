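#' Assemble a run configuration for the analysis pipeline
#'
#' Bundles the input paths and tuning constants of a full run. Defaults
#' mirror the reference analysis: 10,000 permutations, 80% reciprocal SV
#' overlap, >=95% mappability over +/-5 kb windows, singleton rule
#' AC == 1 with AN >= 100,000, common allele frequency >= 5%, scan p-value
#' 1e-4, 5-bp profile bins over +/-1 kb windows, 500-bp enhancer flanks.
#'
#' @param chrom_sizes,peaks,mappable,vcf,svs,enhancers Paths to the input
#'   files (chrom.sizes; peak BED; mappability BED; short-variant VCF; SV
#'   TSV; enhancer BED). `enhancers` may be `NA` to skip enhancer stages.
#' @param sites Named list of per-family site BED paths, or `NULL` to scan
#'   the genome.
#' @param fasta Genome FASTA path (needed when `sites` is `NULL`).
#' @param sex_chromosomes Names of sex chromosomes in the layout.
#' @param n_perm Number of permutations per test.
#' @param seed Integer seed for all randomized stages.
#' @param singleton_min_an,common_min_af Rarity thresholds.
#' @param reciprocal_fraction SV reciprocal-overlap fraction.
#' @param mappability_min,mappability_flank Mappability filter settings.
#' @param scan_pvalue PWM scan p-value.
#' @param profile_window,profile_bin Variant profile window and bin (bp).
#' @param shift_window,shift_step Shifted Z-score profile settings (bp).
#' @param enhancer_flank Enhancer midpoint half-window (bp).
#' @param common_sv_freq SV frequency at or above which an SV record is
#'   treated as common.
#' @return List of class `run_config`.
#' @export
run_config <- function(chrom_sizes, peaks, mappable, vcf, svs,
                       enhancers = NA, sites = NULL, fasta = NA,
                       sex_chromosomes = "chrX",
                       n_perm = 10000L, seed = 1L,
                       singleton_min_an = 100000L, common_min_af = 0.05,
                       reciprocal_fraction = 0.8,
                       mappability_min = 0.95, mappability_flank = 5000L,
                       scan_pvalue = 1e-4,
                       profile_window = 1000L, profile_bin = 5L,
                       shift_window = 1000L, shift_step = 100L,
                       enhancer_flank = 500L,
                       common_sv_freq = 0.01) {
  rc <- as.list(environment())
  must_exist <- c(chrom_sizes, peaks, mappable, vcf, svs,
                  if (!is.na(enhancers)) enhancers,
                  if (!is.na(fasta)) fasta,
                  unlist(sites))
  missing <- must_exist[!file.exists(must_exist)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  class(rc) <- "run_config"
  rc
}

.pipeline_stages <- c("classify", "breakpoints", "enrich", "profile",
                      "shift", "cobound", "enhancers", "clustering",
                      "coincidence", "all")

#' Run the regulatory mutational-load analysis
#'
#' Orchestrates the pipeline stages over the configured inputs, writing one
#' tab-delimited table per stage plus a machine-readable JSON summary of
#' every statistic. Reruns with the same config and seed are deterministic.
#'
#' Stages: `classify` (rarity/size classes from the VCF), `breakpoints`
#' (singleton and common SV breakpoints), `enrich` (permutation enrichment
#' of singleton insertions and breakpoints at peaks and per-family sites),
#' `profile` (binned insertion counts around sites), `shift` (shifted local
#' Z-score profile at peaks), `cobound` (loads at peaks carrying sites of
#' both families, two-family inputs only), `enhancers` (activity partition
#' and disruption odds ratio), `clustering` (X:autosome ratio and grouped
#' accessibility-quartile enrichment), `coincidence` (exact-position
#' insertion/breakpoint coincidence), `all`.
#'
#' @param rc A [run_config()].
#' @param stage One of the stage names above.
#' @param out_dir Output directory for tables and `summary.json`.
#' @return The summary list, invisibly.
#' @export
run_analysis <- function(rc, stage = "all", out_dir = tempfile("germload_")) {
  stopifnot(inherits(rc, "run_config"))
  stage <- match.arg(stage, .pipeline_stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") setdiff(.pipeline_stages, "all") else stage

  g <- read_chrom_sizes(rc$chrom_sizes, sex_chromosomes = rc$sex_chromosomes)
  peaks <- read_bed(rc$peaks, g)
  mappable <- read_bed(rc$mappable, g)
  variants <- classify_variants(read_variant_vcf(rc$vcf),
                                min_an = rc$singleton_min_an,
                                common_min_af = rc$common_min_af)
  variants <- normalize_indels(variants)
  svs <- read_sv_tsv(rc$svs)

  sites <- NULL
  if (!is.null(rc$sites)) {
    site_list <- lapply(seq_along(rc$sites), function(i) {
      s <- read_bed(rc$sites[[i]], g)
      s$family_id <- i
      s
    })
    sites <- GenomicRanges::sort(do.call(c, site_list), ignore.strand = TRUE)
  }
  if (is.null(sites))
    stop("stage dependencies unsatisfied: per-family site BEDs are required ",
         "('sites' in run_config); scanning from FASTA is done upstream ",
         "with scan_sequences()/build_family_sites()")

  summary <- list(seed = rc$seed, n_perm = rc$n_perm)
  singl_ins <- variants[variants$rarity == "singleton" &
                        variants$vclass == "insertion" &
                        variants$size_class == "5-20bp", , drop = FALSE]
  singl_gr <- variants_to_granges(singl_ins, g)
  sv_singleton <- svs[svs$freq < rc$common_sv_freq | is.na(svs$freq), ,
                      drop = FALSE]
  sv_common <- svs[!is.na(svs$freq) & svs$freq >= rc$common_sv_freq, ,
                   drop = FALSE]
  bp_singleton <- extract_breakpoints(sv_singleton, g, "singleton_per_sv")

  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("classify" %in% stages) {
    counts <- as.data.frame(table(rarity = variants$rarity,
                                  size_class = variants$size_class))
    counts <- counts[counts$Freq > 0, , drop = FALSE]
    tsv(counts, "classify_counts")
    summary$classify <- stats::setNames(
      as.list(counts$Freq),
      paste(counts$rarity, counts$size_class, sep = "_"))
  }

  if ("breakpoints" %in% stages) {
    bp_common <- extract_breakpoints(sv_common, g, "common_grouped",
                                     min_fraction = rc$reciprocal_fraction)
    tsv(data.frame(set = c("singleton", "common"),
                   n_breakpoints = c(length(bp_singleton),
                                     length(bp_common))),
        "breakpoint_counts")
    summary$breakpoints <- list(singleton = length(bp_singleton),
                                common = length(bp_common))
    write_bed(bp_singleton, file.path(out_dir, "breakpoints_singleton.bed"))
    if (length(bp_common))
      write_bed(bp_common, file.path(out_dir, "breakpoints_common.bed"))
  }

  if ("enrich" %in% stages) {
    rows <- list()
    pt <- perm_test(singl_gr, peaks, g, n_perm = rc$n_perm, seed = rc$seed)
    rows$ins_peaks <- enrichment_result(pt, "singleton_insertions_at_peaks",
                                        length(peaks))
    if (length(bp_singleton)) {
      pt <- perm_test(bp_singleton, peaks, g, n_perm = rc$n_perm,
                      seed = rc$seed)
      rows$bp_peaks <- enrichment_result(pt, "singleton_breakpoints_at_peaks",
                                         length(peaks))
    }
    for (fam in sort(unique(sites$family_id))) {
      fs <- sites[sites$family_id == fam]
      pt <- perm_test(singl_gr, fs, g, n_perm = rc$n_perm, seed = rc$seed)
      rows[[paste0("fam", fam)]] <- enrichment_result(
        pt, sprintf("singleton_insertions_at_family%d_sites", fam),
        length(fs))
    }
    common_ins <- variants[variants$rarity == "common" &
                           variants$vclass == "insertion" &
                           variants$size_class == "5-20bp", , drop = FALSE]
    if (nrow(common_ins)) {
      pt <- perm_test(variants_to_granges(common_ins, g), sites, g,
                      n_perm = rc$n_perm, seed = rc$seed)
      rows$common <- enrichment_result(pt, "common_insertions_at_sites",
                                       length(sites))
    }
    enr <- do.call(rbind, rows)
    tsv(enr, "enrichment")
    summary$enrichment <- stats::setNames(
      lapply(seq_len(nrow(enr)), function(i)
        list(observed = enr$observed[i], expected = enr$expected[i],
             fold = enr$fold[i], z = enr$z[i], p = enr$p_empirical[i])),
      enr$label)
  }

  if ("profile" %in% stages) {
    prof <- profile_counts(singl_gr, sites, g, window = rc$profile_window,
                           bin = rc$profile_bin)
    tsv(prof, "profile_insertions_sites")
    center <- prof$count[prof$bin_start >= -rc$profile_bin * 2 &
                         prof$bin_end <= rc$profile_bin * 2]
    summary$profile <- list(total = sum(prof$count),
                            center_mass = sum(center))
  }

  if ("shift" %in% stages) {
    sp <- shift_profile(singl_gr, peaks, g, window = rc$shift_window,
                        step = rc$shift_step, n_perm = rc$n_perm,
                        seed = rc$seed)
    tsv(as.data.frame(sp), "shift_profile_peaks")
    summary$shift <- list(z0 = sp$z[sp$shift == 0],
                          peak_shift = sp$shift[order(-sp$z,
                                                      abs(sp$shift))][1])
  }

  if ("cobound" %in% stages) {
    fams <- sort(unique(sites$family_id))
    if (length(fams) >= 2L) {
      cb <- cobound_load(peaks, sites[sites$family_id == fams[1]],
                         sites[sites$family_id == fams[2]], singl_gr, g,
                         n_perm = rc$n_perm, seed = rc$seed,
                         labels = paste0("family", fams[1:2]))
      tsv(cb, "cobound_load")
      summary$cobound <- list(
        n_cobound_peaks = attr(cb, "n_cobound_peaks"),
        folds = stats::setNames(as.list(cb$fold), cb$label))
    }
  }

  if ("enhancers" %in% stages && !is.na(rc$enhancers)) {
    enh <- read_bed(rc$enhancers, g)
    cls <- classify_enhancer_activity(enh, peaks, g,
                                      flank = rc$enhancer_flank)
    or <- enhancer_disruption_or(enh, peaks, singl_gr, g,
                                 flank = rc$enhancer_flank)
    write_bed(cls$active, file.path(out_dir, "enhancers_active.bed"))
    write_bed(cls$inactive, file.path(out_dir, "enhancers_inactive.bed"))
    tsv(data.frame(A = or$counts["A"], B = or$counts["B"],
                   C = or$counts["C"], D = or$counts["D"],
                   OR = or$or, ci_low = or$ci_low, ci_high = or$ci_high),
        "enhancer_odds_ratio")
    summary$enhancers <- list(n_active = length(cls$active),
                              n_inactive = length(cls$inactive),
                              or = or$or, ci_low = or$ci_low,
                              ci_high = or$ci_high)
  }

  if ("clustering" %in% stages) {
    keep <- filter_by_mappability(singl_gr, mappable, g,
                                  flank = rc$mappability_flank,
                                  min_fraction = rc$mappability_min)
    xa <- x_autosome_ratio(keep, mappable, g)
    qs <- if (!is.null(peaks$score)) quartile_labels(peaks$score)
          else rep(1L, length(peaks))
    ge <- grouped_enrichment(singl_gr, peaks, qs, g,
                             n_perm = min(rc$n_perm, 1000L), seed = rc$seed)
    tsv(ge, "grouped_enrichment")
    summary$clustering <- list(
      x_autosome_ratio = xa,
      grouped_folds = stats::setNames(as.list(ge$fold), ge$label))
  }

  if ("coincidence" %in% stages && length(bp_singleton)) {
    ct <- coincidence_test(singl_gr, bp_singleton, g,
                           n_perm = min(rc$n_perm, 1000L), seed = rc$seed)
    tsv(data.frame(observed = ct$observed, expected = ct$mean_exp,
                   z = ct$z, p = ct$p_empirical),
        "coincidence")
    summary$coincidence <- list(observed = ct$observed, z = ct$z,
                                p = ct$p_empirical)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
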