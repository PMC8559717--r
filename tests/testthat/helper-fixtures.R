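# Shared fixture builders for the test suite. All fixtures are built in
# code; coordinates in comments use the BED half-open convention where that
# clarifies the intent.

gr <- function(chrom, start, end, strand = "*", seqlevels = NULL, ...) {
  x <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand, ...)
  if (!is.null(seqlevels)) GenomeInfoDb::seqlevels(x) <- seqlevels
  x
}

tiny_layout <- function(len = 1000L, chroms = "chr1", sex = character()) {
  genome_layout(chroms, rep(len, length(chroms)), sex_chromosomes = sex)
}

# data.frame of short variants with the columns classify_variants expects
variant_df <- function(pos, ref = "A", alt = "AT", ac = 1L, an = 150000L,
                       chrom = "chr1") {
  n <- length(pos)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  vclass <- ifelse(nchar(ref) == nchar(alt), "SNP",
            ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  data.frame(chrom = rep_len(chrom, n), pos = pos, ref = ref, alt = alt,
             vclass = vclass, size = abs(nchar(alt) - nchar(ref)),
             ac = rep_len(ac, n), an = rep_len(an, n),
             cohort = "test", stringsAsFactors = FALSE)
}

sv_df <- function(start, end, chrom = "chr1", type = "deletion",
                  freq = 2e-5) {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end, type = rep_len(type, length(start)),
             freq = rep_len(freq, length(start)), cohort = "test",
             stringsAsFactors = FALSE)
}

# independent brute-force oracle for reciprocal-overlap grouping:
# O(n^2) pairwise links + hand-rolled BFS connected components
brute_reciprocal_groups <- function(svs, min_fraction) {
  n <- nrow(svs)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || svs$chrom[i] != svs$chrom[j]) next
      inter <- min(svs$end[i], svs$end[j]) - max(svs$start[i], svs$start[j]) + 1
      if (inter <= 0) next
      wi <- svs$end[i] - svs$start[i] + 1
      wj <- svs$end[j] - svs$start[j] + 1
      if (inter >= min_fraction * wi && inter >= min_fraction * wj)
        adj[[i]] <- c(adj[[i]], j)
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# enumeration oracle for the p-value -> score threshold map, run on the
# same discretized log-odds matrix the DP uses
enum_threshold <- function(p, pvalue, background = rep(0.25, 4),
                           granularity = 1e-3) {
  lo <- pwm_log_odds(p, background)
  q <- round(lo / granularity) * granularity
  L <- ncol(q)
  seqs <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(seqs))
  probs <- numeric(nrow(seqs))
  bg <- background / sum(background)
  for (r in seq_len(nrow(seqs))) {
    scores[r] <- sum(q[cbind(seqs[r, ], seq_len(L))])
    probs[r] <- prod(bg[seqs[r, ]])
  }
  sup <- sort(unique(scores))
  surv <- vapply(sup, function(s) sum(probs[scores >= s - 1e-12]), numeric(1))
  ok <- which(surv <= pvalue)
  if (!length(ok)) return(NA_real_)
  sup[ok[1]]
}
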