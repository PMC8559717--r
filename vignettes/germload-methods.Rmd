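---
title: "Quantifying mutational load at germline regulatory sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutational load at germline regulatory sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germload)
library(GenomicRanges)
```

## The scientific problem

Active regulatory regions in the male germline -- accessible chromatin
peaks and the transcription-factor binding sites (TFBSs) footprinted
within them -- are hypothesised to incur locally elevated mutation rates:
protein binding interferes with replication and repair, and PRDM9 binding
additionally nucleates meiotic double-strand breaks. The observable
signature is an excess of *extremely rare* variants (singletons in large
cohorts, a proxy for new mutations) at binding sites, together with a
*depletion* of common variants at the same sites (purifying selection
removes regulatory damage before it becomes common).

`germload` implements the statistical machinery to measure this
signature: rarity classification of short variants from VCF allele
counts, structural-variant (SV) breakpoint extraction, motif-family
construction and genome scanning, circular-permutation null models with
shifted local Z-score profiles, and the downstream summary statistics
(insertion fold enrichment, cobound-peak loads, enhancer odds ratios,
homotypic clustering ratios). A synthetic-data generator with planted
effect sizes closes the loop: every stage can be validated against known
truth.

## Coordinate conventions

All genomic containers are `GenomicRanges::GRanges`, i.e. 1-based closed
coordinates. File formats keep their native conventions: BED and the
SV table are half-open 0-based and are converted at the boundary
(`read_bed()`, `read_sv_tsv()`), VCF positions are 1-based. We chose the
Bioconductor-native convention over carrying a parallel half-open
convention internally because every interval operation delegates to
IRanges/GenomicRanges; the readers and writers are tested to round-trip
files bit-exactly, which is the property that actually matters. Two
consequences worth stating:

* book-ended BED intervals (`[10,20)`, `[20,30)`) merge at `max_gap = 0`
  but do not count as overlapping;
* the 3' breakpoint of an SV written as BED `[start, end)` is the 1-bp
  feature covering its last included base (BED `end - 1`), which keeps
  both breakpoints inside the SV footprint.

Windows clipped at chromosome ends are truncated rather than discarded,
and the mappability fraction of a truncated window uses the truncated
length as its denominator. This treatment of edges is a package decision;
the alternative (discarding edge windows) changes nothing for interior
sites and silently loses telomeric ones.

## Rarity and size classification

`classify_variants()` applies the cohort-scale rules: a **singleton** has
allele count exactly 1 with allele number at least 100,000 (so its
frequency is at most 0.001%); a **common** variant has allele frequency
at least 5%; everything else is `other` and excluded from both extremes.
Indels are binned into 1--2 bp (replication slippage scale) and 5--20 bp
(the break-repair scale that short-read sequencing still resolves
reliably); lengths 3--4 and >20 bp are `excluded`. The indel-gap rule
(`normalize_indels()`) drops indels whose positions lie within 2 bp of
each other; we remove *both* members of a violating pair, a symmetric,
conservative reading of the gap-filter semantics, because call quality of
either member of a close pair is suspect.

One derived constant: a variant seen once across cohorts totalling
`9625 + 10738 + 29084` individuals has carrier frequency at most
`carrier_frequency_bound(c(9625, 10738, 29084))` =
`r round(carrier_frequency_bound(c(9625, 10738, 29084)), 4)`%.

## SV breakpoints and reciprocal-overlap grouping

Breakpoints are analysed as 1-bp features. Singleton SVs contribute both
of their breakpoints individually (never deduplicated). Common SVs are
first grouped by the 80% reciprocal-overlap criterion -- two records are
the same variant when their intersection covers at least 80% of *each* --
with groups taken as connected components of the link graph, matching the
transitive merge of map-then-merge tooling. Each group contributes its
outermost start and end, and coordinates shared between groups are
counted once. `reciprocal_overlap_group()` is tested against an
independent brute-force pairwise + BFS oracle.

The breakpoint features default to exactly 1 bp; array-based cohorts
report breakpoints with confidence intervals of hundreds of bp to tens of
kb, so analyses of such data may widen features with
`midpoint_windows()` before testing. We left the default at 0 padding:
the synthetic data has exact breakpoints, and padding is a data-quality
property, not a method property.

## Motif families and binding sites

JASPAR-format PFMs are read with `read_jaspar_pfm()`, normalised with a
0.1 pseudocount. Consensus strings (e.g. the 13-mer PRDM9 motif
`CCNCCNTNNCCNC`) convert to sharp PWMs with `consensus_to_pwm()`: a
specified base receives `1 - 3 * epsilon` with `epsilon = 0.01`
(configurable; degenerate codes split the remaining mass equally, `N` is
uniform). The epsilon value is our choice -- the conversion is not
standardised anywhere -- and it is sharp enough that a planted consensus
is always recovered at the default scan threshold while a single
mismatch generally is not.

Similar motifs bound by different proteins would otherwise triple-count a
footprint, so PWMs are clustered into families:
`pwm_distance()` is one minus the best Pearson correlation between
flattened probability columns over all ungapped offsets and both
orientations (at least 4 aligned columns), and `cluster_families()` cuts
an average-linkage tree at a threshold (default 0.25). The default was
fixed once as the value giving a stable, interpretable partition of the
bundled consensus fixtures: distinct random 13-mers stay separate while
trivially shifted or reverse-complemented variants merge. The *family
partition* is the contract; we do not claim bit-compatibility with any
particular published clustering tool, whose alignment internals differ.

Scanning (`scan_sequences()`) slides the log2-odds matrix over both
strands, skipping windows containing `N`. The score threshold for a scan
p-value (default 1e-4, the usual scanning default) is computed *exactly*
by `score_threshold()`: per-position score distributions under the
background model, discretised at 1e-3 bits, are convolved by dynamic
programming, and the smallest achievable score whose tail probability is
at most the target is returned. The DP agrees with exhaustive
enumeration of all `4^L` sequences for short motifs (tested to L = 6).
The background is uniform by default; a sequence-derived 0-order
background can be supplied but is not estimated automatically.
Family-level sites merge overlapping member hits and collapse
palindromic duplicates called on both strands
(`build_family_sites()`).

## The permutation engine

The null model conditions on the regulatory landscape and randomises the
variant set. `circular_randomize()` rotates all features of a chromosome
jointly by one uniform offset, preserving their spacing and clustering;
features wrapping past the end are split at the boundary rather than
discarded, so per-chromosome feature counts and covered bases are
invariants. Masked-assembly handling is expressed as an explicit,
testable contract: an optional exclusion track triggers redraws (up to
1,000 attempts, then an error) instead of relying on a masked genome
object. `shuffle_randomize()` is the independent-placement alternative
(each feature uniform where it fits, overlaps allowed), matching
shuffle-style controls.

`perm_test()` evaluates the number of randomized features overlapping
the fixed set (each feature counted once; a mean-distance evaluation is
also exposed). The Z-score standardises the observed count against the
permutation distribution, and the empirical p-value uses add-one
smoothing, so it is never zero. For a single feature of length `a` and a
single fixed interval of length `b` on a chromosome of length `L`, the
rotation-overlap probability is `(a + b - 1)/L` -- the analytic oracle
the engine is tested against. 10,000 permutations is the reference
setting; the test suite uses hundreds against analytic oracles to stay
fast.

`shift_profile()` localises a signal: the feature set is displaced by
fixed offsets and the observed overlap at each offset is standardised
against the *unshifted* permutation distribution, so `z(0)` equals the
global test's Z and a site-specific enrichment decays with displacement
while a broad regional bias stays flat.

## Enrichment statistics and downstream analyses

The **insertion fold enrichment** (IFE) is simply observed/expected with
the expected count taken as the permutation mean; reports also show the
one-decimal rounding used in fold tables. The per-family table layer
(`enrichment_result()`) exposes both, since published ratios are
consistent with rounding before division.

Count profiles (`profile_counts()`) bin variant offsets around site
midpoints (5-bp bins for TFBS-scale plots, 100-bp or 5-kb for
enhancer-scale plots); a variant in the window of two sites counts once
per site, because the profile is site-centric. `coincidence_test()`
restricts both inputs to 1-bp features, making overlap identical to
exact-nucleotide coincidence. `x_autosome_ratio()` is the
variants-per-mappable-base ratio of sex chromosomes to autosomes.
`grouped_enrichment()` stratifies sites (accessibility quartiles use the
left-open type-1 empirical quantile rule) and randomises the group's
sites against the fixed variant set, per the stratified design;
elsewhere the variant set is the randomized one -- both directions are
valid conditional tests and each function documents which it uses.

Enhancer analyses classify each enhancer by whether its midpoint
&plusmn;500 bp window intersects a germline peak, then cross activity
with disruption in the odds ratio
`OR = (A/(B-A))/(C/(D-C))` with the 1.96-sigma log-scale CI. "Disrupted"
defaults to the same midpoint window (the window used for the activity
call); a full-body mode is exposed because the choice is not forced by
the design, and the window mode is the conservative default for
variable-length enhancers. The homotypic clustering ratio compares
median nearest-same-family-motif distances (self-matches excluded)
between target and reference regions, and
`insertion_motif_content()` scans inserted ALT sequences for the
disrupted family's motif -- the direct test of the
tandem-duplication mechanism.

## The synthetic-data generator

`simulate_bundle()` emulates the statistical structure the analysis is
designed to detect, not the biology of a real genome:

* a small multi-chromosome genome (default 3 x 1 Mb, last chromosome
  `chrX`) with i.i.d. uniform sequence and motif instances written at the
  planted binding sites (no GC structure, repeats, or replication-timing
  covariates -- those are confounders the analysis does not model
  either);
* disjoint peaks with log-normal accessibility scores, 2--4 sites per
  peak across (default) two motif families;
* a mappability track with random gaps placed outside peaks;
* singleton 5--20 bp insertions: background placed uniformly on mappable
  bases *outside* site footprints, at-site placed inside footprints at
  `background x fold`. Excluding footprints from the background universe
  makes `fold` the exact planted density ratio -- with background
  everywhere the at-site density would be `(1 + fold) x background` and
  recovery would be biased;
* at-site insertions copy the overlapped motif instance with probability
  `tandem_duplication_probability` (default 0.5), otherwise insert a
  random 5--20-mer;
* common insertions thinned inside footprints by the depletion factor
  (default 0.2), plus `other` (AC = 5), 1--2 bp, and SNP strata so every
  classifier branch is exercised: singletons are written AC = 1 /
  AN = 150,000, common variants at 6% frequency;
* singleton SV deletions whose 5' breakpoints follow the same
  background/at-site machinery, and common-SV groups written as jittered
  near-copies that satisfy the reciprocal-overlap criterion.

Default rates (4e-3 insertions/bp background) are far above human
per-generation rates by design: they are scaled to a 3-Mb genome so that
each stratum yields hundreds of events, the same statistical regime as
650,000 variants on a 3-Gb genome. The defaults were fixed before any
recovery experiment and give >= 200 at-site insertions at the smallest
planted fold (2). The IFE estimator carries a known, quantifiable
compression: with site footprint fraction `s` and fold `f`, the
permutation expectation includes the at-site excess, so the recovered
ratio is `f / (1 + (f - 1) s)` -- about 7% low at `f = 10` with the
default `s ~ 0.01`, well inside the 25% recovery tolerance. Passing
recovery tests therefore demonstrate estimator correctness under the
generator's assumptions (uniform placement, independent variants); they
do not demonstrate robustness to sequence-composition confounding, which
real analyses address by mappability filtering and covariate modelling.

`worked_example()` is the fully hand-checkable case: one 100-kb
chromosome, 10 peaks, 20 sites, 40 singleton insertions of which exactly
30 sit inside sites, 3 SV deletions (6 breakpoints). Every overlap in the
test suite that uses it was enumerated by hand.

```{r worked}
b <- worked_example()
count_overlaps(variants_to_granges(b$variants, b$layout), b$sites)
length(extract_breakpoints(b$svs, b$layout, "singleton_per_sv"))
```

## Numerical choices and degenerate inputs

* Permutation SD of zero yields `z = NA` while the empirical p-value
  remains valid; add-one smoothing bounds p away from 0.
* `fold_enrichment()` returns `NA` for non-positive expected counts; on
  a single small chromosome the circular null can legitimately produce a
  zero permutation mean.
* Degenerate 2x2 tables (`A = 0`, `A = B`, ...) return a flagged
  sentinel rather than infinities.
* `score_threshold()` warns and returns the maximum score when the
  requested p-value is below the best achievable tail.
* Ties in family clustering are broken deterministically (longest
  member, then lexicographic; family ids ordered by representative
  name), so the partition is invariant to input order.
* All randomized operations take explicit seeds and restore the caller's
  RNG state; fixed seeds make permutation vectors and whole bundles
  bit-reproducible.

## Problem sizes used by the test and acceptance runs

The suite validates against analytic oracles with hundreds of
permutations, and runs the planted-fold recovery at the generator's
default scale (3-Mb genome, ~2,000 sites, ~12,000--17,000 variants,
1,000 permutations), which we consider the smallest regime where a 25%
relative tolerance on a fold estimate is comfortably outside Monte Carlo
noise. The reference setting of 10,000 permutations is exercised on the
single-interval analytic oracle, where each permutation is cheap.

## Known limitations

* The circular null conditions on one offset per chromosome; on a
  one-chromosome genome its permutation distribution is coarse and the
  expected count may be zero (see above). Multi-chromosome inputs are
  the intended regime.
* PWM family clustering reproduces a *partition*, not any specific
  published tool's alignment scores; family counts on real motif sets
  are data- and threshold-dependent.
* FIMO-style 0-order background estimation from the scanned sequence is
  not implemented; backgrounds are supplied explicitly.
* The generator plants independent variants; it does not emulate
  mutational signatures, clustered calling artefacts, or
  reference-bias, so recovery results bound estimator error only.
* Quality filters of array-based SV cohorts (wscore, log-ratio, CIFER
  classes) are upstream concerns; records are assumed pre-filtered.
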