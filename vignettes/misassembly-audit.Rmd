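---
title: "Auditing short-read assemblies for collapsed duplications from read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing short-read assemblies for collapsed duplications from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most plant genome assemblies in public databases were built from short
sequencing reads. When two or more near-identical copies of a sequence —
tandem gene arrays, retrogene families, recently duplicated tracts — are
longer than the reads, an assembler may *collapse* them into a single copy.
The collapsed copy then soaks up the reads of every original copy, so its
normalized read depth (RD) sits near the copy number k instead of 1.
Conversely, regions the assembler could not resolve appear as N-filled gaps
with RD near 0. Read depth computed from the assembly's own reads is
therefore a usable misassembly signal: high-coverage (HC) regions flag
candidate collapsed duplications, low-coverage (LC) regions flag gaps and
unassemblable sequence, and the rest is background (BG).

`misasm` implements this audit end to end:

1. **Read depth** (`count_reads_per_bin`, `gc_correct`, `normalize_rd`):
   reads are counted into fixed-width bins, corrected for GC bias, and
   normalized so the genome-wide median is 1.
2. **Region calling** (`segment_bins`, `filter_candidates`,
   `apply_thresholds`, `call_regions`): bins are segmented into candidate
   high/low/background regions, tested against the background mean,
   filtered on a BH-adjusted q-value and on the multi-mapping read fraction
   q0, and classified with a dual RD-threshold scheme.
3. **Misassembly categories** (`parse_coords`, `classify_regions`,
   `intersect_with_coverage`, `cross_assembly_class_map`): whole-genome
   alignment blocks against a trusted (e.g. long-read) assembly assign each
   query region one of six categories — C1/C2/C3 correctly assembled,
   M1/M2/M3 misassembled; 1 non-duplicated, 2 locally duplicated, 3
   duplicated across chromosomes.
4. **Features and models** (`feature_matrix`, `train_region_classifier`):
   per-region and flanking-window genomic features feed balanced
   random-forest classifiers that predict coverage class or misassembly
   status and rank informative features.
5. **Statistics** (`llr`, `enrichment_test`, `density_correlation`,
   `reshuffle_zscore`, `matched_random_regions_zscore`): enrichment of
   functional annotations in HC regions and permutation z-scores for
   co-localization of regions with genomic feature tracks.
6. **Synthetic data** (`genome_spec`, `build_truth_genome`,
   `derive_collapsed_assembly`, `simulate_reads`,
   `emit_alignment_coords`): a generator that plants duplications,
   collapse events, gaps and annotation tracks, so every claim above is
   testable against known truth.

All internal coordinates are 0-based half-open (BED convention); 1-based
formats (GFF3, alignment coords tables) are converted at the I/O boundary.

# Read depth

A read is assigned to a bin iff at least 50% of its length overlaps the
bin, ties going to the earlier bin, so each read counts at most once. The
default bin size is 100 bp; `choose_bin_size` implements the standard
operating rule of selecting the smallest bin size whose mean/SD ratio of
per-bin counts falls in [4, 5] (for Poisson counts the ratio is
sqrt(mean), so this targets roughly 16–25 reads per bin; at 46-fold
coverage with 100 bp reads, 100 bp bins give ~46 reads per bin and a ratio
near 6.8 — slightly conservative, which only helps segmentation).

GC correction stratifies bins into 1-percentage-point GC classes and
rescales each stratum to the global mean count; strata with fewer than 30
bins are too small for a stable mean and keep their raw counts. A final
rescale pins the global mean of corrected counts to the raw mean exactly,
so correction never changes overall coverage. Bins that are mostly N are
excluded from the stratum and global means (their counts are not
informative) but still receive corrected and normalized values.
Normalization divides by the genome-wide *median* (not mean) corrected
count of non-N bins: the median is robust to the heavy right tail that
collapsed regions create, and puts background RD at 1.

# Region calling

The caller works in three layers:

* **Per-bin state.** A bin is candidate-high (low) when its RD exceeds
  (falls below) the genome median by more than `z = 2` robust standard
  deviations (median absolute deviation of non-N RD). The robust scale
  matters: planted RD-0 and RD-2 bins would inflate a plain standard
  deviation and mask themselves.
* **Runs.** Maximal runs of concordant bins become candidate regions;
  up to one discordant bin is bridged between concordant neighbours
  (`max_gap = 1`), but never a bin of the opposite extreme state, so
  high and low candidates cannot overlap. The genomic complement forms
  candidate background regions; together the candidates tile the binned
  genome.
* **Significance and thresholds.** Each candidate gets a two-sided
  one-sample t-test of its bins' RD against the global non-N mean,
  BH-adjusted across all candidates. High/low candidates survive only with
  q < 0.08 and multi-mapping fraction q0 < 0.5 (q0 removes repeat-driven
  pileups that reflect mapping ambiguity rather than collapse). Finally
  the dual RD thresholds apply strictly: HC requires mean RD > 1.76, LC
  requires mean RD < 0.72, background stays BG only inside [0.72, 1.76],
  and any candidate that disagrees with its threshold becomes class
  "other". The default cut values 0.72/1.76 are the scheme's reference
  operating point, derived on a real plant short-read assembly;
  `select_thresholds` recomputes them for any dataset by a
  0.01-resolution grid search minimizing the summed misclassification
  fractions of each adjacent class pair, with ties resolved to the
  midpoint of the tying interval.

Degenerate candidates are handled explicitly: a single-bin candidate has
no within-region variance, its p-value is set to 1 and it is removed by
the q-filter; a zero-variance multi-bin candidate (e.g. an all-N gap at
RD exactly 0) gets p = 0 if its mean differs from background. In
`call_regions` the filtered-out high/low candidates are demoted to
"other" rather than dropped, so HC/LC/BG/other always partition the
binned genome — downstream length-fraction bookkeeping depends on that.

`segment_average_rd` replaces each bin's RD by its region's mean RD. This
is the per-bin value that segmentation-based read-depth callers report,
and it is the right quantity for recovery comparisons: when reads are
resampled from an idealized integer RD profile (0/1/2) at 46-fold
coverage, raw per-bin RD correlates with the input at about r = 0.95 —
the ceiling set by Poisson noise alone (signal variance 0.2 against
sampling variance 1/46) — while the segment-averaged RD recovers the
input at r ≈ 0.98, because averaging over multi-kilobase regions removes
nearly all sampling noise. The package's resampling-fidelity check
(criterion: Pearson ≥ 0.97) is defined on the segment-averaged values for
this reason.

# Misassembly categories

Alignment blocks (MUMmer `show-coords -T` layout) are identity-filtered
at ≥ 95% — matching the constructed ≥ 95% identity of duplicate copies —
then clustered: query intervals overlapping reciprocally by ≥ 50% form
one query region, and within a query region subject intervals merged by
the same reciprocal rule are counted. A query region with ≥ 2 remaining
subject regions is *duplicated*, regardless of subject chromosome.

A duplicated query region is called misassembled (M2 locally, M3
non-locally) only when all three of these hold: the query is at least
100 bp; the union of pairwise overlaps among its subject regions is below
50% of the query length (heavily self-overlapping subjects indicate one
fuzzily-aligned location, not two copies); and the subject regions align
to no other query region. That last privacy condition is the heart of the
call: if the duplication exists in both assemblies, each query copy hits
the same subject copies and they share subjects — correctly assembled
C2/C3. Only a collapsed query (one copy where the truth has k) holds its
subject copies privately. Queries whose shared subject set outnumbers the
sharing query copies are set aside as "complex" and excluded, as such
mixed copy-number cases have no clean binary label.

Non-duplicated regions are misassembled (M1) when their single subject
lies off the expected location. "Expected" is operationalized as: on the
majority subject chromosome for that query chromosome, and on the longest
strictly-increasing chain (by subject start, in query order) of
one-to-one anchor blocks. Blocks off that chain, or on a non-majority
chromosome, are M1. The choice of an LIS anchor chain is the package's
own; it reduces to the intuitive "different location" reading on
collinear assemblies and is validated against enumerated cases in the
tests.

Where the subject-overlap condition is ambiguous between a pairwise-max
and a union reading, the union is used (and a fuzz of overlapping subject
pairs is merged beforehand), which is the stricter of the two.

`intersect_with_coverage` reports length fractions both ways (coverage
class by category and category by coverage class; the latter sums to 1
over HC/BG/LC/other because bases outside called HC/BG/LC count as
other), plus a per-region majority label: a region > 50% covered by M2/M3
becomes `<class>_M2/M3` — the label consumed by the misassembly
discriminator models. `cross_assembly_class_map` projects query regions
through their blocks (linearly interpolated within each block) and
assigns the plurality subject coverage class; on synthetic data collapsed
HC regions project to BG on the truth assembly, since the truth carries
each copy once.

# Features and models

The seven base features are GC content and the densities (covered
fraction, via interval union, so always in [0, 1]) of all genes, tandem
genes, non-tandem genes, pseudogenes, TEs and SSRs. The same seven are
computed over flanking windows of 0.5/1/2/4/8/16/32 kb (upstream and
downstream pooled — the union of both sides; sides are not informative
separately for an orientation-free signal) plus an "all" union window.
Sequence-composition features are per-motif k-mer densities (k = 1..6,
single strand, no reverse-complement collapsing, sliding windows
containing N excluded from numerator and denominator) and per-motif SSR
densities. SSRs are exact adjacent repeats of a 2–64 bp unit, at least
two copies (trailing partial copies extend the tract), reported with the
smallest period; a mismatch-tolerant finder in the style of Tandem
Repeats Finder (Match = 2, Mismatch = 7, Delta = 7, PM = 80, PI = 10,
Minscore = 50, Maxperiod = 500 would be its classical parameters) is out
of scope, so planted and detected repeats are exact. Tandem gene
classification links paralog pairs that are adjacent or separated by at
most 10 non-homologous genes and takes the transitive closure. Because
the number of k-mer/SSR features dwarfs the number of regions, a
Kruskal–Wallis screen (p < 0.05 across classes) precedes model building,
and the top 100/500/1000 by ensemble importance feed the corresponding
catalog models (k-mers and SSR motifs selected separately, each family
getting its own top-n).

Model training follows the balanced protocol: 10% of regions held out
(stratified random, or two random genomic spans per chromosome when a
leakage-controlled split is wanted — span-mode test regions provably
share no coordinates with training regions); the remaining pool is
resampled into 100 balanced datasets (each class downsampled to the
minority class without replacement); hyperparameters (`max_depth`,
`mtry`, `num_trees`) are grid-searched by 10-fold cross-validated
macro-F1 on the first 10 balanced datasets and the best point is reused
for all 100; reports average per-class recall/precision, macro-F1 and
row-normalized confusion matrices over datasets. Random forests are fit
with `ranger` using Gini impurity for splitting and impurity importance
(normalized to sum 1); an entropy/information-gain criterion is not
exposed by the installed R forest implementations, and for importance
*ranking* — the quantity the analysis consumes — the two impurity
measures are interchangeable in practice. On balanced K-class data a
random predictor scores accuracy 1/K and macro-F1 ≈ 1/K, which the tests
verify at K = 2 and 3; these are the floors against which model skill is
measured.

# Randomization statistics

Enrichment of a functional term in HC-region genes uses the 2×2 table
(term × in-HC) with Fisher's exact test, BH adjustment within each
annotation family, and the log-likelihood ratio
LLR = log10((a/b)/(c/d)) for ranking; zero cells get a Haldane +0.5 on
all four cells and are flagged. The LLR is computed as a difference of
row log-odds so that swapping the rows negates it bit-exactly.

Two permutation nulls are provided. `reshuffle_zscore` keeps region
coordinates fixed and permutes class labels (class counts preserved),
recomputing the Spearman correlation between the class's windowed density
(500 kb windows by default) and a feature track; z is the observed
correlation standardized by the null, and the add-one permutation
p-value is exact under exchangeability — with 199 permutations the
rejection probability at α = 0.05 is exactly 10/200, which the 500-replicate
calibration test pins inside [0.03, 0.07]. The alternative reading of
"reshuffling" — re-placing region coordinates rather than relabeling —
is exactly what `matched_random_regions_zscore` provides: each null draw
places the focal set's interval-length multiset (every draw reproduces it
exactly), non-overlapping, uniformly inside the background space by
length-weighted rejection sampling (capped at 10^4 retries per interval),
and feature counts over the placed regions form the null. Label
permutation is the default because it conditions on the observed spatial
pattern of regions; the matched sampler is the right null when the
question is about where regions sit, as for gene-type counts in HC
regions.

# The synthetic generator

The generator emulates the inputs of a short-read assembly audit: a truth
genome with planted tandem clusters, interchromosomal duplicate pairs,
SSR stretches and annotation-only tracks (genes with intron structure,
TEs, pseudogenes, ncRNAs); a derived assembly in which chosen clusters
are collapsed to one copy and chosen intervals become N gaps; per-bin
Poisson read placements; and the alignment-block table an aligner would
produce between the two. Duplicate copies are made by copy-then-point-
mutate at 1% per base (configurable up to 5%), guaranteeing the ≥ 95%
identity filter retains them. Reads are drawn per 100 bp bin at rate
expected_RD × coverage × bin_size / read_length — 46-fold coverage and
100 bp reads by default, a routine modern short-read depth — with an
optional logistic GC-bias multiplier (2·logistic(−gc_bias·(GC − GC_ref)),
so gc_bias = 0 is exactly unbiased), and no read starts inside N gaps.
Reads born in duplicated tracts that the derived assembly retains in ≥ 2
copies are flagged multi-mapping with probability 0.9; collapsed tracts
retain one copy, map uniquely, and keep q0 low — which is precisely why
real collapsed duplications survive the q0 filter while unresolved
repeats do not.

What the generator does *not* emulate: sequencing errors and quality
scores, paired-end structure, a real aligner's mapping ambiguity (the
multi-mapping flag is planted, not inferred), indel variation between
duplicate copies, and the empirical duplication size/identity spectrum of
any particular genome — duplication sizes and rates are free parameters,
not calibrated to any particular species. Passing tests on this
generator therefore demonstrate that the pipeline's logic is correct
under its stated model (Poisson sampling, exact-copy duplications,
clean alignments), not that it is robust to every artifact of real data.

# Problem sizes and numerical choices

The test suite runs on: a ~690 kb two-chromosome genome with seven
planted duplication/gap events at 46-fold coverage (region recovery,
category recovery, q0, subsampling); a 1 Mb featureless genome (Poisson
calibration and the uniform null — zero HC/LC calls); and a 2 Mb
idealized-RD genome with 5 kb blocks at RD 0/1/2 (10%/80%/10%) for the
resampling-fidelity check. The 5 kb block length was chosen once as
representative of called-region scales (real HC/BG region median lengths
are a few to a few tens of kb). The permutation calibration uses 500
replicates of 30 regions × 199 permutations. The acceptance script
(`scripts/acceptance.R`) re-runs the baseline calibrations at n = 60,000
labels and the 2 Mb fidelity and idempotency computations from scratch.

Other numerical choices: the 50%-overlap read assignment resolves exact
ties to the earlier bin (deterministic and order-independent); threshold
grid resolution is 0.01 RD units; BH is used wherever a multiple-testing
adjustment is unspecified; Spearman correlations use the normal
approximation for ties; and all seeds are explicit arguments threaded
through every stochastic step, so any reported number is reproducible
from its call alone.

# Limitations

The caller's run-merging segmentation is deliberately simpler than
mean-shift segmentation; it recovers multi-kilobase planted events
cleanly but will fragment events at the single-bin scale and makes no
attempt to reproduce any particular CNV caller's boundaries. M1 calling
depends on an anchor-chain heuristic that assumes largely collinear
assemblies. The enrichment and model layers treat annotations as given —
no annotation inference is attempted. And genome-scale reference numbers for a real
organism (genome-wide HC/LC percentages, the F1 of a full
hundreds-of-features model, misassembly rates of HC regions) require the
real assemblies and read sets; at desk scale the package verifies the
machinery against synthetic truth and the calibration bounds instead.
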