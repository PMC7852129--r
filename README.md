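# misasm

Read-depth auditing of collapsed duplications in short-read genome
assemblies.

## The problem

Short-read assemblies routinely *collapse* near-identical duplicated
sequence — tandem gene arrays, retrogene families, recent segmental
duplications — into a single copy. When the sequencing reads are mapped
back, the collapsed copy receives the reads of every original copy and its
normalized read depth (RD) rises toward the copy number; unassemblable
sequence shows up as N-filled gaps with RD near 0. `misasm` turns this
signal into a misassembly audit for anyone assessing an assembly they are
about to analyse:

- **Coverage region calling.** Reads are counted into 100 bp bins (a read
  counts in the bin holding ≥ 50% of its length), GC-corrected by 1-point
  GC strata, and normalized to a genome-wide median RD of 1. Runs of
  deviant bins become candidate regions, tested against background
  (two-sided one-sample t-test, Benjamini–Hochberg adjusted), filtered on
  q < 0.08 and on the multi-mapping read fraction q0 < 0.5, and classified
  with strict dual thresholds: **HC** (high coverage) if mean RD > 1.76,
  **LC** if mean RD < 0.72, **BG** (background) inside the band, and
  "other" for candidates that disagree with their threshold.
  `select_thresholds()` re-derives the two cut values for any dataset by
  minimizing the between-class overlap on a 0.01 grid.
- **Six-way misassembly classification.** Alignment blocks against a
  trusted (e.g. long-read) assembly — MUMmer `show-coords` layout,
  identity ≥ 95% — are grouped into query regions with merged subject
  regions. A region with ≥ 2 subjects is *duplicated*; it is called
  **misassembled** (M2 locally on one subject chromosome, M3 across
  chromosomes) iff it is ≥ 100 bp, its subjects' mutual overlap is < 50%
  of the query, and the subjects align to no other query region —
  otherwise it is a duplication present in both assemblies (C2/C3).
  Non-duplicated regions are C1, or M1 when their single subject is off
  the collinear anchor chain. The log-likelihood ratio
  `LLR = log10((a/b)/(c/d))`, Fisher tests, windowed density correlations
  (Spearman ρ over 500 kb windows), label-reshuffling z-scores and
  matched-length random-region z-scores quantify what is enriched in HC
  regions; balanced random-forest models predict region classes from GC,
  gene/TE/pseudogene/SSR densities, flanking windows (0.5–32 kb) and
  k-mer (1–6 bp) composition.
- **Synthetic truth.** A generator plants tandem/interchromosomal
  duplications, collapse events, gaps, SSRs and annotation tracks,
  simulates binned Poisson read placements at a chosen coverage, and emits
  the alignment blocks the derived assembly would produce against the
  truth — so the whole pipeline is testable without any external data.

See the vignette (`vignettes/misassembly-audit.Rmd`) for the model,
parameter rationale and limitations.

## Worked example

Plant a 2-copy tandem cluster and an interchromosomal duplicate pair,
collapse both, add one gap, sequence at 46-fold, and audit:

```r
library(misasm)

spec <- genome_spec(
  chrom_lengths    = c(chr1 = 300000L, chr2 = 200000L),
  tandem_clusters  = data.frame(chrom = "chr1", start = 50000L,
                                unit_len = 3000L, copies = 2L),
  interchrom_pairs = data.frame(chrom1 = "chr1", start1 = 150000L,
                                chrom2 = "chr2", start2 = 60000L, len = 4000L),
  gaps     = data.frame(chrom = "chr1", start = 220000L, len = 5000L),
  collapse = data.frame(type = c("tandem", "interchrom"), id = c(1L, 1L)),
  seed = 7L)

truth     <- build_truth_genome(spec)
collapsed <- derive_collapsed_assembly(truth)
reads     <- simulate_reads(collapsed)
bins      <- compute_rd(reads, seqs = collapsed$seqs)
regions   <- call_regions(bins)
regions[regions$coverage_class %in% c("HC", "LC"),
        c("chrom", "start", "end", "coverage_class", "mean_rd", "q_value", "q0")]
#>     chrom  start    end coverage_class    mean_rd      q_value    q0
#> 1:   chr1  50000  53100             HC 1.97470436 7.087453e-20     0
#> 2:   chr1 147000 151100             HC 1.93526068 7.613836e-26     0
#> 3:   chr1 217000 222100             LC 0.01996292 4.894167e-49     0
```

Both collapsed duplications are recovered as HC regions with mean RD ≈ 2
(twice background, as expected for a collapsed 2-copy cluster) at
vanishing q-values, and the N gap is an LC region at RD ≈ 0. Aligning the
derived assembly back to the truth classifies them:

```r
blocks     <- emit_alignment_coords(truth, collapsed)
categories <- classify_regions(filter_identity(blocks))
categories[categories$category != "C1", ]
#>    qr_id  chrom  start    end n_subjects category
#> 1:     2   chr1  50000  53000          2       M2
#> 2:     4   chr1 147000 151000          2       M3
```

The tandem collapse is a local duplication misassembly (M2), the
interchromosomal collapse a non-local one (M3), each with the 2 truth
copies as subjects. Intersecting categories with coverage classes shows
the HC bases are almost entirely misassembled duplications:

```r
lens <- setNames(Biostrings::width(collapsed$seqs), names(collapsed$seqs))
iw <- intersect_with_coverage(categories[, c("chrom", "start", "end", "category")],
                              regions, lens)
subset(iw$class_by_category, coverage_class == "HC" & fraction > 0)
#>    coverage_class category   fraction
#> 1:             HC       C1 0.02777778
#> 2:             HC       M2 0.41666667
#> 3:             HC       M3 0.55555556
```

`run_pipeline(config)` drives the same stages (plus feature extraction,
permutation statistics, and — given enough regions per class — a balanced
random-forest model) from a single JSON config
and writes a `report.json` bundle; `inst/extdata/demo_config.json` is a
ready-made example.

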