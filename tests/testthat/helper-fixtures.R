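# Shared synthetic fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Two-chromosome genome with collapsed and retained duplications, gaps and
# annotation tracks; sequenced at 46x. Collapsed assembly is ~660 kb.
medium_spec <- function(seed = 42L) {
  genome_spec(
    chrom_lengths = c(chr1 = 500000L, chr2 = 200000L),
    genes = data.frame(chrom = "chr1",
                       start = seq(10000L, 470000L, by = 40000L),
                       len = 3000L, introns = 2L),
    tandem_clusters = data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr2"),
      start = c(50000L, 150000L, 250000L, 30000L),
      unit_len = c(4000L, 3000L, 2500L, 4000L),
      copies = c(2L, 2L, 3L, 2L)),
    interchrom_pairs = data.frame(chrom1 = "chr1", start1 = 350000L,
                                  chrom2 = "chr2", start2 = 120000L,
                                  len = 3000L),
    tes = data.frame(chrom = "chr2", start = seq(5000L, 185000L, by = 20000L),
                     len = 2000L),
    ssrs = data.frame(chrom = "chr1",
                      start = c(420000L, 440000L),
                      unit = c("AT", "CAG"), copies = c(60L, 40L)),
    gaps = data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(200000L, 300000L, 80000L),
                      len = c(4000L, 3000L, 4000L)),
    # collapse two tandem clusters and the interchromosomal pair; keep
    # tandem clusters 3 and 4 duplicated in the derived assembly
    collapse = data.frame(type = c("tandem", "tandem", "interchrom"),
                          id = c(1L, 2L, 1L)),
    coverage = 46, read_length = 100L, seed = seed)
}

medium_dataset <- function() fixture("medium", function() {
  spec <- medium_spec()
  truth <- build_truth_genome(spec)
  collapsed <- derive_collapsed_assembly(truth)
  placements <- simulate_reads(collapsed)
  bins <- compute_rd(placements, seqs = collapsed$seqs)
  regions <- call_regions(bins)
  blocks <- emit_alignment_coords(truth, collapsed)
  list(spec = spec, truth = truth, collapsed = collapsed,
       placements = placements, bins = bins, regions = regions,
       blocks = blocks)
})

# Featureless uniform genome sequenced at 46x (the null control).
uniform_dataset <- function() fixture("uniform", function() {
  spec <- genome_spec(chrom_lengths = c(chr1 = 1000000L), seed = 5L)
  truth <- build_truth_genome(spec)
  collapsed <- as_sequencing_target(truth)
  placements <- simulate_reads(collapsed)
  bins <- compute_rd(placements, seqs = collapsed$seqs)
  list(collapsed = collapsed, placements = placements, bins = bins)
})

# Noiseless bin table: rd exactly as given, one chromosome, 100 bp bins.
bins_from_rd <- function(rd, raw = round(rd * 46), multimap = 0L) {
  n <- length(rd)
  data.table::data.table(
    chrom = "chr1", start = seq(0L, by = 100L, length.out = n),
    end = seq(100L, by = 100L, length.out = n),
    raw_count = raw, multimap_count = rep_len(multimap, n),
    corrected_count = raw, rd = rd, n_frac = 0)
}
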