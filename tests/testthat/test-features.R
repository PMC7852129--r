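# Track densities, flanking windows, k-mer densities with N masking, the
# SSR finder versus a brute-force scanner, tandem classification and
# feature screening.

test_that("track density is the unioned covered fraction", {
  region <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  full <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(track_density(full, region), 1)
  two <- data.table::data.table(chrom = "chr1", start = c(0L, 50L),
                                end = c(100L, 200L))
  expect_equal(track_density(two, region), 0.2)  # union, not sum
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer())
  expect_equal(track_density(empty, region), 0)
  expect_error(track_density(two, data.table::data.table(
    chrom = "chr1", start = 5L, end = 5L)), "zero-length")
})

test_that("flanking windows clip at chromosome bounds", {
  regions <- data.table::data.table(chrom = "chr1", start = c(0L, 5000L),
                                    end = c(1000L, 6000L))
  w <- flanking_windows(regions, sizes = 500, c(chr1 = 10000L))
  first <- w[w$region == 1, ]
  expect_equal(nrow(first), 1L)  # upstream window empty at chromosome start
  expect_equal(first$side, "down")
  mid <- w[w$region == 2, ]
  expect_equal(sum(mid$end - mid$start), 1000L)  # 500 + 500

  set.seed(2)
  rnd <- data.table::data.table(
    chrom = "chr1", start = sample.int(9000L, 50), end = 0L)
  rnd$end <- rnd$start + 500L
  wr <- flanking_windows(rnd, c(500, 2000, 8000), c(chr1 = 10000L))
  expect_true(all(wr$start >= 0 & wr$end <= 10000L))
})

test_that("k-mer densities: sliding-window oracle and N masking", {
  expect_equal(unname(kmer_density("AAAA", 1)["A"]), 1)
  d2 <- kmer_density("ATAT", 2)
  expect_equal(unname(d2["AT"]), 2 / 3)
  expect_equal(unname(d2["TA"]), 1 / 3)
  # N windows excluded from numerator and denominator: "ANAT" has one valid
  # 2-mer window ("AT")
  dn <- kmer_density("ANAT", 2)
  expect_equal(unname(dn["AT"]), 1)
  expect_equal(sum(dn), 1)
  # against Biostrings on N-free random sequence
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  for (k in c(1L, 3L)) {
    ref <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), k) /
      (500 - k + 1)
    expect_equal(kmer_density(s, k), ref)
  }
  expect_warning(kmer_density("ACG", 5), "k exceeds")
})

test_that("1-mer densities sum to 1 over non-N bases", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  expect_equal(sum(kmer_density(s, 1)), 1)
})

# brute force: try every period at every start, extend maximally
ssr_oracle <- function(s, min_unit = 2L, max_unit = 64L) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  good <- chars %in% c("A", "C", "G", "T")
  calls <- list()
  match_at <- function(i, p) i >= 1 && i + p <= L && good[i] && good[i + p] &&
    chars[i] == chars[i + p]
  for (p in min_unit:min(max_unit, floor(L / 2))) {
    for (i in seq_len(L - 2L * p + 1L)) {
      if (match_at(i - 1L, p)) next  # not left-maximal
      j <- i
      while (match_at(j, p)) j <- j + 1L
      span <- j - i + p
      if (span >= 2L * p)
        calls[[length(calls) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + span, period = p,
          unit = substr(s, i, i + p - 1L))
    }
  }
  if (!length(calls)) return(data.frame(start = integer(), end = integer(),
                                        period = integer(), unit = character()))
  do.call(rbind, calls)
}

test_that("SSR finder: definition examples", {
  out <- find_ssrs("ATATATAT")
  expect_equal(nrow(out), 1L)
  expect_equal(out$unit, "AT")
  expect_equal(out$start, 0L)
  expect_equal(out$end, 8L)
  expect_equal(out$copies, 4)
  expect_equal(nrow(find_ssrs("ACGT")), 0L)
  # trailing partial copy extends the tract
  expect_equal(find_ssrs("CAGCAGCA")$end, 8L)
})

test_that("SSR finder equals the brute-force all-period scanner on random sequence", {
  set.seed(11)
  base <- sample(c("A", "C", "G", "T"), 900, replace = TRUE)
  # plant a few tracts so the comparison is not vacuous
  base[101:120] <- rep(c("A", "T"), 10)
  base[301:330] <- rep(c("C", "A", "G"), 10)
  base[601:632] <- rep(strsplit("ACGTACGA", "")[[1]], 4)
  s <- paste(base, collapse = "")
  got <- find_ssrs(s)
  ora <- ssr_oracle(s)
  # oracle reports maximal tracts per period; the finder suppresses
  # multiple-period duplicates of a smaller reported period
  key <- function(d) paste(d$start, d$end, d$period)
  expect_true(all(key(got) %in% key(ora)))
  # every oracle tract is covered by a reported call with dividing period
  for (r in seq_len(nrow(ora))) {
    hit <- got$start <= ora$start[r] & got$end >= ora$end[r] &
      ora$period[r] %% got$period == 0
    expect_true(any(hit), info = paste("oracle row", r))
  }
})

test_that("tandem classification follows the <= 10 intervening non-homolog rule with closure", {
  mk_order <- function(n) data.frame(chrom = "chr1",
                                     id = paste0("g", seq_len(n)),
                                     start = seq_len(n) * 1000L)
  pairs <- data.frame(gene1 = "g1", gene2 = "g2")
  out <- classify_tandem(pairs, mk_order(5))
  expect_true(all(out$tandem[out$id %in% c("g1", "g2")]))
  expect_false(any(out$tandem[out$id == "g3"]))
  # 10 intervening -> tandem; 11 -> not
  out10 <- classify_tandem(data.frame(gene1 = "g1", gene2 = "g12"),
                           mk_order(15))
  expect_true(all(out10$tandem[out10$id %in% c("g1", "g12")]))
  out11 <- classify_tandem(data.frame(gene1 = "g1", gene2 = "g13"),
                           mk_order(15))
  expect_false(any(out11$tandem))
  # chain closure: g1-g7 (gap 5), g7-g13 (gap 5) -> one cluster
  chain <- classify_tandem(data.frame(gene1 = c("g1", "g7"),
                                      gene2 = c("g7", "g13")), mk_order(15))
  cl <- chain$cluster[chain$id %in% c("g1", "g7", "g13")]
  expect_equal(length(unique(cl)), 1L)
  expect_false(anyNA(cl))
  expect_error(classify_tandem(data.frame(gene1 = "g1", gene2 = "gX"),
                               mk_order(5)), "absent")
})

test_that("functional presence flags regions containing annotated genes", {
  regions <- data.table::data.table(chrom = "chr1", start = c(0L, 5000L),
                                    end = c(1000L, 6000L))
  genes <- data.table::data.table(chrom = "chr1", start = 100L, end = 700L,
                                  id = "geneA")
  tm <- data.frame(gene = "geneA", term = "T1")
  m <- functional_presence(regions, genes, tm)
  expect_equal(unname(m[, "T1"]), c(1L, 0L))
})

test_that("feature screening keeps discriminative features and drops constants", {
  set.seed(6)
  labels <- rep(c("HC", "BG", "LC"), each = 30)
  x <- data.frame(
    informative = c(rnorm(30, 0, 0.1), rnorm(30, 0, 0.1), rnorm(30, 10, 0.1)),
    noise = rnorm(90),
    same = rep(rnorm(30), 3),
    constant = 1)
  expect_warning(res <- screen_features(x, labels), "constant")
  expect_true("informative" %in% res$retained)
  expect_false("same" %in% res$retained)
  expect_false("constant" %in% res$retained)
  expect_error(screen_features(x, rep("A", 90)), ">= 2 classes")
})

test_that("planted SSR tracts raise regional SSR density detectably", {
  d <- medium_dataset()
  ssr_track <- d$truth$tracks$ssrs[, c("chrom", "start", "end")]
  set.seed(9)
  # 50 regions per class: on-SSR windows versus background windows
  on <- data.table::data.table(
    chrom = "chr1",
    start = as.integer(runif(50, 419000, 440000)), end = 0L)
  on$end <- on$start + 2000L
  bg <- data.table::data.table(
    chrom = "chr1", start = as.integer(runif(50, 0, 300000)), end = 0L)
  bg$end <- bg$start + 2000L
  dens <- track_density(ssr_track, rbind(on, bg))
  p <- stats::kruskal.test(dens, factor(rep(c("on", "bg"), each = 50)))$p.value
  expect_lt(p, 0.05)
})

test_that("intron counts derive from GFF3 exon structure", {
  gff <- data.table::data.table(
    chrom = "chr1", start = c(0L, 0L, 200L, 400L, 1000L, 1000L),
    end = c(500L, 100L, 300L, 500L, 1500L, 1500L),
    strand = "+", type = c("gene", "exon", "exon", "exon", "gene", "exon"),
    id = c("g1", "g1e1", "g1e2", "g1e3", "g2", "g2e1"),
    parent = c(NA, "g1", "g1", "g1", NA, "g2"))
  ic <- intron_counts(gff)
  expect_equal(ic[["g1"]], 2L)
  expect_equal(ic[["g2"]], 0L)
})

test_that("the feature matrix carries the seven base features and bounded densities", {
  d <- medium_dataset()
  reg <- d$regions[d$regions$coverage_class %in% c("HC", "BG", "LC"), ]
  tracks <- list(genes = d$truth$tracks$genes,
                 tes = d$truth$tracks$tes,
                 ssrs = d$truth$tracks$ssrs)
  fm <- feature_matrix(reg[1:20, ], d$collapsed$seqs, tracks,
                       flank_sizes = c(500, 2000), kmer_k = 1L)
  base7 <- c("gc", "density_genes", "density_tandem_genes",
             "density_nontandem_genes", "density_pseudogenes", "density_tes",
             "density_ssrs")
  expect_true(all(base7 %in% names(fm)))
  dens <- as.matrix(fm[, grep("density", names(fm)), with = FALSE])
  expect_true(all(dens >= 0 & dens <= 1))
  expect_true(all(grepl("^flank_", names(fm)) | names(fm) %in% base7 |
                    grepl("^kmer_", names(fm))))
  km <- as.matrix(fm[, grep("^kmer_", names(fm)), with = FALSE])
  expect_equal(unname(rowSums(km)), rep(1, nrow(km)))
})
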