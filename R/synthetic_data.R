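# Synthetic truth genomes, collapsed derived assemblies with known
# misassemblies, and simulated read placements. The generator is the ground
# truth supplier for every downstream stage: planted collapse events define
# where read depth must double (a collapsed duplication puts the reads of k
# near-identical copies onto one retained copy), gap events define zero-depth
# N runs, and the emitted alignment blocks are what a whole-genome aligner
# would report between the derived and the truth assembly.

BASES <- c("A", "C", "G", "T")

#' Specify a synthetic genome
#'
#' Builds a validated specification for [build_truth_genome()]. All
#' coordinates are 0-based half-open and refer to the truth genome. Features
#' whose sequence is written into the genome (tandem clusters, paired
#' interchromosomal duplicates, SSR stretches) must not overlap each other or
#' gap intervals; annotation-only tracks (genes, TEs, pseudogenes, ncRNAs)
#' only need to be internally disjoint.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc Target GC fraction: a single number, or a data.frame with
#'   `chrom`, `start`, `end`, `gc` describing a piecewise GC landscape.
#' @param genes data.frame(`chrom`, `start`, `len`, `introns`) or NULL.
#' @param tandem_clusters data.frame(`chrom`, `start`, `unit_len`, `copies`):
#'   `copies` adjacent near-identical units are written starting at `start`.
#' @param interchrom_pairs data.frame(`chrom1`, `start1`, `chrom2`, `start2`,
#'   `len`): a tract and its near-identical copy on another chromosome.
#' @param tes,pseudogenes,ncrnas data.frame(`chrom`, `start`, `len`) tracks.
#' @param ssrs data.frame(`chrom`, `start`, `unit`, `copies`): `unit` is the
#'   repeat motif string (2-64 bp), written `copies` times adjacently.
#' @param collapse data.frame(`type` in `"tandem"`/`"interchrom"`, `id` = row
#'   number in the corresponding track): duplicate clusters merged into a
#'   single copy in the derived assembly.
#' @param gaps data.frame(`chrom`, `start`, `len`): intervals of the derived
#'   assembly replaced by N (given in truth coordinates; must fall in unique
#'   sequence).
#' @param coverage Read coverage fold (> 0); default 46, a typical
#'   short-read whole-genome sequencing depth.
#' @param read_length Read length in bp (>= 1).
#' @param gc_bias Strength of the logistic GC bias on read-start rates
#'   (0 = unbiased).
#' @param multimap_fraction Fraction of reads originating in duplicated
#'   tracts retained in >= 2 copies that are flagged multi-mapping.
#' @param mutation_rate Per-base substitution rate applied to duplicate
#'   copies (<= 0.05 so copies stay >= 95% identical).
#' @param seed Integer seed making the whole construction deterministic.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, gc = 0.36,
                        genes = NULL, tandem_clusters = NULL,
                        interchrom_pairs = NULL, tes = NULL, ssrs = NULL,
                        pseudogenes = NULL, ncrnas = NULL,
                        collapse = NULL, gaps = NULL,
                        coverage = 46, read_length = 100, gc_bias = 0,
                        multimap_fraction = 0.9, mutation_rate = 0.01,
                        seed = 1) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_length < 1) stop("read_length must be >= 1")
  if (mutation_rate < 0 || mutation_rate > 0.05)
    stop("mutation_rate must be in [0, 0.05] so duplicate copies keep >= 95% identity")

  asdf <- function(x) if (is.null(x)) NULL else data.table::as.data.table(x)
  spec <- structure(list(
    chrom_lengths = chrom_lengths, gc = gc,
    genes = asdf(genes), tandem_clusters = asdf(tandem_clusters),
    interchrom_pairs = asdf(interchrom_pairs), tes = asdf(tes),
    ssrs = asdf(ssrs), pseudogenes = asdf(pseudogenes),
    ncrnas = asdf(ncrnas), collapse = asdf(collapse), gaps = asdf(gaps),
    coverage = coverage, read_length = read_length, gc_bias = gc_bias,
    multimap_fraction = multimap_fraction, mutation_rate = mutation_rate,
    seed = as.integer(seed)
  ), class = "genome_spec")

  v <- spec_footprints(spec)
  check_bounds <- function(df, label) {
    if (is.null(df) || !nrow(df)) return(invisible())
    bad <- df$start < 0 | df$end > chrom_lengths[df$chrom] |
      !(df$chrom %in% names(chrom_lengths))
    if (any(bad, na.rm = TRUE) || anyNA(bad))
      stop(label, " interval out of chromosome bounds (row ",
           which(bad | is.na(bad))[1], ")")
  }
  for (nm in names(v)) check_bounds(v[[nm]], nm)

  # sequence-defining tracks must be mutually disjoint
  seqdef <- data.table::rbindlist(
    v[c("tandem_clusters", "interchrom_pairs", "ssrs", "gaps")],
    idcol = "track", fill = TRUE)
  if (nrow(seqdef) > 1) {
    gr <- iv_to_gr(seqdef)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, gr))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    clash <- which(q < s)
    if (length(clash)) {
      i <- q[clash[1]]; j <- s[clash[1]]
      stop(sprintf("planted intervals cannot coexist: %s [%s:%d-%d] overlaps %s [%s:%d-%d]",
                   seqdef$track[i], seqdef$chrom[i], seqdef$start[i], seqdef$end[i],
                   seqdef$track[j], seqdef$chrom[j], seqdef$start[j], seqdef$end[j]))
    }
  }
  # annotation tracks: internally disjoint
  for (nm in c("genes", "tes", "pseudogenes", "ncrnas")) {
    df <- v[[nm]]
    if (!is.null(df) && nrow(df) > 1) {
      red <- iv_reduce(df)
      if (sum(red$end - red$start) != sum(df$end - df$start))
        stop(nm, " track contains overlapping intervals")
    }
  }
  if (!is.null(spec$collapse) && nrow(spec$collapse)) {
    for (i in seq_len(nrow(spec$collapse))) {
      type <- spec$collapse$type[i]; id <- spec$collapse$id[i]
      tab <- if (type == "tandem") spec$tandem_clusters else
        if (type == "interchrom") spec$interchrom_pairs else
          stop("unknown collapse type: ", type)
      if (is.null(tab) || id < 1 || id > nrow(tab))
        stop("collapse event ", i, " references absent ", type, " cluster ", id)
    }
  }
  spec
}

# Footprint intervals (chrom/start/end) of each planted track.
spec_footprints <- function(spec) {
  f <- list()
  if (!is.null(spec$genes) && nrow(spec$genes))
    f$genes <- data.table::data.table(chrom = spec$genes$chrom,
      start = spec$genes$start, end = spec$genes$start + spec$genes$len)
  if (!is.null(spec$tandem_clusters) && nrow(spec$tandem_clusters))
    f$tandem_clusters <- data.table::data.table(chrom = spec$tandem_clusters$chrom,
      start = spec$tandem_clusters$start,
      end = spec$tandem_clusters$start +
        spec$tandem_clusters$unit_len * spec$tandem_clusters$copies)
  if (!is.null(spec$interchrom_pairs) && nrow(spec$interchrom_pairs)) {
    p <- spec$interchrom_pairs
    f$interchrom_pairs <- data.table::data.table(
      chrom = c(p$chrom1, p$chrom2), start = c(p$start1, p$start2),
      end = c(p$start1 + p$len, p$start2 + p$len))
  }
  if (!is.null(spec$ssrs) && nrow(spec$ssrs))
    f$ssrs <- data.table::data.table(chrom = spec$ssrs$chrom,
      start = spec$ssrs$start,
      end = spec$ssrs$start + nchar(spec$ssrs$unit) * spec$ssrs$copies)
  for (nm in c("tes", "pseudogenes", "ncrnas", "gaps")) {
    df <- spec[[nm]]
    if (!is.null(df) && nrow(df))
      f[[nm]] <- data.table::data.table(chrom = df$chrom, start = df$start,
                                        end = df$start + df$len)
  }
  f
}

# point-mutate a base vector at `rate`, substituting a different base
mutate_bases <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    repl <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1L), character(1))
    x[hit] <- repl
  }
  x
}

random_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

#' Build a synthetic truth genome
#'
#' Materialises a [genome_spec()]: draws random background sequence at the
#' requested GC landscape, writes planted SSR stretches, tandem clusters and
#' interchromosomal duplicate pairs into it (duplicate copies are created by
#' copy-then-point-mutate at `mutation_rate`, so copies share >= 95%
#' identity), and records all planted tracks plus a duplicate map listing
#' every copy of every duplicated tract. Deterministic for a fixed spec seed.
#'
#' @param spec A `genome_spec`.
#' @return An object of class `truth_genome`: list with `seqs`
#'   ([Biostrings::DNAStringSet]), `tracks` (named list of interval
#'   data.tables), `dup_map` (one row per duplicate copy: `dup_id`, `type`,
#'   `copy`, `chrom`, `start`, `end`) and `spec`.
#' @export
build_truth_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  chroms <- names(spec$chrom_lengths)

  seqs <- list()
  for (ch in chroms) {
    len <- spec$chrom_lengths[[ch]]
    if (is.data.frame(spec$gc)) {
      segs <- spec$gc[spec$gc$chrom == ch, , drop = FALSE]
      x <- random_bases(len, 0.5)
      for (i in seq_len(nrow(segs)))
        x[(segs$start[i] + 1):segs$end[i]] <-
          random_bases(segs$end[i] - segs$start[i], segs$gc[i])
    } else {
      x <- random_bases(len, spec$gc)
    }
    seqs[[ch]] <- x
  }

  # plant SSR stretches
  if (!is.null(spec$ssrs) && nrow(spec$ssrs)) {
    for (i in seq_len(nrow(spec$ssrs))) {
      s <- spec$ssrs[i, ]
      tract <- strsplit(strrep(s$unit, s$copies), "")[[1]]
      seqs[[s$chrom]][(s$start + 1):(s$start + length(tract))] <- tract
    }
  }

  dup_map <- list()
  # tandem clusters: adjacent mutated copies of one random unit
  if (!is.null(spec$tandem_clusters) && nrow(spec$tandem_clusters)) {
    for (i in seq_len(nrow(spec$tandem_clusters))) {
      tc <- spec$tandem_clusters[i, ]
      gc_here <- if (is.data.frame(spec$gc)) 0.36 else spec$gc
      unit <- random_bases(tc$unit_len, gc_here)
      for (k in seq_len(tc$copies)) {
        cp <- if (k == 1) unit else mutate_bases(unit, spec$mutation_rate)
        s0 <- tc$start + (k - 1) * tc$unit_len
        seqs[[tc$chrom]][(s0 + 1):(s0 + tc$unit_len)] <- cp
        dup_map[[length(dup_map) + 1L]] <- data.table::data.table(
          dup_id = paste0("tandem_", i), type = "tandem", copy = k,
          chrom = tc$chrom, start = s0, end = s0 + tc$unit_len)
      }
    }
  }
  # interchromosomal pairs
  if (!is.null(spec$interchrom_pairs) && nrow(spec$interchrom_pairs)) {
    for (i in seq_len(nrow(spec$interchrom_pairs))) {
      p <- spec$interchrom_pairs[i, ]
      src <- seqs[[p$chrom1]][(p$start1 + 1):(p$start1 + p$len)]
      seqs[[p$chrom2]][(p$start2 + 1):(p$start2 + p$len)] <-
        mutate_bases(src, spec$mutation_rate)
      dup_map[[length(dup_map) + 1L]] <- data.table::data.table(
        dup_id = paste0("interchrom_", i), type = "interchrom", copy = 1:2,
        chrom = c(p$chrom1, p$chrom2), start = c(p$start1, p$start2),
        end = c(p$start1 + p$len, p$start2 + p$len))
    }
  }
  dup_map <- if (length(dup_map)) data.table::rbindlist(dup_map) else
    data.table::data.table(dup_id = character(), type = character(),
                           copy = integer(), chrom = character(),
                           start = integer(), end = integer())

  tracks <- spec_footprints(spec)
  if (!is.null(tracks$genes)) {
    tracks$genes$id <- paste0("gene", seq_len(nrow(tracks$genes)))
    tracks$genes$introns <- spec$genes$introns %||% 0L
  }
  if (!is.null(tracks$ssrs)) tracks$ssrs$unit <- spec$ssrs$unit

  dss <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(dss) <- chroms
  structure(list(seqs = dss, tracks = tracks, dup_map = dup_map, spec = spec),
            class = "truth_genome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a collapsed assembly with truth labels
#'
#' Applies the spec's collapse and gap events to a truth genome: every
#' collapsed k-copy duplicate cluster is represented once (copies beyond the
#' first are deleted from the sequence), and gap intervals become runs of N.
#' The returned labels give, for every base of the derived assembly, the
#' expected read depth (k over a collapsed k-copy cluster, 0 over gaps, 1
#' elsewhere), the expected coverage class (HC/BG/LC) and the expected
#' assembly category: M2 for copies collapsed from one truth chromosome, M3
#' for interchromosomal collapses, C2/C3 for duplicates retained in full,
#' C1 for untouched unique sequence.
#'
#' @param truth A `truth_genome`.
#' @param collapse,gaps Override the events recorded in the spec (same
#'   layouts as in [genome_spec()]).
#' @return An object of class `collapsed_assembly`: list with `seqs`,
#'   `labels` (list of interval tables `category`, `expected_rd`,
#'   `coverage_class`, `multimap`), `segment_map` (query<->truth mapping of
#'   kept unique segments), `dup_map` (duplicate copies in derived
#'   coordinates with their truth copies), and `spec`.
#' @export
derive_collapsed_assembly <- function(truth,
                                      collapse = truth$spec$collapse,
                                      gaps = truth$spec$gaps) {
  stopifnot(inherits(truth, "truth_genome"))
  spec <- truth$spec
  dm <- truth$dup_map

  collapsed_ids <- character(0)
  removed <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer())
  if (!is.null(collapse) && nrow(collapse)) {
    for (i in seq_len(nrow(collapse))) {
      id <- paste0(collapse$type[i], "_", collapse$id[i])
      if (!id %in% dm$dup_id)
        stop("collapse of a cluster not present in truth: ", id)
      collapsed_ids <- c(collapsed_ids, id)
      cps <- dm[dm$dup_id == id & dm$copy > 1, ]
      removed <- rbind(removed, cps[, c("chrom", "start", "end")])
    }
  }

  chroms <- names(spec$chrom_lengths)
  seq_chr <- as.character(truth$seqs)
  new_seqs <- character(0)
  segmap <- list()
  shift_of <- function(ch, pos) {  # truth coord -> collapsed coord
    r <- removed[removed$chrom == ch, ]
    pos - sum(pmin(r$end, pos) - pmin(r$start, pos))
  }
  for (ch in chroms) {
    len <- spec$chrom_lengths[[ch]]
    kept <- iv_setdiff(
      data.table::data.table(chrom = ch, start = 0L, end = len),
      removed)
    kept <- kept[order(kept$start), ]
    if (!nrow(kept)) { new_seqs[ch] <- ""; next }
    pieces <- substring(seq_chr[[ch]], kept$start + 1, kept$end)
    new_seqs[ch] <- paste(pieces, collapse = "")
    qend <- cumsum(kept$end - kept$start)
    segmap[[ch]] <- data.table::data.table(
      qchrom = ch, qstart = qend - (kept$end - kept$start), qend = qend,
      tchrom = ch, tstart = kept$start, tend = kept$end)
  }
  segmap <- data.table::rbindlist(segmap)

  # duplicate copies surviving in the derived assembly, with collapsed coords
  dm2 <- dm[!(dm$dup_id %in% collapsed_ids & dm$copy > 1), ]
  dm2$qstart <- if (nrow(dm2))
    as.integer(mapply(shift_of, dm2$chrom, dm2$start)) else integer(0)
  dm2$qend <- dm2$qstart + (dm2$end - dm2$start)
  dm2$collapsed <- dm2$dup_id %in% collapsed_ids
  n_copies <- table(dm$dup_id)
  dm2$total_copies <- as.integer(n_copies[dm2$dup_id])

  # gaps: truth coordinates in unique kept sequence -> N runs
  gap_iv <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer())
  if (!is.null(gaps) && nrow(gaps)) {
    gap_iv <- data.table::data.table(chrom = gaps$chrom,
                                     start = gaps$start,
                                     end = gaps$start + gaps$len)
    if (nrow(iv_intersect(gap_iv, removed)))
      stop("gap events must not overlap collapsed duplicate copies")
    gap_iv$start <- as.integer(mapply(shift_of, gap_iv$chrom, gap_iv$start))
    gap_iv$end <- as.integer(mapply(shift_of, gap_iv$chrom, gap_iv$end))
    for (i in seq_len(nrow(gap_iv))) {
      ch <- gap_iv$chrom[i]
      substr(new_seqs[ch], gap_iv$start[i] + 1, gap_iv$end[i]) <-
        strrep("N", gap_iv$end[i] - gap_iv$start[i])
    }
  }

  q_lens <- nchar(new_seqs)
  genome_iv <- data.table::data.table(chrom = chroms, start = 0L,
                                      end = as.integer(q_lens[chroms]))

  cat_iv <- list()
  add_cat <- function(df, category) {
    if (nrow(df)) {
      df <- df[, c("chrom", "start", "end")]
      df$category <- category
      cat_iv[[length(cat_iv) + 1L]] <<- df
    }
  }
  qdup <- data.table::data.table(chrom = dm2$chrom, start = dm2$qstart,
                                 end = dm2$qend, type = dm2$type,
                                 collapsed = dm2$collapsed)
  add_cat(qdup[qdup$collapsed & qdup$type == "tandem", ], "M2")
  add_cat(qdup[qdup$collapsed & qdup$type == "interchrom", ], "M3")
  add_cat(qdup[!qdup$collapsed & qdup$type == "tandem", ], "C2")
  add_cat(qdup[!qdup$collapsed & qdup$type == "interchrom", ], "C3")
  add_cat(gap_iv, "unaligned")
  taken <- data.table::rbindlist(
    lapply(cat_iv, function(d) d[, c("chrom", "start", "end")]),
    fill = TRUE)
  add_cat(iv_setdiff(genome_iv, taken), "C1")
  category <- data.table::rbindlist(cat_iv)

  rd_iv <- data.table::copy(category)
  rd_iv$start <- as.integer(rd_iv$start)
  rd_iv$end <- as.integer(rd_iv$end)
  rd_iv$expected_rd <- ifelse(rd_iv$category %in% c("M2", "M3"),
    dm2$total_copies[match(paste(rd_iv$chrom, rd_iv$start),
                           paste(dm2$chrom, as.integer(dm2$qstart)))],
    ifelse(rd_iv$category == "unaligned", 0, 1))
  rd_iv$category <- NULL

  cls_iv <- data.table::copy(rd_iv)
  cls_iv$class <- ifelse(cls_iv$expected_rd >= 2, "HC",
                         ifelse(cls_iv$expected_rd == 0, "LC", "BG"))
  cls_iv$expected_rd <- NULL

  multimap <- dm2[!dm2$collapsed,
                  c("chrom", "qstart", "qend")]
  data.table::setnames(multimap, c("chrom", "start", "end"))

  dss <- Biostrings::DNAStringSet(new_seqs)
  structure(list(
    seqs = dss,
    labels = list(category = category, expected_rd = rd_iv,
                  coverage_class = cls_iv, multimap = multimap),
    segment_map = segmap,
    dup_map = dm2,
    truth_dup_map = dm,
    spec = spec
  ), class = "collapsed_assembly")
}

#' Truth labels for sequencing the truth genome itself
#'
#' Convenience wrapper: a truth genome sequenced directly has expected read
#' depth 1 everywhere, every base correctly assembled, and multi-mapping
#' reads over all duplicated tracts (every copy is present).
#'
#' @param truth A `truth_genome`.
#' @return A `collapsed_assembly` with no collapse or gap events applied.
#' @export
as_sequencing_target <- function(truth) {
  derive_collapsed_assembly(truth, collapse = NULL, gaps = NULL)
}

#' Simulate read placements
#'
#' Draws read starts bin-by-bin from a Poisson process whose rate is
#' `expected_rd * coverage * bin_size / read_length`, optionally modulated by
#' a logistic function of bin GC content (`gc_bias`), and flags reads
#' originating inside duplicated tracts retained in >= 2 copies as
#' multi-mapping with probability `multimap_fraction`. No reads start inside
#' N gaps. Deterministic per seed.
#'
#' @param assembly A `collapsed_assembly` (see
#'   [derive_collapsed_assembly()]; use [as_sequencing_target()] for the
#'   truth genome).
#' @param coverage,read_length,gc_bias,multimap_fraction Override the spec.
#' @param seed Integer seed.
#' @param bin_size Bin width of the sampling grid (bp).
#' @return data.table of placements: `read_id`, `chrom`, `start`, `length`,
#'   `multimap`.
#' @export
simulate_reads <- function(assembly,
                           coverage = assembly$spec$coverage,
                           read_length = assembly$spec$read_length,
                           gc_bias = assembly$spec$gc_bias,
                           multimap_fraction = assembly$spec$multimap_fraction,
                           seed = assembly$spec$seed,
                           bin_size = 100L) {
  stopifnot(inherits(assembly, "collapsed_assembly"))
  if (coverage <= 0) stop("coverage must be > 0")
  lens <- Biostrings::width(assembly$seqs)
  names(lens) <- names(assembly$seqs)
  if (any(read_length > lens))
    stop("read_length exceeds the length of chromosome ",
         names(lens)[which(read_length > lens)[1]])
  set.seed(seed)

  rd_iv <- assembly$labels$expected_rd
  gaps <- rd_iv[rd_iv$expected_rd == 0, ]
  mm_iv <- assembly$labels$multimap

  gc_ref <- NULL
  if (gc_bias != 0) {
    af <- Biostrings::alphabetFrequency(assembly$seqs, collapse = TRUE)
    gc_ref <- sum(af[c("C", "G")]) / sum(af[BASES])
  }

  out <- list()
  for (ch in names(lens)) {
    len <- lens[[ch]]
    starts <- seq(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    bins <- data.table::data.table(chrom = ch, start = starts, end = ends)
    # expected rd per bin: length-weighted mean over label intervals
    rdc <- rd_iv[rd_iv$chrom == ch, ]
    lam_rd <- numeric(nrow(bins))
    for (i in seq_len(nrow(rdc))) {
      ov_lo <- pmax(bins$start, rdc$start[i]); ov_hi <- pmin(bins$end, rdc$end[i])
      w <- pmax(0, ov_hi - ov_lo)
      lam_rd <- lam_rd + w * rdc$expected_rd[i]
    }
    lam_rd <- lam_rd / (bins$end - bins$start)
    lambda <- lam_rd * coverage * (bins$end - bins$start) / read_length
    if (gc_bias != 0) {
      gcb <- bin_gc(assembly$seqs[[ch]], bins$start, bins$end)
      mult <- 2 * stats::plogis(-gc_bias * (gcb - gc_ref))
      mult[is.na(mult)] <- 1
      lambda <- lambda * mult
    }
    n <- stats::rpois(length(lambda), lambda)
    tot <- sum(n)
    if (!tot) next
    bin_idx <- rep.int(seq_along(n), n)
    widths <- (bins$end - bins$start)[bin_idx]
    rstart <- bins$start[bin_idx] + floor(stats::runif(tot) * widths)
    rstart <- pmin(rstart, len - read_length)
    dt <- data.table::data.table(chrom = ch, start = as.integer(rstart),
                                 length = as.integer(read_length))
    # no read starts inside N gaps
    gch <- gaps[gaps$chrom == ch, ]
    if (nrow(gch)) {
      ingap <- rep(FALSE, nrow(dt))
      for (i in seq_len(nrow(gch)))
        ingap <- ingap | (dt$start >= gch$start[i] & dt$start < gch$end[i])
      dt <- dt[!ingap, ]
    }
    # multimap flag for reads born in retained duplicated tracts
    mm <- rep(0L, nrow(dt))
    mch <- mm_iv[mm_iv$chrom == ch, ]
    if (nrow(mch)) {
      inmm <- rep(FALSE, nrow(dt))
      for (i in seq_len(nrow(mch)))
        inmm <- inmm | (dt$start >= mch$start[i] & dt$start < mch$end[i])
      mm[inmm] <- as.integer(stats::runif(sum(inmm)) < multimap_fraction)
    }
    dt$multimap <- mm
    out[[ch]] <- dt
  }
  placements <- data.table::rbindlist(out)
  if (!nrow(placements))
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), length = integer(),
                                  multimap = integer()))
  placements$read_id <- sprintf("r%08d", seq_len(nrow(placements)))
  data.table::setcolorder(placements,
                          c("read_id", "chrom", "start", "length", "multimap"))
  placements[]
}

#' Spec for an idealized integer read-depth genome
#'
#' Convenience constructor for resampling-fidelity studies: a
#' single-chromosome derived assembly of `n_blocks * 2 * spacing` bp whose
#' expected read depth is an idealized integer profile -- contiguous 5 kb
#' blocks at RD 2 (collapsed 2-copy tandem clusters) and RD 0 (N gaps),
#' about 10% of the assembly each by default, on an RD 1 background.
#'
#' @param n_blocks Number of RD-2 blocks (and of RD-0 blocks).
#' @param block_len Block length in bp.
#' @param spacing Distance between consecutive planted blocks (bp); must
#'   exceed `2 * block_len`.
#' @param coverage,read_length,seed Passed to [genome_spec()].
#' @return A `genome_spec` whose derived assembly is
#'   `n_blocks * 2 * spacing` bp long.
#' @export
idealized_rd_spec <- function(n_blocks = 40L, block_len = 5000L,
                              spacing = 25000L, coverage = 46,
                              read_length = 100L, seed = 1L) {
  if (spacing <= 2L * block_len) stop("spacing must exceed 2 * block_len")
  truth_len <- n_blocks * 2L * spacing + n_blocks * block_len
  tand <- data.table::data.table(
    chrom = "chr1",
    start = block_len + (seq_len(n_blocks) - 1L) * 2L * spacing,
    unit_len = block_len, copies = 2L)
  gaps <- data.table::data.table(
    chrom = "chr1",
    start = block_len + (seq_len(n_blocks) - 1L) * 2L * spacing + spacing,
    len = block_len)
  genome_spec(chrom_lengths = c(chr1 = truth_len),
              tandem_clusters = tand, gaps = gaps,
              collapse = data.table::data.table(type = "tandem",
                                                id = seq_len(n_blocks)),
              coverage = coverage, read_length = read_length, seed = seed)
}

#' Expected read depth per bin from truth labels
#'
#' Length-weighted mean of the planted expected-RD intervals over each bin:
#' the ground-truth profile that a read-depth recomputation is scored
#' against.
#'
#' @param assembly A `collapsed_assembly`.
#' @param bins Bin table (`chrom`, `start`, `end`).
#' @return Numeric vector of expected rd values, one per bin.
#' @export
expected_rd_per_bin <- function(assembly, bins) {
  rd_iv <- assembly$labels$expected_rd
  out <- numeric(nrow(bins))
  for (i in seq_len(nrow(rd_iv))) {
    same <- bins$chrom == rd_iv$chrom[i]
    w <- pmax(0, pmin(bins$end, rd_iv$end[i]) - pmax(bins$start, rd_iv$start[i]))
    out <- out + ifelse(same, w, 0) * rd_iv$expected_rd[i]
  }
  out / (bins$end - bins$start)
}

# GC fraction of non-N bases per window of one DNAString
bin_gc <- function(seq, starts, ends) {
  v <- Biostrings::Views(seq, start = starts + 1L, end = ends)
  af <- Biostrings::alphabetFrequency(v)
  acgt <- rowSums(af[, BASES, drop = FALSE])
  gc <- rowSums(af[, c("C", "G"), drop = FALSE])
  ifelse(acgt > 0, gc / acgt, NA_real_)
}

#' Emit alignment blocks between a collapsed assembly and its truth genome
#'
#' Produces the block table a whole-genome aligner would report with the
#' derived (collapsed) assembly as query and the truth genome as subject:
#' unique kept segments yield self-blocks at 100% identity (split around
#' retained duplicate copies and N gaps), and every retained duplicate copy
#' yields one block per truth copy of its cluster, with identity measured by
#' direct base comparison. An untouched, feature-free chromosome therefore
#' yields a single full-length self-block. The table round-trips through
#' [write_coords()] / [parse_coords()].
#'
#' @param truth A `truth_genome`.
#' @param collapsed The matching `collapsed_assembly`.
#' @return data.table of blocks: `qchrom`, `qstart`, `qend`, `schrom`,
#'   `sstart`, `send`, `identity`, `orientation` (internal 0-based half-open
#'   coordinates).
#' @export
emit_alignment_coords <- function(truth, collapsed) {
  stopifnot(inherits(truth, "truth_genome"),
            inherits(collapsed, "collapsed_assembly"))
  dm2 <- collapsed$dup_map
  gaps_q <- collapsed$labels$expected_rd
  gaps_q <- gaps_q[gaps_q$expected_rd == 0, c("chrom", "start", "end")]

  blocks <- list()
  # self blocks: kept segments minus dup footprints minus gaps
  segs <- collapsed$segment_map
  dupq <- data.table::data.table(chrom = dm2$chrom, start = dm2$qstart,
                                 end = dm2$qend)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    piece <- data.table::data.table(chrom = s$qchrom, start = s$qstart,
                                    end = s$qend)
    uniq <- iv_setdiff(iv_setdiff(piece, dupq), gaps_q)
    if (!nrow(uniq)) next
    off <- s$tstart - s$qstart
    blocks[[length(blocks) + 1L]] <- data.table::data.table(
      qchrom = s$qchrom, qstart = uniq$start, qend = uniq$end,
      schrom = s$tchrom, sstart = uniq$start + off, send = uniq$end + off,
      identity = 100, orientation = "+")
  }
  # duplicate blocks: retained query copy x every truth copy
  tdm <- collapsed$truth_dup_map
  qseq <- as.character(collapsed$seqs)
  tseq <- as.character(truth$seqs)
  for (i in seq_len(nrow(dm2))) {
    d <- dm2[i, ]
    copies <- tdm[tdm$dup_id == d$dup_id, ]
    qs <- substring(qseq[[d$chrom]], d$qstart + 1, d$qend)
    for (j in seq_len(nrow(copies))) {
      cp <- copies[j, ]
      ss <- substring(tseq[[cp$chrom]], cp$start + 1, cp$end)
      idy <- 100 * mean(strsplit(qs, "")[[1]] == strsplit(ss, "")[[1]])
      blocks[[length(blocks) + 1L]] <- data.table::data.table(
        qchrom = d$chrom, qstart = d$qstart, qend = d$qend,
        schrom = cp$chrom, sstart = cp$start, send = cp$end,
        identity = round(idy, 2), orientation = "+")
    }
  }
  out <- data.table::rbindlist(blocks)
  data.table::setorder(out, qchrom, qstart, schrom, sstart)
  out[]
}
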