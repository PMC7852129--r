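# Per-region genomic features: feature-track densities, GC, k-mer and SSR
# composition, flanking-window variants, tandem-duplicate gene
# classification, functional-term presence and Kruskal-Wallis screening.

#' Density of a feature track inside regions
#'
#' Density is the proportion of each region occupied by the (unioned)
#' track: overlapping track intervals never push density above 1.
#'
#' @param track Interval table of the feature.
#' @param regions Interval table of regions.
#' @return Numeric vector of densities in `[0, 1]`, one per region row.
#' @export
track_density <- function(track, regions) {
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("zero-length region")
  iv_cover_len(regions, track) / len
}

#' Flanking windows of regions
#'
#' For each window size s, the upstream window is `[start - s, start)` and
#' the downstream window `[end, end + s)`, clipped at chromosome bounds;
#' zero-width windows after clipping are dropped. Features are computed over
#' the union of the two windows of a size, with `"all"` denoting the union
#' over every size.
#'
#' @param regions Interval table (rows are identified by position).
#' @param sizes Window sizes in bp (defaults: 0.5 to 32 kb doubling).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return data.table: `region`, `size`, `side`, `chrom`, `start`, `end`.
#' @export
flanking_windows <- function(regions,
                             sizes = c(500, 1000, 2000, 4000, 8000, 16000, 32000),
                             chrom_lengths) {
  out <- list()
  for (s in sizes) {
    up <- data.table::data.table(
      region = seq_len(nrow(regions)), size = s, side = "up",
      chrom = regions$chrom,
      start = pmax(regions$start - s, 0L),
      end = regions$start)
    dn <- data.table::data.table(
      region = seq_len(nrow(regions)), size = s, side = "down",
      chrom = regions$chrom,
      start = regions$end,
      end = pmin(regions$end + s, unname(chrom_lengths[regions$chrom])))
    out[[length(out) + 1L]] <- rbind(up, dn)
  }
  w <- data.table::rbindlist(out)
  w[w$end > w$start, ]
}

#' k-mer densities of a sequence
#'
#' Counts overlapping occurrences on the given strand with no
#' reverse-complement collapsing; sliding windows containing any non-ACGT
#' base are excluded from both numerator and denominator, so density =
#' occurrences / valid windows.
#'
#' @param sequence A [Biostrings::DNAString] or character scalar.
#' @param k Word size (1 to 6).
#' @return Named numeric vector over all 4^k motifs.
#' @export
kmer_density <- function(sequence, k) {
  if (k < 1 || k > 6) stop("k must be in 1..6")
  s <- if (is.character(sequence)) Biostrings::DNAString(sequence) else sequence
  L <- length(s)
  counts <- Biostrings::oligonucleotideFrequency(s, width = k)
  if (k > L) {
    warning("k exceeds sequence length; densities are 0")
    return(counts * 0)
  }
  # valid windows: sum over maximal ACGT runs of (run length - k + 1)
  chars <- strsplit(as.character(s), "")[[1]]
  r <- rle(chars %in% BASES)
  valid <- sum(pmax(0L, r$lengths[r$values] - k + 1L))
  if (valid == 0) {
    warning("no valid (N-free) windows; densities are 0")
    return(counts * 0)
  }
  counts / valid
}

#' Find simple sequence repeats (SSRs)
#'
#' Exact adjacent repeats of a 2-64 bp unit repeated more than once:
#' maximal stretches where the sequence equals itself shifted by the unit
#' length. The smallest-period motif is reported, and calls with larger
#' periods that are multiples of a reported period covering the same
#' stretch are suppressed. Tracts containing non-ACGT bases are not called.
#'
#' @param sequence Character scalar or [Biostrings::DNAString].
#' @param min_unit,max_unit Repeat unit length range (bp).
#' @param min_repeats Minimum number of adjacent copies (> 1).
#' @return data.table: `start`, `end` (0-based half-open), `unit`, `period`,
#'   `copies` (possibly fractional; the tract includes a trailing partial
#'   copy when present).
#' @export
find_ssrs <- function(sequence, min_unit = 2L, max_unit = 64L, min_repeats = 2L) {
  s <- as.character(sequence)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  good <- chars %in% BASES
  calls <- list()
  for (p in min_unit:min(max_unit, floor(L / min_repeats))) {
    eq <- chars[seq_len(L - p)] == chars[(p + 1L):L] &
      good[seq_len(L - p)] & good[(p + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= (min_repeats - 1L) * p)
    for (h in hit) {
      i <- starts[h]; run <- r$lengths[h]
      calls[[length(calls) + 1L]] <- data.table::data.table(
        start = i - 1L, end = i - 1L + run + p,
        unit = substr(s, i, i + p - 1L), period = p,
        copies = (run + p) / p)
    }
  }
  if (!length(calls))
    return(data.table::data.table(start = integer(), end = integer(),
                                  unit = character(), period = integer(),
                                  copies = numeric()))
  calls <- data.table::rbindlist(calls)
  data.table::setorder(calls, start, period)
  # suppress calls whose period is a multiple of a smaller reported period
  # and whose span lies within that call's span
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!keep[i]) next
    sup <- which(keep & calls$period > calls$period[i] &
                   calls$period %% calls$period[i] == 0 &
                   calls$start >= calls$start[i] & calls$end <= calls$end[i])
    keep[setdiff(sup, i)] <- FALSE
  }
  calls[keep, ][]
}

#' Classify genes as tandem or non-tandem duplicates
#'
#' Genes in a paralog pair on the same chromosome that are directly adjacent
#' or separated by at most `max_intervening` non-homologous genes are
#' tandem; transitive closure merges chains into clusters.
#'
#' @param paralog_pairs data.frame with columns `gene1`, `gene2` (symmetric
#'   relation).
#' @param gene_order data.frame with `chrom` and `id`, ordered by position
#'   within each chromosome (or with a `start` column to sort by).
#' @param max_intervening Maximum number of intervening non-homologous
#'   genes.
#' @return data.table: `id`, `tandem` (logical), `cluster` (integer id, NA
#'   for non-tandem genes).
#' @export
classify_tandem <- function(paralog_pairs, gene_order, max_intervening = 10L) {
  go <- data.table::as.data.table(gene_order)
  if ("start" %in% names(go)) data.table::setorder(go, chrom, start)
  go$idx <- stats::ave(seq_len(nrow(go)), go$chrom, FUN = seq_along)
  miss <- setdiff(unique(c(paralog_pairs$gene1, paralog_pairs$gene2)), go$id)
  if (length(miss))
    stop("gene absent from gene order: ", miss[1])
  fam <- split(c(paralog_pairs$gene2, paralog_pairs$gene1),
               c(paralog_pairs$gene1, paralog_pairs$gene2))
  n <- nrow(go)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pos <- stats::setNames(seq_len(n), go$id)
  for (k in seq_len(nrow(paralog_pairs))) {
    g1 <- paralog_pairs$gene1[k]; g2 <- paralog_pairs$gene2[k]
    i <- pos[[g1]]; j <- pos[[g2]]
    if (go$chrom[i] != go$chrom[j]) next
    lo <- min(go$idx[i], go$idx[j]); hi <- max(go$idx[i], go$idx[j])
    between <- go$id[go$chrom == go$chrom[i] & go$idx > lo & go$idx < hi]
    homologs <- unique(c(fam[[g1]], fam[[g2]], g1, g2))
    n_nonhom <- sum(!(between %in% homologs))
    if (n_nonhom <= max_intervening) {
      a <- find(i); b <- find(j)
      if (a != b) parent[b] <- a
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  tandem <- sizes[as.character(comp)] > 1
  cluster <- ifelse(tandem, match(comp, unique(comp[tandem])), NA_integer_)
  data.table::data.table(id = go$id, tandem = as.vector(tandem),
                         cluster = as.integer(cluster))
}

#' Presence of functional terms in regions
#'
#' A region carries a term iff any gene overlapping the region is annotated
#' with it.
#'
#' @param regions Interval table.
#' @param genes Gene intervals with an `id` column.
#' @param term_map data.frame with `gene` and `term` columns.
#' @return Integer 0/1 matrix, regions x terms.
#' @export
functional_presence <- function(regions, genes, term_map) {
  terms <- sort(unique(term_map$term))
  out <- matrix(0L, nrow(regions), length(terms),
                dimnames = list(NULL, terms))
  if (!nrow(genes) || !length(terms)) return(out)
  rg <- iv_to_gr(regions); gg <- iv_to_gr(genes)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rg, gg))
  if (!length(hits)) return(out)
  tm <- split(term_map$term, term_map$gene)
  for (h in seq_along(hits)) {
    gid <- genes$id[S4Vectors::subjectHits(hits)[h]]
    tt <- tm[[gid]]
    if (length(tt)) out[S4Vectors::queryHits(hits)[h], tt] <- 1L
  }
  out
}

#' Screen features by Kruskal-Wallis test across classes
#'
#' Keeps features whose values differ among classes at `p < alpha`
#' (Kruskal-Wallis rank test); constant features have no defined p-value and
#' are dropped with a warning.
#'
#' @param x Numeric matrix or data.frame (observations x features).
#' @param labels Class labels (>= 2 classes with >= 2 observations each).
#' @param alpha Significance cutoff.
#' @return list with `retained` (feature names), `p_values` (named vector).
#' @export
screen_features <- function(x, labels, alpha = 0.05) {
  x <- as.data.frame(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) < 2))
    stop("need >= 2 classes with >= 2 observations each")
  p <- vapply(x, function(col) {
    if (length(unique(col)) < 2) return(NA_real_)
    stats::kruskal.test(col, labels)$p.value
  }, numeric(1))
  if (anyNA(p))
    warning(sum(is.na(p)), " constant feature(s) dropped")
  list(retained = names(p)[!is.na(p) & p < alpha], p_values = p)
}

#' Intron counts per gene from GFF3 records
#'
#' @param gff data.table from [read_gff3()] with `type` and `parent`.
#' @return Named integer vector: exons per gene minus one (0 for single-exon
#'   genes).
#' @export
intron_counts <- function(gff) {
  ex <- gff[gff$type == "exon" & !is.na(gff$parent), ]
  if (!nrow(ex)) return(stats::setNames(integer(0), character(0)))
  tab <- table(ex$parent)
  stats::setNames(pmax(as.integer(tab) - 1L, 0L), names(tab))
}

#' Build the region feature matrix
#'
#' Assembles, per region: GC content; densities of all genes, tandem genes,
#' non-tandem genes, pseudogenes, TEs and all SSRs (the seven base
#' features); the same seven over each flanking-window size plus an "all"
#' aggregate; and optionally per-motif k-mer and SSR-motif densities of the
#' region sequence.
#'
#' @param regions Interval table.
#' @param seqs Assembly sequences.
#' @param tracks Named list of interval tables: `genes`, `tandem_genes`,
#'   `nontandem_genes`, `pseudogenes`, `tes`, `ssrs` (missing tracks yield
#'   zero densities).
#' @param flank_sizes Flanking window sizes in bp (NULL to skip).
#' @param kmer_k Integer vector of k-mer sizes to include (NULL to skip).
#' @param ssr_motifs Include per-SSR-motif densities (logical).
#' @return data.table of features, one row per region.
#' @export
feature_matrix <- function(regions, seqs, tracks = list(),
                           flank_sizes = c(500, 1000, 2000, 4000, 8000, 16000, 32000),
                           kmer_k = NULL, ssr_motifs = FALSE) {
  regions <- data.table::as.data.table(regions)
  chrom_lengths <- Biostrings::width(seqs)
  names(chrom_lengths) <- names(seqs)
  base_tracks <- c("genes", "tandem_genes", "nontandem_genes", "pseudogenes",
                   "tes", "ssrs")
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer())
  for (nm in base_tracks) tracks[[nm]] <- tracks[[nm]] %||% empty

  region_seq <- function(iv) {
    vapply(seq_len(nrow(iv)), function(i)
      as.character(Biostrings::subseq(seqs[[iv$chrom[i]]],
                                      iv$start[i] + 1L, iv$end[i])),
      character(1))
  }
  gc_of <- function(iv) {
    out <- numeric(nrow(iv))
    for (ch in unique(iv$chrom)) {
      idx <- which(iv$chrom == ch)
      out[idx] <- bin_gc(seqs[[ch]], iv$start[idx], iv$end[idx])
    }
    out
  }
  base_feats <- function(iv) {
    dt <- data.table::data.table(gc = gc_of(iv))
    for (nm in base_tracks)
      dt[[paste0("density_", nm)]] <- track_density(tracks[[nm]], iv)
    dt
  }

  out <- base_feats(regions)
  if (!is.null(flank_sizes)) {
    wins <- flanking_windows(regions, flank_sizes, chrom_lengths)
    flank_block <- function(w, tag) {
      # per-region union of windows: densities are length-weighted over the
      # union; GC over the combined windows
      dt <- data.table::data.table(row = seq_len(nrow(regions)))
      cov <- function(track) {
        num <- den <- numeric(nrow(regions))
        if (nrow(w)) {
          wl <- w$end - w$start
          cl <- iv_cover_len(w, track)
          num <- as.numeric(tapply(cl, factor(w$region, levels = seq_len(nrow(regions))), sum))
          den <- as.numeric(tapply(wl, factor(w$region, levels = seq_len(nrow(regions))), sum))
          num[is.na(num)] <- 0; den[is.na(den)] <- 0
        }
        ifelse(den > 0, num / den, 0)
      }
      res <- data.table::data.table(row = seq_len(nrow(regions)))
      gcnum <- gcden <- numeric(nrow(regions))
      if (nrow(w)) {
        wgc <- gc_of(w)
        wl <- w$end - w$start
        fac <- factor(w$region, levels = seq_len(nrow(regions)))
        gcnum <- as.numeric(tapply(ifelse(is.na(wgc), 0, wgc) * wl, fac, sum))
        gcden <- as.numeric(tapply(ifelse(is.na(wgc), 0, wl), fac, sum))
        gcnum[is.na(gcnum)] <- 0; gcden[is.na(gcden)] <- 0
      }
      res[[paste0("flank_", tag, "_gc")]] <- ifelse(gcden > 0, gcnum / gcden, NA_real_)
      for (nm in base_tracks)
        res[[paste0("flank_", tag, "_density_", nm)]] <- cov(tracks[[nm]])
      res$row <- NULL
      res
    }
    for (s in flank_sizes)
      out <- cbind(out, flank_block(wins[wins$size == s, ], format(s)))
    out <- cbind(out, flank_block(wins, "all"))
  }
  if (!is.null(kmer_k) || ssr_motifs) {
    rseq <- region_seq(regions)
    if (!is.null(kmer_k)) {
      for (k in kmer_k) {
        km <- t(vapply(rseq, function(x)
          suppressWarnings(kmer_density(x, k)), numeric(4^k)))
        colnames(km) <- paste0("kmer_", colnames(km))
        out <- cbind(out, data.table::as.data.table(km))
      }
    }
    if (ssr_motifs) {
      calls <- lapply(rseq, find_ssrs)
      motifs <- sort(unique(unlist(lapply(calls, function(d) d$unit))))
      if (length(motifs)) {
        sm <- matrix(0, nrow(regions), length(motifs),
                     dimnames = list(NULL, paste0("ssr_", motifs)))
        for (i in seq_along(calls)) {
          d <- calls[[i]]
          if (nrow(d)) {
            lens <- tapply(d$end - d$start, d$unit, sum)
            sm[i, paste0("ssr_", names(lens))] <-
              lens / (regions$end[i] - regions$start[i])
          }
        }
        out <- cbind(out, data.table::as.data.table(sm))
      }
    }
  }
  out
}
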