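# Per-bin read depth: counting with the >=50%-overlap rule, GC-stratum
# correction, median normalization, bin-size choice and coverage subsampling.

#' Tile chromosomes into fixed-width bins
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width (bp); the terminal bin of each chromosome may be
#'   shorter.
#' @return data.table with `chrom`, `start`, `end`.
#' @export
make_bins <- function(chrom_lengths, bin_size = 100L) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    s <- seq(0L, len - 1L, by = bin_size)
    data.table::data.table(chrom = ch, start = as.integer(s),
                           end = as.integer(pmin(s + bin_size, len)))
  }))
}

#' Count reads per bin
#'
#' A read is counted in a bin iff its overlap with the bin is at least 50% of
#' the read length; each read counts in at most one bin, and an exact 50/50
#' split across two bins is assigned to the earlier bin. Reads spanning more
#' than two bins with no bin reaching 50% are not counted.
#'
#' @param placements Placement table (`read_id`, `chrom`, `start`, `length`,
#'   `multimap`).
#' @param bin_size Bin width (bp).
#' @param chrom_lengths Named vector of chromosome lengths; inferred from
#'   `seqs` when given.
#' @param seqs Optional [Biostrings::DNAStringSet] of the assembly; when
#'   supplied, per-bin GC fraction (of non-N bases) and N fraction are
#'   computed.
#' @return Bin table with `raw_count`, `multimap_count`, and (with `seqs`)
#'   `gc`, `n_frac`.
#' @export
count_reads_per_bin <- function(placements, bin_size = 100L,
                                chrom_lengths = NULL, seqs = NULL) {
  if (!is.null(seqs)) {
    chrom_lengths <- Biostrings::width(seqs)
    names(chrom_lengths) <- names(seqs)
  }
  if (is.null(chrom_lengths))
    stop("supply chrom_lengths or seqs")
  bins <- make_bins(chrom_lengths, bin_size)

  pl <- data.table::as.data.table(placements)
  bad <- !(pl$chrom %in% names(chrom_lengths)) | pl$start < 0 |
    pl$start + pl$length > chrom_lengths[pl$chrom]
  if (any(bad, na.rm = TRUE) || anyNA(bad))
    stop("placement outside chromosome bounds: read ",
         pl$read_id[which(bad | is.na(bad))[1]])

  counts <- integer(nrow(bins)); mm_counts <- integer(nrow(bins))
  offset <- 0L
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    nb <- ceiling(len / bin_size)
    p <- pl[pl$chrom == ch, ]
    if (nrow(p)) {
      # a bin holding >= 50% of the read must contain position m-1 or m,
      # where m = start + floor(length / 2); check the earlier bin first so
      # exact ties go to it
      m <- p$start + p$length %/% 2L
      assigned <- assign_bin(p$start, p$length, m, bin_size, len)
      ok <- !is.na(assigned)
      if (any(ok)) {
        tb <- tabulate(assigned[ok], nbins = nb)
        counts[(offset + 1L):(offset + nb)] <- tb
        mmok <- ok & p$multimap == 1L
        if (any(mmok)) {
          tbm <- tabulate(assigned[mmok], nbins = nb)
          mm_counts[(offset + 1L):(offset + nb)] <- tbm
        }
      }
    }
    offset <- offset + nb
  }
  bins$raw_count <- counts
  bins$multimap_count <- mm_counts
  if (!is.null(seqs)) {
    gc <- numeric(nrow(bins)); nf <- numeric(nrow(bins))
    off <- 0L
    for (ch in names(chrom_lengths)) {
      idx <- which(bins$chrom == ch)
      v <- Biostrings::Views(seqs[[ch]], start = bins$start[idx] + 1L,
                             end = bins$end[idx])
      af <- Biostrings::alphabetFrequency(v)
      acgt <- rowSums(af[, BASES, drop = FALSE])
      gc[idx] <- ifelse(acgt > 0,
                        rowSums(af[, c("C", "G"), drop = FALSE]) / acgt,
                        NA_real_)
      nf[idx] <- af[, "N"] / (bins$end[idx] - bins$start[idx])
    }
    bins$gc <- gc
    bins$n_frac <- nf
  }
  bins[]
}

# 1-based bin index for each read, NA when no bin reaches 50% of read length
assign_bin <- function(start, length, m, bin_size, chrom_len) {
  j1 <- pmax((m - 1L) %/% bin_size, 0L)
  j2 <- m %/% bin_size
  ov <- function(j) {
    lo <- pmax(start, j * bin_size)
    hi <- pmin(start + length, pmin((j + 1L) * bin_size, chrom_len))
    pmax(0L, hi - lo)
  }
  out <- rep(NA_integer_, length(start))
  in1 <- 2L * ov(j1) >= length
  out[in1] <- j1[in1] + 1L
  rest <- !in1 & 2L * ov(j2) >= length
  out[rest] <- j2[rest] + 1L
  out
}

#' Correct bin counts for GC bias
#'
#' Stratifies bins into 1-percentage-point GC classes and rescales each
#' stratum's counts by (global mean count) / (stratum mean count). Strata
#' with fewer than `min_stratum` bins keep their raw counts (factor 1). Bins
#' with more than 50% N content are excluded from the stratum and global
#' means but still receive corrected values. A final rescale makes the
#' global mean of corrected counts match the raw global mean exactly.
#'
#' @param bins Bin table with `raw_count` and `gc` (see
#'   [count_reads_per_bin()]).
#' @param min_stratum Minimum bins per GC stratum for correction.
#' @return Bin table with a `corrected_count` column.
#' @export
gc_correct <- function(bins, min_stratum = 30L) {
  if (!"gc" %in% names(bins)) stop("bins lack a gc column; pass seqs to count_reads_per_bin")
  bins <- data.table::as.data.table(bins)
  eligible <- !is.na(bins$gc)
  if (!is.null(bins$n_frac)) eligible <- eligible & bins$n_frac <= 0.5
  if (!any(eligible)) stop("no bins with defined GC (all bins are N)")
  gmean <- mean(bins$raw_count[eligible])
  stratum <- floor(bins$gc * 100)
  stratum[is.na(stratum)] <- -1L
  factors <- rep(1, nrow(bins))
  for (sv in unique(stratum[eligible])) {
    idx <- eligible & stratum == sv
    if (sum(idx) >= min_stratum) {
      smean <- mean(bins$raw_count[idx])
      if (smean > 0) factors[stratum == sv] <- gmean / smean
    }
  }
  corrected <- bins$raw_count * factors
  cmean <- mean(corrected[eligible])
  if (cmean > 0) corrected <- corrected * gmean / cmean
  bins$corrected_count <- corrected
  bins[]
}

#' Normalize corrected counts to read depth
#'
#' Divides corrected counts by the genome-wide median corrected count of
#' non-N-majority bins, so background read depth sits at 1. Bins that are
#' mostly N still receive rd values (typically 0).
#'
#' @param bins Bin table with `corrected_count` (or `raw_count` as fallback
#'   when GC correction is skipped).
#' @return Bin table with an `rd` column.
#' @export
normalize_rd <- function(bins) {
  bins <- data.table::as.data.table(bins)
  cc <- bins$corrected_count %||% bins$raw_count
  if (is.null(cc)) stop("bins lack counts")
  eligible <- if (!is.null(bins$n_frac)) bins$n_frac <= 0.5 else rep(TRUE, nrow(bins))
  med <- stats::median(cc[eligible])
  if (!is.finite(med) || med == 0)
    stop("median corrected count is 0; coverage too low to normalize")
  bins$rd <- cc / med
  bins[]
}

#' Compute normalized read depth from placements
#'
#' Convenience wrapper chaining [count_reads_per_bin()], [gc_correct()] and
#' [normalize_rd()].
#'
#' @inheritParams count_reads_per_bin
#' @param gc_correction Apply the GC-stratum correction (requires `seqs`).
#' @return Bin table with `raw_count`, `multimap_count`, `corrected_count`,
#'   `rd` (and `gc`, `n_frac` when `seqs` is given).
#' @export
compute_rd <- function(placements, bin_size = 100L, chrom_lengths = NULL,
                       seqs = NULL, gc_correction = !is.null(seqs)) {
  bins <- count_reads_per_bin(placements, bin_size, chrom_lengths, seqs)
  if (gc_correction) bins <- gc_correct(bins)
  normalize_rd(bins)
}

#' Choose a bin size from the mean/SD ratio of per-bin counts
#'
#' Evaluates each candidate bin size and returns the smallest one whose
#' ratio of mean to standard deviation of per-bin read counts falls in
#' `[4, 5]`; if none does, the candidate with ratio closest to 4.5 is
#' chosen. For Poisson counts the ratio is sqrt(mean), so the rule targets
#' roughly 16-25 reads per bin.
#'
#' @param placements Placement table.
#' @param candidate_sizes Integer vector of bin sizes to evaluate (>= 2
#'   candidates expected; a single candidate is returned with a warning).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return list with `bin_size` (the selection) and `ratio_table`
#'   (data.table: `bin_size`, `mean`, `sd`, `ratio`).
#' @export
choose_bin_size <- function(placements, candidate_sizes, chrom_lengths) {
  if (!nrow(placements)) stop("empty placements")
  candidate_sizes <- sort(unique(as.integer(candidate_sizes)))
  if (length(candidate_sizes) < 2)
    warning("only one candidate bin size; returning it")
  tab <- data.table::rbindlist(lapply(candidate_sizes, function(bs) {
    b <- count_reads_per_bin(placements, bs, chrom_lengths)
    data.table::data.table(bin_size = bs, mean = mean(b$raw_count),
                           sd = stats::sd(b$raw_count))
  }))
  tab$ratio <- tab$mean / tab$sd
  inband <- which(tab$ratio >= 4 & tab$ratio <= 5)
  sel <- if (length(inband)) tab$bin_size[inband[1]] else
    tab$bin_size[which.min(abs(tab$ratio - 4.5))]
  list(bin_size = sel, ratio_table = tab[])
}

#' Subsample read placements to a target coverage
#'
#' Uniform sampling of reads without replacement.
#'
#' @param placements Placement table.
#' @param target_fold Desired coverage fold.
#' @param genome_length Total assembly length (bp), used to compute the
#'   source coverage as sum(read lengths) / `genome_length`.
#' @param seed Integer seed.
#' @return Subset of `placements`.
#' @export
subsample_placements <- function(placements, target_fold, genome_length, seed = 1) {
  source_fold <- sum(as.numeric(placements$length)) / genome_length
  if (target_fold > source_fold * (1 + 1e-9))
    stop(sprintf("target fold %.2f exceeds source fold %.2f", target_fold,
                 source_fold))
  n_keep <- min(nrow(placements), round(nrow(placements) * target_fold / source_fold))
  set.seed(seed)
  idx <- sort(sample.int(nrow(placements), n_keep))
  placements[idx, ]
}

#' Correlate two read-depth tracks
#'
#' Pearson and Spearman correlation of `rd` over bins present in both
#' inputs (joined on `chrom` and `start`).
#'
#' @param bins_a,bins_b Bin tables with `rd`.
#' @return list with `pearson` and `spearman`.
#' @export
rd_correlation <- function(bins_a, bins_b) {
  a <- data.table::as.data.table(bins_a)[, c("chrom", "start", "rd")]
  b <- data.table::as.data.table(bins_b)[, c("chrom", "start", "rd")]
  data.table::setnames(b, "rd", "rd_b")
  m <- merge(a, b, by = c("chrom", "start"))
  if (nrow(m) < 3) stop("fewer than 3 shared bins")
  list(pearson = stats::cor(m$rd, m$rd_b, method = "pearson"),
       spearman = stats::cor(m$rd, m$rd_b, method = "spearman"))
}
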