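# Region calling: segment per-bin read depth into candidate high/low/
# background regions, attach q-values and the multi-mapping fraction q0,
# filter, and classify with the dual RD-threshold scheme. The default
# thresholds (RD < 0.72 for low coverage, RD > 1.76 for high coverage,
# q < 0.08, q0 < 0.5) are the scheme's reference operating point.

#' Segment bins into candidate regions
#'
#' Bins are flagged high or low when their rd deviates from the non-N median
#' by more than `z` robust standard deviations (median absolute deviation).
#' Maximal runs of concordant bins are merged into candidate regions,
#' allowing up to `max_gap` discordant bins between concordant neighbours;
#' the remaining genome forms candidate background regions. Each candidate
#' gets a p-value from a two-sided one-sample t-test of its bins' rd against
#' the global non-N mean, BH-adjusted to q-values over all candidates, and
#' q0 = multi-mapping reads / total reads in the region.
#'
#' @param bins Bin table with `rd` (and optionally `multimap_count`,
#'   `raw_count`, `n_frac`).
#' @param z Robust z-score cutoff flagging a bin as high/low.
#' @param max_gap Maximum run of discordant bins bridged inside a candidate.
#' @return data.table of candidate regions: `chrom`, `start`, `end`,
#'   `candidate` (high/low/bg), `n_bins`, `mean_rd`, `p_value`, `q_value`,
#'   `q0`.
#' @export
segment_bins <- function(bins, z = 2, max_gap = 1L) {
  bins <- data.table::as.data.table(bins)
  if (!nrow(bins)) stop("no bins")
  if (!"rd" %in% names(bins)) stop("bins lack rd; run normalize_rd first")
  eligible <- if (!is.null(bins$n_frac)) bins$n_frac <= 0.5 else rep(TRUE, nrow(bins))
  mu <- mean(bins$rd[eligible])
  ctr <- stats::median(bins$rd[eligible])
  s <- stats::mad(bins$rd[eligible], center = ctr)
  if (s == 0) s <- 1e-12
  state <- rep("bg", nrow(bins))
  state[bins$rd > ctr + z * s] <- "high"
  state[bins$rd < ctr - z * s] <- "low"

  regions <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    st <- state[idx]
    cand <- data.table::data.table(lo = integer(), hi = integer(),
                                   candidate = character())
    for (dir in c("high", "low")) {
      pos <- which(st == dir)
      if (!length(pos)) next
      opp <- if (dir == "high") "low" else "high"
      # bridge runs over at most max_gap discordant bins, but never over a
      # bin of the opposite extreme state
      bridge <- function(k) {
        gap <- pos[k + 1L] - pos[k]
        gap <= max_gap + 1L &&
          (gap == 1L || !any(st[(pos[k] + 1L):(pos[k + 1L] - 1L)] == opp))
      }
      splits <- if (length(pos) > 1)
        which(!vapply(seq_len(length(pos) - 1L), bridge, logical(1))) else integer(0)
      brk <- c(0L, splits, length(pos))
      for (k in seq_len(length(brk) - 1L)) {
        lo <- pos[brk[k] + 1L]; hi <- pos[brk[k + 1L]]
        cand <- rbind(cand, data.table::data.table(lo = lo, hi = hi,
                                                   candidate = dir))
      }
    }
    data.table::setorder(cand, lo)
    covered <- rep(FALSE, length(idx))
    for (k in seq_len(nrow(cand))) covered[cand$lo[k]:cand$hi[k]] <- TRUE
    # complement -> background candidates
    if (any(!covered)) {
      r <- rle(!covered)
      endk <- cumsum(r$lengths); startk <- endk - r$lengths + 1L
      bg <- data.table::data.table(lo = startk[r$values], hi = endk[r$values],
                                   candidate = "bg")
      cand <- rbind(cand, bg)
      data.table::setorder(cand, lo)
    }
    if (nrow(cand))
      regions[[ch]] <- data.table::data.table(
        chrom = ch,
        start = bins$start[idx[cand$lo]],
        end = bins$end[idx[cand$hi]],
        candidate = cand$candidate,
        lo = idx[cand$lo], hi = idx[cand$hi])
  }
  regions <- data.table::rbindlist(regions)

  n <- nrow(regions)
  mean_rd <- numeric(n); pval <- numeric(n); q0 <- numeric(n)
  n_bins <- integer(n)
  has_counts <- all(c("raw_count", "multimap_count") %in% names(bins))
  for (i in seq_len(n)) {
    rr <- bins$rd[regions$lo[i]:regions$hi[i]]
    n_bins[i] <- length(rr)
    mean_rd[i] <- mean(rr)
    sdv <- stats::sd(rr)
    pval[i] <- if (length(rr) < 2 || is.na(sdv)) 1
      else if (sdv == 0) { if (rr[1] == mu) 1 else 0 }
      else stats::t.test(rr, mu = mu)$p.value
    q0[i] <- if (has_counts) {
      tot <- sum(bins$raw_count[regions$lo[i]:regions$hi[i]])
      if (tot > 0) sum(bins$multimap_count[regions$lo[i]:regions$hi[i]]) / tot else 0
    } else 0
  }
  regions$lo <- NULL; regions$hi <- NULL
  regions$n_bins <- n_bins
  regions$mean_rd <- mean_rd
  regions$p_value <- pval
  regions$q_value <- stats::p.adjust(pval, method = "BH")
  regions$q0 <- q0
  regions[]
}

#' Filter candidate regions on q-value and q0
#'
#' High/low candidates are kept iff `q_value < q_max` and `q0 < q0_max`;
#' background candidates pass unfiltered.
#'
#' @param regions Candidate regions from [segment_bins()].
#' @param q_max Maximum BH-adjusted p-value (exclusive).
#' @param q0_max Maximum multi-mapping read fraction (exclusive).
#' @return Filtered regions.
#' @export
filter_candidates <- function(regions, q_max = 0.08, q0_max = 0.5) {
  keep <- regions$candidate == "bg" |
    (regions$q_value < q_max & regions$q0 < q0_max)
  regions[keep, ]
}

#' Select RD thresholds minimizing between-class overlap
#'
#' Grid search at 0.01 resolution over cut values between each adjacent
#' class pair (low/background and background/high): for each pair the cut
#' minimizing (fraction of the lower class above the cut + fraction of the
#' upper class below it) is chosen, with ties broken toward the midpoint of
#' the tying interval.
#'
#' @param rd_samples Named list of numeric rd samples with elements `LC`,
#'   `BG`, `HC` (at least two classes with >= 10 samples each).
#' @return Named numeric vector `c(low = ..., high = ...)`; only the cuts
#'   for which both classes are present are returned.
#' @export
select_thresholds <- function(rd_samples) {
  have <- names(rd_samples)[vapply(rd_samples, length, 1L) >= 10]
  if (length(have) < 2) stop("need >= 2 classes with >= 10 rd samples each")
  cut_between <- function(lower, upper) {
    if (identical(sort(lower), sort(upper)))
      stop("degenerate (identical) rd distributions; no separating threshold")
    grid <- seq(floor(min(c(lower, upper)) * 100) / 100,
                ceiling(max(c(lower, upper)) * 100) / 100, by = 0.01)
    loss <- vapply(grid, function(cut)
      mean(lower > cut) + mean(upper < cut), numeric(1))
    best <- which(loss <= min(loss) + 1e-12)
    # ties: midpoint of the tying interval, snapped to the grid
    grid[best[ceiling(length(best) / 2)]]
  }
  out <- c(low = NA_real_, high = NA_real_)
  if (all(c("LC", "BG") %in% have))
    out["low"] <- cut_between(rd_samples$LC, rd_samples$BG)
  if (all(c("BG", "HC") %in% have))
    out["high"] <- cut_between(rd_samples$BG, rd_samples$HC)
  out[!is.na(out)]
}

#' Assign coverage classes by RD thresholds
#'
#' Strict inequalities: a high candidate is HC iff `mean_rd > high`, a low
#' candidate is LC iff `mean_rd < low`, and a background candidate stays BG
#' iff `low <= mean_rd <= high`. Candidates disagreeing with their
#' threshold become class "other".
#'
#' @param regions Candidate regions with `mean_rd` and `candidate`.
#' @param low,high RD thresholds (`low < high`).
#' @return Regions with a `coverage_class` column (HC/LC/BG/other).
#' @export
apply_thresholds <- function(regions, low = 0.72, high = 1.76) {
  if (low >= high) stop("low threshold must be < high threshold")
  cls <- rep("other", nrow(regions))
  cls[regions$candidate == "high" & regions$mean_rd > high] <- "HC"
  cls[regions$candidate == "low" & regions$mean_rd < low] <- "LC"
  cls[regions$candidate == "bg" & regions$mean_rd >= low &
        regions$mean_rd <= high] <- "BG"
  regions <- data.table::as.data.table(regions)
  regions$coverage_class <- cls
  regions[]
}

#' Call coverage regions from binned read depth
#'
#' Full calling pipeline: [segment_bins()], q/q0 filtering and
#' [apply_thresholds()]. High/low candidates failing the q-value or q0
#' filter are demoted to class "other" (rather than dropped), so the
#' returned regions partition the binned genome into
#' HC / LC / BG / other.
#'
#' @inheritParams segment_bins
#' @inheritParams filter_candidates
#' @inheritParams apply_thresholds
#' @return Regions with `coverage_class`.
#' @export
call_regions <- function(bins, z = 2, max_gap = 1L, q_max = 0.08,
                         q0_max = 0.5, low = 0.72, high = 1.76) {
  regions <- segment_bins(bins, z = z, max_gap = max_gap)
  regions <- apply_thresholds(regions, low = low, high = high)
  fail <- regions$candidate %in% c("high", "low") &
    (regions$q_value >= q_max | regions$q0 >= q0_max)
  regions$coverage_class[fail] <- "other"
  regions[]
}

#' Segment-averaged read depth per bin
#'
#' Replaces each bin's rd by the mean rd of the called region containing it,
#' the per-bin value a segmentation-based read-depth caller reports. Used
#' when comparing recomputed read depth against an input profile, where the
#' caller's partition-averaged values are the relevant output.
#'
#' @param bins Bin table with `rd`.
#' @param regions Called regions (a partition of the binned genome, e.g.
#'   from [call_regions()]).
#' @return Numeric vector of smoothed rd values, one per bin.
#' @export
segment_average_rd <- function(bins, regions) {
  out <- bins$rd
  for (ch in unique(bins$chrom)) {
    bidx <- which(bins$chrom == ch)
    r <- regions[regions$chrom == ch, ]
    if (!nrow(r)) next
    r <- r[order(r$start), ]
    # bins are assigned by their start; regions tile the binned genome
    ri <- findInterval(bins$start[bidx], r$start)
    ok <- ri >= 1 & bins$start[bidx] < r$end[pmax(ri, 1L)]
    grp <- factor(ri[ok], levels = seq_len(nrow(r)))
    means <- tapply(bins$rd[bidx][ok], grp, mean)
    out[bidx[ok]] <- means[as.character(ri[ok])]
  }
  unname(out)
}

#' Score region calls against truth
#'
#' Compares called coverage classes with a truth labeling, per class, at
#' nucleotide level (TP = bases carrying class X in both sets) or region
#' level (a called region counts as TP if it overlaps a truth region of the
#' same class by >= 1 bp). When `q_grid` is supplied the high/low calls are
#' re-filtered at each q threshold and the score is emitted per threshold.
#'
#' @param called Regions with `coverage_class` (and `q_value` for q_grid
#'   scoring).
#' @param truth Truth intervals with a `class` column (HC/LC/BG).
#' @param level `"nucleotide"` or `"region"`.
#' @param q_grid Optional numeric vector of q thresholds.
#' @param classes Which classes to score.
#' @return data.table: `q_max`, `class`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
score_region_calls <- function(called, truth, level = c("nucleotide", "region"),
                               q_grid = NULL, classes = c("HC", "LC")) {
  level <- match.arg(level)
  if (!setequal(unique(called$chrom), unique(truth$chrom)))
    stop("called and truth regions cover different chromosome sets")
  cls_col <- if ("coverage_class" %in% names(called)) "coverage_class" else "class"
  one <- function(called_x, truth_x) {
    if (level == "nucleotide") {
      tp <- iv_total_len(iv_intersect(called_x, truth_x))
      fp <- iv_total_len(called_x) - tp
      fn <- iv_total_len(truth_x) - tp
    } else {
      ov_c <- iv_cover_len(called_x, truth_x) > 0
      ov_t <- iv_cover_len(truth_x, called_x) > 0
      tp <- sum(ov_c); fp <- sum(!ov_c); fn <- sum(!ov_t)
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.table::data.table(tp = tp, fp = fp, fn = fn, precision = prec,
                           recall = rec, f1 = f1)
  }
  qs <- if (is.null(q_grid)) NA_real_ else q_grid
  out <- list()
  for (q in qs) {
    eff <- data.table::as.data.table(called)
    if (!is.na(q)) {
      demote <- eff[[cls_col]] %in% c("HC", "LC") & eff$q_value >= q
      eff[[cls_col]][demote] <- "other"
    }
    for (x in classes) {
      sc <- one(eff[eff[[cls_col]] == x, c("chrom", "start", "end")],
                truth[truth$class == x, c("chrom", "start", "end")])
      sc <- cbind(data.table::data.table(q_max = q, class = x), sc)
      out[[length(out) + 1L]] <- sc
    }
  }
  data.table::rbindlist(out)
}

#' N-base fraction of regions
#'
#' @param regions Interval table.
#' @param seqs Assembly sequences ([Biostrings::DNAStringSet]).
#' @return Numeric vector of N fractions, one per region row.
#' @export
region_n_fraction <- function(regions, seqs) {
  lens <- Biostrings::width(seqs); names(lens) <- names(seqs)
  if (any(!(regions$chrom %in% names(lens))) ||
      any(regions$end > lens[regions$chrom]) || any(regions$start < 0))
    stop("region outside assembly bounds")
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    idx <- which(regions$chrom == ch)
    v <- Biostrings::Views(seqs[[ch]], start = regions$start[idx] + 1L,
                           end = regions$end[idx])
    af <- Biostrings::alphabetFrequency(v)
    out[idx] <- af[, "N"] / (regions$end[idx] - regions$start[idx])
  }
  out
}
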