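# Internal interval arithmetic. All package-internal intervals are 0-based,
# half-open (BED convention), as data.frames with columns chrom/start/end.
# GenomicRanges does the heavy lifting; conversion is localized here.

#' @importFrom GenomicRanges GRanges seqnames start end width reduce intersect
#'   setdiff findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

iv_check <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$end <= df$start))
    stop("intervals must satisfy start < end")
  invisible(df)
}

iv_to_gr <- function(df) {
  if (!nrow(df)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

gr_to_iv <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

iv_reduce <- function(df) gr_to_iv(GenomicRanges::reduce(iv_to_gr(df)))

iv_intersect <- function(a, b) {
  gr_to_iv(suppressWarnings(GenomicRanges::intersect(iv_to_gr(a), iv_to_gr(b))))
}

iv_setdiff <- function(a, b) {
  gr_to_iv(suppressWarnings(GenomicRanges::setdiff(iv_to_gr(a), iv_to_gr(b))))
}

iv_total_len <- function(df) {
  if (!nrow(df)) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(iv_to_gr(df))))
}

# Length of union(track) covered inside each row of `regions` (same order).
iv_cover_len <- function(regions, track) {
  if (!nrow(regions)) return(numeric(0))
  if (!nrow(track)) return(numeric(nrow(regions)))
  rg <- iv_to_gr(regions)
  tg <- GenomicRanges::reduce(iv_to_gr(track))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rg, tg))
  out <- numeric(nrow(regions))
  if (length(hits)) {
    qs <- S4Vectors::queryHits(hits)
    ol <- pmin(GenomicRanges::end(rg)[qs], GenomicRanges::end(tg)[S4Vectors::subjectHits(hits)]) -
      pmax(GenomicRanges::start(rg)[qs], GenomicRanges::start(tg)[S4Vectors::subjectHits(hits)]) + 1L
    agg <- tapply(ol, qs, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

# Single-linkage clustering of intervals whose pairwise reciprocal overlap is
# >= frac of both lengths; returns merged (union) intervals plus a membership
# index for the input rows.
iv_merge_reciprocal <- function(df, frac = 0.5) {
  n <- nrow(df)
  if (!n) return(list(merged = df, member = integer(0)))
  gr <- iv_to_gr(df)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, gr))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s
  q <- q[keep]; s <- s[keep]
  if (length(q)) {
    ov <- pmin(df$end[q], df$end[s]) - pmax(df$start[q], df$start[s])
    lq <- df$end[q] - df$start[q]
    ls <- df$end[s] - df$start[s]
    rec <- ov >= frac * lq & ov >= frac * ls
    q <- q[rec]; s <- s[rec]
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, integer(1))
  member <- match(comp, unique(comp))
  mf <- factor(member, levels = seq_len(max(member)))
  merged <- data.table::data.table(
    chrom = df$chrom[!duplicated(member)],
    start = as.integer(tapply(df$start, mf, min)),
    end   = as.integer(tapply(df$end, mf, max))
  )
  list(merged = merged, member = member)
}
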