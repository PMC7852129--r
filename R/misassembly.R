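# Six-way classification of query-assembly regions from whole-genome
# alignment blocks against a reference (truth) assembly. Category semantics:
# 1 = non-duplicated, 2 = locally duplicated (all duplicate subjects on one
# reference chromosome), 3 = non-locally duplicated; C = correctly
# assembled, M = misassembled. A collapsed duplication shows up as a single
# query region with >= 2 private subject copies (M2/M3); a duplication
# preserved in both assemblies has its subjects shared by several query
# regions (C2/C3).

#' Parse a show-coords-style alignment table
#'
#' Reads the tab-separated MUMmer `show-coords -T` layout (no header,
#' columns `S1 E1 S2 E2 LEN1 LEN2 %IDY QUERY SUBJECT`; here the first
#' coordinate pair is the query). 1-based inclusive coordinates are
#' converted to 0-based half-open, and reverse-orientation subject intervals
#' (S2 > E2) are normalized to start < end with orientation "-".
#'
#' @param table Path to a coords file, or a data.frame with the nine columns
#'   above.
#' @return data.table of alignment blocks: `qchrom`, `qstart`, `qend`,
#'   `schrom`, `sstart`, `send`, `identity`, `orientation`.
#' @export
parse_coords <- function(table) {
  df <- if (is.character(table))
    data.table::fread(table, header = FALSE, sep = "\t") else
      data.table::as.data.table(table)
  if (ncol(df) < 9) stop("coords table needs 9 columns (S1 E1 S2 E2 LEN1 LEN2 %IDY QUERY SUBJECT)")
  data.table::setnames(df, 1:9, c("S1", "E1", "S2", "E2", "LEN1", "LEN2",
                                  "IDY", "Q", "S"))
  for (col in c("S1", "E1", "S2", "E2", "IDY")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("malformed coords row at line ", which(is.na(v))[1],
           " (non-numeric ", col, ")")
    df[[col]] <- v
  }
  if (any(df$S1 > df$E1))
    stop("malformed coords row at line ", which(df$S1 > df$E1)[1],
         " (query start > end)")
  rev <- df$S2 > df$E2
  out <- data.table::data.table(
    qchrom = as.character(df$Q),
    qstart = as.integer(df$S1 - 1), qend = as.integer(df$E1),
    schrom = as.character(df$S),
    sstart = as.integer(ifelse(rev, df$E2 - 1, df$S2 - 1)),
    send = as.integer(ifelse(rev, df$S2, df$E2)),
    identity = df$IDY,
    orientation = ifelse(rev, "-", "+"))
  if (any(out$identity < 0 | out$identity > 100))
    stop("identity outside [0, 100] at line ",
         which(out$identity < 0 | out$identity > 100)[1])
  out
}

#' Drop low-identity alignment blocks
#'
#' @param blocks Alignment block table.
#' @param min_identity Minimum percent identity retained (blocks below it
#'   are dropped).
#' @return Filtered blocks.
#' @export
filter_identity <- function(blocks, min_identity = 95) {
  blocks[blocks$identity >= min_identity, ]
}

#' Group alignment blocks into query regions and merged subject regions
#'
#' Blocks are clustered into query regions by single-linkage reciprocal
#' >= 50% overlap of their query intervals; within each query region the
#' subject intervals are merged by the same reciprocal rule before counting,
#' so near-identical subject hits are deduplicated. A query region is
#' "duplicated" iff >= 2 distinct subject regions remain, regardless of
#' subject chromosome.
#'
#' @param blocks Filtered alignment blocks.
#' @param reciprocal Reciprocal overlap fraction used for merging.
#' @return list with `query_regions` (`qr_id`, `chrom`, `start`, `end`,
#'   `n_subjects`), `subjects` (`qr_id`, `chrom`, `start`, `end`) and
#'   `blocks` (input blocks with a `qr_id` column).
#' @export
group_subjects <- function(blocks, reciprocal = 0.5) {
  blocks <- data.table::as.data.table(blocks)
  if (!nrow(blocks))
    return(list(query_regions = data.table::data.table(
      qr_id = integer(), chrom = character(), start = integer(),
      end = integer(), n_subjects = integer()),
      subjects = data.table::data.table(qr_id = integer(), chrom = character(),
                                        start = integer(), end = integer()),
      blocks = blocks))
  qm <- iv_merge_reciprocal(
    data.table::data.table(chrom = blocks$qchrom, start = blocks$qstart,
                           end = blocks$qend), frac = reciprocal)
  blocks$qr_id <- qm$member
  subjects <- list()
  for (id in seq_len(nrow(qm$merged))) {
    b <- blocks[blocks$qr_id == id, ]
    sm <- iv_merge_reciprocal(
      data.table::data.table(chrom = b$schrom, start = b$sstart, end = b$send),
      frac = reciprocal)
    subjects[[id]] <- cbind(data.table::data.table(qr_id = id), sm$merged)
  }
  subjects <- data.table::rbindlist(subjects)
  qr <- data.table::copy(qm$merged)
  qr$qr_id <- seq_len(nrow(qr))
  qr$n_subjects <- as.integer(table(factor(subjects$qr_id,
                                           levels = qr$qr_id)))
  data.table::setcolorder(qr, c("qr_id", "chrom", "start", "end", "n_subjects"))
  list(query_regions = qr, subjects = subjects, blocks = blocks)
}

#' Classify query regions into assembly categories
#'
#' Applies the six-way decision rule to grouped alignment blocks:
#' \itemize{
#'   \item Non-duplicated regions (one subject) are misassembled (M1) iff
#'     their subject lies off the expected location: on a non-majority
#'     subject chromosome for that query chromosome, or off the longest
#'     increasing subsequence of one-to-one anchor blocks; otherwise C1.
#'   \item Duplicated regions (>= 2 merged subjects) are misassembled
#'     (M2/M3) iff the query is at least `min_length` bp, the union of
#'     pairwise overlaps among the subject regions is below 50% of the
#'     query length, and the subjects align to no other query region;
#'     otherwise C2/C3. A duplicated query whose subjects are shared with
#'     other query regions and that has more subject than sharing query
#'     copies is set aside as "complex".
#'   \item Local (2) iff all duplicate subjects share one subject
#'     chromosome, else non-local (3).
#' }
#'
#' @param blocks Identity-filtered alignment blocks (see [parse_coords()],
#'   [filter_identity()]).
#' @param min_length Minimum query length for a duplicated region to be
#'   called misassembled.
#' @param reciprocal Overlap fraction for subject merging/sharing.
#' @return data.table: `qr_id`, `chrom`, `start`, `end`, `n_subjects`,
#'   `category` (C1/C2/C3/M1/M2/M3/complex).
#' @export
classify_regions <- function(blocks, min_length = 100L, reciprocal = 0.5) {
  grp <- group_subjects(blocks, reciprocal = reciprocal)
  qr <- grp$query_regions
  subj <- grp$subjects
  n <- nrow(qr)
  category <- character(n)

  # --- non-duplicated: anchor chain on the majority subject chromosome ---
  single <- qr$qr_id[qr$n_subjects == 1]
  s1 <- subj[subj$qr_id %in% single, ]
  s1 <- s1[match(single, s1$qr_id), ]
  anchor_ok <- rep(TRUE, length(single))
  names(anchor_ok) <- single
  if (length(single)) {
    qinfo <- qr[match(single, qr$qr_id), ]
    for (qc in unique(qinfo$chrom)) {
      sel <- which(qinfo$chrom == qc)
      lens <- qinfo$end[sel] - qinfo$start[sel]
      schroms <- s1$chrom[sel]
      wt <- tapply(lens, schroms, sum)
      major <- names(wt)[which.max(wt)]
      off <- schroms != major
      anchor_ok[sel[off]] <- FALSE
      onc <- sel[!off]
      if (length(onc) > 1) {
        ord <- onc[order(qinfo$start[onc])]
        keep <- lis_indices(s1$start[ord])
        anchor_ok[ord[-keep]] <- FALSE
      }
    }
  }

  for (i in seq_len(n)) {
    id <- qr$qr_id[i]
    ss <- subj[subj$qr_id == id, ]
    m <- nrow(ss)
    if (m == 1) {
      category[i] <- if (anchor_ok[as.character(id)]) "C1" else "M1"
      next
    }
    qlen <- qr$end[i] - qr$start[i]
    # union of pairwise overlaps among subject regions (same chromosome)
    ov_len <- 0
    for (ch in unique(ss$chrom)) {
      sc <- ss[ss$chrom == ch, ]
      if (nrow(sc) < 2) next
      ovs <- list()
      for (a in seq_len(nrow(sc) - 1)) for (b in (a + 1):nrow(sc)) {
        lo <- max(sc$start[a], sc$start[b]); hi <- min(sc$end[a], sc$end[b])
        if (hi > lo)
          ovs[[length(ovs) + 1L]] <- data.table::data.table(
            chrom = ch, start = lo, end = hi)
      }
      if (length(ovs)) ov_len <- ov_len + iv_total_len(data.table::rbindlist(ovs))
    }
    # are these subjects hit by any other query region?
    others <- subj[subj$qr_id != id, ]
    shared_with <- integer(0)
    if (nrow(others)) {
      for (k in seq_len(m)) {
        ov <- pmin(others$end, ss$end[k]) - pmax(others$start, ss$start[k])
        lk <- ss$end[k] - ss$start[k]
        lo <- others$end - others$start
        hit <- others$chrom == ss$chrom[k] & ov >= reciprocal * lk &
          ov >= reciprocal * lo
        shared_with <- union(shared_with, others$qr_id[hit])
      }
    }
    private <- length(shared_with) == 0
    local <- length(unique(ss$chrom)) == 1
    mis <- qlen >= min_length && ov_len < 0.5 * qlen && private
    if (mis) {
      category[i] <- if (local) "M2" else "M3"
    } else if (!private && m > length(shared_with) + 1L) {
      category[i] <- "complex"
    } else {
      category[i] <- if (local) "C2" else "C3"
    }
  }
  out <- data.table::copy(qr)
  out$category <- category
  out[]
}

# indices of one longest strictly-increasing subsequence (O(n log n))
lis_indices <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  tails <- numeric(0); tails_idx <- integer(0); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pos <- findInterval(x[i] - 1e-9, tails) + 1L
    if (pos > 1) prev[i] <- tails_idx[pos - 1L]
    tails[pos] <- x[i]
    tails_idx[pos] <- i
  }
  out <- integer(0)
  i <- tails_idx[length(tails_idx)]
  while (!is.na(i)) { out <- c(i, out); i <- prev[i] }
  out
}

#' Intersect assembly categories with coverage classes
#'
#' Given category intervals on the query assembly and called coverage
#' regions, computes (a) for each coverage class the fraction of its length
#' falling in each category (bases outside every category interval count as
#' "unaligned"); (b) for each category the fraction of its length overlapped
#' by HC/BG/LC/other (bases outside HC/BG/LC count as "other", so the four
#' fractions sum to 1); and (c) a per-region majority label: a region whose
#' length is covered > 50% by M2/M3 (or C2/C3) intervals is labeled
#' `<class>_M2/M3` (`<class>_C2/C3`).
#'
#' @param categories Interval table with a `category` column.
#' @param regions Called regions with `coverage_class`.
#' @param chrom_lengths Named vector of query chromosome lengths.
#' @return list with `class_by_category`, `category_by_class` (both long
#'   data.tables of fractions) and `region_majority` (regions plus
#'   `frac_m23`, `frac_c23`, `majority_label`).
#' @export
intersect_with_coverage <- function(categories, regions, chrom_lengths) {
  genome <- data.table::data.table(chrom = names(chrom_lengths), start = 0L,
                                   end = as.integer(unname(chrom_lengths)))
  cat_iv <- split(
    data.table::as.data.table(categories)[, c("chrom", "start", "end")],
    categories$category)
  cat_iv$unaligned <- rbind(
    if ("unaligned" %in% names(cat_iv)) cat_iv$unaligned else NULL,
    iv_setdiff(genome, categories))
  cat_iv <- Filter(nrow, cat_iv)
  cls_iv <- split(
    data.table::as.data.table(regions)[, c("chrom", "start", "end")],
    regions$coverage_class)
  covered <- data.table::rbindlist(
    cls_iv[intersect(names(cls_iv), c("HC", "BG", "LC"))])
  cls_iv$other <- rbind(if ("other" %in% names(cls_iv)) cls_iv$other else NULL,
                        iv_setdiff(genome, covered))
  cls_iv <- cls_iv[intersect(c("HC", "BG", "LC", "other"), names(cls_iv))]

  a <- list(); b <- list()
  for (cl in names(cls_iv)) {
    tot <- iv_total_len(cls_iv[[cl]])
    for (ca in names(cat_iv)) {
      ov <- iv_total_len(iv_intersect(cls_iv[[cl]], cat_iv[[ca]]))
      a[[length(a) + 1L]] <- data.table::data.table(
        coverage_class = cl, category = ca,
        fraction = if (tot > 0) ov / tot else 0)
      b[[length(b) + 1L]] <- data.table::data.table(
        category = ca, coverage_class = cl, overlap = ov)
    }
  }
  a <- data.table::rbindlist(a)
  b <- data.table::rbindlist(b)
  btot <- tapply(b$overlap, b$category, sum)
  b$fraction <- ifelse(btot[b$category] > 0,
                       b$overlap / btot[b$category], 0)
  b$overlap <- NULL

  reg <- data.table::as.data.table(regions)
  rlen <- reg$end - reg$start
  m23 <- data.table::rbindlist(cat_iv[intersect(c("M2", "M3"), names(cat_iv))])
  c23 <- data.table::rbindlist(cat_iv[intersect(c("C2", "C3"), names(cat_iv))])
  reg$frac_m23 <- if (nrow(m23)) iv_cover_len(reg, m23) / rlen else 0
  reg$frac_c23 <- if (nrow(c23)) iv_cover_len(reg, c23) / rlen else 0
  reg$majority_label <- ifelse(
    reg$frac_m23 > 0.5, paste0(reg$coverage_class, "_M2/M3"),
    ifelse(reg$frac_c23 > 0.5, paste0(reg$coverage_class, "_C2/C3"),
           NA_character_))
  list(class_by_category = a, category_by_class = b, region_majority = reg)
}

#' Map query coverage regions to subject coverage classes
#'
#' Projects each query region through its alignment blocks onto the subject
#' assembly and assigns the subject coverage class covering the plurality of
#' the projected bases; regions with no projected bases are "unaligned".
#'
#' @param regions_q Query regions (e.g. the called HC regions).
#' @param blocks Alignment blocks.
#' @param regions_s Subject regions with `coverage_class` (or `class`).
#' @return `regions_q` with a `subject_class` column.
#' @export
cross_assembly_class_map <- function(regions_q, blocks, regions_s) {
  regions_q <- data.table::as.data.table(regions_q)
  scls_col <- if ("coverage_class" %in% names(regions_s)) "coverage_class" else "class"
  s_by_class <- split(
    data.table::as.data.table(regions_s)[, c("chrom", "start", "end")],
    regions_s[[scls_col]])
  out <- character(nrow(regions_q))
  for (i in seq_len(nrow(regions_q))) {
    r <- regions_q[i, ]
    b <- blocks[blocks$qchrom == r$chrom & blocks$qstart < r$end &
                  blocks$qend > r$start, ]
    if (!nrow(b)) { out[i] <- "unaligned"; next }
    proj <- list()
    for (k in seq_len(nrow(b))) {
      lo <- max(r$start, b$qstart[k]); hi <- min(r$end, b$qend[k])
      scale <- (b$send[k] - b$sstart[k]) / (b$qend[k] - b$qstart[k])
      if (b$orientation[k] == "+") {
        ps <- b$sstart[k] + (lo - b$qstart[k]) * scale
        pe <- b$sstart[k] + (hi - b$qstart[k]) * scale
      } else {
        ps <- b$send[k] - (hi - b$qstart[k]) * scale
        pe <- b$send[k] - (lo - b$qstart[k]) * scale
      }
      proj[[k]] <- data.table::data.table(chrom = b$schrom[k],
                                          start = floor(ps), end = ceiling(pe))
    }
    proj <- data.table::rbindlist(proj)
    proj <- proj[proj$end > proj$start, ]
    if (!nrow(proj)) { out[i] <- "unaligned"; next }
    cover <- vapply(s_by_class, function(sv)
      iv_total_len(iv_intersect(proj, sv)), numeric(1))
    out[i] <- if (all(cover == 0)) "unaligned" else
      names(cover)[which.max(cover)]
  }
  regions_q$subject_class <- out
  regions_q[]
}
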