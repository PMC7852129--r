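# Enrichment and randomization statistics: 2x2 log-likelihood ratios,
# Fisher/BH gene-set enrichment, windowed density correlations, label
# reshuffling z-scores, matched random-region sampling z-scores and standard
# two-sample distribution comparisons.

#' Log likelihood ratio of a 2x2 contingency table
#'
#' `log10((a/b) / (c/d))`, antisymmetric under swapping the two rows. When
#' any cell is zero a Haldane correction (+0.5 to all four cells) is applied
#' and flagged via the `"haldane"` attribute.
#'
#' @param a,b,c,d Non-negative counts: `a` = items with the property in the
#'   focal set, `b` = items without it in the focal set, `c`/`d` the same
#'   outside the focal set.
#' @return Numeric LLR with attribute `haldane` (logical).
#' @export
llr <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
  if (a + b + c + d == 0) stop("empty contingency table")
  hald <- any(c(a, b, c, d) == 0)
  if (hald) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  # evaluated as a difference of the two row log-odds so that swapping the
  # rows negates the value bit-exactly
  structure((log10(a) - log10(b)) - (log10(c) - log10(d)), haldane = hald)
}

#' Gene-set enrichment by Fisher's exact test and LLR
#'
#' For each term, builds the 2x2 table: genes with the term inside the focal
#' region set, genes without it inside, genes with it outside, genes without
#' it outside; computes the Fisher p-value, the LLR and BH q-values within
#' each annotation family.
#'
#' @param focal_genes Character vector of gene ids in the focal regions
#'   (e.g. genes overlapping high-coverage regions).
#' @param universe Character vector of all gene ids.
#' @param term_map data.frame with `gene`, `term` and optionally `family`
#'   (BH adjustment is applied within each family).
#' @return data.table: `term`, `family`, `a`, `b`, `c`, `d`, `llr`,
#'   `p_value`, `q_value`, sorted by decreasing LLR.
#' @export
enrichment_test <- function(focal_genes, universe, term_map) {
  if (!length(universe)) stop("empty gene universe")
  focal_genes <- intersect(unique(focal_genes), universe)
  tm <- data.table::as.data.table(term_map)
  if (!"family" %in% names(tm)) tm$family <- "all"
  tm <- tm[tm$gene %in% universe, ]
  n_focal <- length(focal_genes)
  n_univ <- length(unique(universe))
  out <- tm[, {
    withterm <- unique(gene)
    a <- sum(withterm %in% focal_genes)
    b <- n_focal - a
    c <- length(withterm) - a
    d <- (n_univ - n_focal) - c
    lv <- llr(a, b, c, d)
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    list(a = a, b = b, c = c, d = d, llr = as.numeric(lv),
         haldane = attr(lv, "haldane"), p_value = p)
  }, by = c("family", "term")]
  out[, q_value := stats::p.adjust(p_value, method = "BH"), by = "family"]
  data.table::setorder(out, -llr)
  out[]
}

# density (covered fraction) of a set of intervals in fixed genome windows
window_density <- function(iv, chrom_lengths, window) {
  wins <- make_bins(chrom_lengths, window)
  wins$density <- iv_cover_len(wins, iv) / (wins$end - wins$start)
  wins
}

#' Correlation between region density and a feature track across the genome
#'
#' Tiles the genome into fixed windows (default 500 kb), computes the
#' covered fraction of the regions and of the track per window, and returns
#' the Spearman rank correlation.
#'
#' @param regions,track Interval tables.
#' @param chrom_lengths Named chromosome lengths.
#' @param window Window width in bp.
#' @return list (`StatResult`): `rho`, `pearson`, `p_value` (Spearman test),
#'   `n_windows`.
#' @export
density_correlation <- function(regions, track, chrom_lengths,
                                window = 500000L) {
  wa <- window_density(regions, chrom_lengths, window)
  wb <- window_density(track, chrom_lengths, window)
  if (nrow(wa) < 3) stop("fewer than 3 windows; shrink the window size")
  ct <- suppressWarnings(
    stats::cor.test(wa$density, wb$density, method = "spearman"))
  list(rho = unname(ct$estimate),
       pearson = stats::cor(wa$density, wb$density),
       p_value = ct$p.value,
       n_windows = nrow(wa))
}

#' Reshuffling z-score for a class-track density correlation
#'
#' Observed statistic: Spearman correlation between the windowed density of
#' regions of one class and a feature track. Null: the region class labels
#' are reshuffled (class counts preserved) and the correlation recomputed
#' `n` times; z = (observed - null mean) / null SD, with an add-one
#' two-sided permutation p-value.
#'
#' @param regions Region table with a class column (`coverage_class` or
#'   `class`).
#' @param class_of_interest Which class's density is correlated.
#' @param track Feature interval table.
#' @param chrom_lengths Named chromosome lengths.
#' @param window Window width (bp).
#' @param n Number of reshuffles.
#' @param seed Integer seed.
#' @return list (`StatResult`): `observed`, `null_mean`, `null_sd`, `z`
#'   (NA, flagged, when the null SD is zero), `p_value`, `n_perm`.
#' @export
reshuffle_zscore <- function(regions, class_of_interest, track, chrom_lengths,
                             window = 500000L, n = 1000L, seed = 1L) {
  cls_col <- if ("coverage_class" %in% names(regions)) "coverage_class" else "class"
  labels <- regions[[cls_col]]
  if (!any(labels == class_of_interest)) stop("no regions of class ",
                                              class_of_interest)
  wt <- window_density(track, chrom_lengths, window)
  # region x window overlap matrix, computed once; each permutation is then
  # a cheap column sum over the relabeled regions
  wins <- make_bins(chrom_lengths, window)
  rg <- iv_to_gr(regions[, c("chrom", "start", "end")])
  wg <- iv_to_gr(wins)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rg, wg))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(regions$end[qh], wins$end[sh]) - pmax(regions$start[qh], wins$start[sh])
  M <- matrix(0, nrow(regions), nrow(wins))
  M[cbind(qh, sh)] <- ov / (wins$end[sh] - wins$start[sh])
  stat <- function(lab) {
    dens <- colSums(M[lab == class_of_interest, , drop = FALSE])
    suppressWarnings(stats::cor(dens, wt$density, method = "spearman"))
  }
  observed <- stat(labels)
  set.seed(seed)
  null <- vapply(seq_len(n), function(i) stat(sample(labels)), numeric(1))
  nm <- mean(null); nsd <- stats::sd(null)
  z <- if (nsd > 0) (observed - nm) / nsd else NA_real_
  p <- (1 + sum(abs(null - nm) >= abs(observed - nm))) / (n + 1)
  list(observed = observed, null_mean = nm, null_sd = nsd, z = z,
       p_value = p, n_perm = n, degenerate_null = nsd == 0)
}

#' Matched random-region sampling z-scores
#'
#' Null model for feature counts in a focal region set: each draw places the
#' same number of non-overlapping intervals, with exactly the focal set's
#' length multiset, uniformly inside the allowed background space, and the
#' number of feature intervals overlapping the placed regions is recorded
#' per feature type. z-scores compare the observed counts to this null.
#'
#' @param focal_regions Focal intervals (e.g. called high-coverage regions).
#' @param bg_space Allowed placement space (e.g. background regions).
#' @param features Named list of feature interval tables (one per type).
#' @param n Number of null draws.
#' @param seed Integer seed.
#' @param max_retries Rejection-sampling retries per interval before error.
#' @return data.table: `type`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_value` (add-one, upper tail on |deviation|).
#' @export
matched_random_regions_zscore <- function(focal_regions, bg_space, features,
                                          n = 10000L, seed = 1L,
                                          max_retries = 10000L) {
  lens <- sort(focal_regions$end - focal_regions$start, decreasing = TRUE)
  bg <- data.table::as.data.table(bg_space)[, c("chrom", "start", "end")]
  count_types <- function(iv) {
    vapply(features, function(f) sum(iv_cover_len(f, iv) > 0), numeric(1))
  }
  observed <- count_types(focal_regions[, c("chrom", "start", "end")])
  set.seed(seed)
  draws <- matrix(0, n, length(features),
                  dimnames = list(NULL, names(features)))
  for (d in seq_len(n)) {
    placed <- place_matched(lens, bg, max_retries)
    draws[d, ] <- count_types(placed)
  }
  nm <- colMeans(draws)
  nsd <- apply(draws, 2, stats::sd)
  z <- ifelse(nsd > 0, (observed - nm) / nsd, NA_real_)
  p <- vapply(seq_along(observed), function(i)
    (1 + sum(abs(draws[, i] - nm[i]) >= abs(observed[i] - nm[i]))) / (n + 1),
    numeric(1))
  data.table::data.table(type = names(features), observed = observed,
                         null_mean = nm, null_sd = nsd, z = z, p_value = p)
}

# place intervals with the given length multiset, non-overlapping, inside bg
place_matched <- function(lens, bg, max_retries) {
  placed <- data.table::data.table(chrom = character(), start = numeric(),
                                   end = numeric())
  for (L in lens) {
    fit <- bg[bg$end - bg$start >= L, ]
    if (!nrow(fit))
      stop("background space has no interval of length >= ", L)
    w <- fit$end - fit$start - L + 1
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      i <- sample.int(nrow(fit), 1, prob = w)
      st <- fit$start[i] + floor(stats::runif(1) * w[i])
      cand <- data.table::data.table(chrom = fit$chrom[i], start = st,
                                     end = st + L)
      if (!nrow(placed) ||
          !any(placed$chrom == cand$chrom & placed$start < cand$end &
                 placed$end > cand$start)) {
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to place a ", L, " bp interval after ",
                  max_retries, " retries")
  }
  placed
}

#' Two-sample distribution comparisons
#'
#' Dispatches to the standard two-sided tests used for class-wise feature
#' and read-depth comparisons.
#'
#' @param x,y Numeric samples.
#' @param test `"wilcoxon-ranksum"`, `"ks"`, `"f-variance"` or `"kruskal"`.
#' @return list (`StatResult`): `statistic`, `p_value`, `test`.
#' @export
compare_distributions <- function(x, y,
                                  test = c("wilcoxon-ranksum", "ks",
                                           "f-variance", "kruskal")) {
  test <- match.arg(test)
  if (!length(x) || !length(y)) stop("empty sample")
  res <- switch(test,
    "wilcoxon-ranksum" = stats::wilcox.test(x, y),
    "ks" = suppressWarnings(stats::ks.test(x, y)),
    "f-variance" = stats::var.test(x, y),
    "kruskal" = stats::kruskal.test(list(x, y)))
  list(statistic = unname(res$statistic), p_value = res$p.value, test = test)
}
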