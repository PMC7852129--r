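# Coords parsing, subject grouping, the six-way decision rule (validated
# against a brute-force oracle over all enumerated configurations), coverage
# intersection and cross-assembly class projection.

test_that("coords rows convert 1-based inclusive to 0-based half-open with orientation", {
  df <- data.frame(S1 = 1, E1 = 100, S2 = 1, E2 = 100, LEN1 = 100,
                   LEN2 = 100, IDY = 98.0, Q = "chrQ", S = "chrS")
  b <- parse_coords(df)
  expect_equal(b$qstart, 0L); expect_equal(b$qend, 100L)
  expect_equal(b$sstart, 0L); expect_equal(b$send, 100L)
  expect_equal(b$identity, 98); expect_equal(b$orientation, "+")

  rev <- parse_coords(data.frame(S1 = 1, E1 = 100, S2 = 200, E2 = 101,
                                 LEN1 = 100, LEN2 = 100, IDY = 97,
                                 Q = "chrQ", S = "chrS"))
  expect_equal(rev$sstart, 100L); expect_equal(rev$send, 200L)
  expect_equal(rev$orientation, "-")

  path <- withr::local_tempfile(fileext = ".coords")
  writeLines(c("1\t100\t1\t100\t100\t100\t98.0\tq\ts",
               "5\tx\t1\t50\t50\t50\t99\tq\ts"), path)
  expect_error(parse_coords(path), "line 2")
})

test_that("identity filter keeps >= 95 and drops 94.9", {
  b <- parse_coords(data.frame(S1 = c(1, 1), E1 = c(100, 100),
                               S2 = c(1, 1), E2 = c(100, 100),
                               LEN1 = 100, LEN2 = 100,
                               IDY = c(94.9, 95.0), Q = "q", S = "s"))
  expect_equal(filter_identity(b)$identity, 95)
})

mk_blocks <- function(q, s) {
  data.table::data.table(
    qchrom = q$chrom, qstart = q$start, qend = q$end,
    schrom = s$chrom, sstart = s$start, send = s$end,
    identity = 99, orientation = "+")
}

test_that("subject regions overlapping >= 50% reciprocally merge before counting", {
  # one subject hit -> non-duplicated
  b1 <- mk_blocks(data.frame(chrom = "q1", start = 0L, end = 1000L),
                  data.frame(chrom = "s1", start = 0L, end = 1000L))
  g1 <- group_subjects(b1)
  expect_equal(g1$query_regions$n_subjects, 1L)
  # two disjoint subject hits -> duplicated
  b2 <- rbind(b1, mk_blocks(data.frame(chrom = "q1", start = 0L, end = 1000L),
                            data.frame(chrom = "s1", start = 5000L, end = 6000L)))
  expect_equal(group_subjects(b2)$query_regions$n_subjects, 2L)
  # two hits mutually overlapping 95% -> merged -> non-duplicated
  b3 <- rbind(b1, mk_blocks(data.frame(chrom = "q1", start = 0L, end = 1000L),
                            data.frame(chrom = "s1", start = 50L, end = 1050L)))
  g3 <- group_subjects(b3)
  expect_equal(g3$query_regions$n_subjects, 1L)
  expect_equal(g3$subjects$start, 0L)
  expect_equal(g3$subjects$end, 1050L)
})

test_that("the six-way decision rule matches a brute-force oracle over all configurations", {
  for (qlen_big in c(TRUE, FALSE)) for (ov_big in c(TRUE, FALSE))
    for (private in c(TRUE, FALSE)) for (same_chrom in c(TRUE, FALSE)) {
      qlen <- if (qlen_big) 500L else 80L
      blocks <- list()
      qA <- data.frame(chrom = "q1", start = 1000L, end = 1000L + qlen)
      sub1 <- data.frame(chrom = "s1", start = 5000L, end = 5000L + qlen)
      if (ov_big) {
        # second subject overlaps 60% of the query length but less than
        # half of its own (longer) span, so the two are not merged
        sub2 <- data.frame(chrom = if (same_chrom) "s1" else "s2",
                           start = if (same_chrom) 5000L + as.integer(0.4 * qlen) else 5000L,
                           end = if (same_chrom) 5000L + as.integer(0.4 * qlen) + 3L * qlen
                                 else 5000L + 3L * qlen)
        if (!same_chrom) {
          # cross-chromosome intervals cannot overlap; the union-overlap
          # condition is then automatically met, so skip this combination
          next
        }
      } else {
        sub2 <- data.frame(chrom = if (same_chrom) "s1" else "s2",
                           start = 20000L, end = 20000L + qlen)
      }
      blocks[[1]] <- mk_blocks(qA, sub1)
      blocks[[2]] <- mk_blocks(qA, sub2)
      if (!private) {
        qB <- data.frame(chrom = "q1", start = 50000L, end = 50000L + qlen)
        blocks[[3]] <- mk_blocks(qB, sub2)
      }
      tab <- data.table::rbindlist(blocks)
      res <- classify_regions(tab, min_length = 100L)
      got <- res$category[res$start == 1000L]

      # independent restatement of the rule
      mis <- qlen >= 100L && !ov_big && private
      expected <- if (mis) {
        if (same_chrom) "M2" else "M3"
      } else {
        if (same_chrom) "C2" else "C3"
      }
      expect_equal(got, expected,
                   info = sprintf("qlen_big=%s ov_big=%s private=%s same=%s",
                                  qlen_big, ov_big, private, same_chrom))
    }
})

test_that("non-duplicated regions off the anchor chain or chromosome are M1", {
  # five collinear anchors, one out-of-order hit, one on another chromosome
  q <- data.frame(chrom = "q1", start = seq(0L, 60000L, by = 10000L),
                  end = seq(5000L, 65000L, by = 10000L))
  s_start <- c(0L, 10000L, 50000L, 30000L, 40000L, 20000L, 60000L)
  s <- data.frame(chrom = c(rep("s1", 6), "s2"),
                  start = s_start, end = s_start + 5000L)
  res <- classify_regions(mk_blocks(q, s))
  expect_equal(res$category[res$start == 70000L - 10000L], "M1")  # other chrom
  expect_equal(res$category[res$start == 20000L], "M1")           # off the chain
  expect_equal(res$category[res$start == 0L], "C1")
  expect_equal(sum(res$category == "C1"), 4L)
})

test_that("query duplicates sharing extra subject copies are set aside as complex", {
  qlen <- 400L
  q1 <- data.frame(chrom = "q1", start = 0L, end = qlen)
  q2 <- data.frame(chrom = "q1", start = 10000L, end = 10000L + qlen)
  subs <- lapply(c(0L, 5000L, 50000L), function(st)
    data.frame(chrom = "s1", start = st, end = st + qlen))
  blocks <- data.table::rbindlist(c(
    lapply(subs, function(s) mk_blocks(q1, s)),
    lapply(subs, function(s) mk_blocks(q2, s))))
  res <- classify_regions(blocks)
  expect_true(all(res$category == "complex"))
})

test_that("planted collapse events are recovered as M2/M3 at >= 90% base recall", {
  d <- medium_dataset()
  called <- classify_regions(filter_identity(d$blocks))
  truth_cat <- d$collapsed$labels$category
  for (cat in c("M2", "M3")) {
    tr <- truth_cat[truth_cat$category == cat, ]
    ca <- called[called$category == cat, c("chrom", "start", "end")]
    recall <- misasm:::iv_total_len(misasm:::iv_intersect(tr, ca)) /
      misasm:::iv_total_len(tr)
    expect_gte(recall, 0.9)
  }
})

test_that("coverage-class/category fractions behave and majority labels follow the >50% rule", {
  chrom_lengths <- c(chr1 = 10000L)
  categories <- data.table::data.table(
    chrom = "chr1", start = c(0L, 2000L), end = c(2000L, 10000L),
    category = c("M2", "C1"))
  regions <- data.table::data.table(
    chrom = "chr1", start = c(0L, 2000L, 3000L), end = c(2000L, 3000L, 10000L),
    coverage_class = c("HC", "other", "BG"))
  iw <- intersect_with_coverage(categories, regions, chrom_lengths)
  a <- iw$class_by_category
  expect_equal(a$fraction[a$coverage_class == "HC" & a$category == "M2"], 1)
  b <- iw$category_by_class
  for (cat in unique(b$category))
    expect_equal(sum(b$fraction[b$category == cat]), 1, tolerance = 1e-9)
  # 1000 bp HC region with 600 bp in M2 -> HC_M2/M3
  regions2 <- data.table::data.table(chrom = "chr1", start = 1400L,
                                     end = 2400L, coverage_class = "HC")
  iw2 <- intersect_with_coverage(categories, regions2, chrom_lengths)
  expect_equal(iw2$region_majority$majority_label, "HC_M2/M3")
})

test_that("fractions sum to 1 per category on real synthetic calls", {
  d <- medium_dataset()
  called <- classify_regions(filter_identity(d$blocks))
  lens <- Biostrings::width(d$collapsed$seqs)
  names(lens) <- names(d$collapsed$seqs)
  iw <- intersect_with_coverage(
    called[, c("chrom", "start", "end", "category")], d$regions, lens)
  b <- iw$category_by_class
  for (cat in unique(b$category))
    expect_equal(sum(b$fraction[b$category == cat]), 1, tolerance = 1e-9)
})

test_that("cross-assembly projection: identity maps classes to themselves, gaps are unaligned", {
  regions_q <- data.table::data.table(
    chrom = "q1", start = c(0L, 5000L), end = c(1000L, 6000L),
    coverage_class = c("HC", "HC"))
  blocks <- data.table::data.table(
    qchrom = "q1", qstart = 0L, qend = 4000L,
    schrom = "q1", sstart = 0L, send = 4000L,
    identity = 100, orientation = "+")
  regions_s <- data.table::data.table(
    chrom = "q1", start = c(0L, 1000L), end = c(1000L, 4000L),
    coverage_class = c("HC", "BG"))
  out <- cross_assembly_class_map(regions_q, blocks, regions_s)
  expect_equal(out$subject_class, c("HC", "unaligned"))
})

test_that("collapsed HC regions project to background on the truth assembly", {
  d <- medium_dataset()
  truth_called <- fixture("truth_called", function() {
    tgt <- as_sequencing_target(d$truth)
    pl <- simulate_reads(tgt, seed = 99L)
    call_regions(compute_rd(pl, seqs = tgt$seqs))
  })
  called_cat <- classify_regions(filter_identity(d$blocks))
  m23 <- called_cat[called_cat$category %in% c("M2", "M3"), ]
  hc <- d$regions[d$regions$coverage_class == "HC", ]
  hc_m23 <- hc[misasm:::iv_cover_len(hc, m23) / (hc$end - hc$start) > 0.5, ]
  expect_gt(nrow(hc_m23), 0)
  out <- cross_assembly_class_map(hc_m23, d$blocks, truth_called)
  expect_true(all(out$subject_class == "BG"))
})
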