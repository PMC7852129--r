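# Balanced resampling, holdout splitting, metric calibration, grid search,
# feature selection and the model catalog.

test_that("balanced datasets downsample every class to the minority count", {
  labels <- rep(c("HC", "BG", "LC"), c(20, 200, 150))
  sets <- make_balanced_datasets(labels, n_datasets = 5, seed = 2)
  expect_length(sets, 5)
  for (s in sets) {
    expect_equal(unname(table(labels[s])), rep(20L, 3), ignore_attr = TRUE)
    expect_false(any(duplicated(s)))
  }
  expect_identical(sets, make_balanced_datasets(labels, 5, seed = 2))
  # already balanced: every dataset is the whole set
  bal <- rep(c("A", "B"), each = 10)
  for (s in make_balanced_datasets(bal, 3, seed = 1))
    expect_setequal(s, seq_along(bal))
  expect_error(make_balanced_datasets(factor(c("A", "A"), levels = c("A", "B"))),
               "0 instances")
})

test_that("random holdout is stratified at the requested fraction", {
  labels <- rep(c("HC", "BG", "LC"), each = 100)
  sp <- split_holdout(labels, 0.1, seed = 3)
  expect_length(sp$test, 30)
  expect_length(sp$train, 270)
  expect_equal(unname(table(labels[sp$test])), rep(10L, 3), ignore_attr = TRUE)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("span holdout keeps training regions outside every test span", {
  set.seed(4)
  regions <- data.table::data.table(
    chrom = rep(c("chr1", "chr2"), each = 150),
    start = as.integer(c(sort(runif(150, 0, 990000)),
                         sort(runif(150, 0, 990000)))))
  regions$end <- regions$start + 1000L
  labels <- rep(c("HC", "BG", "LC"), 100)
  chrom_lengths <- c(chr1 = 1000000L, chr2 = 1000000L)
  sp <- split_holdout(labels, 0.15, mode = "span", regions = regions,
                      chrom_lengths = chrom_lengths, seed = 5)
  expect_gt(length(sp$test), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  # pairwise distance between test and train regions exceeds zero overlap:
  # no train region may fall inside the span of any test region's span; the
  # construction guarantees disjointness, so just check min distances
  min_dist <- min(vapply(sp$test, function(i) {
    same <- sp$train[regions$chrom[sp$train] == regions$chrom[i]]
    if (!length(same)) return(Inf)
    min(pmax(regions$start[same] - regions$end[i],
             regions$start[i] - regions$end[same]))
  }, numeric(1)))
  expect_gte(min_dist, 0)

  one_chr <- c(chr1 = 50000L)
  reg2 <- data.table::data.table(chrom = "chr1",
                                 start = seq(20000L, 29000L, by = 1000L))
  reg2$end <- reg2$start + 900L
  lab2 <- rep("HC", nrow(reg2))
  expect_error(split_holdout(lab2, 0.999, mode = "span", regions = reg2,
                             chrom_lengths = one_chr, seed = 1),
               "every instance")
})

test_that("span-mode test regions are farther from training regions than random-mode ones", {
  set.seed(14)
  regions <- data.table::data.table(chrom = "chr1",
                                    start = sort(as.integer(runif(300, 0, 995000))))
  regions$end <- regions$start + 1000L
  labels <- rep(c("HC", "BG", "LC"), 100)
  cl <- c(chr1 = 1000000L)
  dist_to_train <- function(sp) {
    stats::median(vapply(sp$test, function(i) {
      tr <- sp$train
      min(abs((regions$start[tr] + regions$end[tr]) / 2 -
                (regions$start[i] + regions$end[i]) / 2))
    }, numeric(1)))
  }
  d_rand <- dist_to_train(split_holdout(labels, 0.1, "random", seed = 6))
  d_span <- dist_to_train(split_holdout(labels, 0.1, "span", regions = regions,
                                        chrom_lengths = cl, seed = 6))
  expect_gt(d_span, d_rand)
})

test_that("metric calibration: perfect, three-class random, and binary random predictions", {
  labels <- rep(c("HC", "BG", "LC"), each = 400)
  perfect <- evaluate_predictions(labels, labels)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_true(all(diag(perfect$confusion) == 1))

  set.seed(7)
  rand <- evaluate_predictions(labels, sample(labels))
  expect_equal(rand$accuracy, 1 / 3, tolerance = 0.1)
  expect_equal(rand$macro_f1, 1 / 3, tolerance = 0.1)

  bin <- rep(c("HC", "BG"), each = 600)
  rand2 <- evaluate_predictions(bin, sample(bin))
  expect_equal(rand2$accuracy, 0.5, tolerance = 0.1)
})

test_that("random-prediction macro-F1 converges to 1/K as n grows", {
  set.seed(8)
  for (K in c(2L, 3L)) {
    labels <- rep(paste0("c", seq_len(K)), each = 2000)
    m <- mean(replicate(5, evaluate_predictions(labels, sample(labels))$macro_f1))
    expect_equal(m, 1 / K, tolerance = 0.03)
  }
})

test_that("grid search: separable data scores ~1, permuted labels ~chance, singleton grid returned", {
  set.seed(9)
  n <- 60
  y <- rep(c("A", "B", "C"), each = n / 3)
  x <- data.frame(signal = as.numeric(factor(y)) + rnorm(n, 0, 0.05),
                  noise = rnorm(n))
  g1 <- data.frame(max_depth = 0L, mtry_frac = NA_real_, num_trees = 100L)
  res <- grid_search_train(x, y, grid = g1, folds = 5, seed = 1)
  expect_equal(nrow(res$best_params), 1L)
  expect_gte(res$cv_macro_f1, 0.9)

  yp <- sample(y)
  resp <- grid_search_train(x, yp, grid = g1, folds = 5, seed = 1)
  expect_lt(resp$cv_macro_f1, 0.55)

  expect_error(grid_search_train(x, y, grid = g1[0, ]), "empty")
  expect_error(grid_search_train(x, y, grid = g1, folds = 50), "fold count")
})

test_that("ensemble evaluation averages over balanced datasets", {
  set.seed(10)
  n <- 90
  y <- rep(c("A", "B", "C"), each = n / 3)
  x <- data.frame(signal = as.numeric(factor(y)) + rnorm(n, 0, 0.1))
  g1 <- data.frame(max_depth = 0L, mtry_frac = NA_real_, num_trees = 50L)
  fits <- lapply(1:3, function(i)
    grid_search_train(x, y, grid = g1, folds = 3, seed = i))
  rep <- evaluate_ensemble(fits, x, y)
  expect_gte(rep$test_macro_f1[["mean"]], 0.9)
  expect_equal(unname(rowSums(rep$confusion_test)), rep(1, 3))
  expect_equal(sum(rep$importance), 1)
  expect_error(evaluate_ensemble(fits, x[0, , drop = FALSE], y[0]), "empty")
})

test_that("a classifier on planted composition beats the random baseline by >= 0.2 macro-F1", {
  # 90 windows of 600 bp: high-coverage-like windows carry a 300 bp AT
  # microsatellite, low-coverage-like windows are GC-rich, background is
  # genome-average sequence
  set.seed(15)
  bases <- c("A", "C", "G", "T")
  rnd <- function(n, gc) paste(sample(bases, n, replace = TRUE,
                                      prob = c((1 - gc) / 2, gc / 2,
                                               gc / 2, (1 - gc) / 2)),
                               collapse = "")
  cls <- rep(c("HC", "BG", "LC"), 30)
  wins <- lapply(cls, function(cl) switch(cl,
    HC = paste0(strrep("AT", 150), rnd(300, 0.36)),
    BG = rnd(600, 0.36),
    LC = rnd(600, 0.70)))
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(unlist(wins), collapse = "")))
  regions <- data.table::data.table(chrom = "chr1",
                                    start = seq(0L, by = 600L, length.out = 90L))
  regions$end <- regions$start + 600L
  ssr_track <- regions[cls == "HC", ]
  ssr_track$end <- ssr_track$start + 300L
  fm <- feature_matrix(regions, seqs, list(ssrs = ssr_track),
                       flank_sizes = NULL, kmer_k = 1:2)
  X <- as.data.frame(fm); X[is.na(X)] <- 0
  grid <- data.frame(max_depth = 0L, mtry_frac = NA_real_, num_trees = 100L)
  res <- train_region_classifier(X, cls, n_datasets = 5,
                                 n_search = 1, grid = grid, folds = 3,
                                 fraction = 0.2, seed = 11)
  expect_gte(res$test_macro_f1[["mean"]], 1 / 3 + 0.2)
})

test_that("balanced training folds have equal class counts (within 1)", {
  labels <- rep(c("HC", "BG", "LC"), c(30, 120, 90))
  sets <- make_balanced_datasets(labels, 3, seed = 12)
  for (s in sets) {
    counts <- table(labels[s])
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("top-feature selection ranks informative features first with lexicographic ties", {
  set.seed(13)
  y <- rep(c(0, 1), each = 50)
  x <- data.frame(informative = y + rnorm(100, 0, 0.05),
                  constant = 1,
                  noise = rnorm(100))
  fit <- ranger::ranger(x = x, y = factor(y), num.trees = 100,
                        importance = "impurity", seed = 1, num.threads = 1)
  imp <- ranger::importance(fit)
  expect_equal(select_top_features(imp, 1), "informative")
  expect_warning(all3 <- select_top_features(imp, 10), "exceeds")
  expect_setequal(all3, names(imp))
  # exact ties: lexicographic
  tied <- c(zeta = 0.5, alpha = 0.5, mid = 0.7)
  expect_equal(select_top_features(tied, 3), c("mid", "alpha", "zeta"))
  # group ranks
  gr <- feature_group_ranks(tied, list(greek = c("zeta", "alpha")))
  expect_equal(gr$median_rank, 2.5)
})

test_that("the model catalog wires the expected feature sets and round-trips through JSON", {
  cat <- model_catalog()
  m1 <- model_spec("1")
  feats <- resolve_model_features(
    m1, c("gc", "density_genes", "density_tandem_genes",
          "density_nontandem_genes", "density_pseudogenes", "density_tes",
          "density_ssrs", "flank_500_gc", "kmer_A", "term_T1"))
  expect_length(feats, 7)
  m2 <- model_spec("2")
  expect_false(m2$base)
  expect_equal(m2$flanks, "500")
  expect_true(model_spec("37")$classes == "HC_M2/M3 vs HC_C2/C3")
  expect_error(model_spec("nope"), "unknown model")

  json <- jsonlite::toJSON(cat, dataframe = "rows")
  back <- data.table::as.data.table(jsonlite::fromJSON(json))
  expect_equal(back, cat)
})
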