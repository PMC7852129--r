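# Balanced random-forest region classifiers: balanced resampling to the
# minority class, stratified or genomic-span holdout, grid-searched
# hyperparameters, cross-validated and held-out evaluation, and
# importance-based feature selection.

#' Make balanced datasets by downsampling to the minority class
#'
#' Each dataset draws, without replacement, minority-class-many instances
#' from every class; repeated draws give `n_datasets` balanced index sets.
#'
#' @param labels Class label vector.
#' @param n_datasets Number of balanced datasets.
#' @param seed Integer seed.
#' @return list of integer index vectors into `labels`.
#' @export
make_balanced_datasets <- function(labels, n_datasets = 100L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  if (any(counts == 0)) stop("class with 0 instances: ",
                             names(counts)[counts == 0][1])
  n_min <- min(counts)
  set.seed(seed)
  lapply(seq_len(n_datasets), function(d) {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) == n_min) idx else sort(sample(idx, n_min))
    }), use.names = FALSE)
  })
}

#' Hold out a test set
#'
#' `"random"` mode draws a class-stratified random fraction. `"span"` mode
#' draws `n_spans` random genomic spans per chromosome and takes test
#' regions only from inside them, with training regions strictly outside
#' every span -- a leakage control keeping test regions distant from
#' training regions.
#'
#' @param labels Class labels.
#' @param fraction Held-out fraction in (0, 1).
#' @param mode `"random"` or `"span"`.
#' @param regions Region coordinates (required for span mode).
#' @param chrom_lengths Named chromosome lengths (span mode).
#' @param n_spans Spans per chromosome (span mode).
#' @param seed Integer seed.
#' @return list with `train` and `test` integer index vectors.
#' @export
split_holdout <- function(labels, fraction = 0.10,
                          mode = c("random", "span"), regions = NULL,
                          chrom_lengths = NULL, n_spans = 2L, seed = 1L) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  labels <- as.factor(labels)
  set.seed(seed)
  if (mode == "random") {
    test <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sort(sample(idx, max(1L, round(fraction * length(idx)))))
    }), use.names = FALSE)
    return(list(train = setdiff(seq_along(labels), test), test = sort(test)))
  }
  if (is.null(regions) || is.null(chrom_lengths))
    stop("span mode needs regions and chrom_lengths")
  spans <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    span_len <- max(1, round(fraction * len))
    s <- sort(sample.int(max(1L, len - span_len), n_spans))
    data.table::data.table(chrom = ch, start = s, end = pmin(s + span_len, len))
  }))
  inside <- regions$start >= 0 & vapply(seq_len(nrow(regions)), function(i) {
    any(spans$chrom == regions$chrom[i] & spans$start <= regions$start[i] &
          spans$end >= regions$end[i])
  }, logical(1))
  overlaps <- vapply(seq_len(nrow(regions)), function(i) {
    any(spans$chrom == regions$chrom[i] & spans$start < regions$end[i] &
          spans$end > regions$start[i])
  }, logical(1))
  test <- which(inside)
  train <- which(!overlaps)
  for (cl in levels(labels))
    if (all(which(labels == cl) %in% test))
      stop("test spans cover every instance of class ", cl)
  list(train = train, test = test)
}

#' Per-class and macro classification metrics
#'
#' @param truth,pred Label vectors of equal length.
#' @return list with `accuracy`, `per_class` (data.table of precision,
#'   recall, f1), `macro_f1` and `confusion` (row-normalized matrix,
#'   truth in rows).
#' @export
evaluate_predictions <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  if (!length(truth)) stop("empty evaluation set")
  cm <- table(truth = truth, pred = pred)
  per <- data.table::rbindlist(lapply(levels(truth), function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.table::data.table(class = cl, precision = prec, recall = rec, f1 = f1)
  }))
  conf <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  list(accuracy = mean(as.character(truth) == as.character(pred)),
       per_class = per,
       macro_f1 = mean(per$f1),
       confusion = unclass(conf))
}

default_rf_grid <- function() {
  expand.grid(max_depth = c(0L, 3L, 5L, 10L),
              mtry_frac = c(NA_real_, 0.25, 0.5),  # NA = sqrt(p)
              num_trees = c(100L, 500L))
}

fit_ranger <- function(x, y, params, seed) {
  mtry <- if (is.na(params$mtry_frac)) max(1L, floor(sqrt(ncol(x)))) else
    max(1L, floor(params$mtry_frac * ncol(x)))
  ranger::ranger(x = x, y = as.factor(y),
                 num.trees = params$num_trees,
                 mtry = mtry,
                 max.depth = params$max_depth,
                 importance = "impurity",
                 seed = seed,
                 num.threads = 1L)
}

#' Grid-search random-forest hyperparameters by cross-validated macro-F1
#'
#' Evaluates every grid point by k-fold cross-validation and refits the best
#' point on the full training data.
#'
#' @param x Feature matrix/data.frame (training rows).
#' @param y Class labels.
#' @param grid data.frame with columns `max_depth` (0 = unlimited),
#'   `mtry_frac` (NA = sqrt(p)) and `num_trees`.
#' @param folds Cross-validation folds.
#' @param seed Integer seed.
#' @return list with `best_params`, `model` (a fitted [ranger::ranger]),
#'   `cv_results` (grid with mean macro-F1), `cv_macro_f1`.
#' @export
grid_search_train <- function(x, y, grid = default_rf_grid(), folds = 10L,
                              seed = 1L) {
  if (!nrow(grid)) stop("empty parameter grid")
  y <- as.factor(y)
  if (folds > min(table(y))) stop("fold count exceeds smallest class size")
  x <- as.data.frame(x)
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1s <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_ranger(x[tr, , drop = FALSE], y[tr], grid[g, ], seed + f)
      pred <- stats::predict(fit, data = x[!tr, , drop = FALSE])$predictions
      evaluate_predictions(y[!tr], pred)$macro_f1
    }, numeric(1))
    score[g] <- mean(f1s)
  }
  best <- grid[which.max(score), , drop = FALSE]
  model <- fit_ranger(x, y, best, seed)
  cv <- cbind(grid, macro_f1 = score)
  list(best_params = best, model = model, cv_results = cv,
       cv_macro_f1 = max(score))
}

#' Evaluate an ensemble of balanced-dataset models
#'
#' Averages per-class recall/precision and macro-F1 over the fitted models'
#' cross-validation results and over their predictions on a common held-out
#' test set, with row-normalized confusion matrices for both.
#'
#' @param fits list of results from [grid_search_train()] (one per balanced
#'   dataset), each carrying `model` and `cv_macro_f1`.
#' @param x_test,y_test Held-out test data.
#' @return list (`ModelReport`): `cv_macro_f1` (mean, sd), `test_macro_f1`
#'   (mean, sd), `test_accuracy`, `per_class_test`, `confusion_test`,
#'   `importance` (mean decrease in impurity, normalized to sum 1).
#' @export
evaluate_ensemble <- function(fits, x_test, y_test) {
  if (!length(y_test)) stop("empty test set")
  x_test <- as.data.frame(x_test)
  y_test <- as.factor(y_test)
  cvf <- vapply(fits, function(f) f$cv_macro_f1, numeric(1))
  evals <- lapply(fits, function(f) {
    pred <- stats::predict(f$model, data = x_test)$predictions
    evaluate_predictions(y_test, pred)
  })
  mf <- vapply(evals, `[[`, numeric(1), "macro_f1")
  acc <- vapply(evals, `[[`, numeric(1), "accuracy")
  per <- data.table::rbindlist(lapply(evals, `[[`, "per_class"))
  per_mean <- per[, lapply(.SD, mean), by = "class",
                  .SDcols = c("precision", "recall", "f1")]
  conf <- Reduce(`+`, lapply(evals, `[[`, "confusion")) / length(evals)
  imp <- Reduce(`+`, lapply(fits, function(f)
    ranger::importance(f$model))) / length(fits)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(cv_macro_f1 = c(mean = mean(cvf), sd = stats::sd(cvf)),
       test_macro_f1 = c(mean = mean(mf), sd = stats::sd(mf)),
       test_accuracy = c(mean = mean(acc), sd = stats::sd(acc)),
       per_class_test = per_mean,
       confusion_test = conf,
       importance = imp)
}

#' Select top features by mean importance
#'
#' @param importances Named numeric vector, or matrix with one row per
#'   dataset and named columns, of importance values.
#' @param n Number of features to keep (all, with a warning, if `n` exceeds
#'   the feature count). Ties break lexicographically by feature name.
#' @return Character vector of selected feature names (rank order).
#' @export
select_top_features <- function(importances, n) {
  imp <- if (is.matrix(importances)) colMeans(importances) else importances
  if (n > length(imp)) {
    warning("n exceeds feature count; returning all features")
    n <- length(imp)
  }
  names(imp)[order(-imp, names(imp))][seq_len(n)]
}

#' Median importance rank per feature group
#'
#' @param importances Named importance vector.
#' @param groups Named list mapping group name to feature names (or a
#'   function of feature names returning group labels).
#' @return data.table with `group` and `median_rank` (rank 1 = most
#'   important).
#' @export
feature_group_ranks <- function(importances, groups) {
  rk <- rank(-importances, ties.method = "first")
  data.table::rbindlist(lapply(names(groups), function(g) {
    f <- intersect(groups[[g]], names(importances))
    data.table::data.table(group = g,
                           median_rank = stats::median(rk[f]))
  }))
}

#' Train and evaluate a balanced region classifier end to end
#'
#' The full protocol: hold out a test fraction, build balanced datasets from
#' the training pool, grid-search hyperparameters on the first
#' `n_search` balanced datasets, fit one forest per balanced dataset with
#' the best parameters, and evaluate on the common held-out set.
#'
#' @param x Feature matrix (all regions).
#' @param y Class labels (all regions).
#' @param n_datasets Balanced datasets to fit.
#' @param n_search How many datasets take part in the grid search.
#' @param grid,folds See [grid_search_train()].
#' @param fraction,mode,regions,chrom_lengths See [split_holdout()].
#' @param seed Integer seed (recorded in the report).
#' @return `ModelReport` list from [evaluate_ensemble()] plus
#'   `best_params`, `holdout` and `seed`.
#' @export
train_region_classifier <- function(x, y, n_datasets = 100L, n_search = 10L,
                                    grid = default_rf_grid(), folds = 10L,
                                    fraction = 0.10, mode = "random",
                                    regions = NULL, chrom_lengths = NULL,
                                    seed = 1L) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  hold <- split_holdout(y, fraction, mode, regions, chrom_lengths, seed = seed)
  ytr <- droplevels(y[hold$train])
  xtr <- x[hold$train, , drop = FALSE]
  sets <- make_balanced_datasets(ytr, n_datasets, seed = seed + 1L)
  # grid search on the first n_search balanced datasets; best point reused
  search_sets <- sets[seq_len(min(n_search, length(sets)))]
  scores <- 0
  for (s in seq_along(search_sets)) {
    idx <- search_sets[[s]]
    gs <- grid_search_train(xtr[idx, , drop = FALSE], ytr[idx], grid,
                            folds = folds, seed = seed + s)
    scores <- scores + gs$cv_results$macro_f1
  }
  best <- grid[which.max(scores), , drop = FALSE]
  fits <- lapply(seq_along(sets), function(s) {
    idx <- sets[[s]]
    gs <- grid_search_train(xtr[idx, , drop = FALSE], ytr[idx],
                            best, folds = folds, seed = seed + 100L + s)
    gs
  })
  rep <- evaluate_ensemble(fits, x[hold$test, , drop = FALSE],
                           droplevels(y[hold$test]))
  rep$best_params <- best
  rep$holdout <- hold
  rep$seed <- seed
  rep
}

#' Catalog of the model families
#'
#' Declarative registry of the model grid: base-features-only (model 1),
#' flank-only at each window size (2-8), base+flanks (9), base plus top
#' k-mers/SSRs at 100/500/1000 (10/18/26), all-inclusive (34), plus
#' functional terms (35), functional-only (36), the binary high-vs-background
#' variants (1B/34B/35B/36B), and the misassembly discriminators (37:
#' HC_M2/M3 vs HC_C2/C3; 38: HC_M2/M3 vs BG_M2/M3). Each entry states which
#' feature blocks it consumes and which labels it is trained on; the entry
#' round-trips through JSON.
#'
#' @return data.table: `model`, `classes`, `base`, `flanks`, `top_kmer_ssr`,
#'   `functional`.
#' @export
model_catalog <- function() {
  dt <- function(...) data.table::data.table(...)
  flank_sizes <- c(500, 1000, 2000, 4000, 8000, 16000, 32000)
  rows <- list(
    dt(model = "1", classes = "HC/LC/BG", base = TRUE, flanks = "none",
       top_kmer_ssr = 0L, functional = FALSE))
  for (i in seq_along(flank_sizes))
    rows[[length(rows) + 1L]] <- dt(model = as.character(i + 1L),
      classes = "HC/LC/BG", base = FALSE,
      flanks = as.character(flank_sizes[i]), top_kmer_ssr = 0L,
      functional = FALSE)
  rows <- c(rows, list(
    dt(model = "9", classes = "HC/LC/BG", base = TRUE, flanks = "all",
       top_kmer_ssr = 0L, functional = FALSE),
    dt(model = "10", classes = "HC/LC/BG", base = TRUE, flanks = "none",
       top_kmer_ssr = 100L, functional = FALSE),
    dt(model = "18", classes = "HC/LC/BG", base = TRUE, flanks = "none",
       top_kmer_ssr = 500L, functional = FALSE),
    dt(model = "26", classes = "HC/LC/BG", base = TRUE, flanks = "none",
       top_kmer_ssr = 1000L, functional = FALSE),
    dt(model = "34", classes = "HC/LC/BG", base = TRUE, flanks = "all",
       top_kmer_ssr = 100L, functional = FALSE),
    dt(model = "35", classes = "HC/LC/BG", base = TRUE, flanks = "all",
       top_kmer_ssr = 100L, functional = TRUE),
    dt(model = "36", classes = "HC/LC/BG", base = FALSE, flanks = "none",
       top_kmer_ssr = 0L, functional = TRUE),
    dt(model = "1B", classes = "HC/BG", base = TRUE, flanks = "none",
       top_kmer_ssr = 0L, functional = FALSE),
    dt(model = "34B", classes = "HC/BG", base = TRUE, flanks = "all",
       top_kmer_ssr = 100L, functional = FALSE),
    dt(model = "35B", classes = "HC/BG", base = TRUE, flanks = "all",
       top_kmer_ssr = 100L, functional = TRUE),
    dt(model = "36B", classes = "HC/BG", base = FALSE, flanks = "none",
       top_kmer_ssr = 0L, functional = TRUE),
    dt(model = "37", classes = "HC_M2/M3 vs HC_C2/C3", base = TRUE,
       flanks = "all", top_kmer_ssr = 100L, functional = TRUE),
    dt(model = "38", classes = "HC_M2/M3 vs BG_M2/M3", base = TRUE,
       flanks = "all", top_kmer_ssr = 100L, functional = TRUE)))
  data.table::rbindlist(rows)
}

#' Look up a model definition
#'
#' @param name Model identifier in [model_catalog()].
#' @return One-row data.table.
#' @export
model_spec <- function(name) {
  cat <- model_catalog()
  row <- cat[cat$model == name, ]
  if (!nrow(row)) stop("unknown model name: ", name)
  row
}

#' Resolve the feature columns a catalog model consumes
#'
#' @param spec One-row model definition from [model_spec()].
#' @param feature_names Available feature column names (as produced by
#'   [feature_matrix()] and [functional_presence()]).
#' @param top_kmer,top_ssr Ranked k-mer / SSR-motif feature names (from
#'   [select_top_features()]); the spec's `top_kmer_ssr` count is applied to
#'   each family separately.
#' @return Character vector of feature columns.
#' @export
resolve_model_features <- function(spec, feature_names,
                                   top_kmer = character(0),
                                   top_ssr = character(0)) {
  base7 <- c("gc", "density_genes", "density_tandem_genes",
             "density_nontandem_genes", "density_pseudogenes", "density_tes",
             "density_ssrs")
  out <- character(0)
  if (spec$base) out <- c(out, intersect(base7, feature_names))
  if (spec$flanks == "all") {
    out <- c(out, grep("^flank_", feature_names, value = TRUE))
  } else if (spec$flanks != "none") {
    out <- c(out, grep(paste0("^flank_", spec$flanks, "_"), feature_names,
                       value = TRUE))
  }
  if (spec$top_kmer_ssr > 0)
    out <- c(out, utils::head(top_kmer, spec$top_kmer_ssr),
             utils::head(top_ssr, spec$top_kmer_ssr))
  if (spec$functional)
    out <- c(out, grep("^term_", feature_names, value = TRUE))
  unique(out)
}
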