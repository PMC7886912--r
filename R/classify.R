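#' Default cell-line to radio-sensitivity mapping
#'
#' H460 (lung) and MCF7 (breast) are radioresistant; LNCaP (prostate) is
#' radiosensitive.
#'
#' @return Named character vector mapping cell line to class label.
#' @export
default_radio_class_map <- function() {
  c(H460 = "radioresistant", MCF7 = "radioresistant", LNCaP = "radiosensitive")
}

radio_levels <- c("radiosensitive", "radioresistant")

#' Assign radio-sensitivity class labels from cell lines
#'
#' @param meta Metadata data frame with a `cell_line` column (or a
#'   `score_table`).
#' @param mapping Named vector mapping each cell line to
#'   `"radiosensitive"` or `"radioresistant"`.
#' @return Factor of per-row labels with levels
#'   (radiosensitive, radioresistant).
#' @export
assign_radio_class <- function(meta, mapping = default_radio_class_map()) {
  if (inherits(meta, "score_table")) meta <- meta$meta
  lines <- unique(as.character(meta$cell_line))
  unmapped <- setdiff(lines, names(mapping))
  if (length(unmapped))
    stop_gbr("gbr_unmapped_line_error", "no radio-class mapping for cell line(s): %s",
             paste(unmapped, collapse = ", "))
  bad <- setdiff(unique(mapping[lines]), radio_levels)
  if (length(bad))
    stop_gbr("gbr_parameter_error", "labels must be one of: %s",
             paste(radio_levels, collapse = ", "))
  factor(unname(mapping[as.character(meta$cell_line)]), levels = radio_levels)
}

#' Stratified train/test split
#'
#' Randomly splits rows into a training and a testing set, stratified by
#' class so that class proportions are preserved to within one observation.
#' The same seed always yields the same split.
#'
#' @param scores A `score_table` (or plain matrix).
#' @param labels Per-row class factor.
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return List with `train_idx`, `test_idx` and, for a `score_table`
#'   input, `train` and `test` sub-tables plus the split labels.
#' @export
split_train_test <- function(scores, labels, fraction = 0.75, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop_gbr("gbr_parameter_error", "fraction must be in (0, 1)")
  labels <- as.factor(labels)
  n <- length(labels)
  if (any(table(labels) < 2L))
    stop_gbr("gbr_parameter_error", "every class needs at least 2 members")
  set.seed(seed)
  train_idx <- integer(0)
  for (lev in levels(labels)) {
    idx <- which(labels == lev)
    n_train <- round(fraction * length(idx))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sort(sample(idx, n_train)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  out <- list(train_idx = train_idx, test_idx = test_idx,
              train_labels = labels[train_idx], test_labels = labels[test_idx])
  if (inherits(scores, "score_table")) {
    out$train <- score_table(scores$scores[train_idx, , drop = FALSE],
                             scores$meta[train_idx, , drop = FALSE])
    out$test <- score_table(scores$scores[test_idx, , drop = FALSE],
                            scores$meta[test_idx, , drop = FALSE])
  }
  out
}

score_matrix <- function(scores) {
  if (inherits(scores, "score_table")) scores$scores else as.matrix(scores)
}

#' Train a radio-sensitivity random forest
#'
#' Thin wrapper around [randomForest::randomForest()] with the defaults
#' used throughout the package: 200 trees and 5 candidate variables per
#' split.
#'
#' @param scores Training `score_table` or matrix (columns = factors).
#' @param labels Training class factor.
#' @param n_trees Number of trees (default 200).
#' @param mtry Variables tried at each split (default 5).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return The fitted `randomForest` object with an `oob_error_pct`
#'   attribute and the settings recorded in attribute `settings`.
#' @export
train_random_forest <- function(scores, labels, n_trees = 200, mtry = 5,
                                seed = 1L) {
  x <- score_matrix(scores)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop_gbr("gbr_parameter_error", "training labels contain a single class")
  if (mtry > ncol(x))
    stop_gbr("gbr_parameter_error", "mtry (%d) exceeds variable count (%d)",
             mtry, ncol(x))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = labels, ntree = n_trees,
                                    mtry = mtry)
  attr(fit, "oob_error_pct") <- 100 * fit$err.rate[n_trees, "OOB"]
  attr(fit, "settings") <- list(n_trees = n_trees, mtry = mtry, seed = seed)
  fit
}

#' Confusion matrix of a classifier on held-out data
#'
#' @param classifier A fitted random forest.
#' @param test Held-out `score_table` or matrix.
#' @param labels True labels of the held-out rows.
#' @return 2 x 2 (or c x c) `confusion_matrix`: rows = observed, columns =
#'   predicted, in the label-level order.
#' @export
evaluate_classifier <- function(classifier, test, labels) {
  x <- score_matrix(test)
  if (nrow(x) == 0L) stop_gbr("gbr_empty_error", "test set is empty")
  labels <- as.factor(labels)
  train_levels <- levels(classifier$y)
  unseen <- setdiff(levels(droplevels(labels)), train_levels)
  if (length(unseen))
    stop_gbr("gbr_label_error", "test labels contain unseen class(es): %s",
             paste(unseen, collapse = ", "))
  pred <- predict(classifier, x)
  cm <- table(observed = factor(labels, levels = train_levels),
              predicted = factor(pred, levels = train_levels))
  confusion_matrix(unclass(cm))
}

#' Construct a confusion matrix
#'
#' @param counts Square matrix of non-negative counts; rows = observed,
#'   columns = predicted, with matching dimnames.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0) || sum(counts) <= 0)
    stop_gbr("gbr_parameter_error",
             "counts must be a square non-negative matrix with positive total")
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @exportS3Method print confusion_matrix
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> observed (rows) x predicted (columns)\n")
  print(unclass(x))
  invisible(x)
}

#' Derived metrics of a 2 x 2 confusion matrix
#'
#' Accuracy = diagonal / total; sensitivity = TP / (TP + FN); specificity =
#' TN / (TN + FP); false-positive share = FP / total. All reported as
#' percentages at full precision, with 1-decimal display values alongside.
#' Undefined ratios (zero denominators) are returned as `NA`.
#'
#' @param cm A 2 x 2 `confusion_matrix`.
#' @param positive Label of the positive class (a row/column name of `cm`);
#'   defaults to the first label.
#' @return Data frame with one row per metric: `metric`, `value_pct`
#'   (full precision), `display` (1 decimal).
#' @export
confusion_metrics <- function(cm, positive = rownames(cm)[1]) {
  if (nrow(cm) != 2L)
    stop_gbr("gbr_parameter_error", "metrics are defined for 2 x 2 matrices")
  labs <- rownames(cm)
  if (!positive %in% labs)
    stop_gbr("gbr_parameter_error", "positive class '%s' not in labels (%s)",
             positive, paste(labs, collapse = ", "))
  neg <- setdiff(labs, positive)
  tp <- cm[positive, positive]; fn <- cm[positive, neg]
  fp <- cm[neg, positive]; tn <- cm[neg, neg]
  total <- tp + fn + fp + tn
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  vals <- c(accuracy = ratio(tp + tn, total),
            sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            ppv = ratio(tp, tp + fp),
            false_positive_share = ratio(fp, total))
  data.frame(metric = names(vals), value_pct = unname(vals),
             display = round(unname(vals), 1))
}

#' Permutation (mean decrease accuracy) variable importance
#'
#' Repeats `n_models` independent stratified split + forest fits; for each
#' model, the held-out accuracy drop is measured when each score column of
#' the test set is randomly permuted (`n_perm` permutations per variable,
#' averaged). Importance is reported as the mean and SD of the accuracy
#' decrease over the repeated models, for every score column including any
#' unconstrained factor.
#'
#' @param scores A `score_table` or matrix of factor scores.
#' @param labels Per-row class factor.
#' @param n_models Number of repeated split+fit models (default 10).
#' @param split_fraction Training fraction per repeat (default 0.75).
#' @param n_trees,mtry Forest hyperparameters (defaults 200 and 5).
#' @param n_perm Permutations per variable per model (default 10).
#' @param seed Base seed; model i uses `seed + i` (recorded in the output).
#' @return Data frame with `variable`, `mda_mean`, `mda_sd` (decrease in
#'   held-out accuracy, in accuracy fraction units), `rank`; attribute
#'   `"seeds"` records the per-model seeds.
#' @export
mda_importance <- function(scores, labels, n_models = 10,
                           split_fraction = 0.75, n_trees = 200, mtry = 5,
                           n_perm = 10, seed = 1L) {
  x <- score_matrix(scores)
  if (ncol(x) < 1L) stop_gbr("gbr_parameter_error", "need at least one variable")
  labels <- as.factor(labels)
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  seeds <- seed + seq_len(n_models)
  drops <- matrix(NA_real_, n_models, ncol(x))
  for (mdl in seq_len(n_models)) {
    sp <- split_train_test(x, labels, fraction = split_fraction,
                           seed = seeds[mdl])
    fit <- train_random_forest(x[sp$train_idx, , drop = FALSE],
                               labels[sp$train_idx],
                               n_trees = n_trees, mtry = mtry,
                               seed = seeds[mdl])
    xt <- x[sp$test_idx, , drop = FALSE]
    yt <- labels[sp$test_idx]
    base_acc <- mean(predict(fit, xt) == yt)
    set.seed(seeds[mdl])
    for (j in seq_len(ncol(x))) {
      acc <- numeric(n_perm)
      for (r in seq_len(n_perm)) {
        xp <- xt
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        acc[r] <- mean(predict(fit, xp) == yt)
      }
      drops[mdl, j] <- base_acc - mean(acc)
    }
  }
  out <- data.frame(variable = vars,
                    mda_mean = colMeans(drops),
                    mda_sd = apply(drops, 2L, sd))
  out$rank <- rank(-out$mda_mean, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "seeds") <- seeds
  out
}

#' Out-of-bag error over a hyperparameter grid
#'
#' Fits forests for every combination of tree count and mtry, averaging the
#' out-of-bag error percentage over `n_reps` seeded fits per cell.
#'
#' @param scores A `score_table` or matrix.
#' @param labels Per-row class factor.
#' @param trees_range Vector of tree counts (default 100 to 2000 by 100).
#' @param mtry_range Vector of mtry values (default 1 to 30).
#' @param n_reps Fits averaged per cell (default 5).
#' @param seed Base seed.
#' @return Matrix of OOB error percentages, rows = tree counts, columns =
#'   mtry values, with dimnames; class `oob_grid`.
#' @export
oob_hyperparameter_grid <- function(scores, labels,
                                    trees_range = seq(100, 2000, by = 100),
                                    mtry_range = 1:30, n_reps = 5, seed = 1L) {
  x <- score_matrix(scores)
  labels <- as.factor(labels)
  if (!length(trees_range) || !length(mtry_range))
    stop_gbr("gbr_parameter_error", "hyperparameter ranges must be non-empty")
  if (max(mtry_range) > ncol(x))
    stop_gbr("gbr_parameter_error", "mtry_range max (%d) exceeds variable count (%d)",
             max(mtry_range), ncol(x))
  grid <- matrix(NA_real_, length(trees_range), length(mtry_range),
                 dimnames = list(trees = trees_range, mtry = mtry_range))
  for (a in seq_along(trees_range)) {
    for (b in seq_along(mtry_range)) {
      errs <- vapply(seq_len(n_reps), function(r) {
        set.seed(seed + 1000L * a + 10L * b + r)
        fit <- randomForest::randomForest(x = x, y = labels,
                                          ntree = trees_range[a],
                                          mtry = mtry_range[b])
        100 * fit$err.rate[trees_range[a], "OOB"]
      }, numeric(1))
      grid[a, b] <- mean(errs)
    }
  }
  structure(grid, class = c("oob_grid", "matrix"))
}

#' Full radio-sensitivity classification report
#'
#' Runs the standard evaluation: a stratified split, a forest fit at the
#' default hyperparameters, held-out confusion matrix and derived metrics,
#' OOB error, and mean-decrease-accuracy importance averaged over repeated
#' models.
#'
#' @param scores A `score_table`.
#' @param mapping Cell-line to class mapping.
#' @param n_trees,mtry,split_fraction,n_models,n_perm,seed See
#'   [train_random_forest()] and [mda_importance()].
#' @return An object of class `rf_report`: list with `confusion`, `metrics`
#'   (all orientations), `oob_error_pct`, `importance`, `settings`.
#' @export
classify_radiosensitivity <- function(scores,
                                      mapping = default_radio_class_map(),
                                      n_trees = 200, mtry = 5,
                                      split_fraction = 0.75, n_models = 10,
                                      n_perm = 10, seed = 1L) {
  labels <- assign_radio_class(scores, mapping)
  sp <- split_train_test(scores, labels, fraction = split_fraction, seed = seed)
  fit <- train_random_forest(sp$train, sp$train_labels, n_trees = n_trees,
                             mtry = mtry, seed = seed)
  cm <- evaluate_classifier(fit, sp$test, sp$test_labels)
  metrics <- do.call(rbind, lapply(rownames(cm), function(pos) {
    m <- confusion_metrics(cm, positive = pos)
    cbind(positive = pos, m)
  }))
  imp <- mda_importance(scores, labels, n_models = n_models,
                        split_fraction = split_fraction, n_trees = n_trees,
                        mtry = mtry, n_perm = n_perm, seed = seed)
  structure(list(confusion = cm, metrics = metrics,
                 oob_error_pct = attr(fit, "oob_error_pct"),
                 importance = imp,
                 settings = list(n_trees = n_trees, mtry = mtry,
                                 split_fraction = split_fraction,
                                 n_models = n_models, n_perm = n_perm,
                                 seed = seed,
                                 importance_seeds = attr(imp, "seeds"))),
            class = "rf_report")
}

#' @exportS3Method print rf_report
print.rf_report <- function(x, ...) {
  cat("<rf_report>\n")
  print(x$confusion)
  acc <- x$metrics[x$metrics$positive == rownames(x$confusion)[1] &
                     x$metrics$metric == "accuracy", "display"]
  cat(sprintf("test accuracy: %.1f%%; OOB error: %.1f%%\n",
              acc, x$oob_error_pct))
  cat("top variables (mean decrease accuracy):\n")
  print(utils::head(x$importance, 5))
  invisible(x)
}

#' Write an `rf_report` to disk (JSON report + CSV importance table)
#'
#' @param report An `rf_report`.
#' @param dir Output directory.
#' @export
write_rf_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(confusion = list(labels = rownames(report$confusion),
                          counts = unclass(report$confusion)),
         metrics = report$metrics,
         oob_error_pct = report$oob_error_pct,
         settings = report$settings),
    file.path(dir, "rf_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(report$importance, file.path(dir, "importance.csv"),
            row.names = FALSE)
  invisible(dir)
}
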