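test_that("radio-class assignment follows the line mapping and flags unknown lines", {
  meta <- tiny_meta(3)
  meta$cell_line <- c("H460", "MCF7", "LNCaP")
  lab <- assign_radio_class(meta)
  expect_equal(as.character(lab),
               c("radioresistant", "radioresistant", "radiosensitive"))
  expect_equal(levels(lab), c("radiosensitive", "radioresistant"))

  meta$cell_line[2] <- "PC3"
  err <- expect_error(assign_radio_class(meta),
                      class = "gbr_unmapped_line_error")
  expect_match(conditionMessage(err), "PC3")
})

test_that("stratified splits are exact partitions with preserved class balance", {
  y <- factor(rep(c("s", "r"), c(600, 400)))
  x <- matrix(rnorm(1000 * 3), 1000)
  colnames(x) <- paste0("v", 1:3)
  sp <- split_train_test(x, y, fraction = 0.75, seed = 42)
  expect_equal(length(sp$train_idx), 750)
  expect_equal(length(sp$test_idx), 250)
  expect_equal(sum(y[sp$train_idx] == "s"), 450)
  expect_equal(sum(y[sp$train_idx] == "r"), 300)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:1000)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- split_train_test(x, y, fraction = 0.75, seed = 42)
  expect_identical(sp$train_idx, sp2$train_idx)

  expect_error(split_train_test(x, y, fraction = 1.2),
               class = "gbr_parameter_error")
  expect_error(split_train_test(x[1:3, ], factor(c("a", "b", "b"))),
               class = "gbr_parameter_error")
})

test_that("the forest records its settings and separates separable classes", {
  d <- separable_scores(n_per_class = 80, n_vars = 8, n_informative = 2,
                        shift = 3, seed = 6)
  fit <- train_random_forest(d$x, d$y, n_trees = 200, mtry = 5, seed = 1)
  st <- attr(fit, "settings")
  expect_equal(st$n_trees, 200)
  expect_equal(st$mtry, 5)
  expect_lte(attr(fit, "oob_error_pct"), 1)

  # permuted labels: OOB accuracy near the majority-class share
  set.seed(7)
  yperm <- sample(d$y)
  fit0 <- train_random_forest(d$x, yperm, n_trees = 200, mtry = 3, seed = 2)
  oob_acc <- 100 - attr(fit0, "oob_error_pct")
  expect_lt(abs(oob_acc - 50), 7)

  expect_error(train_random_forest(d$x, factor(rep("a", nrow(d$x)))),
               class = "gbr_parameter_error")
  expect_error(train_random_forest(d$x, d$y, mtry = 100),
               class = "gbr_parameter_error")
})

test_that("held-out evaluation produces exact confusion counts", {
  d <- separable_scores(n_per_class = 100, n_vars = 6, shift = 6, seed = 3)
  sp <- split_train_test(d$x, d$y, seed = 5)
  fit <- train_random_forest(d$x[sp$train_idx, ], d$y[sp$train_idx], seed = 5)
  cm <- evaluate_classifier(fit, d$x[sp$test_idx, ], d$y[sp$test_idx])
  expect_equal(sum(cm), length(sp$test_idx))
  expect_gte(sum(diag(cm)) / sum(cm), 0.99)

  bad <- factor(rep("unknown", length(sp$test_idx)))
  expect_error(evaluate_classifier(fit, d$x[sp$test_idx, ], bad),
               class = "gbr_label_error")
})

test_that("confusion metrics match their defining formulas", {
  # printed-table worked example
  cm <- confusion_matrix(matrix(c(1066, 5, 0, 548), 2,
                                dimnames = list(c("radiosensitive", "radioresistant"),
                                                c("radiosensitive", "radioresistant"))))
  met <- confusion_metrics(cm, positive = "radiosensitive")
  get <- function(m) met$value_pct[met$metric == m]
  expect_equal(round(get("false_positive_share"), 1), 0.3)
  expect_equal(get("accuracy"), 100 * 1614 / 1619, tolerance = 1e-12)
  expect_equal(get("sensitivity"), 100)
  expect_equal(get("specificity"), 100 * 548 / 553, tolerance = 1e-12)

  # identities on random matrices
  set.seed(9)
  for (i in 1:20) {
    counts <- matrix(sample(0:50, 4, replace = TRUE), 2,
                     dimnames = list(c("p", "n"), c("p", "n")))
    if (sum(counts) == 0) next
    m <- confusion_metrics(confusion_matrix(counts), positive = "p")
    tp <- counts[1, 1]; fn <- counts[1, 2]; fp <- counts[2, 1]; tn <- counts[2, 2]
    expect_equal(m$value_pct[m$metric == "accuracy"],
                 100 * (tp + tn) / sum(counts))
    if (tp + fn > 0)
      expect_equal(m$value_pct[m$metric == "sensitivity"], 100 * tp / (tp + fn))
    else
      expect_true(is.na(m$value_pct[m$metric == "sensitivity"]))
  }

  perfect <- confusion_matrix(matrix(c(10, 0, 0, 20), 2,
                                     dimnames = list(c("p", "n"), c("p", "n"))))
  expect_equal(confusion_metrics(perfect)$value_pct[1], 100)
})

test_that("permutation importance finds planted signal and stays null on noise", {
  d <- separable_scores(n_per_class = 100, n_vars = 12, n_informative = 1,
                        shift = 3, seed = 10)
  imp <- mda_importance(d$x, d$y, n_models = 4, n_trees = 100, n_perm = 4,
                        seed = 11)
  expect_equal(nrow(imp), 12)
  expect_equal(imp$variable[1], "v1")
  expect_gt(imp$mda_mean[1], 5 * max(abs(imp$mda_mean[-1])))

  # all-noise variables: importance indistinguishable from zero
  set.seed(12)
  xn <- matrix(rnorm(160 * 6), 160)
  colnames(xn) <- paste0("n", 1:6)
  yn <- factor(rep(c("a", "b"), 80))
  imp0 <- mda_importance(xn, yn, n_models = 4, n_trees = 100, n_perm = 4,
                         seed = 13)
  expect_true(all(abs(imp0$mda_mean) <= pmax(2 * imp0$mda_sd, 0.05)))

  # a duplicated informative variable is not penalised below noise level
  xd <- cbind(d$x, v1_copy = d$x[, 1])
  impd <- mda_importance(xd, d$y, n_models = 4, n_trees = 100, n_perm = 4,
                         seed = 14)
  expect_gte(impd$mda_mean[impd$variable == "v1_copy"], 0)
  expect_lte(max(impd$rank[impd$variable %in% c("v1", "v1_copy")]), 2)
})

test_that("the OOB hyperparameter grid has range-driven shape and sane values", {
  d <- separable_scores(n_per_class = 40, n_vars = 8, n_informative = 2,
                        shift = 4, seed = 15)
  grid <- oob_hyperparameter_grid(d$x, d$y, trees_range = c(50, 100),
                                  mtry_range = c(2, 5), n_reps = 2, seed = 16)
  expect_equal(dim(grid), c(2, 2))
  expect_equal(dimnames(grid)$trees, c("50", "100"))
  expect_true(all(grid >= 0 & grid <= 100))
  expect_true(all(grid <= 5))   # separable classes: low OOB error everywhere

  expect_error(oob_hyperparameter_grid(d$x, d$y, mtry_range = 1:40),
               class = "gbr_parameter_error")
})
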