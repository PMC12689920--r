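# Exhaustive subset search, SVM grid, CV scheme and metrics.

test_that("the fast libsvm path agrees exactly with e1071::svm", {
  skip_if_not_installed("e1071")
  set.seed(42)
  kernels <- c(linear = "linear", rbf = "radial", poly = "polynomial")
  for (case in 1:60) {
    n <- sample(20:40, 1); p <- sample(1:6, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- sample(0:1, n, replace = TRUE)
    while (min(table(y)) < 2) y <- sample(0:1, n, replace = TRUE)
    kn <- sample(names(kernels), 1)
    g <- runif(1, 0.01, 1); dg <- sample(2:3, 1)
    C <- sample(c(0.01, 0.1, 1, 10, 100), 1)
    ref <- e1071::svm(x, factor(y), kernel = kernels[[kn]], cost = C,
                      gamma = g, degree = dg, coef0 = 0, scale = FALSE,
                      fitted = FALSE)
    xt <- matrix(rnorm(8 * p), 8, p)
    dv <- attr(predict(ref, xt, decision.values = TRUE), "decision.values")
    # orient the reference scores so positive favours class "1"
    ref_scores <- if (colnames(dv) == "1/0") dv[, 1] else -dv[, 1]
    fit <- pdcog:::svm_train_fast(x, y + 1L, kernels[[kn]], C, g, dg)
    expect_equal(unname(pdcog:::svm_decision_fast(fit, xt)),
                 unname(ref_scores), tolerance = 1e-8)
  }
})

test_that("rank-based AUC matches the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (case in 1:20) {
    n <- sample(10:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(0:1, n, replace = TRUE)
    s <- rnorm(n) + y
    if (case %% 3 == 0) s <- round(s)  # exercise ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(pdcog:::auc_rank(s, y == 1), ref, tolerance = 1e-12)
  }
})

test_that("the hyperparameter grid enumerates 65 configurations", {
  g <- svm_grid()
  expect_identical(nrow(g), 65L)
  expect_identical(sum(g$kernel == "linear"), 5L)
  expect_identical(sum(g$kernel == "rbf"), 20L)
  expect_identical(sum(g$kernel == "poly"), 40L)
  expect_true(all(is.na(g$gamma[g$kernel == "linear"])))
  expect_true(all(is.na(g$degree[g$kernel != "poly"])))
  expect_setequal(unique(g$C), c(0.01, 0.1, 1, 10, 100))
})

test_that("subset enumeration is lexicographic with binomial counts", {
  subs <- enumerate_subsets(letters[1:5], 2L)
  expect_identical(length(subs), 10L)
  expect_identical(subs[[1]], c("a", "b"))
  expect_identical(subs[[10]], c("d", "e"))
  expect_identical(enumerate_subsets(letters[1:4], 4L), list(letters[1:4]))
  expect_error(enumerate_subsets(letters[1:3], 4L), "size")
  expect_identical(n_subsets(50, 6), choose(50, 6))
  expect_identical(n_subsets(10, 1:2), 55)
})

test_that("classification metrics follow the confusion-count formulas", {
  perfect <- classification_metrics(5, 5, 0, 0)
  expect_identical(unlist(perfect), c(accuracy = 1, precision = 1,
                                      recall = 1, f1 = 1))
  m <- classification_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.60)
  expect_equal(m$f1, 0.6667, tolerance = 1e-4)
  degenerate <- classification_metrics(tp = 0, tn = 8, fp = 0, fn = 2)
  expect_identical(unlist(degenerate[c("precision", "recall", "f1")]),
                   c(precision = 0, recall = 0, f1 = 0))
  expect_error(classification_metrics(0, 0, 0, 0), "at least one")
  expect_error(classification_metrics(-1, 2, 0, 0), "non-negative")
})

test_that("stratified folds partition subjects with every class present", {
  labels <- rep(c(1L, 0L), c(20L, 18L))
  cv <- make_cv_folds(labels, n_folds = 10L, n_repeats = 3L, seed = 5L)
  expect_identical(length(cv$splits), 30L)
  for (r in 1:3) {
    splits <- Filter(function(s) s$repeat_id == r, cv$splits)
    test_all <- sort(unlist(lapply(splits, `[[`, "test")))
    expect_identical(test_all, seq_along(labels))
    for (s in splits) {
      expect_setequal(c(s$train, s$test), seq_along(labels))
      expect_true(all(table(labels[s$test]) >= 1))
    }
  }
  expect_identical(make_cv_folds(labels, 10, 2, seed = 1)$splits,
                   make_cv_folds(labels, 10, 2, seed = 1)$splits)
  expect_error(make_cv_folds(rep(c(0L, 1L), c(30L, 5L)), n_folds = 10L),
               "stratify")
})

test_that("a linearly separable subset scores perfectly", {
  tab <- separable_table(n = 40L, sep_sd = 0.05, seed = 4)
  cv <- make_cv_folds(tab$labels, 5L, 2L, seed = 3L)
  mr <- evaluate_subset(tab, "sep", cv)
  expect_equal(mr$accuracy, 1)
  expect_equal(mr$roc_auc, 1)
  expect_equal(mr$precision, 1)
  expect_equal(mr$f1, 1)
})

test_that("XOR structure defeats the linear kernel but not RBF", {
  tab <- withr::with_seed(14, {
    cl <- rep(0:3, each = 50)
    x1 <- ifelse(cl %in% c(0, 1), -1, 1) + rnorm(200, sd = 0.2)
    x2 <- ifelse(cl %in% c(0, 2), -1, 1) + rnorm(200, sd = 0.2)
    toy_table(cbind(f1 = x1, f2 = x2), as.integer(cl %in% c(1, 2)))
  })
  cv <- make_cv_folds(tab$labels, 5L, 1L, seed = 8L)
  mr <- evaluate_subset(tab, c("f1", "f2"), cv)
  g <- svm_grid()
  # a half-plane cannot resolve XOR: best linear accuracy is capped near
  # 0.625 (threshold freedom can sacrifice one corner cluster) while a
  # kernel model separates cleanly
  expect_lt(max(mr$grid_accuracy[g$kernel == "linear"]), 0.75)
  expect_gte(max(mr$grid_accuracy[g$kernel == "rbf"]), 0.9)
  expect_true(mr$kernel %in% c("rbf", "poly"))
  expect_gte(mr$accuracy, 0.9)
})

test_that("per-fold metrics re-derive from the stored confusion counts", {
  tab <- separable_table(n = 30L, sep_sd = 1.5, seed = 6)
  cv <- make_cv_folds(tab$labels, 5L, 2L, seed = 9L)
  mr <- evaluate_subset(tab, c("sep", "noise_01"), cv)
  pf <- mr$per_fold
  for (i in seq_len(nrow(pf))) {
    m <- classification_metrics(pf$tp[i], pf$tn[i], pf$fp[i], pf$fn[i])
    expect_equal(pf$accuracy[i], m$accuracy)
    expect_equal(pf$precision[i], m$precision)
    expect_equal(pf$recall[i], m$recall)
    expect_equal(pf$f1[i], m$f1)
  }
  expect_equal(mr$accuracy, mean(pf$accuracy))
  expect_equal(mr$roc_auc, mean(pf$roc_auc))
  expect_true(all(unlist(pf[, c("accuracy", "precision", "recall", "f1")]) >= 0))
  expect_true(all(unlist(pf[, c("accuracy", "precision", "recall", "f1")]) <= 1))
})

test_that("a jointly separating pair wins the size-2 search", {
  tab <- withr::with_seed(20, {
    n <- 60L
    f1 <- rnorm(n); f2 <- rnorm(n)
    labels <- as.integer(f1 + f2 + rnorm(n, sd = 0.3) > 0)
    features <- cbind(f1 = f1, f2 = f2, matrix(rnorm(n * 6), n, 6))
    colnames(features) <- c("f1", "f2", sprintf("n%02d", 1:6))
    toy_table(features, labels)
  })
  sr <- subset_search(tab, colnames(tab$features), max_size = 2L,
                      n_folds = 5L, n_repeats = 2L, seed = 2L,
                      verbose = FALSE)
  expect_setequal(sr$models[[2]]$subset, c("f1", "f2"))
  # monotone trend: the richer model does not do worse
  expect_gte(sr$summary$accuracy[2], sr$summary$accuracy[1] - 0.02)
})

test_that("the search is deterministic and worker-count invariant", {
  tab <- separable_table(n = 30L, n_noise = 5L, sep_sd = 1, seed = 10)
  run <- function(workers) {
    subset_search(tab, colnames(tab$features), max_size = 2L, n_folds = 5L,
                  n_repeats = 2L, seed = 6L, n_workers = workers,
                  verbose = FALSE)
  }
  s1 <- run(1L)
  s2 <- run(2L)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$models[[2]]$per_fold, s2$models[[2]]$per_fold)
})

test_that("checkpoints resume a search without re-evaluation", {
  tab <- separable_table(n = 24L, n_noise = 3L, seed = 12)
  dir <- withr::local_tempdir()
  s1 <- subset_search(tab, colnames(tab$features), max_size = 2L,
                      n_folds = 4L, n_repeats = 1L, seed = 3L,
                      checkpoint_dir = dir, verbose = FALSE)
  expect_true(file.exists(file.path(dir, "search_size_01.rds")))
  msgs <- capture_messages(
    s2 <- subset_search(tab, colnames(tab$features), max_size = 2L,
                        n_folds = 4L, n_repeats = 1L, seed = 3L,
                        checkpoint_dir = dir, verbose = TRUE))
  expect_true(any(grepl("restored from checkpoint", msgs)))
  expect_identical(s1$summary, s2$summary)
})

test_that("the pre-run cost estimate reports the full enumeration", {
  tab <- separable_table(n = 20L, n_noise = 9L, seed = 13)
  msgs <- capture_messages(
    subset_search(tab, colnames(tab$features), max_size = 2L, n_folds = 4L,
                  n_repeats = 1L, seed = 1L, grid = svm_grid("linear"),
                  verbose = TRUE))
  expect_true(any(grepl("55 subsets", msgs)))   # C(10,1) + C(10,2)
})
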