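# Exhaustive feature-subset search over ranked candidates with an SVM
# kernel/hyperparameter grid under repeated stratified k-fold
# cross-validation.

#' SVM hyperparameter grid
#'
#' The default grid is 65 configurations: a linear kernel over
#' C in \{0.01, 0.1, 1, 10, 100\} (5), an RBF kernel over the same C
#' crossed with gamma in \{1e-3, 1e-2, 1e-1, "scale"\} (20), and a
#' polynomial kernel additionally crossed with degree in \{2, 3\} (40).
#' `"scale"` gamma resolves per training fold to
#' `1 / (n_features * var(X_train))` with `var` the pooled variance of
#' all training entries. Row order is fixed and is the final tie-break
#' of model selection.
#'
#' @param kernels,costs,gammas,degrees grid axes; `gammas` may mix
#'   numbers and the string `"scale"`.
#' @return data frame with columns `kernel`, `C`, `gamma`, `degree`.
#' @export
svm_grid <- function(kernels = c("linear", "rbf", "poly"),
                     costs = c(0.01, 0.1, 1, 10, 100),
                     gammas = c("0.001", "0.01", "0.1", "scale"),
                     degrees = c(2L, 3L)) {
  rows <- list()
  if ("linear" %in% kernels) {
    rows$linear <- data.frame(kernel = "linear", C = costs,
                              gamma = NA_character_, degree = NA_integer_,
                              stringsAsFactors = FALSE)
  }
  if ("rbf" %in% kernels) {
    g <- expand.grid(gamma = as.character(gammas), C = costs,
                     stringsAsFactors = FALSE)
    rows$rbf <- data.frame(kernel = "rbf", C = g$C, gamma = g$gamma,
                           degree = NA_integer_, stringsAsFactors = FALSE)
  }
  if ("poly" %in% kernels) {
    g <- expand.grid(degree = as.integer(degrees),
                     gamma = as.character(gammas), C = costs,
                     stringsAsFactors = FALSE)
    rows$poly <- data.frame(kernel = "poly", C = g$C, gamma = g$gamma,
                            degree = g$degree, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' Enumerate feature subsets of a given size
#'
#' Yields all `choose(n, size)` subsets of the candidate vector in
#' lexicographic order of candidate indices (the order `utils::combn()`
#' produces), which fixes the subset-level tie-break of the search.
#'
#' @param candidates vector of candidate features.
#' @param size subset size, `1 <= size <= length(candidates)`.
#' @return list of subsets (each a vector like `candidates`).
#' @export
#' @examples
#' length(enumerate_subsets(letters[1:5], 2))  # 10
enumerate_subsets <- function(candidates, size) {
  n <- length(candidates)
  if (!is_count(size, 1L) || size > n) {
    stop("size must be an integer in [1, ", n, "]")
  }
  idx <- utils::combn(n, size)
  lapply(seq_len(ncol(idx)), function(j) candidates[idx[, j]])
}

#' Number of subsets evaluated up to a maximum size
#' @param n candidate count.
#' @param sizes subset sizes (default `1:max_size` style vector).
#' @return total count `sum(choose(n, sizes))`.
#' @export
#' @examples
#' n_subsets(50, 6)    # 15,890,700
#' n_subsets(10, 1:2)  # 55
n_subsets <- function(n, sizes) sum(choose(n, sizes))

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and the F1 score (harmonic mean of precision and
#' recall). Degenerate denominators follow the usual conventions:
#' precision and recall are 0 when their denominator is 0, and F1 is 0
#' when precision + recall is 0. The positive class is PD-CD: TP counts
#' impaired patients flagged by both the MoCA label and the model.
#'
#' @param tp,tn,fp,fn non-negative confusion counts, total >= 1.
#' @return named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' classification_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one observation is required")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall, f1 = f1)
}

#' Repeated stratified k-fold cross-validation scheme
#'
#' Fold assignments are drawn once per (seed, repeat) and shared across
#' every subset and grid configuration evaluated under the scheme, so
#' all model comparisons are paired. Stratification deals each class
#' round-robin; every class must have at least `n_folds` members so that
#' every fold contains both classes.
#'
#' @param labels 0/1 class labels.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 10).
#' @param seed RNG seed of the assignment.
#' @return object of class `cv_scheme`: list of `splits` (train/test
#'   index pairs, `n_folds * n_repeats` of them) plus the scheme
#'   parameters.
#' @export
make_cv_folds <- function(labels, n_folds = 10L, n_repeats = 10L, seed = 1L) {
  stopifnot(is_count(n_folds, 2L), is_count(n_repeats, 1L))
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  if (min(tab) < n_folds) {
    stop("smallest class has ", min(tab), " subjects; cannot stratify into ",
         n_folds, " folds with every class in every fold")
  }
  y <- as.integer(labels) + 1L
  splits <- with_local_seed(seed, {
    out <- vector("list", n_folds * n_repeats)
    s <- 0L
    for (r in seq_len(n_repeats)) {
      ids <- stratified_fold_ids(y, n_folds)
      for (f in seq_len(n_folds)) {
        s <- s + 1L
        out[[s]] <- list(train = which(ids != f), test = which(ids == f),
                         repeat_id = r, fold_id = f)
      }
    }
    out
  })
  structure(list(splits = splits, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' @noRd
kernel_internal <- c(linear = "linear", rbf = "radial", poly = "polynomial")

#' @noRd
prepare_splits <- function(x, y, cv, normalize) {
  lapply(cv$splits, function(sp) {
    xtr <- x[sp$train, , drop = FALSE]
    xte <- x[sp$test, , drop = FALSE]
    if (normalize) {
      sc <- apply(xtr, 2L, stats::sd)
      sc[sc == 0] <- 1  # constant-in-fold feature carries no information
      fit_z <- list(center = colMeans(xtr), scale = sc)
      xtr <- zscore_apply(fit_z, xtr)
      xte <- zscore_apply(fit_z, xte)
    }
    list(xtr = xtr, ytr = y[sp$train], xte = xte, pos = y[sp$test] == 2L,
         gamma_scale = 1 / (ncol(xtr) * mean((xtr - mean(xtr))^2)),
         repeat_id = sp$repeat_id, fold_id = sp$fold_id)
  })
}

#' @noRd
config_means <- function(splits, grid) {
  ns <- length(splits)
  acc <- auc <- matrix(NA_real_, nrow(grid), ns)
  for (ci in seq_len(nrow(grid))) {
    kern <- kernel_internal[[grid$kernel[ci]]]
    cost <- grid$C[ci]
    degree <- if (is.na(grid$degree[ci])) 3L else grid$degree[ci]
    g_spec <- grid$gamma[ci]
    for (si in seq_len(ns)) {
      sp <- splits[[si]]
      gamma <- if (kern == "linear") 0
               else if (identical(g_spec, "scale")) sp$gamma_scale
               else as.numeric(g_spec)
      fit <- svm_train_fast(sp$xtr, sp$ytr, kern, cost, gamma, degree)
      s <- svm_decision_fast(fit, sp$xte)
      pred_pos <- s > 0
      acc[ci, si] <- mean(pred_pos == sp$pos)
      auc[ci, si] <- auc_rank(s, sp$pos)
    }
  }
  list(acc = rowMeans(acc), auc = rowMeans(auc),
       acc_folds = acc, auc_folds = auc)
}

#' Evaluate one feature subset over the whole hyperparameter grid
#'
#' Every grid configuration is scored on the same fold assignments; the
#' configuration with the highest mean accuracy wins (ties: higher mean
#' per-fold ROC-AUC, then earlier grid row). Metrics are means of
#' per-fold values; ROC-AUC is the mean of per-fold AUCs computed from
#' decision scores. Per-fold confusion counts of the winning
#' configuration are retained.
#'
#' @param table a normalized cohort table.
#' @param subset feature names (or column indices) to evaluate.
#' @param cv a [make_cv_folds()] scheme on the table's labels.
#' @param grid an [svm_grid()].
#' @return object of class `model_result`: winning configuration, mean
#'   `accuracy`, `precision`, `recall`, `f1`, `roc_auc`, and a
#'   `per_fold` data frame with raw confusion counts and per-fold
#'   metrics.
#' @export
evaluate_subset <- function(table, subset, cv, grid = svm_grid()) {
  stopifnot(inherits(table, "cohort_table"), inherits(cv, "cv_scheme"))
  if (is.character(subset)) {
    missing <- setdiff(subset, colnames(table$features))
    if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
  }
  x <- table$features[, subset, drop = FALSE]
  y <- table$labels + 1L
  normalize <- identical(table$normalization, "per_training_fold")
  splits <- prepare_splits(x, y, cv, normalize)
  cm <- config_means(splits, grid)
  best <- order(-cm$acc, -cm$auc, seq_len(nrow(grid)))[1L]

  # Detailed per-fold pass for the winning configuration.
  kern <- kernel_internal[[grid$kernel[best]]]
  degree <- if (is.na(grid$degree[best])) 3L else grid$degree[best]
  g_spec <- grid$gamma[best]
  per_fold <- do.call(rbind, lapply(splits, function(sp) {
    gamma <- if (kern == "linear") 0
             else if (identical(g_spec, "scale")) sp$gamma_scale
             else as.numeric(g_spec)
    fit <- svm_train_fast(sp$xtr, sp$ytr, kern, grid$C[best], gamma, degree)
    s <- svm_decision_fast(fit, sp$xte)
    pred_pos <- s > 0
    tp <- sum(pred_pos & sp$pos); tn <- sum(!pred_pos & !sp$pos)
    fp <- sum(pred_pos & !sp$pos); fn <- sum(!pred_pos & sp$pos)
    m <- classification_metrics(tp, tn, fp, fn)
    data.frame(repeat_id = sp$repeat_id, fold_id = sp$fold_id,
               tp = tp, tn = tn, fp = fp, fn = fn,
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1,
               roc_auc = auc_rank(s, sp$pos))
  }))
  structure(list(
    subset = if (is.character(subset)) subset else colnames(table$features)[subset],
    kernel = grid$kernel[best], C = grid$C[best], gamma = grid$gamma[best],
    degree = grid$degree[best], config_index = best,
    accuracy = mean(per_fold$accuracy), precision = mean(per_fold$precision),
    recall = mean(per_fold$recall), f1 = mean(per_fold$f1),
    roc_auc = mean(per_fold$roc_auc),
    grid_accuracy = cm$acc, grid_roc_auc = cm$auc,
    per_fold = per_fold
  ), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result: {%s} %s C=%g%s | acc %.3f, auc %.3f>\n",
              paste(x$subset, collapse = ", "), x$kernel, x$C,
              if (!is.na(x$gamma)) paste0(" gamma=", x$gamma) else "",
              x$accuracy, x$roc_auc))
  invisible(x)
}

#' Exhaustive subset search over ranked candidates
#'
#' Evaluates every subset of `candidates` of size 1..`max_size` under
#' the full hyperparameter grid and repeated stratified k-fold CV, and
#' reports the best model per subset size (highest mean accuracy; ties
#' broken by higher mean ROC-AUC, then lexicographic subset order, then
#' grid order). Fold assignments are fixed by `seed` and shared by every
#' candidate model, so the comparison is paired and the result is
#' independent of the number of workers.
#'
#' @param table a normalized cohort table.
#' @param candidates candidate feature names, e.g. the `top_k_list` of a
#'   [rank_features()] ranking.
#' @param max_size largest subset size (default 6).
#' @param grid an [svm_grid()].
#' @param n_folds,n_repeats,seed the CV scheme (defaults 10, 10).
#' @param n_workers parallel workers over subsets (fork-based; results
#'   are identical for any worker count).
#' @param checkpoint_dir optional directory; each completed subset-size
#'   block is saved there and re-used when the search is re-run.
#' @param verbose print the pre-run cost estimate and per-size progress.
#' @return object of class `search_result`: data frame `summary` (one
#'   row per size: `n`, `features`, `kernel`, `C`, `gamma`, `degree`,
#'   `accuracy`, `precision`, `recall`, `f1`, `roc_auc`) plus the full
#'   [evaluate_subset()] results in `models`.
#' @export
subset_search <- function(table, candidates, max_size = 6L, grid = svm_grid(),
                          n_folds = 10L, n_repeats = 10L, seed = 1L,
                          n_workers = 1L, checkpoint_dir = NULL,
                          verbose = TRUE) {
  stopifnot(inherits(table, "cohort_table"))
  candidates <- as.character(candidates)
  if (max_size > length(candidates)) {
    stop("max_size (", max_size, ") exceeds the number of candidates (",
         length(candidates), ")")
  }
  missing <- setdiff(candidates, colnames(table$features))
  if (length(missing)) stop("unknown candidate features: ",
                            paste(missing, collapse = ", "))
  cv <- make_cv_folds(table$labels, n_folds, n_repeats, seed)
  n_sub <- n_subsets(length(candidates), seq_len(max_size))
  n_fits <- n_sub * nrow(grid) * length(cv$splits)
  if (verbose) {
    message(sprintf(
      "subset search: %s subsets (sizes 1-%d of %d candidates) x %d configurations x %d folds = %s SVM fits",
      format(n_sub, big.mark = ","), max_size, length(candidates),
      nrow(grid), length(cv$splits), format(n_fits, big.mark = ",")))
  }

  x_all <- table$features[, candidates, drop = FALSE]
  y <- table$labels + 1L
  normalize <- identical(table$normalization, "per_training_fold")

  score_subset <- function(cols) {
    splits <- prepare_splits(x_all[, cols, drop = FALSE], y, cv, normalize)
    cm <- config_means(splits, grid)
    best <- order(-cm$acc, -cm$auc, seq_len(nrow(grid)))[1L]
    c(acc = cm$acc[best], auc = cm$auc[best], cfg = best)
  }

  models <- vector("list", max_size)
  for (size in seq_len(max_size)) {
    ck <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("search_size_%02d.rds", size))
    }
    if (!is.null(ck) && file.exists(ck)) {
      models[[size]] <- readRDS(ck)
      if (verbose) message("size ", size, ": restored from checkpoint")
      next
    }
    idx <- utils::combn(length(candidates), size)
    cols_list <- lapply(seq_len(ncol(idx)), function(j) idx[, j])
    scores <- if (n_workers > 1L) {
      parallel::mclapply(cols_list, score_subset, mc.cores = n_workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(cols_list, score_subset)
    }
    scores <- do.call(rbind, scores)
    best_j <- order(-scores[, "acc"], -scores[, "auc"],
                    seq_len(nrow(scores)))[1L]
    models[[size]] <- evaluate_subset(table, candidates[cols_list[[best_j]]],
                                      cv, grid)
    if (!is.null(ck)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(models[[size]], ck)
    }
    if (verbose) {
      message(sprintf("size %d: best {%s} acc %.3f auc %.3f", size,
                      paste(models[[size]]$subset, collapse = ", "),
                      models[[size]]$accuracy, models[[size]]$roc_auc))
    }
  }

  summary <- do.call(rbind, lapply(seq_len(max_size), function(size) {
    m <- models[[size]]
    data.frame(n = size, features = paste(m$subset, collapse = ";"),
               kernel = m$kernel, C = m$C, gamma = m$gamma, degree = m$degree,
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, roc_auc = m$roc_auc,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, models = models, candidates = candidates,
                 cv = cv, seed = as.integer(seed)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a search summary to CSV (one row per subset size)
#' @param result a `search_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_search_result <- function(result, path) {
  stopifnot(inherits(result, "search_result"))
  utils::write.csv(result$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
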