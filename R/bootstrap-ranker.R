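# Bootstrapped greedy forward feature selection: B iterations of
# random-order greedy selection accepted on cross-validated ROC-AUC of a
# linear SVM, aggregated into per-feature selection frequencies.

#' Configuration of the bootstrap feature ranker
#'
#' @param n_iterations number of bootstrap iterations B (default 1000).
#' @param inner_cv_folds folds of the inner cross-validation that scores
#'   each candidate addition (default 5).
#' @param top_k length of the candidate list derived from the ranking
#'   (default 50).
#' @param resample_subjects draw a with-replacement bootstrap resample of
#'   subjects each iteration (default TRUE); `FALSE` reproduces the pure
#'   random-feature-order reading, where only the feature order and CV
#'   folds are randomized.
#' @param accept_first_above ROC-AUC an empty model is credited with; the
#'   first feature is accepted only if it beats this chance level
#'   (default 0.5).
#' @param inner_cost linear-SVM regularization C of the inner classifier
#'   (default 1).
#' @param max_redraws bounded retries when a bootstrap resample misses a
#'   class (default 100).
#' @param seed master seed; per-iteration streams are derived from it.
#' @return an object of class `ranker_config`.
#' @export
ranker_config <- function(n_iterations = 1000L, inner_cv_folds = 5L,
                          top_k = 50L, resample_subjects = TRUE,
                          accept_first_above = 0.5, inner_cost = 1,
                          max_redraws = 100L, seed = 1L) {
  stopifnot(is_count(n_iterations, 1L), is_count(inner_cv_folds, 2L),
            is_count(top_k, 1L), is.logical(resample_subjects))
  structure(list(n_iterations = as.integer(n_iterations),
                 inner_cv_folds = as.integer(inner_cv_folds),
                 top_k = as.integer(top_k),
                 resample_subjects = isTRUE(resample_subjects),
                 accept_first_above = accept_first_above,
                 inner_cost = inner_cost,
                 max_redraws = as.integer(max_redraws),
                 seed = as.integer(seed)),
            class = "ranker_config")
}

#' One greedy random-order forward-selection iteration
#'
#' Starts from an empty feature set and walks a random permutation of the
#' feature pool. Each candidate is scored by the mean per-fold ROC-AUC of
#' a linear SVM over a stratified inner cross-validation of the
#' (optionally resampled) subjects; a candidate is kept only if it
#' strictly increases the best ROC-AUC so far, so the accepted trajectory
#' is strictly increasing. Every feature is considered at most once.
#'
#' @param table a normalized [assemble_features()] cohort table.
#' @param config a [ranker_config()].
#' @param iteration_seed seed of this iteration's RNG stream (resample,
#'   feature order and fold assignment all derive from it).
#' @return list with `accepted` (feature names in acceptance order),
#'   `auc_trajectory` (ROC-AUC after each acceptance), `resample`
#'   (subject indices used).
#' @export
greedy_iteration <- function(table, config, iteration_seed) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "ranker_config"))
  x_all <- table$features
  y_all <- table$labels + 1L       # 1 = PD-ND, 2 = PD-CD (positive)
  p <- ncol(x_all)
  if (p == 0L) {
    return(list(accepted = character(0), auc_trajectory = numeric(0),
                resample = seq_along(y_all)))
  }
  normalize <- identical(table$normalization, "per_training_fold")
  with_local_seed(iteration_seed, {
    n <- length(y_all)
    if (config$resample_subjects) {
      idx <- NULL
      for (try in seq_len(config$max_redraws)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (min(tabulate(y_all[cand], 2L)) >= 2L) { idx <- cand; break }
      }
      if (is.null(idx)) {
        stop("could not draw a bootstrap resample containing both classes ",
             "after ", config$max_redraws, " attempts")
      }
    } else {
      idx <- seq_len(n)
    }
    x <- x_all[idx, , drop = FALSE]
    y <- y_all[idx]
    fold_ids <- stratified_fold_ids(y, config$inner_cv_folds)
    order <- sample.int(p)

    accepted <- integer(0)
    trajectory <- numeric(0)
    best <- config$accept_first_above
    for (f in order) {
      cols <- c(accepted, f)
      xs <- x[, cols, drop = FALSE]
      auc <- cv_auc_maybe_normalized(xs, y, fold_ids, config$inner_cost,
                                     normalize)
      if (!is.na(auc) && auc > best) {
        accepted <- cols
        trajectory <- c(trajectory, auc)
        best <- auc
      }
    }
    list(accepted = colnames(x_all)[accepted],
         auc_trajectory = trajectory, resample = idx)
  })
}

#' @noRd
cv_auc_maybe_normalized <- function(x, y, fold_ids, cost, normalize) {
  if (!normalize) return(svm_cv_auc(x, y, fold_ids, cost))
  k <- max(fold_ids)
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- fold_ids == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L || !any(test)) next
    xtr <- x[!test, , drop = FALSE]
    sc <- apply(xtr, 2L, stats::sd)
    if (any(sc == 0)) next
    fit_z <- list(center = colMeans(xtr), scale = sc)
    m <- svm_train_fast(zscore_apply(fit_z, xtr), ytr, "linear", cost)
    scores <- svm_decision_fast(m, zscore_apply(fit_z, x[test, , drop = FALSE]))
    aucs[f] <- auc_rank(scores, y[test] == 2L)
  }
  if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
}

#' Rank features by bootstrap selection frequency
#'
#' Runs [greedy_iteration()] `B` times with per-iteration seeds derived
#' from the master seed and aggregates how often each feature was
#' accepted. Features are ordered by descending count with ties broken by
#' ascending feature name, so the ranking is deterministic across
#' platforms.
#'
#' @param table a normalized cohort table.
#' @param config a [ranker_config()].
#' @param keep_iterations keep each iteration's accepted sequence in the
#'   result (default TRUE; the audit record behind the monotone-AUC
#'   property).
#' @return object of class `selection_ranking`: list with `ranking` (data
#'   frame `feature`, `count`, `rank`), `top_k_list`, `n_iterations`,
#'   `config`, and optionally `iterations`.
#' @export
rank_features <- function(table, config = ranker_config(),
                          keep_iterations = TRUE) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "ranker_config"))
  seeds <- derive_seeds(config$seed, config$n_iterations, salt = 101L)
  iterations <- lapply(seeds, function(s) greedy_iteration(table, config, s))
  features <- colnames(table$features)
  counts <- table(factor(unlist(lapply(iterations, `[[`, "accepted")),
                         levels = features))
  ord <- order(-as.integer(counts), features)
  ranking <- data.frame(feature = features[ord],
                        count = as.integer(counts)[ord],
                        rank = seq_along(features),
                        stringsAsFactors = FALSE)
  structure(list(
    ranking = ranking,
    top_k_list = ranking$feature[seq_len(min(config$top_k, nrow(ranking)))],
    n_iterations = config$n_iterations,
    config = config,
    iterations = if (keep_iterations) iterations else NULL
  ), class = "selection_ranking")
}

#' @export
print.selection_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<selection_ranking: %d features over %d bootstrap iterations>\n",
              nrow(x$ranking), x$n_iterations))
  print(utils::head(x$ranking, n))
  invisible(x)
}

#' Write a ranking to CSV (`feature`, `count`, `rank`)
#' @param ranking a `selection_ranking`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "selection_ranking"))
  utils::write.csv(ranking$ranking, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
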