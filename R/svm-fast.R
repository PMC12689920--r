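# Low-overhead binary SVM training for the repeated tiny fits in the
# bootstrap ranker and the exhaustive subset search.
#
# Both stages fit hundreds of thousands of support vector machines on
# samples of a few dozen subjects. `e1071::svm()` carries ~0.5 ms of R-side
# bookkeeping (data.frame conversion, NA handling, fitted values) per call,
# which dominates the actual libsvm solve at this problem size. The trainer
# below invokes the same compiled libsvm routine that e1071 registers
# (`svmtrain`), restricted to the one case the pipeline needs: dense binary
# C-classification. Decision values are reconstructed from the returned
# support vectors and coefficients. Agreement with `e1071::svm()` +
# `predict()` is exact and is asserted in the test suite.

.pdcog <- new.env(parent = emptyenv())

svmtrain_symbol <- function() {
  if (is.null(.pdcog$svmtrain)) {
    # e1071 is an Import, so its DLL is loaded with this package.
    .pdcog$svmtrain <- getNativeSymbolInfo("svmtrain", "e1071")
  }
  .pdcog$svmtrain
}

SVM_KERNEL_CODES <- c(linear = 0L, polynomial = 1L, radial = 2L)

#' Train a binary C-classification SVM via e1071's compiled libsvm
#'
#' @param x numeric matrix (subjects x features), already on model scale.
#' @param y integer class codes: 1 = negative class, 2 = positive class.
#'   Both classes must be present.
#' @param kernel one of "linear", "polynomial", "radial".
#' @param cost,gamma,degree,coef0 libsvm hyperparameters; `gamma` is ignored
#'   for the linear kernel.
#' @return list with support vectors, dual coefficients, rho and kernel
#'   parameters; scores from [svm_decision_fast()] are oriented so that
#'   positive values favour class code 2.
#' @noRd
svm_train_fast <- function(x, y, kernel, cost, gamma = 0, degree = 3L, coef0 = 0) {
  nr <- nrow(x)
  empty_err <- strrep(" ", 255L)
  cret <- .C(svmtrain_symbol(),
    as.double(t(x)), as.integer(nr), as.integer(ncol(x)), as.double(y),
    as.integer(0L), as.integer(0L),            # sparse index slots (unused)
    as.integer(0L),                            # svm type: C-classification
    as.integer(SVM_KERNEL_CODES[[kernel]]),
    as.integer(degree), as.double(gamma), as.double(coef0),
    as.double(cost), as.double(0.5),           # cost, nu (unused)
    as.integer(0L), as.double(0), as.integer(0L),  # no class weights
    as.double(40), as.double(0.001), as.double(0.1),  # cachesize, tol, eps
    as.integer(1L),                            # shrinking
    as.integer(0L), as.integer(0L), as.integer(0L),  # cross, sparse, prob
    nclasses = integer(1L), nr = integer(1L), index = integer(nr),
    labels = integer(2L), nSV = integer(2L), rho = double(1L),
    coefs = double(nr), sigma = double(1L), probA = double(1L),
    probB = double(1L), cresults = double(0L), ctotal1 = double(1L),
    ctotal2 = double(1L), error = empty_err)
  if (cret$error != empty_err) {
    stop("libsvm: ", trimws(cret$error), call. = FALSE)
  }
  if (cret$nclasses != 2L) {
    stop("svm_train_fast() requires both classes in the training data",
         call. = FALSE)
  }
  idx <- cret$index[seq_len(cret$nr)]
  list(
    sv = x[idx, , drop = FALSE],
    coefs = cret$coefs[seq_len(cret$nr)],
    rho = cret$rho[1L],
    positive_first = cret$labels[1L] == 2L,
    kernel = kernel, gamma = gamma, degree = degree, coef0 = coef0
  )
}

#' Decision scores of a [svm_train_fast()] model, positive = class code 2
#' @noRd
svm_decision_fast <- function(fit, newx) {
  K <- switch(fit$kernel,
    linear = tcrossprod(newx, fit$sv),
    radial = {
      d2 <- outer(rowSums(newx^2), rowSums(fit$sv^2), "+") -
        2 * tcrossprod(newx, fit$sv)
      exp(-fit$gamma * pmax(d2, 0))
    },
    polynomial = (fit$gamma * tcrossprod(newx, fit$sv) + fit$coef0)^fit$degree
  )
  s <- drop(K %*% fit$coefs) - fit$rho
  if (fit$positive_first) s else -s
}

#' Mean per-fold ROC-AUC of a linear SVM over fixed CV folds
#'
#' Workhorse of the greedy bootstrap ranker. Folds whose training split
#' lacks a class, or whose test split is single-class, contribute NA and
#' are dropped from the mean.
#' @noRd
svm_cv_auc <- function(x, y, fold_ids, cost = 1) {
  k <- max(fold_ids)
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- fold_ids == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L || !any(test)) next
    fit <- svm_train_fast(x[!test, , drop = FALSE], ytr,
                          kernel = "linear", cost = cost)
    scores <- svm_decision_fast(fit, x[test, , drop = FALSE])
    aucs[f] <- auc_rank(scores, y[test] == 2L)
  }
  if (all(is.na(aucs))) return(NA_real_)
  mean(aucs, na.rm = TRUE)
}
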