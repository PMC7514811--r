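#' Cross-validated SVM classification on a precomputed kernel
#'
#' The evaluation protocol used throughout the package: a C-support
#' vector machine on the precomputed Gram matrix, 10-fold
#' cross-validation with the regularisation constant `C` tuned
#' independently for each held-out fold by an inner cross-validation on
#' the training folds only, repeated over `reps` random stratified
#' partitions.  Reported as mean accuracy with its standard error
#' (`sd / sqrt(reps)`).
#'
#' Partitions are stratified by class; when the smallest class has
#' fewer members than `folds`, stratification is relaxed with a
#' warning.  Indefinite kernel matrices (possible for the standard,
#' non-pd variant) are passed to the SVM as-is by default;
#' `clip = TRUE` projects the matrix onto the positive semi-definite
#' cone by clipping negative eigenvalues first.
#'
#' @param km a `qw_gram` or plain symmetric kernel matrix.
#' @param labels class labels, one per graph (2 or more classes).
#' @param folds number of outer folds (default 10).
#' @param reps number of repeated random partitions (default 100).
#' @param c_grid candidate values for `C` (default `10^(-3:3)`).
#' @param seed integer seed controlling all partitions.
#' @param inner_folds folds of the inner tuning loop (default 5).
#' @param clip spectrally clip the kernel matrix to PSD first.
#' @return an object of class `qw_cv_result` with fields
#'   `per_repetition_accuracies`, `mean_accuracy`, `standard_error` and
#'   `config`.
#' @export
cross_validate <- function(km, labels, folds = 10, reps = 100,
                           c_grid = 10^(-3:3), seed = 1,
                           inner_folds = 5, clip = FALSE) {
  K <- unclass(km)
  K <- matrix(as.numeric(K), nrow(K), ncol(K))
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  if (anyNA(K)) stop("kernel matrix contains missing values")
  y <- factor(labels)
  if (length(y) != nrow(K))
    stop("labels length must match the kernel matrix")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (clip) {
    e <- eigen(K, symmetric = TRUE)
    K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    K <- (K + t(K)) / 2
  } else {
    mineig <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (mineig < -1e-8)
      message(sprintf(
        "note: kernel matrix is indefinite (min eigenvalue %.3e); %s",
        mineig, "pass clip = TRUE to project onto the PSD cone"))
  }
  stratify <- TRUE
  if (min(table(y)) < folds) {
    warning("smallest class has fewer members than folds; ",
            "stratification relaxed")
    stratify <- FALSE
  }
  accs <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      fold_of <- assign_folds(y, folds, stratify)
      correct <- 0L
      for (f in seq_len(folds)) {
        te <- which(fold_of == f)
        tr <- which(fold_of != f)
        if (length(te) == 0) next
        C_best <- tune_C(K, y, tr, c_grid, inner_folds)
        pred <- svm_fit_predict(K, y, tr, te, C_best)
        correct <- correct + sum(pred == y[te])
      }
      correct / length(y)
    }, numeric(1))
  })
  structure(
    list(per_repetition_accuracies = accs,
         mean_accuracy = mean(accs),
         standard_error = stats::sd(accs) / sqrt(reps),
         config = list(folds = folds, reps = reps, c_grid = c_grid,
                       seed = seed, inner_folds = inner_folds,
                       clip = clip)),
    class = "qw_cv_result"
  )
}

# Random (stratified) fold assignment; uses the current RNG stream.
assign_folds <- function(y, folds, stratify = TRUE) {
  n <- length(y)
  fold_of <- integer(n)
  if (stratify) {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold_of[sample(n)] <- rep_len(seq_len(folds), n)
  }
  fold_of
}

# Inner CV over the training rows only; returns the C with the best
# mean inner accuracy (ties broken toward the smallest C).
tune_C <- function(K, y, tr, c_grid, inner_folds) {
  ytr <- droplevels(y[tr])
  nf <- min(inner_folds, min(table(ytr)))
  if (nf < 2) return(c_grid[1])
  inner_fold <- assign_folds(ytr, nf, stratify = TRUE)
  scores <- vapply(c_grid, function(C) {
    correct <- 0L
    for (f in seq_len(nf)) {
      ite <- tr[inner_fold == f]
      itr <- tr[inner_fold != f]
      if (length(unique(y[itr])) < 2) next
      pred <- svm_fit_predict(K, y, itr, ite, C)
      correct <- correct + sum(pred == y[ite])
    }
    correct / length(tr)
  }, numeric(1))
  c_grid[which.max(scores)]
}

svm_fit_predict <- function(K, y, tr, te, C) {
  ytr <- factor(y[tr])
  if (nlevels(droplevels(ytr)) < 2) {
    # degenerate training fold: predict its single class
    return(factor(rep(as.character(ytr[1]), length(te)),
                  levels = levels(y)))
  }
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE]),
                         ytr, type = "C-svc", C = C, kernel = "matrix")
  Kte <- K[te, tr, drop = FALSE][, kernlab::SVindex(model), drop = FALSE]
  pred <- kernlab::predict(model, kernlab::as.kernelMatrix(Kte))
  factor(as.character(pred), levels = levels(y))
}

#' @export
print.qw_cv_result <- function(x, ...) {
  cat(sprintf(
    "<qw_cv_result> accuracy %.2f%% +/- %.2f%% (%d-fold CV, %d repetitions)\n",
    100 * x$mean_accuracy, 100 * x$standard_error,
    x$config$folds, x$config$reps))
  invisible(x)
}
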