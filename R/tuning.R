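# Hyperparameter tuning of KELM by QHSBOA: inner-CV accuracy as the tuning
# objective over the [1,20]^2 box, nested stratified cross-validation for
# unbiased evaluation, and the headline classification metrics.

#' Binary classification metrics
#'
#' Confusion-matrix metrics with the positive class = label 1 (diabetic).
#' Accuracy, sensitivity (= recall), specificity and F1 are reported in
#' percent; the Matthews correlation coefficient on its natural [-1, 1]
#' scale.  Any metric whose denominator is zero (for MCC, any zero factor
#' under the square root) is defined as 0.
#'
#' @param y_true,y_pred Equal-length 0/1 label vectors.
#' @return An object of class `classification_metrics`: named list with
#'   `acc`, `mcc`, `sensitivity`, `specificity`, `f1`, `recall`, and the
#'   confusion counts `tp`, `tn`, `fp`, `fn`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' lengths differ", call. = FALSE)
  if (length(y_true) < 1L) stop("need at least one sample", call. = FALSE)
  yt <- as.integer(y_true); yp <- as.integer(y_pred)
  tp <- sum(yt == 1L & yp == 1L)
  tn <- sum(yt == 0L & yp == 0L)
  fp <- sum(yt == 0L & yp == 1L)
  fn <- sum(yt == 1L & yp == 0L)
  n <- tp + tn + fp + fn
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  structure(list(acc = 100 * (tp + tn) / n, mcc = mcc,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 f1 = 100 * f1, recall = 100 * sens,
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  MCC %.4f  Sens %.2f%%  Spec %.2f%%  F1 %.2f%%\n",
              x$acc, x$mcc, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Stratified k-fold indices
#'
#' Partitions `1..n` into `k` folds preserving class proportions: within each
#' class, shuffled members are dealt round-robin across folds, so per-fold
#' class counts differ by at most one from exact proportionality.
#'
#' @param y Label vector.
#' @param k Number of folds (each class must have at least `k` members).
#' @return List of `k` disjoint integer index vectors covering `1..n`.
#' @export
stratified_folds <- function(y, k) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  tab <- table(y)
  if (any(tab < k))
    stop("every class needs at least k = ", k, " members", call. = FALSE)
  folds <- vector("list", k)
  for (cl in names(tab)) {
    idx <- sample(which(y == cl))
    assign_to <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  lapply(folds, sort)
}

# preprocessing fitted on the training split, applied to both splits:
# mean imputation then [0,1] min-max normalization (leakage-free).
.preprocess_split <- function(X_train, X_test) {
  imp <- impute_mean(X_train)
  nrm <- minmax_normalize(imp$X)
  Xte <- impute_mean(X_test, imp$column_means)$X
  Xte <- minmax_normalize(Xte, nrm$ranges)$X
  list(train = nrm$X, test = Xte)
}

#' Cross-validated KELM accuracy as a tuning fitness
#'
#' `fitness = 1 - avgAcc` where `avgAcc` is the mean held-out accuracy of a
#' KELM with penalty `C` and kernel width `width` over `k` stratified folds.
#' Within each fold, imputation and normalization statistics are fitted on
#' the training portion only.  A degenerate single-class training fold falls
#' back to the constant classifier.
#'
#' @param C,width KELM hyperparameters.
#' @param X,y Data (X may contain `NA`; imputed per fold).
#' @param k Number of folds (used only when `folds` is `NULL`).
#' @param folds Optional explicit fold index list (makes the value
#'   deterministic and permutation-invariant).
#' @return Scalar fitness in `[0, 1]` (lower is better).
#' @export
cv_fitness <- function(C, width, X, y, k = 5, folds = NULL) {
  X <- as.matrix(X)
  if (is.null(folds)) folds <- stratified_folds(y, k)
  accs <- vapply(folds, function(test_idx) {
    tr <- setdiff(seq_len(nrow(X)), test_idx)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) {
      pred <- rep(names(which.max(table(ytr))), length(test_idx))
      return(mean(as.integer(pred) == y[test_idx]))
    }
    pp <- .preprocess_split(X[tr, , drop = FALSE], X[test_idx, , drop = FALSE])
    fit <- kelm(pp$train, ytr, C = C, width = width)
    mean(predict(fit, pp$test) == y[test_idx])
  }, numeric(1))
  1 - mean(accs)
}

#' Tune KELM hyperparameters with QHSBOA
#'
#' Runs the quantum-enhanced secretary bird optimizer on the 2-D problem
#' `(C, width)` over the given box, minimizing `1 - avgAcc` from
#' [cv_fitness()] with a fixed inner fold assignment (so the objective is
#' deterministic during the search).
#'
#' @param X,y Training data.
#' @param C_range,width_range Search intervals (default `[1, 20]` each).
#' @param inner_folds Inner CV folds (default 5).
#' @param pop_size,max_iter Optimizer budget (defaults 20 and 30: the 2-D
#'   box is small, so a desk-scale budget suffices).
#' @param seed Integer seed governing fold assignment and the search.
#' @param optimizer One of `"qhsboa"`, `"sboa"`, `"pso"`.
#' @return List with `C`, `width`, `fitness` (best `1 - avgAcc`), and the
#'   full `swarm_run` object.
#' @export
tune_kelm <- function(X, y, C_range = c(1, 20), width_range = c(1, 20),
                      inner_folds = 5, pop_size = 20, max_iter = 30,
                      seed = 1, optimizer = c("qhsboa", "sboa", "pso")) {
  optimizer <- match.arg(optimizer)
  X <- as.matrix(X)
  set.seed(as.integer(seed))
  folds <- stratified_folds(y, inner_folds)
  problem <- objective_problem(
    "kelm_cv",
    search_space(2, c(C_range[1], width_range[1]),
                 c(C_range[2], width_range[2])),
    function(par) cv_fitness(par[1], par[2], X, y, folds = folds))
  runner <- switch(optimizer, qhsboa = run_qhsboa, sboa = run_sboa,
                   pso = run_reference_pso)
  res <- runner(problem, pop_size = pop_size, max_iter = max_iter, seed = seed)
  list(C = res$best_position[1], width = res$best_position[2],
       fitness = res$best_fitness, run = res)
}

#' Nested cross-validated evaluation of the tuned KELM pipeline
#'
#' For each repeat and each outer fold: hyperparameters are tuned on the
#' outer-training portion by [tune_kelm()] (inner stratified CV), a single
#' KELM is refit with the tuned `(C, width)` on the full outer-training
#' portion, and the held-out fold is scored.  The held-out fold never enters
#' fold construction, tuning, preprocessing statistics, or training for its
#' own evaluation.  Aggregates are means over folds, then repeats.
#'
#' @param X,y Data (X may contain `NA`).
#' @param outer_folds Outer CV folds (default 10).
#' @param inner_folds Inner CV folds used by the tuner (default 5).
#' @param repeats Rounds of outer CV (default 30).
#' @param pop_size,max_iter Optimizer budget per tuning run.
#' @param seed Base seed; repeat `r`, fold `f` uses derived seeds below 2^31.
#' @param optimizer Passed to [tune_kelm()].
#' @return Object of class `nested_cv`: data frame `per_fold` (one row per
#'   repeat x fold with metrics and tuned parameters) plus `aggregate`
#'   metrics and the configuration echo.
#' @examples
#' \donttest{
#' ds <- generate_pidd_like(n = 120, n_positive = 40, seed = 1)
#' nested_cv_kelm(ds$X, ds$y, outer_folds = 3, repeats = 1,
#'                pop_size = 4, max_iter = 4)
#' }
#' @export
nested_cv_kelm <- function(X, y, outer_folds = 10, inner_folds = 5,
                           repeats = 30, pop_size = 20, max_iter = 30,
                           seed = 1, optimizer = "qhsboa") {
  X <- as.matrix(X)
  rows <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- (as.integer(seed) + 7919L * (r - 1L)) %% 2147483647L
    set.seed(rep_seed)
    folds <- stratified_folds(y, outer_folds)
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      tr <- setdiff(seq_len(nrow(X)), test_idx)
      tune_seed <- (rep_seed + 131L * f) %% 2147483647L
      tuned <- tune_kelm(X[tr, , drop = FALSE], y[tr],
                         inner_folds = inner_folds, pop_size = pop_size,
                         max_iter = max_iter, seed = tune_seed,
                         optimizer = optimizer)
      pp <- .preprocess_split(X[tr, , drop = FALSE],
                              X[test_idx, , drop = FALSE])
      fit <- kelm(pp$train, y[tr], C = tuned$C, width = tuned$width)
      m <- classification_metrics(y[test_idx], predict(fit, pp$test))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, n_test = length(test_idx),
        C = tuned$C, width = tuned$width,
        acc = m$acc, mcc = m$mcc, sensitivity = m$sensitivity,
        specificity = m$specificity, f1 = m$f1, recall = m$recall)
    }
  }
  per_fold <- do.call(rbind, rows)
  per_repeat <- stats::aggregate(
    per_fold[c("acc", "mcc", "sensitivity", "specificity", "f1", "recall")],
    by = list(repeat_ = per_fold$repeat_), FUN = mean)
  agg <- colMeans(per_repeat[-1])
  structure(list(per_fold = per_fold, per_repeat = per_repeat,
                 aggregate = as.list(agg),
                 config = list(outer_folds = outer_folds,
                               inner_folds = inner_folds, repeats = repeats,
                               pop_size = pop_size, max_iter = max_iter,
                               seed = seed, optimizer = optimizer)),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Nested CV (%d repeats x %d outer folds, %s tuner)\n",
              x$config$repeats, x$config$outer_folds, x$config$optimizer))
  cat(sprintf("  ACC %.2f%%  MCC %.4f  Sens %.2f%%  Spec %.2f%%  F1 %.2f%%  Recall %.2f%%\n",
              a$acc, a$mcc, a$sensitivity, a$specificity, a$f1, a$recall))
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, ...) {
  print(object)
  cat("Per-fold accuracy spread:\n")
  print(summary(object$per_fold$acc))
  invisible(object)
}

#' Fit a QHSBOA-tuned KELM classifier
#'
#' The headline fitting function: imputes and normalizes the data, tunes
#' `(C, width)` over `[1, 20]^2` by QHSBOA with inner stratified CV, and
#' refits a single KELM on the full data with the tuned hyperparameters.
#' Use [nested_cv_kelm()] for an unbiased generalization estimate.
#'
#' @param x Feature matrix (may contain `NA`), or a formula.
#' @param y 0/1 label vector (default method).
#' @param ... Passed to [tune_kelm()] (`inner_folds`, `pop_size`,
#'   `max_iter`, `seed`, ranges).
#' @return Object of class `qhsboa_kelm` inheriting from `kelm`, with extra
#'   fields `tuning` (the [tune_kelm()] result) and `preprocess` (fitted
#'   imputation means and normalization ranges applied by `predict`).
#' @examples
#' \donttest{
#' ds <- generate_pidd_like(n = 150, n_positive = 50, seed = 2)
#' fit <- qhsboa_kelm(ds$X, ds$y, pop_size = 5, max_iter = 5)
#' mean(predict(fit, ds$X) == ds$y)
#' }
#' @export
qhsboa_kelm <- function(x, ...) UseMethod("qhsboa_kelm")

#' @rdname qhsboa_kelm
#' @export
qhsboa_kelm.default <- function(x, y, ...) {
  X <- as.matrix(x)
  tuned <- tune_kelm(X, y, ...)
  imp <- impute_mean(X)
  nrm <- minmax_normalize(imp$X)
  fit <- kelm(nrm$X, y, C = tuned$C, width = tuned$width)
  fit$tuning <- tuned
  fit$preprocess <- list(column_means = imp$column_means, ranges = nrm$ranges)
  class(fit) <- c("qhsboa_kelm", class(fit))
  fit
}

#' @rdname qhsboa_kelm
#' @param formula Model formula, e.g. `Outcome ~ .`.
#' @param data Data frame holding the variables.
#' @export
qhsboa_kelm.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- as.matrix(mf[-1])
  fit <- qhsboa_kelm.default(X, y, ...)
  fit$terms <- attr(mf, "terms")
  fit
}

#' @export
predict.qhsboa_kelm <- function(object, newdata, type = c("class", "score"),
                                ...) {
  type <- match.arg(type)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass)
    newdata <- as.matrix(mf)
  }
  Xn <- impute_mean(as.matrix(newdata), object$preprocess$column_means)$X
  Xn <- minmax_normalize(Xn, object$preprocess$ranges)$X
  predict.kelm(structure(object, class = "kelm"), Xn, type = type)
}

#' @export
print.qhsboa_kelm <- function(x, ...) {
  cat("QHSBOA-tuned kernel ELM\n")
  cat(sprintf("  tuned C = %.4f, width = %.4f (inner-CV accuracy %.2f%%)\n",
              x$C, x$width, 100 * (1 - x$tuning$fitness)))
  cat(sprintf("  %d training points, %d features\n",
              nrow(x$train_X), ncol(x$train_X)))
  invisible(x)
}
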