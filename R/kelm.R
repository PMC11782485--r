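# Kernel extreme learning machine.  The kernel form solves
# (I/C + Omega) beta = T with Omega the Gaussian-RBF Gram matrix of the
# training points, subsuming the random-feature formulation: the hidden-layer
# feature map never needs to be materialized.

#' Gaussian RBF kernel matrix
#'
#' `K[i, j] = exp(-||a_i - b_j||^2 / (2 width^2))`.
#'
#' @param A p x d numeric matrix.
#' @param B q x d numeric matrix (defaults to `A`).
#' @param width Kernel width `c > 0` (the Gaussian sigma).
#' @return p x q kernel matrix.
#' @export
rbf_kernel <- function(A, B = A, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("'width' must be a positive scalar", call. = FALSE)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("feature dimensions of A and B differ", call. = FALSE)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * width^2))
}

#' Fit a kernel extreme learning machine
#'
#' Binary labels are encoded as a single +/-1 target column (first factor
#' level, conventionally 0, maps to -1; the positive class to +1) and the dual
#' coefficients solve the regularized kernel system
#' `(I/C + Omega) beta = T` with `Omega[i, j] = K(x_i, x_j)` by a symmetric
#' linear solve (no explicit inverse).  More than two classes use one-hot
#' targets with an argmax decision.
#'
#' @param x Feature matrix (n x d) for the default method, or a formula.
#' @param ... Passed between methods.
#' @return An object of class `kelm` with components `train_X`, `dual_coef`,
#'   `C`, `width`, `classes`, `binary`.
#' @examples
#' X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
#' y <- c(0, 1, 1, 0)            # XOR
#' fit <- kelm(X, y, C = 100, width = 0.5)
#' predict(fit, X)
#' @export
kelm <- function(x, ...) UseMethod("kelm")

#' @rdname kelm
#' @param y Length-n label vector (factor, character or numeric; 0/1 typical).
#' @param C Penalty parameter, `C > 0`.
#' @param width Kernel width, `> 0`.
#' @export
kelm.default <- function(x, y, C = 1, width = 1, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training samples", call. = FALSE)
  if (length(y) != n) stop("'y' length must match nrow(x)", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("'C' must be positive", call. = FALSE)
  yf <- factor(y)
  classes <- levels(yf)
  binary <- length(classes) <= 2L
  if (binary) {
    # single-class data still trains: all targets share one sign
    tgt <- matrix(ifelse(as.integer(yf) == length(classes), 1, -1), n, 1)
  } else {
    tgt <- matrix(-1, n, length(classes))
    tgt[cbind(seq_len(n), as.integer(yf))] <- 1
  }
  Omega <- rbf_kernel(X, X, width)
  A <- Omega
  diag(A) <- diag(A) + 1 / C
  dual <- tryCatch(solve(A, tgt),
                   error = function(e)
                     stop("kernel system is singular; decrease C or add ",
                          "ridge jitter to duplicated rows", call. = FALSE))
  structure(list(train_X = X, dual_coef = dual, C = C, width = width,
                 classes = classes, binary = binary),
            class = "kelm")
}

#' @rdname kelm
#' @param formula Model formula, e.g. `Outcome ~ .`.
#' @param data Data frame holding the variables.
#' @export
kelm.formula <- function(formula, data, C = 1, width = 1, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- kelm.default(X, y, C = C, width = width, ...)
  fit$terms <- attr(mf, "terms")
  fit
}

#' Decision scores of a fitted KELM
#'
#' `scores = K(Xnew, train_X) %*% dual_coef`: the kernel output function
#' evaluated at new points.
#'
#' @param model A fitted [kelm()] object.
#' @param newdata q x d matrix (q may be 0).
#' @return Length-q score vector (binary) or q x m score matrix.
#' @export
kelm_decision <- function(model, newdata) {
  stopifnot(inherits(model, "kelm"))
  Xnew <- as.matrix(newdata)
  if (nrow(Xnew) == 0L) {
    return(if (model$binary) numeric(0)
           else matrix(0, 0, length(model$classes)))
  }
  if (ncol(Xnew) != ncol(model$train_X))
    stop("newdata has ", ncol(Xnew), " features; model was trained with ",
         ncol(model$train_X), call. = FALSE)
  S <- rbf_kernel(Xnew, model$train_X, model$width) %*% model$dual_coef
  if (model$binary) as.numeric(S) else S
}

#' Predict class labels or decision scores
#'
#' @param object A fitted [kelm()] object.
#' @param newdata New feature matrix or data frame.
#' @param type `"class"` (default) or `"score"`.
#' @param ... Ignored.
#' @return Labels (binary rule: positive class iff score >= 0, so an exact
#'   tie goes to the positive class) or raw scores.
#' @export
predict.kelm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata)
    newdata <- stats::model.matrix(tt, mf)
    newdata <- newdata[, colnames(newdata) != "(Intercept)", drop = FALSE]
  }
  S <- kelm_decision(object, newdata)
  if (type == "score") return(S)
  if (object$binary) {
    pos <- object$classes[length(object$classes)]
    neg <- object$classes[1L]
    out <- ifelse(S >= 0, pos, neg)
  } else {
    out <- object$classes[max.col(S, ties.method = "first")]
  }
  lv <- type.convert(object$classes, as.is = TRUE)
  if (is.numeric(lv)) as.numeric(out) else out
}

#' @export
print.kelm <- function(x, ...) {
  cat(sprintf("Kernel ELM: %d training points, %d features\n",
              nrow(x$train_X), ncol(x$train_X)))
  cat(sprintf("  C = %g, kernel width = %g, classes: %s\n",
              x$C, x$width, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.kelm <- function(object, ...) {
  s <- kelm_decision(object, object$train_X)
  pred <- predict(object, object$train_X)
  yhat <- factor(pred, levels = type.convert(object$classes, as.is = TRUE))
  cat(sprintf("Kernel ELM (C = %g, width = %g)\n", object$C, object$width))
  cat(sprintf("  training points: %d  features: %d\n",
              nrow(object$train_X), ncol(object$train_X)))
  if (object$binary)
    cat(sprintf("  training score range: [%.3f, %.3f]\n", min(s), max(s)))
  print(table(predicted = yhat))
  invisible(object)
}

#' @export
coef.kelm <- function(object, ...) object$dual_coef

#' Serialize a fitted KELM to JSON
#'
#' Stores training inputs, dual coefficients and hyperparameters with full
#' double precision so that a round trip reproduces decisions exactly.
#'
#' @param model A fitted [kelm()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kelm_json <- function(model, path) {
  stopifnot(inherits(model, "kelm"))
  obj <- list(train_X = model$train_X,
              dual_coef = model$dual_coef,
              C = model$C, width = model$width,
              classes = model$classes, binary = model$binary)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Restore a KELM from JSON
#' @param path File written by [write_kelm_json()].
#' @return A `kelm` object.
#' @export
read_kelm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_X = as.matrix(obj$train_X),
                 dual_coef = as.matrix(obj$dual_coef),
                 C = obj$C, width = obj$width,
                 classes = as.character(obj$classes),
                 binary = isTRUE(obj$binary)),
            class = "kelm")
}
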