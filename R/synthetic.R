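# Synthetic diabetes-like tabular data.  The generator emulates the shape of
# the Pima Indians diabetes cohort (768 records, 8 features, 268 positive /
# 500 negative, scattered missing values) with controllable class separation,
# so every classification stage is testable without external downloads.

#' Generate a synthetic diabetes-like dataset
#'
#' Two Gaussian class-conditional clouds: a random subset of `ceiling(d/2)`
#' informative features has class-1 mean `effect_size` (class 0 mean 0); the
#' rest are pure unit-variance noise.  Class counts are honored exactly,
#' rows are shuffled, and missing entries are inserted completely at random
#' in the feature columns only.
#'
#' @param n Total rows (default 768).
#' @param n_positive Positive-class rows (default 268).
#' @param d Number of features (default 8).
#' @param effect_size Per-feature mean shift of the positive class on the
#'   informative features (default 1.3, giving a Mahalanobis separation of
#'   about 2.6 and a Bayes accuracy near 90%).
#' @param missing_rate MCAR missingness fraction in `[0, 1)` (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `tabular_dataset`: list with `X` (n x d matrix,
#'   `NA` = missing), `y` (0/1 integer vector), `feature_names`, and a
#'   `provenance` echo of the generation parameters.
#' @examples
#' ds <- generate_pidd_like(n = 60, n_positive = 20, seed = 1)
#' table(ds$y)
#' @export
generate_pidd_like <- function(n = 768, n_positive = 268, d = 8,
                               effect_size = 1.3, missing_rate = 0.05,
                               seed = 1) {
  if (n_positive <= 0 || n_positive >= n)
    stop("'n_positive' must satisfy 0 < n_positive < n", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  n_info <- ceiling(d / 2)
  info <- sort(sample.int(d, n_info))
  y <- sample(rep(c(1L, 0L), c(n_positive, n - n_positive)))
  X <- matrix(stats::rnorm(n * d), n, d)
  X[y == 1L, info] <- X[y == 1L, info] + effect_size
  if (missing_rate > 0) {
    miss <- stats::runif(n * d) < missing_rate
    X[miss] <- NA_real_
  }
  structure(list(X = X, y = y,
                 feature_names = paste0("feature_", seq_len(d)),
                 provenance = list(n = n, n_positive = n_positive, d = d,
                                   effect_size = effect_size,
                                   missing_rate = missing_rate, seed = seed,
                                   informative = info)),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("Tabular dataset: %d rows, %d features, %d positive / %d negative\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  nm <- sum(is.na(x$X))
  if (nm > 0) cat(sprintf("  %d missing entries (%.1f%%)\n",
                          nm, 100 * nm / length(x$X)))
  invisible(x)
}

#' Mean imputation with fit-on-train semantics
#'
#' Missing entries are replaced by the supplied column means, or by the
#' column means of the observed entries, which are returned so a test split
#' can reuse the training means.
#'
#' @param X Feature matrix (may contain `NA`).
#' @param column_means Optional length-d means fitted on training data.
#' @return List with the imputed matrix `X` and the `column_means` used.
#' @export
impute_mean <- function(X, column_means = NULL) {
  X <- as.matrix(X)
  if (is.null(column_means)) {
    column_means <- colMeans(X, na.rm = TRUE)
    if (any(!is.finite(column_means)))
      stop("a column has no observed values; supply 'column_means'",
           call. = FALSE)
  } else if (length(column_means) != ncol(X)) {
    stop("'column_means' length must match ncol(X)", call. = FALSE)
  }
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- column_means[j]
  }
  list(X = X, column_means = as.numeric(column_means))
}

#' Min-max normalization to [0, 1] with fit-on-train semantics
#'
#' `x' = (x - min) / (max - min)` per column.  When fitting, a constant
#' column maps to all zeros.  When applying fitted ranges to new data, values
#' outside the training range are passed through unclipped (they may fall
#' outside `[0, 1]`).
#'
#' @param X Feature matrix with no missing values.
#' @param ranges Optional list with `min` and `max` vectors fitted on
#'   training data.
#' @return List with the normalized matrix `X` and the fitted `ranges`.
#' @export
minmax_normalize <- function(X, ranges = NULL) {
  X <- as.matrix(X)
  if (is.null(ranges)) {
    ranges <- list(min = apply(X, 2L, min), max = apply(X, 2L, max))
  }
  span <- ranges$max - ranges$min
  out <- sweep(X, 2L, ranges$min, "-")
  const <- span <= 0
  span[const] <- 1          # constant column -> all zeros after centering
  out <- sweep(out, 2L, span, "/")
  out[, const] <- 0
  list(X = out, ranges = ranges)
}

#' Read a CSV classification dataset
#'
#' Comma-separated with a header row; empty cells are missing; the label
#' column must contain only 0/1 after parsing.
#'
#' @param path CSV file path.
#' @param label_col Name of the label column (default `"Outcome"`).
#' @return A `tabular_dataset`.
#' @export
read_csv_dataset <- function(path, label_col = "Outcome") {
  df <- utils::read.csv(path, header = TRUE, na.strings = c("", "NA"))
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found in ", path, call. = FALSE)
  y <- df[[label_col]]
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("label column must contain only 0/1", call. = FALSE)
  Xdf <- df[setdiff(names(df), label_col)]
  X <- as.matrix(Xdf)
  storage.mode(X) <- "double"
  structure(list(X = X, y = as.integer(y),
                 feature_names = colnames(X),
                 provenance = list(path = path, label_col = label_col)),
            class = "tabular_dataset")
}

#' Write a dataset as CSV
#'
#' Inverse of [read_csv_dataset()]: missing entries become empty cells;
#' values are written with 17 significant digits so the round trip is
#' lossless for finite doubles.
#'
#' @param data A `tabular_dataset`.
#' @param path Output path.
#' @param label_col Label column name (default `"Outcome"`).
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(data, path, label_col = "Outcome") {
  ch <- matrix(sprintf("%.17g", data$X), nrow(data$X), ncol(data$X))
  ch[is.na(data$X)] <- ""
  df <- as.data.frame(ch, stringsAsFactors = FALSE)
  names(df) <- data$feature_names
  df[[label_col]] <- data$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
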