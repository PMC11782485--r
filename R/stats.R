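# Multi-run benchmarking harness: Ave/Std/Rank summaries, rank-sum
# significance tables, Friedman mean ranks, convergence export.

#' Run a multi-run optimizer experiment
#'
#' Executes every algorithm on every problem `runs` times.  Run `r` of every
#' algorithm uses seed `base_seed + r - 1` (common random numbers across
#' algorithms, which pairs the samples and reduces comparison variance).
#'
#' @param problems Named list of [objective_problem()]s.
#' @param algorithms Named list of optimizer functions with the signature of
#'   [run_sboa()] (e.g. from [make_variant()]).
#' @param runs Independent runs per cell (default 30).
#' @param base_seed Integer base seed.
#' @param pop_size,max_iter Budget forwarded to every optimizer.
#' @return Data frame of class `run_records`: one row per
#'   (algorithm, problem, run) with `final_fitness` and `seed`; the
#'   per-iteration histories are kept in the `histories` attribute as a list
#'   parallel to the rows.
#' @export
run_experiment <- function(problems, algorithms, runs = 30, base_seed = 1,
                           pop_size = 30, max_iter = 500) {
  if (runs < 1L) stop("'runs' must be at least 1", call. = FALSE)
  rows <- list(); hist <- list()
  for (pn in names(problems)) {
    for (an in names(algorithms)) {
      for (r in seq_len(runs)) {
        seed <- as.integer(base_seed) + r - 1L
        res <- tryCatch(
          algorithms[[an]](problems[[pn]], pop_size = pop_size,
                           max_iter = max_iter, seed = seed),
          error = function(e)
            stop(sprintf("optimizer '%s' failed on '%s' (run %d): %s",
                         an, pn, r, conditionMessage(e)), call. = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = an, problem = pn, run_index = r,
          final_fitness = res$best_fitness, seed = seed)
        hist[[length(hist) + 1L]] <- res$history
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "histories") <- hist
  class(out) <- c("run_records", class(out))
  out
}

#' Summarize an experiment into an Ave/Std/Rank table
#'
#' Per (problem, algorithm): `ave` = sample mean of final fitness, `std` =
#' sample standard deviation (n-1 denominator), `rank` = rank of `ave`
#' within the problem (ascending, average ranks on ties).  Per algorithm the
#' Friedman mean rank is the mean of its per-problem ranks.
#'
#' @param records A `run_records` data frame from [run_experiment()].
#' @return List of class `summary_table` with data frames `table`
#'   (problem, algorithm, ave, std, rank) and `friedman`
#'   (algorithm, mean_rank), plus the Friedman chi-squared test on the
#'   paired per-run finals (`friedman_test`, `NULL` when fewer than two
#'   algorithms).
#' @export
summarize_experiment <- function(records) {
  des <- table(records$problem, records$algorithm)
  if (length(unique(as.vector(des))) != 1L)
    stop("incomplete design: every algorithm must run every problem equally often",
         call. = FALSE)
  agg <- stats::aggregate(final_fitness ~ problem + algorithm, records,
                          function(v) c(ave = mean(v), std = stats::sd(v)))
  tab <- data.frame(problem = agg$problem, algorithm = agg$algorithm,
                    ave = agg$final_fitness[, "ave"],
                    std = agg$final_fitness[, "std"])
  tab$rank <- stats::ave(tab$ave, tab$problem, FUN = rank)
  fried <- stats::aggregate(rank ~ algorithm, tab, mean)
  names(fried)[2] <- "mean_rank"
  ftest <- NULL
  if (length(unique(records$algorithm)) >= 2L) {
    # paired by (problem, run): common random numbers make runs comparable
    wide <- stats::reshape(
      records[c("algorithm", "problem", "run_index", "final_fitness")],
      idvar = c("problem", "run_index"), timevar = "algorithm",
      direction = "wide")
    m <- as.matrix(wide[-(1:2)])
    ftest <- stats::friedman.test(m)
  }
  structure(list(table = tab[order(tab$problem, tab$rank), ],
                 friedman = fried[order(fried$mean_rank), ],
                 friedman_test = ftest),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("\nFriedman mean ranks:\n")
  print(x$friedman, row.names = FALSE)
  if (!is.null(x$friedman_test))
    cat(sprintf("Friedman chi-squared = %.4g, df = %d, p = %.4g\n",
                unname(x$friedman_test$statistic),
                unname(x$friedman_test$parameter),
                x$friedman_test$p.value))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution when `length(a) + length(b) <= 12` and the pooled
#' sample is tie-free; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b Non-empty numeric sample vectors.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b) <= 12L) && !ties
  stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
}

#' Pairwise significance table against a reference algorithm
#'
#' Rank-sum p-values of the reference's final-fitness sample against every
#' other algorithm, per problem, flagged at the 5% level.
#'
#' @param records A `run_records` data frame.
#' @param reference_algorithm Name of the reference algorithm.
#' @param alpha Significance level (default 0.05).
#' @return Data frame (problem, algorithm, p_value, significant).
#' @export
significance_table <- function(records, reference_algorithm, alpha = 0.05) {
  algs <- unique(records$algorithm)
  if (!reference_algorithm %in% algs)
    stop("reference algorithm '", reference_algorithm, "' not in records",
         call. = FALSE)
  out <- list()
  for (pn in unique(records$problem)) {
    ref <- records$final_fitness[records$problem == pn &
                                   records$algorithm == reference_algorithm]
    for (an in algs) {
      other <- records$final_fitness[records$problem == pn &
                                       records$algorithm == an]
      p <- if (an == reference_algorithm) 1 else wilcoxon_rank_sum(ref, other)
      out[[length(out) + 1L]] <- data.frame(
        problem = pn, algorithm = an, p_value = p,
        significant = p <= alpha & an != reference_algorithm)
    }
  }
  do.call(rbind, out)
}

#' Export per-iteration convergence histories as long-format CSV
#'
#' @param records A `run_records` data frame (histories attribute required).
#' @param path Output CSV path.
#' @return `path`, invisibly.  Columns: algorithm, problem, run, iteration,
#'   best_fitness.
#' @export
export_convergence <- function(records, path) {
  hist <- attr(records, "histories")
  if (is.null(hist)) stop("records carry no histories", call. = FALSE)
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    h <- hist[[i]]
    data.frame(algorithm = records$algorithm[i],
               problem = records$problem[i],
               run = records$run_index[i],
               iteration = seq_along(h),
               best_fitness = h)
  })
  utils::write.csv(do.call(rbind, pieces), path, row.names = FALSE)
  invisible(path)
}
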