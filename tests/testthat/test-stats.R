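# helper: hand-built complete-design record set
fake_records <- function(ave_by_cell, runs = 4, noise = 0) {
  rows <- list()
  set.seed(1)
  for (pn in rownames(ave_by_cell)) for (an in colnames(ave_by_cell))
    for (r in seq_len(runs))
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = an, problem = pn, run_index = r,
        final_fitness = ave_by_cell[pn, an] + noise * rnorm(1), seed = r)
  out <- do.call(rbind, rows)
  class(out) <- c("run_records", class(out))
  out
}

test_that("experiments pair seeds across algorithms and are reproducible", {
  suite <- make_standard_suite(3)
  algs <- list(sboa = run_sboa, qhsboa = run_qhsboa)
  rec <- run_experiment(suite[c("sphere", "ackley")], algs, runs = 3,
                        base_seed = 5, pop_size = 5, max_iter = 10)
  expect_equal(nrow(rec), 12L)                      # 2 problems x 2 algs x 3
  expect_equal(sort(unique(rec$seed)), c(5L, 6L, 7L))
  # seeds identical across algorithms for pairing
  expect_equal(rec$seed[rec$algorithm == "sboa"],
               rec$seed[rec$algorithm == "qhsboa"])
  rec2 <- run_experiment(suite[c("sphere", "ackley")], algs, runs = 3,
                         base_seed = 5, pop_size = 5, max_iter = 10)
  expect_equal(rec$final_fitness, rec2$final_fitness)
  expect_length(attr(rec, "histories"), 12L)
})

test_that("summaries rank by average with average-rank ties", {
  ave <- matrix(c(1, 2, 3,     # p1: a < b < c
                  5, 5, 7,     # p2: tie between a and b
                  9, 8, 7,     # p3: reversed
                  1, 1, 1),    # p4: three-way tie
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("p", 1:4), c("a", "b", "c")))
  s <- summarize_experiment(fake_records(ave))
  t <- s$table
  get_rank <- function(p, a) t$rank[t$problem == p & t$algorithm == a]
  expect_equal(sapply(c("a", "b", "c"), get_rank, p = "p1"),
               c(a = 1, b = 2, c = 3))
  expect_equal(get_rank("p2", "a"), 1.5)
  expect_equal(get_rank("p2", "b"), 1.5)
  expect_equal(get_rank("p3", "c"), 1)
  expect_equal(get_rank("p4", "a"), 2)              # three-way tie -> 2
  # std uses the n-1 denominator
  expect_equal(t$std, rep(0, nrow(t)))
  fr <- s$friedman
  expect_equal(fr$mean_rank[fr$algorithm == "a"], mean(c(1, 1.5, 3, 2)))
})

test_that("an algorithm best on every problem gets Friedman mean rank 1", {
  ave <- matrix(c(1, 2, 3,
                  0.1, 5, 9,
                  2, 4, 8), 3, byrow = TRUE,
                dimnames = list(paste0("p", 1:3), c("best", "mid", "worst")))
  s <- summarize_experiment(fake_records(ave))
  expect_equal(s$friedman$mean_rank[s$friedman$algorithm == "best"], 1)
  # single algorithm: all ranks 1
  s1 <- summarize_experiment(fake_records(ave[, 1, drop = FALSE]))
  expect_true(all(s1$table$rank == 1))
  # incomplete design rejected
  rec <- fake_records(ave)
  expect_error(summarize_experiment(rec[-1, ]), "incomplete design")
})

test_that("rank-sum p-values follow exact and approximate paths correctly", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)  # ties -> approx
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  # spot agreement with enumeration away from the extreme arrangement
  a <- c(0.1, 2.3, 4.5, 1.1); b <- c(0.7, 3.2, 5.5)
  expect_equal(wilcoxon_rank_sum(a, b), oracle_ranksum_enum(a, b))
})

test_that("exact and approximate paths agree closely on tie-free 6v6 samples", {
  set.seed(17)
  for (i in 1:40) {
    a <- rnorm(6); b <- rnorm(6, mean = runif(1, -1, 1))
    p_exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
    expect_equal(wilcoxon_rank_sum(a, b), p_exact)   # 12 obs -> exact path
  }
})

test_that("significance tables flag at the 5% level against the reference", {
  ave <- matrix(c(0, 10), 1, 2,
                dimnames = list("p1", c("ref", "other")))
  rec <- fake_records(ave, runs = 30, noise = 0.01)
  st <- significance_table(rec, "ref")
  expect_equal(st$p_value[st$algorithm == "ref"], 1)
  expect_false(st$significant[st$algorithm == "ref"])
  # disjoint support, 30 vs 30: decisively significant
  expect_lt(st$p_value[st$algorithm == "other"], 0.05)
  expect_true(st$significant[st$algorithm == "other"])
  expect_error(significance_table(rec, "absent"), "not in records")
})

test_that("summaries are invariant to record order", {
  ave <- matrix(c(1, 2, 3, 1.5, 0.5, 4), 2, 3,
                dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  rec <- fake_records(ave, runs = 3, noise = 0.1)
  s1 <- summarize_experiment(rec)
  rec_shuffled <- rec[sample(nrow(rec)), ]
  attr(rec_shuffled, "histories") <- NULL
  s2 <- summarize_experiment(rec_shuffled)
  o1 <- s1$table[order(s1$table$problem, s1$table$algorithm), ]
  o2 <- s2$table[order(s2$table$problem, s2$table$algorithm), ]
  expect_equal(o1$ave, o2$ave)
  expect_equal(o1$rank, o2$rank)
})

test_that("convergence export writes one row per iteration and round-trips", {
  suite <- make_standard_suite(2)
  rec <- run_experiment(suite["sphere"], list(sboa = run_sboa), runs = 2,
                        base_seed = 1, pop_size = 4, max_iter = 5)
  path <- tempfile(fileext = ".csv")
  export_convergence(rec, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 2 * 5)           # sum of history lengths
  h1 <- attr(rec, "histories")[[1]]
  expect_equal(got$best_fitness[got$run == 1], h1)
  expect_true(all(c("algorithm", "problem", "run", "iteration",
                    "best_fitness") %in% names(got)))
  unlink(path)
})
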