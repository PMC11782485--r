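# Independent oracles used across the suite.  These deliberately take the
# naive route (explicit inverses, full enumeration, per-element loops) so
# they share no code with the implementation they check.

# KELM decision scores via the explicit pseudo-inverse of the regularized
# kernel system (the textbook formula, no linear solve).
oracle_kelm_scores <- function(X, y01, C, width, Xnew) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * width^2))
  Tenc <- ifelse(y01 == 1, 1, -1)
  beta <- MASS::ginv(diag(n) / C + K) %*% Tenc
  Kn <- matrix(0, nrow(Xnew), n)
  for (i in seq_len(nrow(Xnew))) for (j in seq_len(n))
    Kn[i, j] <- exp(-sum((Xnew[i, ] - X[j, ])^2) / (2 * width^2))
  as.numeric(Kn %*% beta)
}

# Two-sided rank-sum p-value by full enumeration of all C(n1+n2, n1)
# assignments of the pooled tie-free sample.
oracle_ranksum_enum <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Confusion-matrix metrics computed straight from the four counts.
oracle_metrics <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1); tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  div <- function(a, b) if (b == 0) 0 else a / b
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(acc = 100 * (tp + tn) / length(y_true),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
       sens = 100 * div(tp, tp + fn), spec = 100 * div(tn, tn + fp),
       f1 = 100 * div(2 * tp, 2 * tp + fp + fn))
}

# small quadratic bowl used where a cheap custom problem is handy
make_bowl <- function(dim = 3, lb = -5, ub = 5) {
  objective_problem("bowl", search_space(dim, lb, ub), function(x) sum(x^2),
                    optimum_location = rep(0, dim))
}
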