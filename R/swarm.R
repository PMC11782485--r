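# Secretary bird optimization: base algorithm, improvement strategies and
# the assembled QHSBOA.  One vectorized engine drives all variants; the
# strategy flags select which update rules are active, so disabling every
# strategy IS the base algorithm (identical code path, identical RNG stream).

#' Mantegna Levy-flight step
#'
#' Heavy-tailed random step `RL = 0.5 * 0.01 * u * sigma / |v|^(1/eta)` with
#' `eta = 1.5`, `u, v` standard-normal and `sigma` the Mantegna constant
#' `(Gamma(1+eta) sin(pi eta/2) / (Gamma((1+eta)/2) eta 2^((eta-1)/2)))^(1/eta)`.
#'
#' @param dim Number of components (may be 0).
#' @param eta Stability index, fixed at 1.5 by default.
#' @return Length-`dim` numeric vector.
#' @export
levy_flight <- function(dim, eta = 1.5) {
  if (dim == 0L) return(numeric(0))
  sigma <- levy_sigma(eta)
  u <- stats::rnorm(dim)
  v <- stats::rnorm(dim)
  0.5 * 0.01 * u * sigma / abs(v)^(1 / eta)
}

levy_sigma <- function(eta = 1.5) {
  (gamma(1 + eta) * sin(pi * eta / 2) /
     (gamma((1 + eta) / 2) * eta * 2^((eta - 1) / 2)))^(1 / eta)
}

# --- pure stage kernels (random inputs injected, hence unit-testable) ----

# P1 prey search: differential move toward two random peers.
hunt_p1 <- function(X, idx1, idx2, R2) {
  X + R2 * (X[idx1, , drop = FALSE] - X[idx2, , drop = FALSE])
}

# P2 prey exhaustion (base): exp((iter/T)^4)-scaled Brownian move about the
# incumbent best.  The exponent grows with iter as printed in the source
# recurrence; see the methods vignette for discussion.
hunt_p2_base <- function(X, xbest, iter, T, RB) {
  scale <- exp((iter / T)^4)
  B <- matrix(xbest, nrow(X), ncol(X), byrow = TRUE)
  B + scale * (RB - 0.5) * (B - X)
}

# P3 attack: (1 - iter/T)^(2 iter/T)-damped Levy move about the best.
hunt_p3 <- function(X, xbest, iter, T, RL) {
  damp <- (1 - iter / T)^(2 * iter / T)
  B <- matrix(xbest, nrow(X), ncol(X), byrow = TRUE)
  B + damp * X * RL
}

# Escape S1: fly away from predators around the best, damping (1 - iter/T)^2.
escape_s1 <- function(X, xbest, iter, T, RB) {
  B <- matrix(xbest, nrow(X), ncol(X), byrow = TRUE)
  B + (2 * RB - 1) * (1 - iter / T)^2 * X
}

# Escape S2: camouflage using a random peer; l in {1, 2}.
escape_s2 <- function(X, idx_rand, R4, l) {
  X + R4 * (X[idx_rand, , drop = FALSE] - l * X)
}

#' PSO velocity search update
#'
#' `v <- w v + c1 a1 (pbest - x) + c2 a2 (gbest - x)` with inertia
#' `w = 1 - iter/T`; the proposal is `x + v`.  `a1`, `a2` are fresh U(0,1)
#' per entry (injected so the kernel is deterministic and testable).
#'
#' @param X,V,pbest N x D current positions, velocities, personal bests.
#' @param gbest Length-D global best.
#' @param iter,T Current iteration and budget.
#' @param c1,c2 Individual/social learning factors.
#' @param A1,A2 N x D matrices of U(0,1) draws.
#' @return List with `velocities` and `proposals` (both N x D).
#' @export
pso_velocity_update <- function(X, V, pbest, gbest, iter, T, c1, c2, A1, A2) {
  w <- 1 - iter / T
  G <- matrix(gbest, nrow(X), ncol(X), byrow = TRUE)
  Vnew <- w * V + c1 * A1 * (pbest - X) + c2 * A2 * (G - X)
  list(velocities = Vnew, proposals = X + Vnew)
}

#' Clamp positions into the box
#' @param positions N x D numeric matrix.
#' @param space A [search_space()].
#' @return Matrix with each entry clamped into `[lb_j, ub_j]`.
#' @export
clip_to_bounds <- function(positions, space) {
  positions <- as.matrix(positions)
  L <- matrix(space$lb, nrow(positions), space$dim, byrow = TRUE)
  U <- matrix(space$ub, nrow(positions), space$dim, byrow = TRUE)
  pmin(pmax(positions, L), U)
}

#' Dynamic boundary repair anchored on the best individual
#'
#' Out-of-bounds entries are replaced by the midpoint between the violated
#' bound and the anchoring individual's coordinate: above `ub_j` the entry
#' becomes `(anchor_j + ub_j)/2`, below `lb_j` it becomes `(anchor_j + lb_j)/2`.
#' In-bounds entries are untouched.  With in-bounds anchors the output is
#' always feasible (midpoint of two in-box points).
#'
#' @param positions N x D matrix of proposals.
#' @param pbest_positions N x D matrix of in-bounds anchors (personal bests; a
#'   single row is recycled, which yields global-best anchoring).
#' @param space A [search_space()].
#' @return Repaired N x D matrix.
#' @export
dynamic_boundary_repair <- function(positions, pbest_positions, space) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  P <- as.matrix(pbest_positions)
  if (nrow(P) == 1L && n > 1L) P <- P[rep(1L, n), , drop = FALSE]
  L <- matrix(space$lb, n, space$dim, byrow = TRUE)
  U <- matrix(space$ub, n, space$dim, byrow = TRUE)
  hi <- positions > U
  lo <- positions < L
  positions[hi] <- (P[hi] + U[hi]) / 2
  positions[lo] <- (P[lo] + L[lo]) / 2
  positions
}

#' Greedy replacement
#'
#' Individual `i` adopts its proposal iff the proposal fitness is strictly
#' lower (ties keep the incumbent).
#'
#' @param positions,fitness Current N x D matrix and length-N fitness.
#' @param proposals,proposal_fitness Candidate matrix and fitness.
#' @return List with updated `positions`, `fitness`, and logical `accepted`.
#' @export
greedy_select <- function(positions, fitness, proposals, proposal_fitness) {
  acc <- proposal_fitness < fitness
  positions[acc, ] <- proposals[acc, , drop = FALSE]
  fitness[acc] <- proposal_fitness[acc]
  list(positions = positions, fitness = fitness, accepted = acc)
}

#' Quantum-rotation mutation with Student-t scaling
#'
#' Perturbs the incumbent global best through a single-qubit amplitude
#' construction: per-dimension angles `phi_j ~ U[0, 2*pi)` define amplitudes
#' `alpha_j = cos(phi_j)`, `beta_j = sin(phi_j)` (so `alpha^2 + beta^2 = 1`),
#' which are mapped back to solution scale by the Euclidean norm of the best
#' position and a Rademacher sign per dimension.  One shared rotation angle
#' `theta ~ U[0, 2*pi]` applied through the rotation gate yields two further
#' amplitude vectors.  Each of the four images is scaled per dimension by an
#' independent Student-t draw with `df = iter` and added to the best position;
#' candidates are clipped to the box, evaluated, and the best is adopted only
#' on strict improvement (elite selection).
#'
#' @param gbest_position Length-D incumbent best position.
#' @param gbest_fitness Its fitness.
#' @param iter Current iteration (t degrees of freedom).
#' @param problem An [objective_problem()].
#' @param phi,theta,signs,tdraws Optional pinned draws for testing: `phi`
#'   length-D, `theta` scalar, `signs` and `tdraws` 4 x D matrices.  Missing
#'   draws are taken from the RNG stream in the order phi, theta, signs,
#'   tdraws.
#' @return List with `position`, `fitness`, and logical `improved`.
#' @export
quantum_t_mutation <- function(gbest_position, gbest_fitness, iter, problem,
                               phi = NULL, theta = NULL, signs = NULL,
                               tdraws = NULL) {
  if (iter < 1) stop("'iter' must be >= 1", call. = FALSE)
  d <- length(gbest_position)
  if (is.null(phi))    phi    <- stats::runif(d, 0, 2 * pi)
  if (is.null(theta))  theta  <- stats::runif(1, 0, 2 * pi)
  if (is.null(signs))  signs  <- matrix(2 * (stats::runif(4 * d) < 0.5) - 1, 4, d)
  if (is.null(tdraws)) tdraws <- matrix(stats::rt(4 * d, df = iter), 4, d)
  alpha <- cos(phi)
  beta  <- sin(phi)
  alpha_r <- cos(theta) * alpha - sin(theta) * beta
  beta_r  <- sin(theta) * alpha + cos(theta) * beta
  nrm <- sqrt(sum(gbest_position^2))
  amps <- rbind(alpha, beta, alpha_r, beta_r) * nrm * signs
  cand <- matrix(gbest_position, 4, d, byrow = TRUE) + tdraws * amps
  cand <- clip_to_bounds(cand, problem$space)
  fit <- evaluate_batch(problem, cand)
  k <- which.min(fit)
  if (fit[k] < gbest_fitness)
    list(position = cand[k, ], fitness = fit[k], improved = TRUE)
  else
    list(position = gbest_position, fitness = gbest_fitness, improved = FALSE)
}

# random peer indices excluding self, one uniform draw per individual
.peer_indices <- function(N) {
  r <- floor(stats::runif(N) * (N - 1)) + 1L
  r <- pmin(r, N - 1L)           # guard against runif returning exactly 1
  r + (r >= seq_len(N))
}

# --- engine --------------------------------------------------------------

# strategies: list(pso=, boundary=, quantum=) of logicals.
run_swarm_engine <- function(problem, pop_size, max_iter, seed,
                             c1 = 2, c2 = 2, strategies, algorithm,
                             pbest_anchor = c("personal", "global")) {
  stopifnot(inherits(problem, "objective_problem"))
  if (pop_size < 2L) stop("'pop_size' must be at least 2", call. = FALSE)
  if (max_iter < 3L) stop("'max_iter' must be at least 3", call. = FALSE)
  pbest_anchor <- match.arg(pbest_anchor)
  space <- problem$space
  N <- as.integer(pop_size); T <- as.integer(max_iter); D <- space$dim
  set.seed(as.integer(seed))
  n_eval0 <- n_evaluations(problem)

  # initialization: x_ij = (ub_j - lb_j) r + lb_j, fresh U(0,1) per entry
  L <- matrix(space$lb, N, D, byrow = TRUE)
  U <- matrix(space$ub, N, D, byrow = TRUE)
  X <- L + (U - L) * matrix(stats::runif(N * D), N, D)
  X0 <- X
  fitness <- evaluate_batch(problem, X)
  V <- matrix(0, N, D)
  pbest <- X
  pbest_fit <- fitness
  gi <- which.min(fitness)
  gbest <- X[gi, ]
  gbest_fit <- fitness[gi]

  repair <- function(P) {
    if (strategies$boundary) {
      anchor <- if (pbest_anchor == "personal") pbest
                else matrix(gbest, 1, D)
      dynamic_boundary_repair(P, anchor, space)
    } else clip_to_bounds(P, space)
  }
  refresh_best <- function() {
    imp <- fitness < pbest_fit
    pbest[imp, ] <<- X[imp, , drop = FALSE]
    pbest_fit[imp] <<- fitness[imp]
    gi <- which.min(pbest_fit)
    if (pbest_fit[gi] < gbest_fit) {
      gbest <<- pbest[gi, ]
      gbest_fit <<- pbest_fit[gi]
    }
  }

  history <- numeric(T)
  max_violation <- 0
  for (iter in seq_len(T)) {
    # hunting phase (three stages cut at T/3 and 2T/3)
    if (iter < T / 3) {
      idx1 <- .peer_indices(N)
      idx2 <- .peer_indices(N)
      R2 <- matrix(stats::runif(N * D), N, D)
      prop <- hunt_p1(X, idx1, idx2, R2)
    } else if (iter < 2 * T / 3) {
      if (strategies$pso) {
        A1 <- matrix(stats::runif(N * D), N, D)
        A2 <- matrix(stats::runif(N * D), N, D)
        upd <- pso_velocity_update(X, V, pbest, gbest, iter, T, c1, c2, A1, A2)
        V <- upd$velocities
        prop <- upd$proposals
      } else {
        RB <- matrix(stats::rnorm(N * D), N, D)
        prop <- hunt_p2_base(X, gbest, iter, T, RB)
      }
    } else {
      RL <- matrix(0.5 * 0.01 * stats::rnorm(N * D) * levy_sigma() /
                     abs(stats::rnorm(N * D))^(1 / 1.5), N, D)
      prop <- hunt_p3(X, gbest, iter, T, RL)
    }
    prop <- repair(prop)
    sel <- greedy_select(X, fitness, prop, evaluate_batch(problem, prop))
    X <- sel$positions; fitness <- sel$fitness
    refresh_best()

    # escape phase: per-individual Bernoulli split at q = 0.5
    branch <- stats::runif(N)
    RB <- matrix(stats::rnorm(N * D), N, D)
    idxr <- .peer_indices(N)
    R4 <- matrix(stats::rnorm(N * D), N, D)
    l <- 1L + (stats::runif(N) < 0.5)
    p1 <- escape_s1(X, gbest, iter, T, RB)
    p2 <- escape_s2(X, idxr, R4, l)
    s1 <- branch > 0.5                      # q < r3 -> flee (S1)
    prop <- p2
    prop[s1, ] <- p1[s1, , drop = FALSE]
    prop <- repair(prop)
    sel <- greedy_select(X, fitness, prop, evaluate_batch(problem, prop))
    X <- sel$positions; fitness <- sel$fitness
    refresh_best()

    # quantum-rotation t-mutation of the global best (elite selection)
    if (strategies$quantum) {
      mut <- quantum_t_mutation(gbest, gbest_fit, iter, problem)
      gbest <- mut$position
      gbest_fit <- mut$fitness
    }

    max_violation <- max(max_violation,
                         max(0, X - U), max(0, L - X))
    history[iter] <- gbest_fit
  }

  structure(list(algorithm = algorithm,
                 problem = problem$name,
                 best_position = gbest,
                 best_fitness = gbest_fit,
                 history = history,
                 initial_positions = X0,
                 final_positions = X,
                 final_fitness = fitness,
                 n_evaluations = n_evaluations(problem) - n_eval0,
                 max_bound_violation = max_violation,
                 config = list(pop_size = N, max_iter = T, seed = seed,
                               c1 = c1, c2 = c2, strategies = strategies)),
            class = "swarm_run")
}

#' Run the base secretary bird optimization algorithm
#'
#' Each iteration applies the three-stage hunting update (differential prey
#' search, Brownian prey exhaustion about the best, Levy-flight attack) with
#' greedy replacement, then the two-branch escape update (flee / camouflage)
#' with greedy replacement; proposals are clamped into the box.
#'
#' @param problem An [objective_problem()].
#' @param pop_size Population size N (default 30).
#' @param max_iter Iteration budget T (default 500).
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @return A `swarm_run` object: `best_position`, `best_fitness`,
#'   per-iteration `history` of the incumbent best (non-increasing),
#'   `final_positions`, `n_evaluations`, and the configuration echo.
#' @seealso [run_qhsboa()], [run_reference_pso()], [make_variant()]
#' @examples
#' p <- make_standard_suite(5)$sphere
#' r <- run_sboa(p, pop_size = 10, max_iter = 50, seed = 1)
#' r$best_fitness
#' @export
run_sboa <- function(problem, pop_size = 30, max_iter = 500, seed = 1) {
  run_swarm_engine(problem, pop_size, max_iter, seed,
                   strategies = list(pso = FALSE, boundary = FALSE,
                                     quantum = FALSE),
                   algorithm = "SBOA")
}

#' Run QHSBOA (quantum-enhanced secretary bird optimization)
#'
#' Base SBOA augmented by up to three strategies: a PSO velocity search that
#' replaces the middle hunting stage (inertia `w = 1 - iter/T`, learning
#' factors `c1 = c2 = 2`), dynamic boundary repair anchored on the best
#' individual in place of clamping, and a quantum-rotation Student-t mutation
#' of the global best once per iteration.  With all three disabled the run is
#' bit-identical to [run_sboa()].
#'
#' @inheritParams run_sboa
#' @param c1,c2 Individual/social learning factors of the velocity update.
#' @param strategies Named logical list enabling `pso`, `boundary`, `quantum`
#'   (all `TRUE` by default).
#' @param pbest_anchor Whether boundary repair anchors on each individual's
#'   personal best (`"personal"`, default) or the global best (`"global"`).
#' @return A `swarm_run` object (see [run_sboa()]).
#' @examples
#' p <- make_standard_suite(5)$sphere
#' r <- run_qhsboa(p, pop_size = 10, max_iter = 60, seed = 1)
#' r$best_fitness
#' @export
run_qhsboa <- function(problem, pop_size = 30, max_iter = 500, seed = 1,
                       c1 = 2, c2 = 2,
                       strategies = list(pso = TRUE, boundary = TRUE,
                                         quantum = TRUE),
                       pbest_anchor = "personal") {
  strategies <- utils::modifyList(
    list(pso = TRUE, boundary = TRUE, quantum = TRUE), as.list(strategies))
  run_swarm_engine(problem, pop_size, max_iter, seed, c1, c2,
                   strategies = strategies, algorithm = "QHSBOA",
                   pbest_anchor = pbest_anchor)
}

#' Ablation variants of QHSBOA
#'
#' Returns an optimizer function enabling exactly the strategy subset named:
#' `PSBOA` (PSO velocity search only), `DSBOA` (dynamic boundary repair only),
#' `QSBOA` (quantum mutation only), `QHSBOA` (all three), or `SBOA` (none).
#'
#' @param variant_name One of `"SBOA"`, `"PSBOA"`, `"DSBOA"`, `"QSBOA"`,
#'   `"QHSBOA"`.
#' @return A function with the signature of [run_sboa()].
#' @export
make_variant <- function(variant_name) {
  flags <- switch(toupper(variant_name),
    SBOA   = list(pso = FALSE, boundary = FALSE, quantum = FALSE),
    PSBOA  = list(pso = TRUE,  boundary = FALSE, quantum = FALSE),
    DSBOA  = list(pso = FALSE, boundary = TRUE,  quantum = FALSE),
    QSBOA  = list(pso = FALSE, boundary = FALSE, quantum = TRUE),
    QHSBOA = list(pso = TRUE,  boundary = TRUE,  quantum = TRUE),
    stop("unknown variant '", variant_name, "'", call. = FALSE))
  nm <- toupper(variant_name)
  function(problem, pop_size = 30, max_iter = 500, seed = 1) {
    run_swarm_engine(problem, pop_size, max_iter, seed,
                     strategies = flags, algorithm = nm)
  }
}

#' Reference global-best particle swarm optimizer
#'
#' Standard PSO with constant inertia `w = 0.9` and learning factors
#' `c1 = c2 = 1.49445`, used as the in-repo comparison optimizer.  Positions
#' are clamped into the box after each move; personal and global bests are
#' tracked; history records the incumbent global best per iteration.
#'
#' @inheritParams run_sboa
#' @param w Inertia weight.
#' @param c1,c2 Learning factors.
#' @return A `swarm_run` object (see [run_sboa()]).
#' @export
run_reference_pso <- function(problem, pop_size = 30, max_iter = 500, seed = 1,
                              w = 0.9, c1 = 1.49445, c2 = 1.49445) {
  stopifnot(inherits(problem, "objective_problem"))
  if (pop_size < 2L) stop("'pop_size' must be at least 2", call. = FALSE)
  space <- problem$space
  N <- as.integer(pop_size); T <- as.integer(max_iter); D <- space$dim
  set.seed(as.integer(seed))
  n_eval0 <- n_evaluations(problem)
  L <- matrix(space$lb, N, D, byrow = TRUE)
  U <- matrix(space$ub, N, D, byrow = TRUE)
  X <- L + (U - L) * matrix(stats::runif(N * D), N, D)
  V <- matrix(0, N, D)
  fitness <- evaluate_batch(problem, X)
  pbest <- X; pbest_fit <- fitness
  gi <- which.min(fitness); gbest <- X[gi, ]; gbest_fit <- fitness[gi]
  history <- numeric(T)
  for (iter in seq_len(T)) {
    A1 <- matrix(stats::runif(N * D), N, D)
    A2 <- matrix(stats::runif(N * D), N, D)
    G <- matrix(gbest, N, D, byrow = TRUE)
    V <- w * V + c1 * A1 * (pbest - X) + c2 * A2 * (G - X)
    X <- clip_to_bounds(X + V, space)
    fitness <- evaluate_batch(problem, X)
    imp <- fitness < pbest_fit
    pbest[imp, ] <- X[imp, , drop = FALSE]
    pbest_fit[imp] <- fitness[imp]
    gi <- which.min(pbest_fit)
    if (pbest_fit[gi] < gbest_fit) {
      gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
    }
    history[iter] <- gbest_fit
  }
  structure(list(algorithm = "PSO", problem = problem$name,
                 best_position = gbest, best_fitness = gbest_fit,
                 history = history, final_positions = X,
                 final_fitness = fitness,
                 n_evaluations = n_evaluations(problem) - n_eval0,
                 max_bound_violation = 0,
                 config = list(pop_size = N, max_iter = T, seed = seed,
                               w = w, c1 = c1, c2 = c2)),
            class = "swarm_run")
}

#' @export
print.swarm_run <- function(x, ...) {
  cat(sprintf("%s run on '%s' (N = %d, T = %d, seed = %s)\n",
              x$algorithm, x$problem, x$config$pop_size, x$config$max_iter,
              format(x$config$seed)))
  cat(sprintf("  best fitness: %.6g after %d evaluations\n",
              x$best_fitness, x$n_evaluations))
  invisible(x)
}

#' @export
plot.swarm_run <- function(x, log = "y", ...) {
  h <- x$history
  if (identical(log, "y") && any(h <= 0)) log <- ""
  graphics::plot(seq_along(h), h, type = "l", log = log,
                 xlab = "iteration", ylab = "best fitness",
                 main = sprintf("%s on %s", x$algorithm, x$problem), ...)
  invisible(x)
}
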