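#' Box-bounded search space
#'
#' Defines the rectangular feasible region of a minimization problem.
#' Scalar bounds are recycled to length `dim`.
#'
#' @param dim Positive integer dimension.
#' @param lb,ub Lower/upper bounds; scalars or length-`dim` vectors with
#'   `lb[j] <= ub[j]`.
#' @return An object of class `search_space` with fields `dim`, `lb`, `ub`.
#' @examples
#' search_space(3, -5, 5)
#' @export
search_space <- function(dim, lb, ub) {
  dim <- as.integer(dim)
  if (length(dim) != 1L || is.na(dim) || dim < 1L)
    stop("'dim' must be a positive integer", call. = FALSE)
  lb <- rep_len(as.numeric(lb), dim)
  ub <- rep_len(as.numeric(ub), dim)
  if (any(lb > ub)) stop("each lower bound must not exceed its upper bound",
                         call. = FALSE)
  structure(list(dim = dim, lb = lb, ub = ub), class = "search_space")
}

#' Objective problem
#'
#' Bundles a deterministic objective with its search space and (optionally)
#' a known optimum.  The returned object carries an evaluation counter that
#' [evaluate_batch()] increments.
#'
#' @param name Character label.
#' @param space A [search_space()].
#' @param objective Function mapping a length-`dim` numeric vector to a scalar.
#' @param optimum_location Optional known minimizer (length-`dim` vector).
#' @param optimum_value Optional value at `optimum_location`; if omitted but a
#'   location is given, the objective is evaluated there once.
#' @return An object of class `objective_problem`.
#' @export
objective_problem <- function(name, space, objective,
                              optimum_location = NULL, optimum_value = NULL) {
  stopifnot(inherits(space, "search_space"), is.function(objective))
  if (!is.null(optimum_location)) {
    optimum_location <- as.numeric(optimum_location)
    if (length(optimum_location) != space$dim)
      stop("optimum location has wrong length", call. = FALSE)
    at <- objective(optimum_location)
    if (is.null(optimum_value)) optimum_value <- at
    else if (abs(at - optimum_value) > 1e-12)
      stop("objective(optimum_location) does not match optimum_value",
           call. = FALSE)
  }
  structure(list(name = name, space = space, objective = objective,
                 optimum_location = optimum_location,
                 optimum_value = optimum_value,
                 counter = new.env(parent = emptyenv())),
            class = "objective_problem")
}

#' @export
print.objective_problem <- function(x, ...) {
  cat(sprintf("Objective problem '%s' (D = %d)\n", x$name, x$space$dim))
  cat(sprintf("  bounds: [%g, %g] (first coordinate)\n",
              x$space$lb[1], x$space$ub[1]))
  if (!is.null(x$optimum_value))
    cat(sprintf("  known optimum value: %g\n", x$optimum_value))
  invisible(x)
}

#' Evaluate a batch of candidate positions
#'
#' @param problem An [objective_problem()].
#' @param positions An N x D numeric matrix (N may be 0).
#' @return Length-N numeric vector of objective values.  The problem's
#'   evaluation counter is incremented by N.
#' @export
evaluate_batch <- function(problem, positions) {
  stopifnot(inherits(problem, "objective_problem"))
  positions <- as.matrix(positions)
  if (nrow(positions) == 0L) return(numeric(0))
  if (ncol(positions) != problem$space$dim)
    stop("positions have ", ncol(positions), " columns but problem dimension is ",
         problem$space$dim, call. = FALSE)
  f <- apply(positions, 1L, problem$objective)
  n0 <- problem$counter$n
  problem$counter$n <- (if (is.null(n0)) 0L else n0) + nrow(positions)
  as.numeric(f)
}

#' Number of objective evaluations consumed so far
#' @param problem An [objective_problem()].
#' @return Integer count (0 if never evaluated).
#' @export
n_evaluations <- function(problem) {
  n <- problem$counter$n
  if (is.null(n)) 0L else n
}

#' Reset the evaluation counter
#' @param problem An [objective_problem()].
#' @return The problem, invisibly.
#' @export
reset_evaluations <- function(problem) {
  problem$counter$n <- 0L
  invisible(problem)
}

# --- analytic test functions --------------------------------------------
# Conventional boxes: Sphere [-100,100], Rosenbrock [-30,30],
# Rastrigin [-5.12,5.12], Ackley [-32.768,32.768], Griewank [-600,600],
# Levy [-10,10], Schwefel 2.26 [-500,500].

f_sphere     <- function(x) sum(x^2)
f_rosenbrock <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
}
f_rastrigin  <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
f_ackley     <- function(x) {
  d <- length(x)
  -20 * exp(-0.2 * sqrt(sum(x^2) / d)) - exp(sum(cos(2 * pi * x)) / d) +
    20 + exp(1)
}
f_griewank   <- function(x) {
  sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
}
f_levy       <- function(x) {
  w <- 1 + (x - 1) / 4
  n <- length(x)
  term1 <- sin(pi * w[1])^2
  term3 <- (w[n] - 1)^2 * (1 + sin(2 * pi * w[n])^2)
  wm <- w[-n]
  sum(term1, (wm - 1)^2 * (1 + 10 * sin(pi * wm + 1)^2), term3)
}
f_schwefel226 <- function(x) {
  418.9828872724337998 * length(x) - sum(x * sin(sqrt(abs(x))))
}

# Minimizer of -x sin(sqrt|x|) on [-500, 500], to full double precision.
.schwefel_xstar <- 420.96874635998194

#' Built-in analytic benchmark suite
#'
#' Seven classic minimization test functions at a chosen dimension, each with
#' its conventional box and known optimum.  The suite serves as the in-repo
#' benchmark surface; randomly shifted/rotated variants are produced by
#' [make_shifted_rotated()].
#'
#' @param dim Positive integer dimension.
#' @return Named list of [objective_problem()]s: `sphere`, `rosenbrock`,
#'   `rastrigin`, `ackley`, `griewank`, `levy`, `schwefel226`.
#' @examples
#' suite <- make_standard_suite(5)
#' evaluate_batch(suite$sphere, matrix(0, 1, 5))  # 0 at the origin
#' @export
make_standard_suite <- function(dim) {
  dim <- as.integer(dim)
  if (length(dim) != 1L || is.na(dim) || dim < 1L)
    stop("'dim' must be a positive integer", call. = FALSE)
  mk <- function(name, fn, half_width, loc)
    objective_problem(name, search_space(dim, -half_width, half_width), fn,
                      optimum_location = rep(loc, dim))
  list(
    sphere      = mk("sphere",      f_sphere,      100,    0),
    rosenbrock  = mk("rosenbrock",  f_rosenbrock,  30,     1),
    rastrigin   = mk("rastrigin",   f_rastrigin,   5.12,   0),
    ackley      = mk("ackley",      f_ackley,      32.768, 0),
    griewank    = mk("griewank",    f_griewank,    600,    0),
    levy        = mk("levy",        f_levy,        10,     1),
    schwefel226 = mk("schwefel226", f_schwefel226, 500,    .schwefel_xstar)
  )
}

#' Seeded shift and rotation of a benchmark problem
#'
#' Produces `f(Q (x - s))` where `Q` is a random orthogonal matrix (QR of a
#' seeded Gaussian matrix, sign-fixed so the factorization is unique) and `s`
#' a seeded uniform shift inside the central 80% of the box.  Orthogonal
#' invariance preserves the optimum value; the minimizer moves to `s` (the
#' base problem must have its optimum at the origin).
#'
#' @param problem An [objective_problem()] with optimum at the origin.
#' @param seed Integer seed; the same seed always yields the same `Q` and `s`.
#' @return A new [objective_problem()] with optimum at `s`.
#' @export
make_shifted_rotated <- function(problem, seed) {
  stopifnot(inherits(problem, "objective_problem"))
  if (is.null(problem$optimum_location) ||
      any(problem$optimum_location != 0))
    stop("base problem must have a known optimum at the origin", call. = FALSE)
  d <- problem$space$dim
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  qr_out <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_out)
  # fix signs so Q is a deterministic function of the Gaussian draw
  Q <- Q %*% diag(sign(diag(qr.R(qr_out))), d, d)
  span <- problem$space$ub - problem$space$lb
  s <- problem$space$lb + span * (0.1 + 0.8 * stats::runif(d))
  base_fn <- problem$objective
  objective_problem(paste0(problem$name, "_sr"), problem$space,
                    function(x) base_fn(as.numeric(Q %*% (x - s))),
                    optimum_location = s)
}
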