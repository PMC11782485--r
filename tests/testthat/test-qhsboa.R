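test_that("PSO velocity update obeys its fixed points", {
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  P <- X; G <- X[1, ]
  A1 <- matrix(0.3, 2, 2); A2 <- matrix(0.6, 2, 2)
  # inertia vanishes at iter = T
  upd <- pso_velocity_update(X, matrix(5, 2, 2), P, G, iter = 10, T = 10,
                             c1 = 2, c2 = 2, A1, A2)
  Gm <- matrix(G, 2, 2, byrow = TRUE)
  expect_equal(upd$velocities, 2 * 0.6 * (Gm - X))
  # v = 0 and x = pbest = gbest: stationary
  upd2 <- pso_velocity_update(X, matrix(0, 2, 2), X, X[1, ], 1, 10, 2, 2,
                              A1, A2)
  expect_equal(upd2$proposals[1, ], X[1, ])
  # hand evaluation of the full recurrence
  V <- matrix(c(0.1, -0.1, 0.2, 0), 2, 2)
  upd3 <- pso_velocity_update(X, V, P + 1, G, iter = 4, T = 10, c1 = 2,
                              c2 = 0.5, A1, A2)
  w <- 1 - 4 / 10
  expect_equal(upd3$velocities,
               w * V + 2 * 0.3 * (P + 1 - X) + 0.5 * 0.6 * (Gm - X))
  expect_equal(upd3$proposals, X + upd3$velocities)
})

test_that("dynamic boundary repair replaces violations by anchored midpoints", {
  sp <- search_space(1, -1, 1)
  expect_equal(dynamic_boundary_repair(matrix(1.2), matrix(0.5), sp),
               matrix(0.75))
  expect_equal(dynamic_boundary_repair(matrix(-3), matrix(0), sp),
               matrix(-0.5))
  expect_equal(dynamic_boundary_repair(matrix(0.3), matrix(0.9), sp),
               matrix(0.3))
  # property: with in-bounds anchors the output is always feasible
  set.seed(8)
  sp3 <- search_space(3, c(-1, 0, 2), c(1, 4, 2.5))
  for (i in 1:100) {
    X <- matrix(rnorm(15, sd = 5), 5, 3)
    A <- clip_to_bounds(matrix(rnorm(15), 5, 3), sp3)
    R <- dynamic_boundary_repair(X, A, sp3)
    L <- matrix(sp3$lb, 5, 3, byrow = TRUE)
    U <- matrix(sp3$ub, 5, 3, byrow = TRUE)
    expect_true(all(R >= L & R <= U))
    inb <- X >= L & X <= U
    expect_identical(R[inb], X[inb])
  }
})

test_that("quantum amplitudes stay normalized through rotation", {
  set.seed(21)
  for (i in 1:50) {
    phi <- runif(6, 0, 2 * pi)
    theta <- runif(1, 0, 2 * pi)
    a <- cos(phi); b <- sin(phi)
    ar <- cos(theta) * a - sin(theta) * b
    br <- sin(theta) * a + cos(theta) * b
    expect_equal(a^2 + b^2, rep(1, 6), tolerance = 1e-12)
    expect_equal(ar^2 + br^2, rep(1, 6), tolerance = 1e-12)
  }
})

test_that("quantum mutation builds its four candidates as specified", {
  p <- make_bowl(2)
  gb <- c(0.6, -0.8)                      # norm exactly 1
  gf <- sum(gb^2)
  phi <- c(pi / 3, pi / 6); theta <- pi / 4
  signs <- matrix(1, 4, 2)
  # zero t-draws: all candidates equal the incumbent, which is returned
  out0 <- quantum_t_mutation(gb, gf, iter = 2, p, phi = phi, theta = theta,
                             signs = signs, tdraws = matrix(0, 4, 2))
  expect_false(out0$improved)
  expect_identical(out0$position, gb)

  # unit t-draws: candidates are gbest + amplitude images, checked by hand
  td <- matrix(1, 4, 2)
  a <- cos(phi); b <- sin(phi)
  ar <- cos(theta) * a - sin(theta) * b
  br <- sin(theta) * a + cos(theta) * b
  cand <- rbind(gb + a, gb + b, gb + ar, gb + br)   # ||gb|| = 1, signs +1
  cand <- pmin(pmax(cand, -5), 5)
  fits <- rowSums(cand^2)
  out1 <- quantum_t_mutation(gb, gf, iter = 2, p, phi = phi, theta = theta,
                             signs = signs, tdraws = td)
  k <- which.min(fits)
  if (fits[k] < gf) {
    expect_equal(out1$position, cand[k, ])
    expect_equal(out1$fitness, fits[k])
  } else {
    expect_identical(out1$position, gb)
  }
  expect_error(quantum_t_mutation(gb, gf, iter = 0, p), "iter")
})

test_that("elite selection never worsens the incumbent best", {
  p <- make_bowl(4)
  set.seed(31)
  for (i in 1:200) {
    gb <- runif(4, -5, 5)
    gf <- sum(gb^2)
    out <- quantum_t_mutation(gb, gf, iter = sample(1:50, 1), p)
    expect_lte(out$fitness, gf)
    expect_true(all(out$position >= -5 & out$position <= 5))
  }
})

test_that("disabling all strategies reproduces base SBOA bit-exactly", {
  suite <- make_standard_suite(6)
  for (fn in c("sphere", "rastrigin")) {
    a <- run_sboa(suite[[fn]], pop_size = 8, max_iter = 30, seed = 11)
    b <- run_qhsboa(suite[[fn]], pop_size = 8, max_iter = 30, seed = 11,
                    strategies = list(pso = FALSE, boundary = FALSE,
                                      quantum = FALSE))
    expect_identical(a$history, b$history)
    expect_identical(a$best_position, b$best_position)
    expect_identical(a$final_positions, b$final_positions)
  }
})

test_that("ablation variants enable exactly their strategy subset", {
  suite <- make_standard_suite(4)
  full <- make_variant("QHSBOA")(suite$sphere, 6, 20, seed = 2)
  ref <- run_qhsboa(suite$sphere, 6, 20, seed = 2)
  expect_identical(full$history, ref$history)
  expect_equal(full$config$strategies,
               list(pso = TRUE, boundary = TRUE, quantum = TRUE))
  expect_equal(make_variant("psboa")(suite$sphere, 6, 20, 1)$config$strategies,
               list(pso = TRUE, boundary = FALSE, quantum = FALSE))
  expect_equal(make_variant("DSBOA")(suite$sphere, 6, 20, 1)$config$strategies,
               list(pso = FALSE, boundary = TRUE, quantum = FALSE))
  expect_equal(make_variant("QSBOA")(suite$sphere, 6, 20, 1)$config$strategies,
               list(pso = FALSE, boundary = FALSE, quantum = TRUE))
  expect_error(make_variant("XSBOA"), "unknown variant")
})

test_that("boundary repair differs from clamping only at violation entries", {
  sp <- search_space(3, -1, 1)
  set.seed(12)
  X <- matrix(rnorm(30, sd = 1.5), 10, 3)
  A <- clip_to_bounds(matrix(rnorm(30, sd = 0.5), 10, 3), sp)
  dyn <- dynamic_boundary_repair(X, A, sp)
  clp <- clip_to_bounds(X, sp)
  violated <- X < -1 | X > 1
  expect_true(any(violated))            # the draw spread guarantees some
  expect_identical(dyn[!violated], clp[!violated])
  expect_true(all(abs(dyn[violated] - clp[violated]) > 0 |
                    A[violated] == clp[violated]))
})

test_that("QHSBOA histories are monotone on a spread of seeds and problems", {
  suite <- make_standard_suite(5)
  for (fn in c("sphere", "ackley", "rastrigin")) {
    for (s in 1:4) {
      r <- run_qhsboa(suite[[fn]], pop_size = 8, max_iter = 30, seed = s)
      expect_true(all(diff(r$history) <= 0))
      expect_equal(r$max_bound_violation, 0)
    }
  }
})
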