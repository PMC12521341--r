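# Hamiltonian, adjoint, stationarity and the boundary value solver.

test_that("hamiltonian combines running cost and lambda-weighted dynamics", {
  prob <- default_problem(two_population_model(0.5, 0.5))
  expect_equal(hamiltonian(prob, c(0, 0), c(0, 0), c(0, 0)), 0)
  # lambda = 0 leaves the pure running cost
  x <- c(1, 2); u <- c(0.5, 0.5)
  expect_equal(hamiltonian(prob, x, u, c(0, 0)),
               0.5 * (sum(x^2) + 0.1 * sum(u^2)))
  # worked value: Q = I, R = 0.1 I, x = (1,1), u = 0, lam = (1,1):
  # H = 1 + lam . (A x) = 1 + (1, 1) . (1, 0) = 2
  expect_equal(hamiltonian(prob, c(1, 1), c(0, 0), c(1, 1)), 2)
})

test_that("adjoint dynamics equal -dH/dx (finite-difference oracle)", {
  set.seed(11)
  # structural reductions
  m <- random_model(n = 2, m = 2, with_D = FALSE)
  prob0 <- oc_problem(m, cost_spec(diag(0, 2), diag(2), NULL, 1), c(1, 1))
  lam <- c(0.3, -0.7)
  expect_equal(adjoint_rhs(prob0, c(1, 1), c(0, 0), lam),
               -drop(t(m$A) %*% lam))
  probQ <- oc_problem(m, cost_spec(diag(2), diag(2), NULL, 1), c(1, 1))
  x <- c(0.4, 1.3)
  expect_equal(adjoint_rhs(probQ, x, c(0, 0), c(0, 0)), -x)
  # random models against central differences
  for (rep in 1:25) {
    model <- random_model()
    prob <- random_problem(model)
    n <- model$n; mm <- model$m
    x <- runif(n); u <- runif(mm, -1, 1); lam <- runif(n, -1, 1)
    fd <- -num_grad(function(xx) hamiltonian(prob, xx, u, lam), x)
    an <- adjoint_rhs(prob, x, u, lam)
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("stationary control zeroes dH/du and respects structure", {
  set.seed(12)
  # C = D = 0, B = 0: stationary point is exactly zero
  m0 <- controlled_ode_model(A = matrix(c(-1, 0, 0, -1), 2), m = 2)
  p0 <- oc_problem(m0, cost_spec(diag(2), diag(2), NULL, 1), c(1, 1))
  sc0 <- stationary_control(p0, c(1, 1), c(0.5, -0.5))
  expect_equal(sc0$u_free, c(0, 0))
  expect_equal(sc0$u, c(0, 0))
  # C = D = 0, B != 0 recovers the LQR control -R^{-1} B' lam
  A <- matrix(c(-1, 0.2, 0.1, -0.5), 2)
  B <- matrix(c(1, 0.3, -0.2, 0.8), 2)
  R <- diag(0.5, 2)
  mB <- controlled_ode_model(A = A, B = B)
  pB <- oc_problem(mB, cost_spec(diag(2), R, NULL, 1), c(1, 1),
                   control_bounds = list(lower = -1e8, upper = 1e8))
  lam <- c(0.4, -1.1)
  expect_equal(stationary_control(pB, c(1, 1), lam)$u,
               drop(-solve(R, t(B) %*% lam)), tolerance = 1e-12)
  # random models: unconstrained point zeroes the u-gradient of H
  for (rep in 1:25) {
    model <- random_model()
    prob <- random_problem(model)
    x <- runif(model$n); lam <- runif(model$n, -1, 1)
    sc <- stationary_control(prob, x, lam)
    g <- num_grad(function(u) hamiltonian(prob, x, u, lam), sc$u_free)
    expect_lt(max(abs(g)), 1e-6 * (1 + max(abs(sc$u_free))))
  }
})

test_that("projected control agrees with a dense grid search over the box", {
  # two-population instance: minimise H over [0,1]^2 by brute force
  prob <- default_problem(two_population_model(0.3, 0.4))
  set.seed(3)
  for (rep in 1:5) {
    x <- runif(2, 0, 2); lam <- runif(2, -2, 2)
    u_grid <- grid_min_H(prob, x, lam, steps = 401)
    sc <- stationary_control(prob, x, lam)
    expect_equal(sc$u, u_grid, tolerance = 1e-3 + 1 / 400)
  }
})

test_that("singular stationarity systems are refused, not pseudo-inverted", {
  m <- two_population_model(0.2, 0.2)
  # legal (positive definite) penalty whose condition number exceeds the
  # singularity threshold
  p <- oc_problem(m, cost_spec(diag(2), diag(c(1, 5e-11)), NULL, 1),
                  c(1, 1))
  expect_error(stationary_control(p, c(1, 1), c(1, 1)),
               class = "octherapy_singular_optimality")
})

test_that("zero state cost yields the uncontrolled flow with zero adjoint", {
  m <- two_population_model(0.3, 0.3)
  prob <- oc_problem(m, cost_spec(diag(0, 2), diag(0.1, 2), NULL, T = 2),
                     c(1, 1))
  sol <- solve_oc(prob, fast_settings())
  expect_true(sol$converged)
  expect_equal(max(abs(sol$lam)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sol$u)), 0, tolerance = 1e-10)
  flow <- simulate_forward(m, c(1, 1), c(0, 0), 2, t_out = sol$t)
  expect_equal(unname(sol$x), unname(flow$x), tolerance = 1e-6)
})

test_that("two-population solve satisfies interior stationarity", {
  prob <- default_problem(two_population_model(0.5, 0.5))
  sol <- solve_oc(prob)
  expect_true(sol$converged)
  expect_lt(sol$stationarity_residual, 1e-3)
  # transversality: no terminal penalty, so lambda(T) = 0
  expect_lt(max(abs(sol$lam[nrow(sol$lam), ])), 1e-8)
  expect_true(all(sol$u >= 0 & sol$u <= 1))
})

test_that("transversality holds with a nonzero terminal penalty", {
  m <- two_population_model(0.4, 0.4)
  M <- diag(c(2, 1))
  prob <- oc_problem(m, cost_spec(diag(2), diag(0.1, 2), M, T = 3), c(1, 1))
  sol <- solve_oc(prob, fast_settings())
  xT <- sol$x[nrow(sol$x), ]
  lamT <- sol$lam[nrow(sol$lam), ]
  expect_equal(unname(lamT), unname(drop(M %*% xT)), tolerance = 1e-7)
})

test_that("solve matches the backward-Riccati LQR reference", {
  set.seed(20)
  for (rep in 1:3) {
    sys <- random_stable_lqr()
    model <- controlled_ode_model(A = sys$A, B = sys$B)
    prob <- oc_problem(model, cost_spec(sys$Q, sys$R, sys$M, T = 2),
                       sys$x0,
                       control_bounds = list(lower = -1e6, upper = 1e6))
    sol <- suppressWarnings(solve_oc(prob, oc_solver_settings(n_nodes = 201)))
    orc <- riccati_lqr(sys$A, sys$B, sys$Q, sys$R, sys$M, 2, sys$x0, sol$t)
    expect_lt(max(abs(sol$x - orc$x)), 1e-5)
    expect_lt(max(abs(sol$u - orc$u)), 1e-5)
  }
})

test_that("forward simulation reproduces closed forms and solved schedules", {
  # constant state when nothing moves
  m0 <- controlled_ode_model(A = matrix(0, 1, 1), m = 1)
  traj <- simulate_forward(m0, 2, function(t) 0, T = 5)
  expect_equal(unname(traj$x[, 1]), rep(2, length(traj$t)), tolerance = 1e-10)
  # scalar exponential growth
  mg <- controlled_ode_model(A = matrix(0.3, 1, 1), m = 1)
  tg <- seq(0, 4, length.out = 41)
  traj <- simulate_forward(mg, 1.5, function(t) 0, T = 4, t_out = tg)
  expect_equal(unname(traj$x[, 1]), 1.5 * exp(0.3 * tg), tolerance = 1e-6)
  # replaying a solved schedule reproduces the solution state
  prob <- default_problem(two_population_model(0.5, 0.5))
  sol <- solve_oc(prob)
  replay <- simulate_forward(prob$model, prob$x0, control_schedule(sol), 7,
                             t_out = sol$t)
  expect_lt(max(abs(replay$x - sol$x)), 5e-4)
})

test_that("non-convergence raises a diagnosable error with history", {
  prob <- default_problem(two_population_model(0.5, 0.5))
  err <- tryCatch(
    solve_oc(prob, oc_solver_settings(n_nodes = 61, max_iter = 1)),
    error = function(e) e)
  expect_s3_class(err, "octherapy_nonconvergence")
  expect_true(length(err$history) >= 1)
})
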