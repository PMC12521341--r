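# Proportion-control variant: simplex dynamics, adjoint/gradient exactness,
# equivalence with normalised count dynamics, and the solver.

make_prop <- function(model = neuroblastoma_reduced_model(0.3, 0.2, 0.4),
                      target = c(0.2, 0.6, 0.2), T = 3,
                      r0 = rep(1, 3) / 3) {
  proportion_problem(model, target = target, W_state = diag(length(target)),
                     W_control = diag(0.1, model$m), T = T, r0 = r0)
}

test_that("proportion dynamics conserve the simplex identically", {
  set.seed(51)
  pp <- make_prop()
  for (rep in 1:20) {
    r <- runif(3); r <- r / sum(r)
    u <- runif(4)
    expect_equal(sum(proportion_rhs(pp, r, u)), 0, tolerance = 1e-14)
  }
  # uniform growth preserves proportions
  mu <- controlled_ode_model(A = diag(0.7, 2), m = 2)
  ppu <- proportion_problem(mu, target = c(0.5, 0.5), W_state = diag(2),
                            W_control = diag(2), T = 1, r0 = c(0.3, 0.7))
  expect_equal(proportion_rhs(ppu, c(0.3, 0.7), c(0, 0)), c(0, 0),
               tolerance = 1e-14)
})

test_that("proportion rate matches differentiated normalised counts", {
  # oracle: simulate the count dynamics from matching absolute counts and
  # numerically differentiate x / N at t = 0
  A <- matrix(c(0, 0, 1, -1), 2)
  m <- controlled_ode_model(A = A, m = 1)
  pp <- proportion_problem(m, target = c(0.5, 0.5), W_state = diag(2),
                           W_control = diag(1, 1), T = 1, r0 = c(0.5, 0.5))
  r <- c(0.5, 0.5); u <- 0
  drdt <- proportion_rhs(pp, r, u)
  # with sum(f) = 0 here the rate is the flux itself
  expect_equal(drdt, c(0.5, -0.5))
  h <- 1e-5
  traj <- simulate_forward(m, 4 * r, function(t) 0, T = h,
                           t_out = c(0, h), atol = 1e-12, rtol = 1e-12)
  rT <- traj$x[2, ] / sum(traj$x[2, ])
  expect_equal(unname((rT - r) / h), drdt, tolerance = 1e-4)
})

test_that("proportion adjoint and u-gradient are exact derivatives of H", {
  set.seed(52)
  pp <- make_prop()
  for (rep in 1:15) {
    r <- runif(3); r <- r / sum(r)
    u <- runif(4); lam <- runif(3, -1, 1)
    fd_adj <- -num_grad(function(rr) proportion_hamiltonian(pp, rr, u, lam), r)
    expect_equal(proportion_adjoint_rhs(pp, r, u, lam), fd_adj,
                 tolerance = 1e-6)
    fd_g <- num_grad(function(uu) proportion_hamiltonian(pp, r, uu, lam), u)
    expect_equal(proportion_optimality_gradient(pp, r, u, lam), fd_g,
                 tolerance = 1e-6)
  }
  # structural checks
  r <- c(0.2, 0.6, 0.2)
  expect_equal(proportion_optimality_gradient(pp, r, rep(0, 4), rep(0, 3)),
               rep(0, 4))
  # at lambda = 0, r = target the state-cost gradient vanishes, so the
  # adjoint rate is zero
  expect_equal(proportion_adjoint_rhs(pp, pp$target, runif(4), rep(0, 3)),
               rep(0, 3), tolerance = 1e-12)
  # C = D = 0: gradient reduces to W_control u, zero only at u = 0
  m0 <- controlled_ode_model(A = matrix(c(-1, 1, 1, -1), 2), m = 2)
  pp0 <- proportion_problem(m0, target = c(0.5, 0.5), W_state = diag(2),
                            W_control = diag(0.3, 2), T = 1,
                            r0 = c(0.5, 0.5))
  u <- c(0.4, 0.9)
  expect_equal(proportion_optimality_gradient(pp0, c(0.4, 0.6), u, c(1, -1)),
               0.3 * u)
})

test_that("models with additive control are rejected", {
  mB <- controlled_ode_model(A = diag(2), B = matrix(1, 2, 2))
  expect_error(proportion_problem(mB, c(0.5, 0.5), diag(2), diag(2), 1,
                                  c(0.5, 0.5)),
               "B = 0")
})

test_that("proportion and normalised count dynamics agree along schedules", {
  m <- two_population_model(0.3, 0.4)
  pp <- proportion_problem(m, target = c(0.8, 0.2), W_state = diag(2),
                           W_control = diag(0.1, 2), T = 5, r0 = c(0.4, 0.6))
  sched <- function(t) c(0.5 + 0.3 * sin(t), 0.7 * exp(-t / 3))
  tt <- seq(0, 5, length.out = 101)
  counts <- simulate_forward(m, c(0.8, 1.2), sched, 5, t_out = tt,
                             atol = 1e-10, rtol = 1e-10)
  rc <- counts$x / rowSums(counts$x)
  # integrate the proportion ODE directly with the same schedule
  dr <- function(t, r, parms) list(proportion_rhs(pp, r, sched(t)))
  rp <- deSolve::ode(c(0.4, 0.6), tt, dr, NULL, atol = 1e-10, rtol = 1e-10)
  expect_lt(max(abs(rc - rp[, -1])), 1e-7)
})

test_that("solve_proportion stays on the simplex and tracks the target", {
  m <- two_population_model(0.3, 0.4)
  pp <- proportion_problem(m, target = c(0.8, 0.2), W_state = diag(2),
                           W_control = diag(0.1, 2), T = 7, r0 = c(0.5, 0.5))
  sol <- solve_proportion(pp, fast_settings(161))
  expect_true(sol$converged)
  expect_lt(max(abs(rowSums(sol$x) - 1)), 1e-8)
  expect_lt(max(abs(sol$lam[nrow(sol$lam), ])), 1e-8)
  # closer to the target than the uncontrolled composition
  un <- simulate_forward(m, c(0.5, 0.5), c(0, 0), 7)
  r_un <- un$x[nrow(un$x), ] / sum(un$x[nrow(un$x), ])
  dev_ctrl <- max(abs(sol$x[nrow(sol$x), ] - pp$target))
  dev_un <- max(abs(r_un - pp$target))
  expect_lt(dev_ctrl, dev_un)
})

test_that("a target equal to the uncontrolled equilibrium needs no drug", {
  # uncontrolled equilibrium proportions of the two-population system: the
  # dominant eigenvector of A
  m <- two_population_model(0.3, 0.3)
  ev <- eigen(m$A)
  v <- ev$vectors[, which.max(Re(ev$values))]
  req <- abs(v) / sum(abs(v))
  pp <- proportion_problem(m, target = req, W_state = diag(2),
                           W_control = diag(0.1, 2), T = 5, r0 = req)
  sol <- solve_proportion(pp, fast_settings(121))
  expect_lt(max(abs(sol$u)), 2e-2)
  expect_lt(sol$J, 1e-3)
})
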