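# Independent oracles and generators used across the suite.  Everything
# here is deliberately written as direct scalar transcriptions or textbook
# reference algorithms, independent of the package internals they check.

# direct scalar evaluation of the two-population dynamics
# (x = (N_A, N_B), u = (u_c, u_p))
twopop_rhs_scalar <- function(alpha, beta, x, u) {
  c(2 * x[2] * (1 - u[2]) - x[1] * (1 - u[1]) - alpha * u[1] * x[1],
    -x[2] * (1 - u[2]) + x[1] * (1 - u[1]) - beta * u[2] * x[2])
}

# direct scalar evaluation of the full neuroblastoma dynamics
# (x = (n_I, n_N, n_S), u = (u_RA, u_chemo, u_trk, u_NGF))
nb_full_rhs_scalar <- function(p, x, u) {
  nI <- x[1]; nN <- x[2]; nS <- x[3]
  uRA <- u[1]; uch <- u[2]; utrk <- u[3]; ungf <- u[4]
  dI <- p$lambda_I * nI -
    (p$k[["IN"]] + p$k[["IS"]]) * nI + p$k[["NI"]] * nN + p$k[["SI"]] * nS -
    p$delta_RA * uRA * nI - p$delta_chemo * uch * nI -
    p$delta_diff * (1 - utrk) * ungf * nI +
    p$delta_BDNF * (1 - utrk) * nN
  dN <- p$lambda_N * nN -
    (p$k[["NS"]] + p$k[["NI"]]) * nN + p$k[["IN"]] * nI + p$k[["SN"]] * nS +
    p$delta_RA * uRA * nI -
    p$delta_trkNGF * (1 - ungf) * (1 - utrk) * nN +
    p$delta_diff * (1 - utrk) * ungf * nI -
    2 * p$delta_BDNF * (1 - utrk) * nN
  dS <- p$lambda_S * nS -
    (p$k[["SN"]] + p$k[["SI"]]) * nS + p$k[["IS"]] * nI + p$k[["NS"]] * nN +
    p$delta_BDNF * (1 - utrk) * nN
  c(dI, dN, dS)
}

# direct scalar evaluation of the reduced neuroblastoma dynamics
nb_reduced_rhs_scalar <- function(lambda, delta, delta_apop, x, u) {
  nI <- x[1]; nN <- x[2]; nS <- x[3]
  uRA <- u[1]; uch <- u[2]; utrk <- u[3]; ungf <- u[4]
  c((lambda - 2) * nI + nN + nS -
      (delta * uRA + 2 * lambda * uch + delta * (1 - utrk) * ungf) * nI +
      delta * (1 - utrk) * nN,
    -2 * nN + nI + nS + delta * (uRA + (1 - utrk) * ungf) * nI -
      (delta_apop * (1 - ungf) * (1 - utrk) + 2 * delta * (1 - utrk)) * nN,
    -2 * nS + nI + nN + delta * (1 - utrk) * nN)
}

random_nb_params <- function() {
  list(lambda = runif(1, 0.05, 0.5), delta = runif(1, 0.05, 0.5),
       delta_apop = runif(1, 0.05, 0.5))
}

# random fully-featured small model (entries in [-1, 1])
random_model <- function(n = sample(2:3, 1), m = sample(2:4, 1),
                         with_D = TRUE) {
  A <- matrix(runif(n * n, -1, 1), n)
  B <- matrix(runif(n * m, -1, 1), n, m)
  C <- replicate(n, matrix(runif(n * m, -1, 1), n, m), simplify = FALSE)
  D <- replicate(n, replicate(n, {
    d <- matrix(0, m, m)
    if (with_D) d[lower.tri(d)] <- runif(m * (m - 1) / 2, -1, 1)
    d
  }, simplify = FALSE), simplify = FALSE)
  controlled_ode_model(A, B, C, D, m = m)
}

# random problem with wide bounds around a random model
random_problem <- function(model, T = 1, wide = TRUE) {
  n <- model$n; m <- model$m
  Q <- crossprod(matrix(runif(n * n, -1, 1), n))
  R <- crossprod(matrix(runif(m * m, -1, 1), m)) + diag(m)
  bounds <- if (wide) list(lower = -1e8, upper = 1e8)
            else list(lower = 0, upper = 1)
  oc_problem(model, cost_spec(Q, R, NULL, T), x0 = runif(n),
             control_bounds = bounds)
}

# central finite difference of a scalar function
num_grad <- function(f, x, e = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + e
    xm <- x; xm[i] <- xm[i] - e
    (f(xp) - f(xm)) / (2 * e)
  }, numeric(1))
}

# textbook LQR reference: integrate the Riccati equation backward with a
# dense output, then the closed-loop state forward.
riccati_lqr <- function(A, B, Q, R, M, T, x0, t_out) {
  n <- nrow(A)
  dPs <- function(s, p, parms) {
    P <- matrix(p, n, n)
    list(as.vector(t(A) %*% P + P %*% A -
                     P %*% B %*% solve(R, t(B) %*% P) + Q))
  }
  ts <- seq(0, T, length.out = 2001)
  solP <- deSolve::ode(as.vector(M), ts, dPs, NULL,
                       atol = 1e-10, rtol = 1e-10)
  Pf <- apply(solP[, -1, drop = FALSE], 2,
              function(col) stats::splinefun(ts, col))
  Pt <- function(t) matrix(vapply(Pf, function(f) f(T - t), 0), n, n)
  dx <- function(t, x, parms) {
    u <- -solve(R, t(B) %*% Pt(t) %*% x)
    list(as.vector(A %*% x + B %*% u))
  }
  xs <- deSolve::ode(x0, t_out, dx, NULL, atol = 1e-10, rtol = 1e-10)
  x <- unname(xs[, -1, drop = FALSE])
  u <- t(vapply(seq_along(t_out), function(i) {
    as.vector(-solve(R, t(B) %*% Pt(t_out[i]) %*% x[i, ]))
  }, numeric(ncol(B))))
  list(x = x, u = u)
}

# stable random system for LQR checks
random_stable_lqr <- function(n = 2, m = 2) {
  A <- matrix(rnorm(n * n), n)
  A <- A - diag(max(Re(eigen(A)$values)) + 0.5, n)
  B <- matrix(rnorm(n * m), n, m)
  list(A = A, B = B, Q = diag(n), R = diag(m) * 0.5,
       M = matrix(0, n, n), x0 = runif(n, 0.5, 1.5))
}

# brute-force box minimiser of the Hamiltonian in u on a dense grid
grid_min_H <- function(problem, x, lam, steps = 201) {
  m <- problem$model$m
  gr <- seq(0, 1, length.out = steps)
  if (m == 2) {
    best <- c(NA, NA); bestH <- Inf
    for (u1 in gr) for (u2 in gr) {
      H <- hamiltonian(problem, x, c(u1, u2), lam)
      if (H < bestH) { bestH <- H; best <- c(u1, u2) }
    }
    return(best)
  }
  stop("grid oracle implemented for m = 2 only")
}

fast_settings <- function(n_nodes = 101L) oc_solver_settings(n_nodes = n_nodes)
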