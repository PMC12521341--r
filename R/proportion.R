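#' Optimal control problem over cell-type proportions
#'
#' For a population with counts \eqn{x} and total \eqn{N = 1^T x}, the
#' proportions \eqn{r = x / N} obey autonomous dynamics: writing
#' \eqn{f(r, u)} for the count right-hand side evaluated at \eqn{r} (valid
#' when there is no additive control, \eqn{B = 0}, so the right-hand side
#' is homogeneous of degree one in the state), the quotient rule gives
#' \deqn{\dot r = f(r, u) - (1^T f(r, u))\, r,}
#' which preserves \eqn{\sum_i r_i = 1} exactly.  The cost penalises
#' deviation from a target composition \eqn{\tilde r} and control effort:
#' \deqn{J = \tfrac12 \int_0^T \{(r - \tilde r)^T W_{state} (r - \tilde r)
#'   + u^T W_{control}\, u\}\, dt.}
#' The weight matrices are named neutrally (`W_state` penalises the state
#' deviation, `W_control` the dose) to avoid any ambiguity with the
#' count-problem matrices Q and R, whose roles they play respectively.
#' There is no terminal cost, so the transversality condition is
#' \eqn{\lambda(T) = 0}.
#'
#' @param model a [controlled_ode_model()] with `B = 0` (models with
#'   additive control are rejected: proportion dynamics are only autonomous
#'   without it).
#' @param target length-n target proportions (must sum to 1).
#' @param W_state n x n symmetric positive semi-definite deviation weight.
#' @param W_control m x m symmetric positive-definite dose weight.
#' @param T horizon.
#' @param r0 initial proportions (must sum to 1).
#' @param control_bounds as in [oc_problem()].
#' @return An object of class `proportion_problem`.
#' @export
proportion_problem <- function(model, target, W_state, W_control, T, r0,
                               control_bounds = list(lower = 0, upper = 1)) {
  stopifnot(inherits(model, "controlled_ode_model"))
  if (any(model$B != 0)) {
    stop("proportion dynamics require B = 0 (no additive control)")
  }
  if (length(target) != model$n || abs(sum(target) - 1) > 1e-10) {
    stop("target proportions must have length n and sum to 1")
  }
  if (length(r0) != model$n || abs(sum(r0) - 1) > 1e-10) {
    stop("initial proportions must have length n and sum to 1")
  }
  if (any(r0 < 0) || any(target < 0)) {
    stop("proportions must be nonnegative")
  }
  cost <- cost_spec(Q = W_state, R = W_control, M = NULL, T = T)
  lower <- rep_len(control_bounds$lower, model$m)
  upper <- rep_len(control_bounds$upper, model$m)
  structure(list(model = model, cost = cost, target = as.numeric(target),
                 x0 = as.numeric(r0), lower = lower, upper = upper),
            class = c("proportion_problem", "oc_problem"))
}

#' Normalised flux f(r, u): the count right-hand side evaluated at the
#' proportion vector (B = 0).
#' @noRd
proportion_flux <- function(model, r, u) {
  drop(model$A %*% r) + linear_control_term(model, r, u) +
    interaction_term(model, r, u)
}

#' Proportion dynamics
#'
#' Evaluates \eqn{\dot r = f(r, u) - (1^T f)\, r} at a single point.  The
#' components always sum to zero when \eqn{\sum r_i = 1}, so the simplex is
#' invariant.
#'
#' @param problem a [proportion_problem()].
#' @param r proportion vector.
#' @param u control vector.
#' @return Length-n rate vector summing to zero on the simplex.
#' @export
proportion_rhs <- function(problem, r, u) {
  f <- proportion_flux(problem$model, r, u)
  f - sum(f) * r
}

#' Hamiltonian of the proportion problem
#'
#' \deqn{H = \tfrac12\{(r-\tilde r)^T W_{state} (r-\tilde r) +
#'   u^T W_{control} u\} + \lambda\cdot\dot r.}
#'
#' @inheritParams proportion_rhs
#' @param lam adjoint vector.
#' @return Scalar.
#' @export
proportion_hamiltonian <- function(problem, r, u, lam) {
  dev <- r - problem$target
  0.5 * (drop(dev %*% cost_Q(problem$cost) %*% dev) +
           drop(u %*% cost_R(problem$cost) %*% u)) +
    sum(lam * proportion_rhs(problem, r, u))
}

#' Adjoint dynamics of the proportion problem
#'
#' Evaluates \eqn{\dot\lambda = -\partial H / \partial r}.  With
#' \eqn{J_f = \partial f/\partial r} (state Jacobian of the normalised
#' flux), the quotient structure of the dynamics yields
#' \deqn{\dot\lambda = -\big[W_{state}(r - \tilde r) + J_f^T\lambda
#'   - (\lambda^T r)\, J_f^T 1 - (1^T f)\,\lambda\big].}
#'
#' @inheritParams proportion_hamiltonian
#' @return Length-n co-state rate vector.
#' @export
proportion_adjoint_rhs <- function(problem, r, u, lam) {
  model <- problem$model
  f <- proportion_flux(model, r, u)
  Jf <- model_state_jacobian(model, u)
  dev <- r - problem$target
  -(drop(cost_Q(problem$cost) %*% dev) + drop(t(Jf) %*% lam) -
      sum(lam * r) * drop(t(Jf) %*% rep(1, model$n)) -
      sum(f) * lam)
}

#' Gradient of the proportion Hamiltonian in the control
#'
#' The Hamiltonian is quadratic in \eqn{u}:
#' \eqn{\partial H/\partial u = G_p u + b_p} with
#' \deqn{G_p = W_{control} + \sum_{i,j} r_i \lambda_j S^{ij}
#'   - (\lambda^T r) \sum_i r_i \sum_j S^{ij}, \qquad
#'   b_p = W(r)^T\big(\lambda - (\lambda^T r)\,1\big),}
#' where \eqn{S^{ij} = D^{ij} + (D^{ij})^T} and
#' \eqn{W(r) = \sum_i r_i C_i}.
#'
#' @inheritParams proportion_hamiltonian
#' @return Length-m gradient vector.
#' @export
proportion_optimality_gradient <- function(problem, r, u, lam) {
  gb <- proportion_G_b_point(problem, r, lam)
  drop(gb$G %*% u) + gb$b
}

#' @noRd
proportion_G_b_point <- function(problem, r, lam) {
  model <- problem$model
  G <- cost_R(problem$cost)
  lr <- sum(lam * r)
  for (blk in nonzero_interactions(model)) {
    G <- G + r[blk$i] * (lam[blk$j] - lr) * blk$Sm
  }
  W <- model_control_matrix(model, r)   # B = 0 here
  b <- drop(t(W) %*% (lam - lr * rep(1, model$n)))
  list(G = G, b = b)
}

#' Vectorised stage functions for the proportion problem.
#' @noRd
make_prop_stage <- function(problem, settings) {
  model <- problem$model
  n <- model$n; m <- model$m
  A <- model$A; C <- model$C
  blocks <- nonzero_interactions(model)
  Ws <- cost_Q(problem$cost); Wc <- cost_R(problem$cost)
  lower <- problem$lower; upper <- problem$upper
  target <- problem$target
  ones <- rep(1, n)

  quadU <- function(Dm, U) {
    q <- numeric(ncol(U))
    nz <- which(Dm != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      q <- q + Dm[nz[r, 1], nz[r, 2]] * U[nz[r, 1], ] * U[nz[r, 2], ]
    }
    q
  }

  G_b <- function(Rm, LAM) {
    N <- ncol(Rm)
    lr <- colSums(LAM * Rm)
    # b = W(r)' (lam - lr 1) = sum_i r_i C_i' (lam - lr 1)
    b <- matrix(0, m, N)
    LL <- LAM - rep(lr, each = n)
    for (i in seq_len(n)) {
      b <- b + crossprod(C[[i]], LL) * rep(Rm[i, ], each = m)
    }
    if (length(blocks) == 0L) return(list(G = Wc, b = b))
    G <- array(0, c(m, m, N))
    G[] <- rep(as.vector(Wc), N)
    for (blk in blocks) {
      w <- Rm[blk$i, ] * (LAM[blk$j, ] - lr)
      nz <- which(blk$Sm != 0, arr.ind = TRUE)
      for (q in seq_len(nrow(nz))) {
        k <- nz[q, 1]; l <- nz[q, 2]
        G[k, l, ] <- G[k, l, ] + blk$Sm[k, l] * w
      }
    }
    list(G = G, b = b)
  }

  eps <- if (is.null(settings$smooth_eps)) 0 else settings$smooth_eps
  control <- function(Rm, LAM, t) {
    gb <- G_b(Rm, LAM)
    boxqp_traj(gb$G, gb$b, lower, upper, sweeps = settings$cd_sweeps,
               eps = eps)
  }

  control_gradient <- function(Rm, LAM, U, t) {
    gb <- G_b(Rm, LAM)
    if (is.matrix(gb$G)) {
      gb$G %*% U + gb$b
    } else {
      g <- gb$b
      for (k in seq_len(m)) for (l in seq_len(m)) {
        g[k, ] <- g[k, ] + gb$G[k, l, ] * U[l, ]
      }
      g
    }
  }

  flux <- function(Rm, U) {
    out <- A %*% Rm
    for (i in seq_len(n)) {
      out <- out + (C[[i]] %*% U) * rep(Rm[i, ], each = n)
    }
    for (blk in blocks) {
      out[blk$j, ] <- out[blk$j, ] + Rm[blk$i, ] * quadU(blk$Dm, U)
    }
    out
  }

  f <- function(Rm, U, t) {
    fx <- flux(Rm, U)
    fx - Rm * rep(colSums(fx), each = n)
  }

  adj <- function(Rm, U, LAM, t) {
    N <- ncol(Rm)
    fx <- flux(Rm, U)
    sumf <- colSums(fx)
    lr <- colSums(LAM * Rm)
    # Jf' lam and Jf' 1, column by column in vectorised pieces
    JtL <- crossprod(A, LAM)
    Jt1 <- matrix(colSums(A), n, N)
    for (i in seq_len(n)) {
      CU <- C[[i]] %*% U
      JtL[i, ] <- JtL[i, ] + colSums(CU * LAM)
      Jt1[i, ] <- Jt1[i, ] + colSums(CU)
    }
    for (blk in blocks) {
      q <- quadU(blk$Dm, U)
      JtL[blk$i, ] <- JtL[blk$i, ] + q * LAM[blk$j, ]
      Jt1[blk$i, ] <- Jt1[blk$i, ] + q
    }
    dev <- Rm - target
    -(Ws %*% dev + JtL - Jt1 * rep(lr, each = n) -
        LAM * rep(sumf, each = n))
  }

  terminal <- function(rT, lamT) lamT

  list(n = n, m = m, control = control, control_gradient = control_gradient,
       f = f, adj = adj, terminal = terminal)
}

#' Solve the proportion-control problem
#'
#' Same collocation machinery as [solve_oc()], applied to the coupled
#' system \eqn{\dot r = f - (1^T f) r}, \eqn{\dot\lambda = -\partial
#' H/\partial r}, with the control eliminated pointwise by minimising the
#' (quadratic-in-u) Hamiltonian over the admissible box, boundary
#' conditions \eqn{r(0) = r_0} and \eqn{\lambda(T) = 0}.
#'
#' @param problem a [proportion_problem()].
#' @param settings an [oc_solver_settings()].
#' @param init optional initial guess (see [solve_oc()]).
#' @return An `oc_solution` whose state columns are proportions `r_1..r_n`.
#' @export
solve_proportion <- function(problem, settings = oc_solver_settings(),
                             init = NULL) {
  stopifnot(inherits(problem, "proportion_problem"))
  raw <- run_bvp(problem, settings, init,
                 function(s) make_prop_stage(problem, s))
  stage <- make_prop_stage(problem, settings)
  sol <- finish_solution(raw, problem, stage, settings, kind = "prop")
  drift <- max(abs(rowSums(sol$x) - 1))
  if (drift > 1e-8) {
    warning(sprintf("proportions drift off the simplex by %.3g", drift))
  }
  sol
}
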