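#' Quadratic cost specification for a finite-horizon control problem
#'
#' Defines the functional
#' \deqn{J(u) = \tfrac12\Big[x(T)^T M x(T) +
#'   \int_0^T \{x^T Q x + u^T R u\}\,dt\Big],}
#' with `M` (terminal-state penalty) and `Q` (running-state penalty)
#' symmetric positive semi-definite and `R` (control/toxicity penalty)
#' symmetric positive definite.  `Q` and `R` may be supplied as functions of
#' time; every shipped example uses constants.
#'
#' @param Q n x n running-state penalty (matrix, or function of t
#'   returning one).
#' @param R m x m control penalty (matrix, or function of t).
#' @param M n x n terminal-state penalty; defaults to zero (in which case
#'   the transversality condition reduces to \eqn{\lambda(T) = 0}).
#' @param T horizon in rescaled time (> 0).
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(Q, R, M = NULL, T) {
  stopifnot(is.numeric(T), length(T) == 1L, T > 0)
  Q0 <- if (is.function(Q)) Q(0) else Q
  R0 <- if (is.function(R)) R(0) else R
  if (!is_square(Q0)) stop("Q must be a square matrix")
  if (!is_square(R0)) stop("R must be a square matrix")
  if (is.null(M)) M <- matrix(0, nrow(Q0), nrow(Q0))
  check_penalty <- function(mat, name, definite = FALSE) {
    if (!is_symmetric_rel(mat, 1e-12)) {
      stop(sprintf("%s must be symmetric (to 1e-12 relative)", name))
    }
    ev <- eigen((mat + t(mat)) / 2, symmetric = TRUE, only.values = TRUE)$values
    tol <- 1e-12 * (max(abs(ev)) + 1)
    if (definite && min(ev) <= tol) {
      stop(sprintf("%s must be positive definite", name))
    }
    if (!definite && min(ev) < -tol) {
      stop(sprintf("%s must be positive semi-definite", name))
    }
  }
  check_penalty(Q0, "Q"); check_penalty(M, "M")
  check_penalty(R0, "R", definite = TRUE)
  structure(list(Q = Q, R = R, M = M, T = T,
                 n = nrow(Q0), m = nrow(R0)),
            class = "cost_spec")
}

#' @noRd
cost_Q <- function(cost, t = 0) if (is.function(cost$Q)) cost$Q(t) else cost$Q

#' @noRd
cost_R <- function(cost, t = 0) if (is.function(cost$R)) cost$R(t) else cost$R

#' Optimal control problem: model + cost + initial state + control bounds
#'
#' @param model a [controlled_ode_model()].
#' @param cost a [cost_spec()] with dimensions matching the model.
#' @param x0 length-n nonnegative initial state.
#' @param control_bounds list with numeric vectors `lower` and `upper`
#'   (length m or scalars); defaults to the pharmacodynamic box
#'   \eqn{[0, 1]^m}.
#' @return An object of class `oc_problem`.
#' @export
oc_problem <- function(model, cost, x0,
                       control_bounds = list(lower = 0, upper = 1)) {
  stopifnot(inherits(model, "controlled_ode_model"),
            inherits(cost, "cost_spec"))
  if (cost$n != model$n || cost$m != model$m) {
    stop("cost matrices are not dimensioned for this model")
  }
  if (length(x0) != model$n) stop("x0 has the wrong length")
  if (any(x0 < 0)) stop("x0 must be nonnegative")
  lower <- rep_len(control_bounds$lower, model$m)
  upper <- rep_len(control_bounds$upper, model$m)
  if (any(lower >= upper)) stop("control bounds require lower < upper")
  structure(list(model = model, cost = cost, x0 = as.numeric(x0),
                 lower = lower, upper = upper),
            class = "oc_problem")
}

#' @export
print.oc_problem <- function(x, ...) {
  cat(sprintf("Optimal control problem on [0, %g]: n = %d, m = %d\n",
              x$cost$T, x$model$n, x$model$m))
  cat(sprintf("  x0 = (%s); control box [%s] x [%s]\n",
              paste(signif(x$x0, 4), collapse = ", "),
              paste(x$lower, collapse = ", "),
              paste(x$upper, collapse = ", ")))
  invisible(x)
}

#' Control Hamiltonian
#'
#' \deqn{H(x, u, \lambda, t) = \tfrac12\big(x^T Q x + u^T R u\big) +
#'   \lambda \cdot f(x, u),}
#' with \eqn{f} the model right-hand side.  The adjoint dynamics are
#' \eqn{\dot\lambda = -\partial H/\partial x} and the optimal control makes
#' \eqn{H} stationary in \eqn{u} on the admissible box.
#'
#' @param problem an [oc_problem()].
#' @param x state vector.
#' @param u control vector.
#' @param lam adjoint (co-state) vector.
#' @param t time (used only for time-varying penalties).
#' @return Scalar value of H.
#' @export
hamiltonian <- function(problem, x, u, lam, t = 0) {
  Q <- cost_Q(problem$cost, t); R <- cost_R(problem$cost, t)
  0.5 * (drop(x %*% Q %*% x) + drop(u %*% R %*% u)) +
    sum(lam * model_rhs(problem$model, x, u))
}

#' Adjoint (co-state) dynamics
#'
#' Evaluates \eqn{\dot\lambda = -\partial H/\partial x =
#' -Qx - J_f(x, u)^T \lambda}, where \eqn{J_f} is the state Jacobian of the
#' dynamics; expanded, the bilinear term contributes
#' \eqn{-\sum_i e_i (C_i u)^T\lambda} and the synergy term
#' \eqn{-\sum_i e_i (\sum_j e_j u^T D^{ij} u)^T\lambda}.
#'
#' @inheritParams hamiltonian
#' @return Length-n rate vector for the co-state.
#' @export
adjoint_rhs <- function(problem, x, u, lam, t = 0) {
  Q <- cost_Q(problem$cost, t)
  Jf <- model_state_jacobian(problem$model, u)
  -drop(Q %*% x) - drop(t(Jf) %*% lam)
}

#' Box-constrained stationary control
#'
#' The Hamiltonian is quadratic in the control with Hessian
#' \deqn{G = R + \sum_{i,j} x_i \lambda_j \big(D^{ij} + (D^{ij})^T\big)}
#' and linear coefficient \eqn{b = (B + \sum_i x_i C_i)^T \lambda}.  The
#' unconstrained stationary point is \eqn{-G^{-1} b}; the returned control
#' is its projection onto the admissible box (componentwise clipping when
#' \eqn{G} is diagonal, with an exact coordinate-descent refinement
#' otherwise).
#'
#' @inheritParams hamiltonian
#' @param singular_tol condition-number threshold above which the
#'   stationarity system is declared singular (an error of class
#'   `octherapy_singular_optimality` is raised; singular-arc synthesis is
#'   out of scope).
#' @return List with elements `u` (projected control), `u_free`
#'   (unconstrained stationary point), `G`, `b` and `cond` (condition number
#'   of `G`).
#' @export
stationary_control <- function(problem, x, lam, t = 0,
                               singular_tol = 1e10) {
  model <- problem$model
  R <- cost_R(problem$cost, t)
  G <- R
  for (blk in nonzero_interactions(model)) {
    G <- G + x[blk$i] * lam[blk$j] * blk$Sm
  }
  b <- drop(t(model_control_matrix(model, x)) %*% lam)
  cond <- kappa(G, exact = TRUE)
  if (!is.finite(cond) || cond > singular_tol) {
    stop(structure(
      class = c("octherapy_singular_optimality", "error", "condition"),
      list(message = sprintf(
        "stationarity system is singular (condition number %.3g): the Hamiltonian has no isolated minimiser in u",
        cond),
        call = sys.call(-1), x = x, lam = lam, cond = cond)))
  }
  u_free <- drop(solve(G, -b))
  u <- drop(boxqp_traj(G, matrix(b, model$m, 1), problem$lower,
                       problem$upper))
  list(u = u, u_free = u_free, G = G, b = b, cond = cond)
}
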