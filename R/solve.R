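#' Solver settings for the state-costate boundary value problem
#'
#' The two-point boundary value problem is discretised by compact
#' Hermite--Simpson collocation (fourth order) on a uniform mesh and solved
#' with a damped Newton iteration on the full set of node unknowns, using a
#' sparse finite-difference Jacobian.  The control is eliminated pointwise
#' at every node and collocation midpoint through the box-constrained
#' stationarity condition.
#'
#' @param n_nodes number of mesh nodes on `[0, T]`.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the scaled residual infinity norm
#'   (collocation defects and boundary conditions alike).
#' @param cd_sweeps maximum coordinate-descent sweeps used to refine the
#'   projected control when the control Hessian is not diagonal.
#' @param singular_tol condition-number threshold for declaring the
#'   stationarity system singular (checked on the converged solution).
#' @param verbose print Newton residual norms.
#' @return A list of class `oc_solver_settings`.
#' @export
oc_solver_settings <- function(n_nodes = 241L, max_iter = 60L, tol = 1e-8,
                               cd_sweeps = 20L, singular_tol = 1e10,
                               verbose = FALSE) {
  stopifnot(n_nodes >= 5L, max_iter >= 1L, tol > 0)
  structure(list(n_nodes = as.integer(n_nodes),
                 max_iter = as.integer(max_iter), tol = tol,
                 cd_sweeps = as.integer(cd_sweeps),
                 singular_tol = singular_tol, verbose = isTRUE(verbose)),
            class = "oc_solver_settings")
}

# ---- vectorised trajectory kernels (count problem) -------------------------

#' Stage functions of the count optimal-control problem, vectorised over a
#' whole grid.  X, LAM are n x N; U is m x N; t is the length-N time vector.
#' @noRd
make_count_stage <- function(problem, settings) {
  model <- problem$model
  n <- model$n; m <- model$m
  A <- model$A; B <- model$B; C <- model$C
  blocks <- nonzero_interactions(model)
  lower <- problem$lower; upper <- problem$upper
  constQ <- !is.function(problem$cost$Q)
  constR <- !is.function(problem$cost$R)
  Qc <- cost_Q(problem$cost); Rc <- cost_R(problem$cost)

  quadU <- function(Dm, U) {
    # u' Dm u per column of U, exploiting sparsity of Dm
    q <- numeric(ncol(U))
    nz <- which(Dm != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      q <- q + Dm[nz[r, 1], nz[r, 2]] * U[nz[r, 1], ] * U[nz[r, 2], ]
    }
    q
  }

  control_G_b <- function(X, LAM, t) {
    N <- ncol(X)
    b <- crossprod(B, LAM)
    for (i in seq_len(n)) {
      b <- b + (crossprod(C[[i]], LAM)) * rep(X[i, ], each = m)
    }
    if (length(blocks) == 0L) {
      G <- if (constR) Rc else NULL
      if (is.null(G)) {
        G <- array(0, c(m, m, N))
        for (p in seq_len(N)) G[, , p] <- cost_R(problem$cost, t[p])
      }
    } else {
      G <- array(0, c(m, m, N))
      if (constR) {
        G[] <- rep(as.vector(Rc), N)
      } else {
        for (p in seq_len(N)) G[, , p] <- cost_R(problem$cost, t[p])
      }
      for (blk in blocks) {
        w <- X[blk$i, ] * LAM[blk$j, ]
        nz <- which(blk$Sm != 0, arr.ind = TRUE)
        for (r in seq_len(nrow(nz))) {
          k <- nz[r, 1]; l <- nz[r, 2]
          G[k, l, ] <- G[k, l, ] + blk$Sm[k, l] * w
        }
      }
    }
    list(G = G, b = b)
  }

  eps <- if (is.null(settings$smooth_eps)) 0 else settings$smooth_eps
  control <- function(X, LAM, t) {
    gb <- control_G_b(X, LAM, t)
    boxqp_traj(gb$G, gb$b, lower, upper, sweeps = settings$cd_sweeps,
               eps = eps)
  }

  # gradient of H in u along a trajectory (for stationarity diagnostics)
  control_gradient <- function(X, LAM, U, t) {
    gb <- control_G_b(X, LAM, t)
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

  f <- function(X, U, t) {
    N <- ncol(X)
    out <- A %*% X + B %*% U
    for (i in seq_len(n)) {
      out <- out + (C[[i]] %*% U) * rep(X[i, ], each = n)
    }
    for (blk in blocks) {
      out[blk$j, ] <- out[blk$j, ] + X[blk$i, ] * quadU(blk$Dm, U)
    }
    out
  }

  adj <- function(X, U, LAM, t) {
    N <- ncol(X)
    if (constQ) {
      QX <- Qc %*% X
    } else {
      QX <- X
      for (p in seq_len(N)) QX[, p] <- cost_Q(problem$cost, t[p]) %*% X[, p]
    }
    out <- -QX - crossprod(A, LAM)
    for (i in seq_len(n)) {
      out[i, ] <- out[i, ] - colSums((C[[i]] %*% U) * LAM)
    }
    for (blk in blocks) {
      out[blk$i, ] <- out[blk$i, ] - quadU(blk$Dm, U) * LAM[blk$j, ]
    }
    out
  }

  terminal <- function(xT, lamT) lamT - drop(problem$cost$M %*% xT)

  list(n = n, m = m, control = control, control_gradient = control_gradient,
       f = f, adj = adj, terminal = terminal)
}

# ---- collocation core ------------------------------------------------------

#' Hermite--Simpson collocation + damped Newton on the coupled
#' state/co-state system with pointwise control elimination.
#' @noRd
solve_collocation <- function(stage, x0, T, settings, init = NULL) {
  n <- stage$n
  N <- settings$n_nodes
  h <- T / (N - 1)
  tgrid <- seq(0, T, length.out = N)
  tmid <- (tgrid[-N] + tgrid[-1]) / 2
  d <- 2L * n

  residual <- function(Yv) {
    YM <- matrix(Yv, d, N)
    X <- YM[seq_len(n), , drop = FALSE]
    LAM <- YM[n + seq_len(n), , drop = FALSE]
    U <- stage$control(X, LAM, tgrid)
    FY <- rbind(stage$f(X, U, tgrid), stage$adj(X, U, LAM, tgrid))
    Ymid <- (YM[, -N, drop = FALSE] + YM[, -1, drop = FALSE]) / 2 +
      (h / 8) * (FY[, -N, drop = FALSE] - FY[, -1, drop = FALSE])
    Xm <- Ymid[seq_len(n), , drop = FALSE]
    Lm <- Ymid[n + seq_len(n), , drop = FALSE]
    Um <- stage$control(Xm, Lm, tmid)
    FYm <- rbind(stage$f(Xm, Um, tmid), stage$adj(Xm, Um, Lm, tmid))
    defect <- YM[, -1, drop = FALSE] - YM[, -N, drop = FALSE] -
      (h / 6) * (FY[, -N, drop = FALSE] + 4 * FYm + FY[, -1, drop = FALSE])
    c(as.vector(defect),
      X[, 1] - x0,
      stage$terminal(X[, N], LAM[, N]))
  }

  # residual rows influenced by the unknowns at a given node
  rows_of_node <- function(nd) {
    r <- integer(0)
    if (nd > 1L) r <- c(r, (nd - 2L) * d + seq_len(d))
    if (nd < N) r <- c(r, (nd - 1L) * d + seq_len(d))
    if (nd == 1L) r <- c(r, (N - 1L) * d + seq_len(n))
    if (nd == N) r <- c(r, (N - 1L) * d + n + seq_len(n))
    r
  }

  jacobian <- function(Yv, F0) {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (color in 0:2) {
      nodes <- which((seq_len(N) - 1L) %% 3L == color)
      for (comp in seq_len(d)) {
        cols <- (nodes - 1L) * d + comp
        eps <- 1e-7 * (1 + abs(Yv[cols]))
        Yp <- Yv
        Yp[cols] <- Yp[cols] + eps
        dF <- residual(Yp) - F0
        for (q in seq_along(nodes)) {
          r <- rows_of_node(nodes[q])
          val <- dF[r] / eps[q]
          keep <- val != 0
          if (any(keep)) {
            ii <- c(ii, r[keep])
            jj <- c(jj, rep.int(cols[q], sum(keep)))
            xx <- c(xx, val[keep])
          }
        }
      }
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d * N, d * N))
  }

  # initial guess: supplied trajectory or x == x0, lambda == 0
  YM <- matrix(0, d, N)
  YM[seq_len(n), ] <- x0
  if (!is.null(init)) {
    if (inherits(init, "oc_solution")) {
      init <- list(t = init$t, x = t(init$x), lam = t(init$lam))
    }
    YM[seq_len(n), ] <- resample_traj(init$t, init$x, tgrid)
    YM[n + seq_len(n), ] <- resample_traj(init$t, init$lam, tgrid)
  }
  Yv <- as.vector(YM)

  F0 <- residual(Yv)
  history <- max(abs(F0))
  converged <- max(abs(F0)) < settings$tol * (1 + max(abs(Yv)))
  iter <- 0L
  while (!converged && iter < settings$max_iter) {
    iter <- iter + 1L
    J <- jacobian(Yv, F0)
    dY <- tryCatch(as.numeric(Matrix::solve(J, -F0)),
                   error = function(e) NULL)
    if (is.null(dY) || any(!is.finite(dY))) {
      # regularised fallback for a (numerically) singular iteration matrix
      Jd <- J + Matrix::Diagonal(d * N, 1e-8)
      dY <- tryCatch(as.numeric(Matrix::solve(Jd, -F0)),
                     error = function(e) NULL)
      if (is.null(dY) || any(!is.finite(dY))) break
    }
    nrm0 <- sqrt(sum(F0^2))
    step <- 1
    repeat {
      Ft <- residual(Yv + step * dY)
      if (all(is.finite(Ft)) && sqrt(sum(Ft^2)) < (1 - 1e-4 * step) * nrm0) {
        break
      }
      step <- step / 2
      if (step < 2^-24) break
    }
    if (step < 2^-24) {
      # stagnation: accept no further progress
      break
    }
    Yv <- Yv + step * dY
    F0 <- Ft
    history <- c(history, max(abs(F0)))
    if (settings$verbose) {
      message(sprintf("  newton iter %2d: |F|_inf = %.3e (step %.3g)",
                      iter, max(abs(F0)), step))
    }
    converged <- max(abs(F0)) < settings$tol * (1 + max(abs(Yv)))
  }

  YM <- matrix(Yv, d, N)
  X <- YM[seq_len(n), , drop = FALSE]
  LAM <- YM[n + seq_len(n), , drop = FALSE]
  U <- stage$control(X, LAM, tgrid)
  list(t = tgrid, X = X, LAM = LAM, U = U, converged = converged,
       residual_norm = max(abs(F0)), n_iter = iter, history = history)
}

#' Run the collocation solver with globalisation.  Plain damped Newton from
#' the supplied guess is tried first.  If it stagnates (the residual is only
#' piecewise smooth at control-saturation kinks, and the coupled
#' state/co-state system grows stiffer with the horizon), the problem is
#' re-solved by horizon continuation: converged solutions on shorter
#' horizons, extended constantly in time, warm-start progressively longer
#' ones.  A stage that still fails is retried along a smoothing homotopy in
#' which the box projection of the control is rounded with a softplus
#' corner of radius eps driven to zero.
#' @noRd
run_bvp <- function(problem, settings, init, stage_builder) {
  T <- problem$cost$T
  attempt <- function(Tk, guess, eps = 0) {
    sk <- settings
    sk$smooth_eps <- eps
    solve_collocation(stage_builder(sk), problem$x0, Tk, sk, init = guess)
  }
  raw <- attempt(T, init)
  if (raw$converged) return(raw)
  cur <- init
  for (Tk in T * c(0.15, 0.3, 0.5, 0.75, 1)) {
    raw <- attempt(Tk, cur)
    if (!raw$converged) {
      cur2 <- cur
      for (eps in c(0.05, 0.01, 0)) {
        raw <- attempt(Tk, cur2, eps = eps)
        if (raw$converged) cur2 <- list(t = raw$t, x = raw$X, lam = raw$LAM)
      }
    }
    if (raw$converged) cur <- list(t = raw$t, x = raw$X, lam = raw$LAM)
    else if (Tk == T) return(raw)
  }
  raw
}

#' @noRd
finish_solution <- function(raw, problem, stage, settings, kind = "count") {
  tgrid <- raw$t
  X <- raw$X; LAM <- raw$LAM; U <- raw$U
  if (!raw$converged) {
    stop(structure(
      class = c("octherapy_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "boundary value solver did not converge (final residual %.3e after %d iterations)",
        raw$residual_norm, raw$n_iter),
        call = NULL, history = raw$history)))
  }
  g <- stage$control_gradient(X, LAM, U, tgrid)
  proj <- U - clip(U - g, problem$lower, problem$upper)
  stationarity <- max(abs(proj))
  # running cost by composite trapezoid on the solver mesh
  Q <- cost_Q(problem$cost); R <- cost_R(problem$cost)
  if (kind == "count") {
    run <- colSums(X * (Q %*% X)) + colSums(U * (R %*% U))
    J <- 0.5 * (drop(X[, ncol(X)] %*% problem$cost$M %*% X[, ncol(X)]) +
                  trapz(tgrid, run))
  } else {
    dev <- X - problem$target
    run <- colSums(dev * (Q %*% dev)) + colSums(U * (R %*% U))
    J <- 0.5 * trapz(tgrid, run)
  }
  lbl <- problem$model$labels
  state_names <- if (kind == "prop") paste0("r_", seq_len(problem$model$n))
                 else paste0("x_", seq_len(problem$model$n))
  xm <- t(X); colnames(xm) <- state_names
  lm <- t(LAM); colnames(lm) <- paste0("lam_", seq_len(problem$model$n))
  um <- t(U); colnames(um) <- paste0("u_", seq_len(problem$model$m))
  structure(list(
    t = tgrid, x = xm, lam = lm, u = um, J = J,
    converged = raw$converged,
    stationarity_residual = stationarity,
    bvp_diagnostics = list(residual_norm = raw$residual_norm,
                           n_nodes = length(tgrid),
                           n_iter = raw$n_iter,
                           history = raw$history),
    labels = lbl, kind = kind, problem = problem),
    class = "oc_solution")
}

#' Solve the optimal control problem
#'
#' Eliminates the control through the box-constrained stationarity
#' condition at every collocation point and solves the resulting
#' \eqn{2n}-dimensional two-point boundary value problem
#' \deqn{\dot x = f(x, u^\star(x,\lambda)), \qquad
#'       \dot\lambda = -\partial H/\partial x,}
#' with \eqn{x(0) = x_0} and the transversality condition
#' \eqn{\lambda(T) = M x(T)} (which reduces to \eqn{\lambda(T) = 0} for a
#' zero terminal penalty).
#'
#' @param problem an [oc_problem()].
#' @param settings an [oc_solver_settings()].
#' @param init optional initial guess: an `oc_solution` (e.g. from a nearby
#'   problem, for continuation) or a list with fields `t`, `x` (n x N) and
#'   `lam` (n x N).  The default guess is \eqn{x \equiv x_0},
#'   \eqn{\lambda \equiv 0}.
#' @return An object of class `oc_solution` with fields `t`, `x`, `lam`,
#'   `u` (node trajectories, one column per component), `J` (cost value by
#'   trapezoidal quadrature on the mesh), `stationarity_residual` (maximum
#'   projected-gradient norm of H in u over the mesh) and
#'   `bvp_diagnostics`.  Non-convergence raises an error of class
#'   `octherapy_nonconvergence` carrying the residual history.
#' @examples
#' prob <- default_problem(two_population_model(0.5, 0.5))
#' sol <- solve_oc(prob, oc_solver_settings(n_nodes = 61))
#' sol$J
#' @export
solve_oc <- function(problem, settings = oc_solver_settings(),
                     init = NULL) {
  stopifnot(inherits(problem, "oc_problem"))
  raw <- run_bvp(problem, settings, init,
                 function(s) make_count_stage(problem, s))
  stage <- make_count_stage(problem, settings)
  sol <- finish_solution(raw, problem, stage, settings, kind = "count")
  check_singularity(problem, sol, settings)
  state_nonneg_diagnostic(sol$x)
  sol
}

#' On the converged trajectory, verify the control Hessian stays
#' well-conditioned (otherwise the pointwise elimination was not licit).
#' @noRd
check_singularity <- function(problem, sol, settings) {
  blocks <- nonzero_interactions(problem$model)
  R <- cost_R(problem$cost)
  if (length(blocks) == 0L) {
    cond <- kappa(R, exact = TRUE)
    if (cond > settings$singular_tol) {
      stop(structure(
        class = c("octherapy_singular_optimality", "error", "condition"),
        list(message = "control penalty R is numerically singular",
             call = NULL, cond = cond)))
    }
    return(invisible(TRUE))
  }
  idx <- unique(round(seq(1, length(sol$t), length.out = 25)))
  for (p in idx) {
    G <- R
    for (blk in blocks) {
      G <- G + sol$x[p, blk$i] * sol$lam[p, blk$j] * blk$Sm
    }
    cond <- kappa(G, exact = TRUE)
    if (!is.finite(cond) || cond > settings$singular_tol) {
      stop(structure(
        class = c("octherapy_singular_optimality", "error", "condition"),
        list(message = sprintf(
          "stationarity system is singular along the trajectory (t = %.3g, condition number %.3g)",
          sol$t[p], cond), call = NULL, cond = cond)))
    }
  }
  invisible(TRUE)
}

#' Runtime diagnostic on state nonnegativity: warn below a small tolerance,
#' error on clearly negative populations.
#' @noRd
state_nonneg_diagnostic <- function(x, warn_tol = -1e-8) {
  mn <- min(x)
  if (mn < warn_tol) {
    if (mn < -1e-4) {
      warning(sprintf(
        "state trajectory becomes markedly negative (min = %.3g); model signs are likely ill-posed",
        mn))
    } else {
      warning(sprintf("state trajectory dips slightly negative (min = %.3g)",
                      mn))
    }
  }
  invisible(mn)
}

#' @export
print.oc_solution <- function(x, ...) {
  cat(sprintf("Optimal control solution (%s problem)\n",
              if (x$kind == "prop") "proportion" else "cell-count"))
  cat(sprintf("  mesh: %d nodes on [0, %g]; converged: %s (residual %.2e, %d Newton iterations)\n",
              x$bvp_diagnostics$n_nodes, max(x$t),
              x$converged, x$bvp_diagnostics$residual_norm,
              x$bvp_diagnostics$n_iter))
  cat(sprintf("  J = %.6g; stationarity residual = %.2e\n",
              x$J, x$stationarity_residual))
  cat(sprintf("  final state: (%s)\n",
              paste(signif(x$x[nrow(x$x), ], 5), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.oc_solution <- function(x, ...) {
  data.frame(t = x$t, x$x, x$lam, x$u, check.names = FALSE)
}

# ---- forward simulation ----------------------------------------------------

#' @noRd
as_control_function <- function(u, m, T) {
  if (is.function(u)) return(u)
  if (is.numeric(u) && is.null(dim(u))) {
    stopifnot(length(u) == m)
    force(u)
    return(function(t) u)
  }
  if (is.list(u) && !is.null(u$t)) {
    tt <- u$t
    um <- u$u
    if (is.null(dim(um))) um <- matrix(um, ncol = 1)
    if (nrow(um) != length(tt)) um <- t(um)
    fns <- lapply(seq_len(ncol(um)), function(k) {
      stats::approxfun(tt, um[, k], rule = 2)
    })
    return(function(t) vapply(fns, function(f) f(t), numeric(1)))
  }
  stop("unsupported control schedule; supply a function, a constant vector, or list(t =, u =)")
}

#' Simulate the controlled dynamics forward under a given dosing schedule
#'
#' Integrates the model with a prescribed (open-loop) control schedule
#' using an adaptive, stiffness-switching integrator.  Used for
#' constant-dose comparators, replaying optimal schedules and the dosing
#' noise robustness analysis.
#'
#' @param model a [controlled_ode_model()].
#' @param x0 initial state (length n).
#' @param u dosing schedule: a function of time returning an m-vector, a
#'   constant m-vector, or a sampled trajectory `list(t =, u =)` (linearly
#'   interpolated).
#' @param T horizon.
#' @param t_out output time grid (default: 201 uniform points).
#' @param atol,rtol integrator tolerances.
#' @return A list of class `state_trajectory` with fields `t`, `x`
#'   (length(t) x n) and `u` (length(t) x m).
#' @export
simulate_forward <- function(model, x0, u, T, t_out = NULL,
                             atol = 1e-8, rtol = 1e-8) {
  stopifnot(inherits(model, "controlled_ode_model"), length(x0) == model$n)
  ufun <- as_control_function(u, model$m, T)
  if (is.null(t_out)) t_out <- seq(0, T, length.out = 201L)
  deriv <- function(t, x, parms) {
    list(model_rhs(model, x, ufun(t)))
  }
  out <- deSolve::ode(y = as.numeric(x0), times = t_out, func = deriv,
                      parms = NULL, method = "lsoda",
                      atol = atol, rtol = rtol)
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("forward integration failed; last accepted time %.6g",
                 max(out[, 1], na.rm = TRUE)))
  }
  xm <- unname(out[, -1, drop = FALSE])
  colnames(xm) <- paste0("x_", seq_len(model$n))
  um <- matrix(vapply(t_out, ufun, numeric(model$m)),
               nrow = length(t_out), ncol = model$m, byrow = TRUE)
  colnames(um) <- paste0("u_", seq_len(model$m))
  structure(list(t = t_out, x = xm, u = um), class = "state_trajectory")
}

#' Extract the control schedule of a solution as an interpolating function
#'
#' @param sol an `oc_solution`.
#' @return A function of time returning the (linearly interpolated)
#'   m-vector of controls.
#' @export
control_schedule <- function(sol) {
  as_control_function(list(t = sol$t, u = sol$u), ncol(sol$u), max(sol$t))
}

#' Resample a solution onto a uniform grid
#'
#' Linear interpolation of state, co-state and control onto `n_out`
#' uniformly spaced points; used to decouple integral summaries from the
#' solver mesh.
#'
#' @param sol an `oc_solution`.
#' @param n_out number of output points.
#' @return A list with fields `t`, `x`, `lam`, `u` (matrices with one row
#'   per output time).
#' @export
resample_solution <- function(sol, n_out = 2001L) {
  tt <- seq(0, max(sol$t), length.out = n_out)
  list(t = tt,
       x = t(resample_traj(sol$t, t(sol$x), tt)),
       lam = t(resample_traj(sol$t, t(sol$lam), tt)),
       u = t(resample_traj(sol$t, t(sol$u), tt)))
}
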