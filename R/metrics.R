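#' Evaluate the cost functional along sampled trajectories
#'
#' Computes
#' \deqn{J = \tfrac12\Big[x(T)^T M x(T) + \int_0^T \{x^T Q x +
#'   u^T R u\}\,dt\Big]}
#' by composite trapezoidal quadrature on the common time grid of the
#' supplied trajectories.
#'
#' @param problem an [oc_problem()] providing the penalty matrices.
#' @param traj a list with fields `t` (length N), `x` (N x n) and `u`
#'   (N x m); an `oc_solution` or `state_trajectory` also works, provided
#'   the control is carried on the same grid.
#' @return Scalar cost J.
#' @export
cost_functional <- function(problem, traj) {
  tt <- traj$t
  x <- traj$x; u <- traj$u
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(u))) u <- matrix(u, ncol = 1)
  if (nrow(x) != length(tt) || nrow(u) != length(tt)) {
    stop("trajectories must be co-sampled on a common grid")
  }
  Q <- cost_Q(problem$cost); R <- cost_R(problem$cost)
  run <- rowSums((x %*% Q) * x) + rowSums((u %*% R) * u)
  xT <- x[length(tt), ]
  0.5 * (drop(xT %*% problem$cost$M %*% xT) + trapz(tt, run))
}

#' Time-averaged dose of each drug
#'
#' \deqn{\bar u_k = \frac1T \int_0^T u_k(\tau)\, d\tau,} the constant
#' schedule with the same area under the curve as the supplied one.
#'
#' @param u a sampled control trajectory: `list(t =, u =)` with `u` of
#'   dimension N x m, or an `oc_solution`.
#' @param T horizon; defaults to the last time in the trajectory.
#' @return Length-m vector of mean doses.
#' @export
mean_control <- function(u, T = NULL) {
  if (inherits(u, "oc_solution")) u <- list(t = u$t, u = u$u)
  tt <- u$t
  if (length(tt) < 2L) stop("control trajectory is empty or degenerate")
  um <- u$u
  if (is.null(dim(um))) um <- matrix(um, ncol = 1)
  if (is.null(T)) T <- max(tt)
  apply(um, 2, function(col) trapz(tt, col)) / T
}

#' Integrated drug cost
#'
#' \eqn{\int_0^T u^T R u \, d\tau} by trapezoidal quadrature: the running
#' toxicity penalty accumulated over the treatment window (without the 1/2
#' factor of the full cost functional).
#'
#' @inheritParams mean_control
#' @param R m x m positive-definite control penalty.
#' @return Scalar integrated cost.
#' @export
integrated_drug_cost <- function(u, R) {
  if (inherits(u, "oc_solution")) u <- list(t = u$t, u = u$u)
  um <- u$u
  if (is.null(dim(um))) um <- matrix(um, ncol = 1)
  trapz(u$t, rowSums((um %*% R) * um))
}

#' Per-drug share of the integrated cost, u_k (R u)_k integrated in time.
#' @noRd
per_drug_cost <- function(u, R) {
  um <- u$u
  if (is.null(dim(um))) um <- matrix(um, ncol = 1)
  vapply(seq_len(ncol(um)), function(k) {
    trapz(u$t, um[, k] * (um %*% R)[, k])
  }, numeric(1))
}

#' Efficacy of the optimal schedule against matched constant dosing
#'
#' The comparator delivers each drug at the constant level \eqn{\bar u_k}
#' equal to the time average of the optimal schedule (same total exposure),
#' and only the state is re-simulated -- no new control problem is solved.
#' Efficacy is the ratio of final total cell counts,
#' \deqn{\eta = \frac{\sum_i \bar x_i(T)}{\sum_i x_i(T)},}
#' so \eqn{\eta > 1} means the optimal (time-varying) schedule ends with
#' fewer cells than constant dosing at the same average exposure.
#'
#' Both schedules are resampled onto a uniform 2001-point grid before
#' integration so that the summary does not depend on the solver mesh.
#'
#' @param problem the [oc_problem()] that was solved.
#' @param optimal a converged [solve_oc()] solution for `problem`.
#' @param n_grid resampling grid size.
#' @return An object of class `comparison_result`: a list with `eta`,
#'   `ubar`, `J_optimal`, `J_constant`, `drug_cost_optimal`,
#'   `drug_cost_constant`, `final_counts_optimal`, `final_counts_constant`.
#' @export
efficacy_ratio <- function(problem, optimal, n_grid = 2001L) {
  stopifnot(inherits(optimal, "oc_solution"))
  if (!isTRUE(optimal$converged)) stop("optimal solution did not converge")
  rs <- resample_solution(optimal, n_grid)
  T <- problem$cost$T
  ubar <- mean_control(list(t = rs$t, u = rs$u), T)
  total_opt <- sum(rs$x[length(rs$t), ])
  if (total_opt <= 0) {
    stop("optimal final total cell count is not positive; efficacy ratio undefined")
  }
  const <- simulate_forward(problem$model, problem$x0, ubar, T,
                            t_out = rs$t)
  R <- cost_R(problem$cost)
  res <- list(
    eta = sum(const$x[length(rs$t), ]) / total_opt,
    ubar = ubar,
    J_optimal = cost_functional(problem, list(t = rs$t, x = rs$x, u = rs$u)),
    J_constant = cost_functional(problem, const),
    drug_cost_optimal = integrated_drug_cost(list(t = rs$t, u = rs$u), R),
    drug_cost_constant = integrated_drug_cost(list(t = const$t, u = const$u), R),
    per_drug_cost_optimal = per_drug_cost(list(t = rs$t, u = rs$u), R),
    final_counts_optimal = rs$x[length(rs$t), ],
    final_counts_constant = const$x[length(rs$t), ])
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Efficacy ratio eta = %.4f (%s constant dosing)\n", x$eta,
              if (x$eta > 1) "optimal schedule beats"
              else "optimal schedule does not beat"))
  cat(sprintf("  mean doses: %s\n",
              paste(signif(x$ubar, 4), collapse = ", ")))
  cat(sprintf("  J: optimal %.5g vs constant %.5g; integrated drug cost: %.5g vs %.5g\n",
              x$J_optimal, x$J_constant,
              x$drug_cost_optimal, x$drug_cost_constant))
  invisible(x)
}

#' Write a treatment comparison to a flat key-value summary file
#'
#' One `key = value` line per quantity (efficacy ratio, mean doses, costs,
#' final counts), with full-precision decimal values; suitable to sit
#' alongside exported trajectory tables.
#'
#' @param cmp a [efficacy_ratio()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  stopifnot(inherits(cmp, "comparison_result"))
  kv <- comparison_to_kv(cmp)
  writeLines(paste(names(kv), fmt_num(kv), sep = " = "), path)
  invisible(path)
}

#' Flat key-value serialisation of a comparison result.
#' @noRd
comparison_to_kv <- function(cmp) {
  c(eta = cmp$eta,
    stats::setNames(cmp$ubar, paste0("ubar_", seq_along(cmp$ubar))),
    J_optimal = cmp$J_optimal, J_constant = cmp$J_constant,
    drug_cost_optimal = cmp$drug_cost_optimal,
    drug_cost_constant = cmp$drug_cost_constant,
    stats::setNames(cmp$final_counts_optimal,
                    paste0("final_opt_", seq_along(cmp$final_counts_optimal))),
    stats::setNames(cmp$final_counts_constant,
                    paste0("final_const_", seq_along(cmp$final_counts_constant))))
}
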