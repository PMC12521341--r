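# Parameter-space analyses: efficacy heat maps, toxicity splits, marginal
# maximum drug cost, per-drug sensitivity partition, dosing-noise
# robustness.

#' @noRd
solve_quietly <- function(problem, settings, init = NULL) {
  tryCatch(
    suppressWarnings(solve_oc(problem, settings, init = init)),
    error = function(e) e)
}

#' Efficacy sweep over the two-population kill-rate plane
#'
#' For every grid cell \eqn{(\alpha, \beta)} the two-population problem is
#' solved, the efficacy ratio \eqn{\eta} against matched constant dosing is
#' computed, and drug-cost summaries are recorded.  Cells where the solver
#' fails are flagged and carry no values; the sweep continues.
#'
#' @param alpha,beta numeric grids of rescaled kill rates (defaults: 10
#'   points each on `[0.05, 0.5]`).
#' @param T,R0 problem settings as in [default_problem()].
#' @param settings an [oc_solver_settings()].
#' @return A data frame of class `sweep_result` with one row per cell:
#'   `alpha`, `beta`, `eta`, `J_optimal`, `J_constant`, `drug_cost`,
#'   per-drug costs `cost_u_c`, `cost_u_p`, and `converged`.
#' @export
efficacy_sweep <- function(alpha = seq(0.05, 0.5, length.out = 10),
                           beta = seq(0.05, 0.5, length.out = 10),
                           T = 7, R0 = 0.1,
                           settings = oc_solver_settings()) {
  stopifnot(all(alpha > 0), all(beta > 0))
  grid <- expand.grid(alpha = alpha, beta = beta, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    a <- grid$alpha[g]; b <- grid$beta[g]
    prob <- default_problem(two_population_model(a, b), T = T, R0 = R0)
    sol <- solve_quietly(prob, settings)
    if (inherits(sol, "error")) {
      return(data.frame(alpha = a, beta = b, eta = NA_real_,
                        J_optimal = NA_real_, J_constant = NA_real_,
                        drug_cost = NA_real_, cost_u_c = NA_real_,
                        cost_u_p = NA_real_, converged = FALSE))
    }
    cmp <- efficacy_ratio(prob, sol)
    data.frame(alpha = a, beta = b, eta = cmp$eta,
               J_optimal = cmp$J_optimal, J_constant = cmp$J_constant,
               drug_cost = cmp$drug_cost_optimal,
               cost_u_c = cmp$per_drug_cost_optimal[1],
               cost_u_p = cmp$per_drug_cost_optimal[2],
               converged = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Toxicity-split sweep along the (alpha, beta) path
#'
#' Walks the arc of [toxicity_path()] while splitting a fixed total control
#' penalty \eqn{R_0} unevenly between the two drugs,
#' \eqn{R = \mathrm{diag}(R_\alpha, R_0 - R_\alpha)}, and records the
#' efficacy ratio in every cell.  The symmetric split
#' \eqn{R_\alpha = R_0/2} with \eqn{R_0 = 2\times 10^{-1}} reproduces the
#' baseline penalty \eqn{R = 10^{-1} I}.
#'
#' @param R_alpha grid of cisplatin penalties, each in \eqn{(0, R_0)}.
#' @param phi grid of path positions in \eqn{[0, 2\pi/9]}.
#' @param R0 total penalty (default 0.2).
#' @param gamma0,gamma path parameters (see [toxicity_path()]).
#' @param T horizon.
#' @param settings an [oc_solver_settings()].
#' @return A `sweep_result` data frame with columns `R_alpha`, `R_beta`,
#'   `phi`, `alpha`, `beta`, `eta`, `drug_cost`, `converged`.
#' @export
toxicity_split_sweep <- function(R_alpha = seq(0.02, 0.18, length.out = 9),
                                 phi = seq(0, 2 * pi / 9, length.out = 9),
                                 R0 = 0.2, gamma0 = 0.05, gamma = 0.4,
                                 T = 7,
                                 settings = oc_solver_settings()) {
  stopifnot(all(R_alpha > 0), all(R_alpha < R0))
  grid <- expand.grid(R_alpha = R_alpha, phi = phi, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    Ra <- grid$R_alpha[g]; ph <- grid$phi[g]
    ab <- toxicity_path(ph, gamma0, gamma)
    prob <- default_problem(two_population_model(ab[1, "alpha"],
                                                 ab[1, "beta"]),
                            T = T, R = diag(c(Ra, R0 - Ra)))
    sol <- solve_quietly(prob, settings)
    base <- data.frame(R_alpha = Ra, R_beta = R0 - Ra, phi = ph,
                       alpha = ab[1, "alpha"], beta = ab[1, "beta"])
    if (inherits(sol, "error")) {
      return(cbind(base, eta = NA_real_, drug_cost = NA_real_,
                   converged = FALSE))
    }
    cmp <- efficacy_ratio(prob, sol)
    cbind(base, eta = cmp$eta, drug_cost = cmp$drug_cost_optimal,
          converged = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Maximum marginal drug cost over the neuroblastoma parameter cube
#'
#' For the reduced neuroblastoma model the integrated drug cost
#' \eqn{\tilde c(\lambda, \delta, \delta_{apop}) = \int u^T R u \, d\tau}
#' of the optimal schedule is evaluated on a full 3-d grid.  For each
#' ordered parameter pair the maximum marginal cost
#' \eqn{c(\zeta, \xi) = \max_\rho \tilde c(\zeta, \xi, \rho)} marginalises
#' the third parameter out; one-dimensional traces take the maximum over
#' both remaining parameters.
#'
#' @param lambda,delta,delta_apop parameter grids (defaults: 8 points each
#'   on `[0.05, 0.5]`).
#' @param T,R0 problem settings.
#' @param settings an [oc_solver_settings()].
#' @return A list of class `marginal_cost_result` with `ctilde` (long data
#'   frame over the full cube), `pairs` (named list of pairwise max-marginal
#'   data frames) and `traces` (long data frame of one-dimensional
#'   max-marginal traces).
#' @export
marginal_max_cost <- function(lambda = seq(0.05, 0.5, length.out = 8),
                              delta = seq(0.05, 0.5, length.out = 8),
                              delta_apop = seq(0.05, 0.5, length.out = 8),
                              T = 7, R0 = 0.1,
                              settings = oc_solver_settings()) {
  grid <- expand.grid(lambda = lambda, delta = delta,
                      delta_apop = delta_apop, KEEP.OUT.ATTRS = FALSE)
  grid$cost <- NA_real_
  grid$converged <- FALSE
  for (g in seq_len(nrow(grid))) {
    model <- neuroblastoma_reduced_model(grid$lambda[g], grid$delta[g],
                                         grid$delta_apop[g])
    prob <- default_problem(model, T = T, R0 = R0)
    sol <- solve_quietly(prob, settings)
    if (!inherits(sol, "error")) {
      grid$cost[g] <- integrated_drug_cost(sol, cost_R(prob$cost))
      grid$converged[g] <- TRUE
    }
  }
  vars <- c("lambda", "delta", "delta_apop")
  max_na <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  pairs <- list()
  for (a in seq_along(vars)) for (b in seq_along(vars)) {
    if (a == b) next
    key <- paste(vars[a], vars[b], sep = "_x_")
    agg <- stats::aggregate(grid$cost,
                            by = grid[, c(vars[a], vars[b])], FUN = max_na)
    names(agg)[3] <- "c"
    pairs[[key]] <- agg
  }
  traces <- do.call(rbind, lapply(vars, function(v) {
    agg <- stats::aggregate(grid$cost, by = grid[, v, drop = FALSE],
                            FUN = max_na)
    data.frame(parameter = v, value = agg[[1]], c = agg$x)
  }))
  structure(list(ctilde = grid, pairs = pairs, traces = traces),
            class = "marginal_cost_result")
}

#' Per-drug sensitivity of mean dose to the interconversion rate
#'
#' For each cell of the \eqn{(\lambda, \delta_{apop})} plane, the reduced
#' neuroblastoma problem is solved at every value of the interconversion
#' rate \eqn{\delta} in `delta`, and for each drug the variance (across
#' \eqn{\delta}) of its time-averaged dose is recorded:
#' \deqn{v_\bullet(\lambda, \delta_{apop}) = \mathrm{Var}_\delta
#'   \Big(\tfrac1T \int_0^T u_\bullet\, d\tau\Big).}
#' The drug with the largest variance is the one whose dosing must respond
#' most to the (hard to measure) interconversion rate; ties are broken by
#' the fixed drug order (RA, chemo, trk, NGF).
#'
#' @param lambda,delta_apop grids for the plane.
#' @param delta grid of interconversion rates marginalised into the
#'   variance (default: the three representative values 0.05, 0.25, 0.45).
#' @param T,R0 problem settings.
#' @param settings an [oc_solver_settings()].
#' @return A `sweep_result` data frame with columns `lambda`,
#'   `delta_apop`, `v_RA`, `v_chemo`, `v_trk`, `v_NGF`, `most_sensitive`,
#'   `n_converged`.
#' @export
sensitivity_partition <- function(lambda = seq(0.05, 0.5, length.out = 8),
                                  delta_apop = seq(0.05, 0.5, length.out = 8),
                                  delta = c(0.05, 0.25, 0.45),
                                  T = 7, R0 = 0.1,
                                  settings = oc_solver_settings()) {
  drugs <- c("RA", "chemo", "trk", "NGF")
  grid <- expand.grid(lambda = lambda, delta_apop = delta_apop,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    ubars <- matrix(NA_real_, length(delta), 4)
    for (di in seq_along(delta)) {
      model <- neuroblastoma_reduced_model(grid$lambda[g], delta[di],
                                           grid$delta_apop[g])
      prob <- default_problem(model, T = T, R0 = R0)
      sol <- solve_quietly(prob, settings)
      if (!inherits(sol, "error")) ubars[di, ] <- mean_control(sol)
    }
    ok <- stats::complete.cases(ubars)
    v <- if (sum(ok) >= 2) apply(ubars[ok, , drop = FALSE], 2, stats::var)
         else rep(0, 4)
    if (length(delta) == 1L) v <- rep(0, 4)
    data.frame(lambda = grid$lambda[g], delta_apop = grid$delta_apop[g],
               v_RA = v[1], v_chemo = v[2], v_trk = v[3], v_NGF = v[4],
               most_sensitive = drugs[which.max(v)],
               n_converged = sum(ok))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Ornstein--Uhlenbeck sample paths on a uniform grid (exact
#' discretisation; stationary start).
#' @noRd
ou_path <- function(tgrid, sd, corr_time = 1) {
  N <- length(tgrid)
  z <- numeric(N)
  if (sd == 0) return(z)
  dt <- diff(tgrid)
  a <- exp(-dt / corr_time)
  z[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(N - 1, 0, sd * sqrt(1 - a^2))
  for (i in seq_len(N - 1)) z[i + 1] <- a[i] * z[i] + innov[i]
  z
}

#' Batched fixed-step RK4 integration of the controlled dynamics for many
#' control schedules at once, all sampled on the same uniform grid.
#' `Uarr` is m x N x R (drugs x times x replicates).  Control values at
#' half-steps are the averages of adjacent samples (schedules are
#' piecewise linear).  Returns final states and the cost of each
#' replicate.  On a grid fine enough for the noise (step ~0.01 rescaled
#' time units) the O(h^4) integration error is far below the Monte-Carlo
#' resolution.
#' @noRd
simulate_batch_rk4 <- function(problem, tgrid, Uarr) {
  model <- problem$model
  n <- model$n; m <- model$m
  A <- model$A; B <- model$B; C <- model$C
  blocks <- nonzero_interactions(model)
  N <- length(tgrid); R <- dim(Uarr)[3]
  Q <- cost_Q(problem$cost); Rm <- cost_R(problem$cost)
  f <- function(X, U) {
    out <- A %*% X + B %*% U
    for (i in seq_len(n)) {
      out <- out + (C[[i]] %*% U) * rep(X[i, ], each = n)
    }
    for (blk in blocks) {
      q <- numeric(R)
      nz <- which(blk$Dm != 0, arr.ind = TRUE)
      for (rr in seq_len(nrow(nz))) {
        q <- q + blk$Dm[nz[rr, 1], nz[rr, 2]] *
          U[nz[rr, 1], ] * U[nz[rr, 2], ]
      }
      out[blk$j, ] <- out[blk$j, ] + X[blk$i, ] * q
    }
    out
  }
  X <- matrix(problem$x0, n, R)
  run_prev <- colSums(X * (Q %*% X)) + colSums(Uarr[, 1, ] * (Rm %*% Uarr[, 1, ]))
  Jrun <- numeric(R)
  for (i in seq_len(N - 1L)) {
    h <- tgrid[i + 1L] - tgrid[i]
    U1 <- matrix(Uarr[, i, ], m, R)
    U2 <- matrix(Uarr[, i + 1L, ], m, R)
    Umid <- (U1 + U2) / 2
    k1 <- f(X, U1)
    k2 <- f(X + (h / 2) * k1, Umid)
    k3 <- f(X + (h / 2) * k2, Umid)
    k4 <- f(X + h * k3, U2)
    X <- X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    run_next <- colSums(X * (Q %*% X)) + colSums(U2 * (Rm %*% U2))
    Jrun <- Jrun + (h / 2) * (run_prev + run_next)
    run_prev <- run_next
  }
  Jterm <- colSums(X * (problem$cost$M %*% X))
  list(xT = X, J = 0.5 * (Jterm + Jrun))
}

#' Monte-Carlo robustness of an optimal schedule to dosing noise
#'
#' Perturbs each drug trace of a converged solution with an independent
#' Ornstein--Uhlenbeck process (temporally correlated Gaussian noise with
#' stationary standard deviation equal to the amplitude and correlation
#' time `corr_time`, one rescaled time unit by default), clips the
#' perturbed schedule to the admissible box, re-simulates the state ODEs
#' and records final total cell counts and cost differences relative to the
#' unperturbed optimum.  Fully seeded and reproducible.
#'
#' @param problem the solved [oc_problem()].
#' @param optimal a converged [solve_oc()] solution.
#' @param amplitudes noise standard deviations to test (may include 0).
#' @param replicates Monte-Carlo replicates per amplitude.
#' @param seed integer seed.
#' @param corr_time noise correlation time in rescaled time units.
#' @param n_grid uniform grid size for the noise paths.
#' @return A list of class `robustness_result` with `replicates` (long data
#'   frame: amplitude, replicate, final total count, relative deviation,
#'   cost difference), `summary` (per-amplitude maximum relative deviation
#'   of the final total count, in percent), the baseline final count and
#'   the seed.
#' @export
noise_robustness <- function(problem, optimal, amplitudes = c(0.01, 0.02, 0.05),
                             replicates = 200L, seed = 1L, corr_time = 1,
                             n_grid = 701L) {
  stopifnot(inherits(optimal, "oc_solution"), replicates >= 1L,
            all(amplitudes >= 0))
  T <- problem$cost$T
  rs <- resample_solution(optimal, n_grid)
  m <- problem$model$m
  # baseline through the same integrator, so deviations at amplitude zero
  # are exactly zero
  base <- simulate_batch_rk4(problem, rs$t,
                             array(t(rs$u), c(m, n_grid, 1L)))
  base_final <- sum(base$xT)
  J_opt <- base$J
  set.seed(seed)
  rows <- vector("list", length(amplitudes))
  for (si in seq_along(amplitudes)) {
    sig <- amplitudes[si]
    Uarr <- array(0, c(m, n_grid, replicates))
    for (rep_i in seq_len(replicates)) {
      noise <- vapply(seq_len(m), function(k) ou_path(rs$t, sig, corr_time),
                      numeric(n_grid))
      Uarr[, , rep_i] <- t(clip(rs$u + noise,
                                rep(problem$lower, each = n_grid),
                                rep(problem$upper, each = n_grid)))
    }
    sim <- simulate_batch_rk4(problem, rs$t, Uarr)
    fin <- colSums(sim$xT)
    bad <- !is.finite(fin)
    rows[[si]] <- data.frame(
      amplitude = sig, replicate = seq_len(replicates),
      final_total = ifelse(bad, NA_real_, fin),
      rel_dev = ifelse(bad, NA_real_, abs(fin - base_final) / base_final),
      dJ = ifelse(bad, NA_real_, sim$J - J_opt),
      failed = bad)
  }
  reps <- do.call(rbind, rows)
  summ <- stats::aggregate(rel_dev ~ amplitude, data = reps,
                           FUN = function(v) 100 * max(v))
  names(summ)[2] <- "max_rel_dev_pct"
  structure(list(replicates = reps, summary = summ,
                 baseline_final_total = base_final, seed = seed,
                 corr_time = corr_time),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("Dosing-noise robustness (Ornstein-Uhlenbeck perturbations)\n")
  cat(sprintf("  baseline final total count: %.6g; correlation time %g\n",
              x$baseline_final_total, x$corr_time))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  amplitude %.3g: max relative final-count deviation %.2f%%\n",
                x$summary$amplitude[i], x$summary$max_rel_dev_pct[i]))
  }
  invisible(x)
}
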