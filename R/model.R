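#' Controlled ODE model with multiplicative control and drug synergies
#'
#' Constructs the semi-linear controlled system
#' \deqn{\dot x = Ax + Bu + L(u, x) + N(u, x),}
#' where \eqn{x \in R^n} holds (rescaled, dimensionless) cell counts and
#' \eqn{u \in [0, 1]^m} the effective pharmacodynamic action of each drug.
#' \eqn{A} collects growth and spontaneous interconversion, \eqn{B} additive
#' control, \eqn{L} the single-drug (bilinear) action and \eqn{N} the
#' pairwise drug-synergy terms.
#'
#' The bilinear term is parameterised by matrices \eqn{C_i} (one per
#' population), where \eqn{(C_i)_{k\ell}} is the coefficient of
#' \eqn{u_\ell x_i} in the equation for \eqn{x_k}.  The synergy term is
#' parameterised by \eqn{m \times m} matrices \eqn{D^{ij}}, where
#' \eqn{(D^{ij})_{k\ell}} is the coefficient of \eqn{x_i u_k u_\ell} in the
#' equation for \eqn{x_j}.  Because \eqn{u_k u_\ell = u_\ell u_k}, each
#' pairwise interaction has one canonical slot: the strictly lower triangle.
#' Constructors accept coefficients in either triangle and fold
#' \eqn{(k,\ell)} and \eqn{(\ell,k)} contributions into the lower slot;
#' diagonal (quadratic, \eqn{u_k^2}) content is rejected, since a drug's own
#' dose-response is already captured by the terms linear in \eqn{u}.
#'
#' @param A n x n growth/interconversion matrix (per unit rescaled time).
#' @param B n x m additive-control matrix, or `NULL` for zero.
#' @param C list of n matrices, each n x m, or `NULL` for all-zero.
#' @param D n x n list-of-lists of m x m interaction matrices `D[[i]][[j]]`,
#'   or `NULL` for all-zero.  Entries may be given in either triangle (or
#'   split symmetrically); they are folded into strictly-lower-triangular
#'   canonical storage.
#' @param m number of drugs; required when `B`, `C` and `D` are all `NULL`.
#' @param labels optional list with character vectors `populations` (length
#'   n) and `drugs` (length m).
#' @param scale record of the rate used to non-dimensionalise time
#'   (\eqn{\tau = k t}); purely documentary.
#'
#' @return An object of class `controlled_ode_model`.
#' @seealso [model_rhs()], [validate_model()], [rescale_model()]
#' @examples
#' m <- two_population_model(alpha = 0.5, beta = 0.5)
#' model_rhs(m, x = c(1, 1), u = c(0, 0))
#' @export
controlled_ode_model <- function(A, B = NULL, C = NULL, D = NULL, m = NULL,
                                 labels = NULL, scale = 1) {
  if (!is_square(A)) stop("A must be a square matrix")
  n <- nrow(A)
  if (is.null(m)) {
    m <- if (!is.null(B)) ncol(B)
    else if (!is.null(C)) ncol(C[[1]])
    else if (!is.null(D)) ncol(D[[1]][[1]])
    else stop("drug count m cannot be inferred; supply B, C, D or m")
  }
  if (is.null(B)) B <- matrix(0, n, m)
  if (is.null(C)) C <- replicate(n, matrix(0, n, m), simplify = FALSE)
  if (is.null(D)) {
    D <- replicate(n, replicate(n, matrix(0, m, m), simplify = FALSE),
                   simplify = FALSE)
  }
  D <- lapply(seq_len(n), function(i) {
    lapply(seq_len(n), function(j) fold_interaction(D[[i]][[j]], i, j))
  })
  if (is.null(labels)) {
    labels <- list(populations = paste0("x", seq_len(n)),
                   drugs = paste0("u", seq_len(m)))
  }
  model <- structure(
    list(n = n, m = m, A = A, B = B, C = C, D = D,
         labels = labels, scale = scale),
    class = "controlled_ode_model")
  viol <- validate_model(model)
  if (length(viol$violations) > 0L) {
    stop("invalid model specification:\n  ",
         paste(viol$violations, collapse = "\n  "))
  }
  model
}

#' Fold an interaction matrix into strictly-lower-triangular storage.
#' Coefficients supplied at (k, l) and (l, k) are summed into the slot with
#' k > l.  Diagonal content is an error (no u_k^2 terms).
#' @noRd
fold_interaction <- function(Dm, i, j, tol = 0) {
  if (!is_square(Dm)) stop(sprintf("D[[%d]][[%d]] must be square", i, j))
  dg <- diag(Dm)
  if (any(abs(dg) > tol)) {
    stop(sprintf(
      "D[[%d]][[%d]] has nonzero diagonal entry (k = %d): quadratic drug terms are not admitted",
      i, j, which(abs(dg) > tol)[1]))
  }
  lower <- Dm * lower.tri(Dm)
  upper <- Dm * upper.tri(Dm)
  lower + t(upper)
}

#' Validate a controlled ODE model
#'
#' Checks dimensional consistency of all coefficient matrices and the
#' strictly-lower-triangular storage convention for the drug-interaction
#' matrices.  Returns a report rather than throwing, so it can be used on
#' hand-assembled objects.
#'
#' @param model a `controlled_ode_model` (or a bare list with the same
#'   fields).
#' @return A list with elements `ok` (logical) and `violations`
#'   (character vector naming each offending matrix).
#' @export
validate_model <- function(model) {
  v <- character(0)
  n <- model$n; m <- model$m
  chk <- function(cond, msg) if (!cond) v <<- c(v, msg)
  chk(is_square(model$A) && nrow(model$A) == n, "A is not n x n")
  chk(is.matrix(model$B) && all(dim(model$B) == c(n, m)), "B is not n x m")
  chk(is.list(model$C) && length(model$C) == n,
      sprintf("C must be a list of %d matrices", n))
  if (is.list(model$C) && length(model$C) == n) {
    for (i in seq_len(n)) {
      chk(is.matrix(model$C[[i]]) && all(dim(model$C[[i]]) == c(n, m)),
          sprintf("C[[%d]] is not n x m", i))
    }
  }
  okD <- is.list(model$D) && length(model$D) == n &&
    all(vapply(model$D, function(d) is.list(d) && length(d) == n, TRUE))
  chk(okD, sprintf("D must be an %d x %d list of m x m matrices", n, n))
  if (okD) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      Dm <- model$D[[i]][[j]]
      if (!(is.matrix(Dm) && all(dim(Dm) == c(m, m)))) {
        v <- c(v, sprintf("D[[%d]][[%d]] is not m x m", i, j))
        next
      }
      dg <- diag(Dm)
      if (any(dg != 0)) {
        for (k in which(dg != 0)) {
          v <- c(v, sprintf("D[[%d]][[%d]] has nonzero diagonal at k = %d",
                            i, j, k))
        }
      }
      if (any((Dm * upper.tri(Dm)) != 0)) {
        v <- c(v, sprintf(
          "D[[%d]][[%d]] has content above the diagonal (canonical storage is strictly lower triangular)",
          i, j))
      }
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

#' @export
print.controlled_ode_model <- function(x, ...) {
  cat(sprintf(
    "Controlled ODE model: %d population(s) [%s], %d drug(s) [%s]\n",
    x$n, paste(x$labels$populations, collapse = ", "),
    x$m, paste(x$labels$drugs, collapse = ", ")))
  nC <- sum(vapply(x$C, function(m) any(m != 0), TRUE))
  nD <- sum(unlist(lapply(x$D, function(row)
    vapply(row, function(m) any(m != 0), TRUE))))
  cat(sprintf("  additive control: %s; bilinear terms in %d population(s); %d drug-interaction block(s)\n",
              if (any(x$B != 0)) "yes" else "no", nC, nD))
  invisible(x)
}

#' @noRd
check_xu <- function(model, x, u) {
  if (length(x) != model$n) {
    stop(sprintf("state x has length %d; model expects n = %d",
                 length(x), model$n))
  }
  if (length(u) != model$m) {
    stop(sprintf("control u has length %d; model expects m = %d",
                 length(u), model$m))
  }
}

#' State-multiplicative (bilinear) drug action \eqn{L(u, x)}
#'
#' Component \eqn{j} equals \eqn{\sum_i \sum_\ell (C_i)_{j\ell} u_\ell x_i}:
#' the total single-drug action on population \eqn{j} from all populations.
#'
#' @param model a `controlled_ode_model`.
#' @param x state vector (length n).
#' @param u control vector (length m).
#' @return Length-n rate vector.
#' @export
linear_control_term <- function(model, x, u) {
  check_xu(model, x, u)
  out <- numeric(model$n)
  for (i in seq_len(model$n)) {
    out <- out + drop(model$C[[i]] %*% u) * x[i]
  }
  out
}

#' Pairwise drug-interaction (synergy) term \eqn{N(u, x)}
#'
#' Component \eqn{j} equals \eqn{\sum_i x_i \, u^T D^{ij} u}; only the
#' strictly-lower-triangular entries of each \eqn{D^{ij}} carry
#' coefficients, so a control with a single active drug contributes
#' nothing.
#'
#' @inheritParams linear_control_term
#' @return Length-n rate vector.
#' @export
interaction_term <- function(model, x, u) {
  check_xu(model, x, u)
  out <- numeric(model$n)
  for (j in seq_len(model$n)) {
    acc <- 0
    for (i in seq_len(model$n)) {
      Dm <- model$D[[i]][[j]]
      if (any(Dm != 0)) acc <- acc + x[i] * drop(u %*% Dm %*% u)
    }
    out[j] <- acc
  }
  out
}

#' Right-hand side of the controlled ODE
#'
#' Evaluates \eqn{Ax + Bu + L(u,x) + N(u,x)} at a single state/control
#' pair.  With all \eqn{C_i = 0} and \eqn{D^{ij} = 0} this reduces exactly
#' to the additive-control (LQR) dynamics \eqn{Ax + Bu}.
#'
#' @inheritParams linear_control_term
#' @return Length-n rate vector.
#' @export
model_rhs <- function(model, x, u) {
  check_xu(model, x, u)
  drop(model$A %*% x) + drop(model$B %*% u) +
    linear_control_term(model, x, u) + interaction_term(model, x, u)
}

#' Rescale a model expressed in raw rates to dimensionless time
#'
#' Dividing every coefficient matrix by the reference rate `k` re-expresses
#' the dynamics on the rescaled clock \eqn{\tau = k t}.  The factor is
#' recorded in the `scale` field.
#'
#' @param model a `controlled_ode_model` in raw time units.
#' @param k reference rate (> 0).
#' @return A `controlled_ode_model` on the rescaled clock.
#' @export
rescale_model <- function(model, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  model$A <- model$A / k
  model$B <- model$B / k
  model$C <- lapply(model$C, function(m) m / k)
  model$D <- lapply(model$D, function(row) lapply(row, function(m) m / k))
  model$scale <- model$scale * k
  model
}

#' Symmetrised (full) interaction matrix D^{ij} + t(D^{ij}).
#' @noRd
sym_interaction <- function(Dm) Dm + t(Dm)

#' Nonzero interaction blocks as a list of (i, j, Dm, Sm) entries.
#' @noRd
nonzero_interactions <- function(model) {
  out <- list()
  for (i in seq_len(model$n)) for (j in seq_len(model$n)) {
    Dm <- model$D[[i]][[j]]
    if (any(Dm != 0)) {
      out[[length(out) + 1L]] <-
        list(i = i, j = j, Dm = Dm, Sm = sym_interaction(Dm))
    }
  }
  out
}

#' Jacobian of the dynamics with respect to the state, at fixed control:
#' (d f / d x)_{j i} = A_{ji} + (C_i u)_j + u' D^{ij} u.
#' @noRd
model_state_jacobian <- function(model, u) {
  Jf <- model$A
  for (i in seq_len(model$n)) {
    Jf[, i] <- Jf[, i] + drop(model$C[[i]] %*% u)
  }
  for (blk in nonzero_interactions(model)) {
    Jf[blk$j, blk$i] <- Jf[blk$j, blk$i] + drop(u %*% blk$Dm %*% u)
  }
  Jf
}

#' Drug-action matrix W(x) = B + sum_i x_i C_i (n x m), i.e. the
#' coefficient of u in the dynamics at state x.
#' @noRd
model_control_matrix <- function(model, x) {
  W <- model$B
  for (i in seq_len(model$n)) W <- W + x[i] * model$C[[i]]
  W
}
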