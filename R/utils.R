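# Internal numerical helpers shared across modules.

#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Smoothed box projection: softplus-rounded clip with corner radius `eps`
#' (exact clip at eps = 0).  Used as a homotopy device: the collocation
#' residual is non-smooth at control-saturation kinks, and Newton iterations
#' on the smoothed problem provide starting points for the exact one.
#' @noRd
softclip <- function(x, lo, hi, eps) {
  if (eps <= 0) return(clip(x, lo, hi))
  sp <- function(z) {
    # eps * log(1 + exp(z / eps)), overflow-safe, shape-preserving
    out <- z
    small <- z <= 30 * eps
    out[small] <- eps * log1p(exp(z[small] / eps))
    out
  }
  v <- lo + sp(x - lo)      # smooth max(lo, x)
  hi - sp(hi - v)           # smooth min(hi, .)
}

#' Trapezoidal quadrature on a (possibly non-uniform) grid.
#' @noRd
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

#' @noRd
is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

#' Symmetry check with relative tolerance.
#' @noRd
is_symmetric_rel <- function(m, tol = 1e-12) {
  s <- max(abs(m)) + 1
  max(abs(m - t(m))) <= tol * s
}

#' Minimise 1/2 u'Gu + b'u over the box [lower, upper], for a whole
#' trajectory at once.
#'
#' `G` is either a constant m x m matrix or an m x m x N array (one matrix
#' per grid point); `b` is m x N.  When every G is diagonal the clipped
#' stationary point is the exact box minimiser; otherwise a cyclic
#' coordinate-descent refinement is applied (exact per-coordinate
#' minimisation, which converges for positive-definite G).
#' @noRd
boxqp_traj <- function(G, b, lower, upper, sweeps = 20L, tol = 1e-10,
                       eps = 0) {
  proj <- function(x, lo, hi) softclip(x, lo, hi, eps)
  m <- nrow(b); N <- ncol(b)
  const_G <- is.matrix(G)
  if (const_G) {
    dG <- diag(G)
    offdiag <- any(abs(G - diag(dG, m)) > 0)
    dmat <- matrix(dG, m, N)
  } else {
    dmat <- matrix(0, m, N)
    for (k in seq_len(m)) dmat[k, ] <- G[k, k, ]
    offdiag <- TRUE
    if (m > 1L) {
      offmax <- 0
      for (k in seq_len(m)) for (l in seq_len(m)) {
        if (k != l) offmax <- max(offmax, max(abs(G[k, l, ])))
      }
      offdiag <- offmax > 0
    }
  }
  # guard against non-positive curvature encountered at intermediate
  # Newton iterates; documented degenerate fallback
  dmat <- pmax(dmat, 1e-12)
  U <- proj(-b / dmat, rep_len(lower, m), rep_len(upper, m))
  if (!offdiag || m == 1L) return(U)
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (k in seq_len(m)) {
      num <- b[k, ]
      for (l in seq_len(m)) {
        if (l == k) next
        gkl <- if (const_G) G[k, l] else G[k, l, ]
        num <- num + gkl * U[l, ]
      }
      uk <- proj(-num / dmat[k, ], lower[k], upper[k])
      delta <- max(delta, max(abs(uk - U[k, ])))
      U[k, ] <- uk
    }
    if (delta < tol) break
  }
  U
}

#' Resample a piecewise-linear trajectory onto a new grid.
#' @noRd
resample_traj <- function(t, Y, t_new) {
  # Y: k x length(t); returns k x length(t_new)
  out <- matrix(0, nrow(Y), length(t_new))
  for (k in seq_len(nrow(Y))) {
    out[k, ] <- stats::approx(t, Y[k, ], xout = t_new, rule = 2)$y
  }
  out
}
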