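#' Two-population cell-cycle model under cisplatin and paclitaxel
#'
#' Cervical cancer cells are split into a G1-phase compartment (A, non
#' proliferative) and an S/G2-phase compartment (B, proliferative).  Cells
#' leave G1 at the cell-cycle rate and each division returns two G1 cells.
#' Cisplatin (`u_c`) blocks the G1-to-S/G2 transition and kills G1 cells at
#' rescaled rate `alpha`; paclitaxel (`u_p`) blocks division and kills
#' S/G2 cells at rescaled rate `beta`.  On the rescaled clock (time in
#' units of the cell-cycle transition rate) the dynamics are
#' \deqn{\dot N_A = 2 N_B (1 - u_p) - N_A (1 - u_c) - \alpha u_c N_A,}
#' \deqn{\dot N_B = -N_B (1 - u_p) + N_A (1 - u_c) - \beta u_p N_B.}
#' There is no additive control and no drug-drug interaction term; the
#' synergy between the two drugs is purely dynamic (they act on different
#' cell-cycle compartments).
#'
#' @param alpha rescaled cisplatin kill rate (> 0; sweeps use 0.05--0.5).
#' @param beta rescaled paclitaxel kill rate (> 0).
#' @return A [controlled_ode_model()] with n = 2 populations (A, B) and
#'   m = 2 drugs in the order (`u_c`, `u_p`).
#' @export
two_population_model <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  A <- matrix(c(-1, 1, 2, -1), 2, 2)
  C1 <- matrix(c(1 - alpha, -1, 0, 0), 2, 2)
  C2 <- matrix(c(0, 0, -2, 1 - beta), 2, 2)
  controlled_ode_model(
    A = A, C = list(C1, C2), m = 2L,
    labels = list(populations = c("A", "B"), drugs = c("u_c", "u_p")))
}

#' Full neuroblastoma differentiation model (raw rates)
#'
#' Three interconverting populations -- multipotent sympathoblasts (I),
#' adrenergic neuroblastic cells (N) and mesenchymal substrate-adherent
#' cells (S) -- treated with four agents: retinoic acid (`u_RA`, drives
#' I-to-N differentiation), a cytotoxic chemotherapeutic (`u_chemo`, kills
#' proliferative I cells), a pan-trk inhibitor (`u_trk`, shuts down both
#' trkA and trkB signalling) and NGF (`u_NGF`).  trkA+NGF signalling
#' differentiates I to N; trkA without NGF drives N-cell apoptosis;
#' trkB+BDNF signalling de-differentiates N cells, returning one cell each
#' to the I and S compartments.  All trk-mediated pathways carry a factor
#' \eqn{(1 - u_{trk})}, so full trk inhibition silences them; the
#' \eqn{(1-u_{trk}) u_{NGF}} and \eqn{(1-u_{NGF})(1-u_{trk})} products
#' expand into bilinear terms plus `u_trk * u_NGF` drug-interaction terms.
#'
#' @param lambda_I,lambda_N,lambda_S proliferation rates.
#' @param k length-6 named vector of spontaneous interconversion rates with
#'   names `IN, IS, NI, SI, NS, SN` (`k["IN"]` converts I to N, etc.).
#' @param delta_RA RA-induced I-to-N differentiation rate.
#' @param delta_chemo chemotherapy-induced I-cell death rate.
#' @param delta_diff trkA+NGF-induced differentiation rate.
#' @param delta_BDNF trkB+BDNF-induced de-differentiation rate.
#' @param delta_trkNGF trkA-without-NGF apoptosis rate.
#' @return A [controlled_ode_model()] with n = 3 (I, N, S) and m = 4 drugs
#'   in the order (`u_RA`, `u_chemo`, `u_trk`, `u_NGF`), in raw time units.
#' @export
neuroblastoma_full_model <- function(lambda_I, lambda_N, lambda_S,
                                     k,
                                     delta_RA, delta_chemo, delta_diff,
                                     delta_BDNF, delta_trkNGF) {
  stopifnot(all(k >= 0), delta_RA >= 0, delta_chemo >= 0, delta_diff >= 0,
            delta_BDNF >= 0, delta_trkNGF >= 0)
  k <- k[c("IN", "IS", "NI", "SI", "NS", "SN")]
  if (any(is.na(k))) stop("k must carry names IN, IS, NI, SI, NS, SN")
  A <- matrix(0, 3, 3)
  A[1, ] <- c(lambda_I - k[["IN"]] - k[["IS"]], k[["NI"]] + delta_BDNF,
              k[["SI"]])
  A[2, ] <- c(k[["IN"]],
              lambda_N - k[["NS"]] - k[["NI"]] - delta_trkNGF - 2 * delta_BDNF,
              k[["SN"]])
  A[3, ] <- c(k[["IS"]], k[["NS"]] + delta_BDNF,
              lambda_S - k[["SN"]] - k[["SI"]])
  # drug order: u_RA, u_chemo, u_trk, u_NGF
  C_I <- rbind(c(-delta_RA, -delta_chemo, 0, -delta_diff),
               c(delta_RA, 0, 0, delta_diff),
               c(0, 0, 0, 0))
  C_N <- rbind(c(0, 0, -delta_BDNF, 0),
               c(0, 0, delta_trkNGF + 2 * delta_BDNF, delta_trkNGF),
               c(0, 0, -delta_BDNF, 0))
  C_S <- matrix(0, 3, 4)
  Dz <- matrix(0, 4, 4)
  pair <- function(val) {
    # coefficient of u_trk * u_NGF, stored in the lower (NGF, trk) slot
    d <- Dz; d[4, 3] <- val; d
  }
  D <- list(
    list(pair(delta_diff), pair(-delta_diff), Dz),   # x_i = I
    list(Dz, pair(-delta_trkNGF), Dz),               # x_i = N
    list(Dz, Dz, Dz))                                # x_i = S
  controlled_ode_model(
    A = A, C = list(C_I, C_N, C_S), D = D, m = 4L,
    labels = list(populations = c("I", "N", "S"),
                  drugs = c("u_RA", "u_chemo", "u_trk", "u_NGF")))
}

#' Reduced neuroblastoma model (rescaled, three parameters)
#'
#' Reduction of [neuroblastoma_full_model()] under biologically motivated
#' ties: all spontaneous interconversion rates equal a common rate `k`
#' (which rescales time, \eqn{\tau = k t}), all drug effects on
#' interconversion share one magnitude \eqn{\delta}
#' (\eqn{\delta_{RA} = \delta_{diff} = \delta_{BDNF} = \delta}), only the
#' I compartment proliferates (rate \eqn{\lambda}), and chemotherapy at
#' full effect kills proliferative cells at their net division rate
#' (\eqn{\delta_{chemo} = 2\lambda}).  The resulting system depends on
#' \eqn{(\lambda, \delta, \delta_{apop})} only, with
#' \deqn{A = \begin{pmatrix} \lambda - 2 & 1 + \delta & 1 \\
#'   1 & -2 - 2\delta - \delta_{apop} & 1 \\ 1 & 1 + \delta & -2
#'   \end{pmatrix}.}
#'
#' @param lambda rescaled I-cell proliferation rate (sweeps use 0.05--0.5).
#' @param delta common rescaled drug-modulated interconversion rate.
#' @param delta_apop rescaled trkA-without-NGF apoptosis rate.
#' @return A [controlled_ode_model()] on the rescaled clock.
#' @export
neuroblastoma_reduced_model <- function(lambda, delta, delta_apop) {
  stopifnot(lambda > 0, delta > 0, delta_apop > 0)
  A <- rbind(c(lambda - 2, 1 + delta, 1),
             c(1, -2 - 2 * delta - delta_apop, 1),
             c(1, 1 + delta, -2))
  # drug order: u_RA, u_chemo, u_trk, u_NGF
  C_I <- rbind(c(-delta, -2 * lambda, 0, -delta),
               c(delta, 0, 0, delta),
               c(0, 0, 0, 0))
  C_N <- rbind(c(0, 0, -delta, 0),
               c(0, 0, delta_apop + 2 * delta, delta_apop),
               c(0, 0, -delta, 0))
  C_S <- matrix(0, 3, 4)
  Dz <- matrix(0, 4, 4)
  pair <- function(val) {
    d <- Dz; d[4, 3] <- val; d   # coefficient of u_trk * u_NGF
  }
  D_IN <- pair(-delta)
  D_NN <- pair(-delta_apop)
  D_II <- -D_IN
  D <- list(list(D_II, D_IN, Dz),
            list(Dz, D_NN, Dz),
            list(Dz, Dz, Dz))
  controlled_ode_model(
    A = A, C = list(C_I, C_N, C_S), D = D, m = 4L,
    labels = list(populations = c("I", "N", "S"),
                  drugs = c("u_RA", "u_chemo", "u_trk", "u_NGF")))
}

#' Default treatment problem for the worked examples
#'
#' A standard one-week course of treatment: on the rescaled clock (cell
#' cycle roughly one day) the horizon is \eqn{T = 7}; every population
#' starts at unit (rescaled) count; the state penalty is the identity and
#' the toxicity penalty \eqn{R = 10^{-1} I}; there is no terminal penalty,
#' so \eqn{\lambda(T) = 0}.
#'
#' @param model a model built by [two_population_model()] or
#'   [neuroblastoma_reduced_model()].
#' @param T horizon (default 7).
#' @param R0 scalar toxicity scale, `R = R0 * I` (default 0.1).
#' @param R optional full control-penalty matrix overriding `R0`.
#' @return An [oc_problem()].
#' @export
default_problem <- function(model, T = 7, R0 = 0.1, R = NULL) {
  stopifnot(inherits(model, "controlled_ode_model"))
  if (is.null(R)) R <- diag(R0, model$m)
  oc_problem(model,
             cost_spec(Q = diag(model$n), R = R, M = NULL, T = T),
             x0 = rep(1, model$n))
}

#' Parameterised path through the (alpha, beta) plane used by the
#' toxicity-split analysis
#'
#' \deqn{\alpha = \gamma_0 + \gamma\sin\varphi, \qquad
#'       \beta = \gamma_0 + \gamma\cos\varphi, \qquad
#'       \varphi \in [0, 2\pi/9],}
#' a circular arc from the high-`beta` corner towards the `alpha` axis.
#'
#' @param phi path parameter (vectorised).
#' @param gamma0 offset (default 0.05).
#' @param gamma radius (default 0.4).
#' @return A matrix with columns `alpha` and `beta`.
#' @export
toxicity_path <- function(phi, gamma0 = 0.05, gamma = 0.4) {
  cbind(alpha = gamma0 + gamma * sin(phi),
        beta = gamma0 + gamma * cos(phi))
}
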