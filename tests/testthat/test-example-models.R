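# The fully parameterised example systems.

test_that("two-population matrices carry the printed coefficients", {
  m <- two_population_model(alpha = 0.5, beta = 0.3)
  expect_equal(m$A, matrix(c(-1, 1, 2, -1), 2))
  expect_equal(m$C[[1]][1, 1], 0.5)        # 1 - alpha
  expect_equal(m$C[[1]][2, 1], -1)
  expect_equal(m$C[[2]][1, 2], -2)
  expect_equal(m$C[[2]][2, 2], 0.7)        # 1 - beta
  expect_true(all(m$B == 0))
  expect_true(validate_model(m)$ok)
})

test_that("two-population rhs matches the scalar dynamics", {
  set.seed(31)
  for (rep in 1:25) {
    a <- runif(1, 0.05, 0.5); b <- runif(1, 0.05, 0.5)
    m <- two_population_model(a, b)
    x <- runif(2, 0, 2); u <- runif(2)
    expect_equal(model_rhs(m, x, u), twopop_rhs_scalar(a, b, x, u),
                 tolerance = 1e-12)
  }
})

test_that("untreated two-population total grows at positive states", {
  m <- two_population_model(0.3, 0.3)
  set.seed(32)
  for (rep in 1:10) {
    x <- runif(2, 0.1, 3)
    expect_gt(sum(model_rhs(m, x, c(0, 0))), 0)
  }
})

test_that("full neuroblastoma model transcribes every pathway", {
  set.seed(33)
  for (rep in 1:25) {
    p <- list(lambda_I = runif(1), lambda_N = runif(1), lambda_S = runif(1),
              k = stats::setNames(runif(6), c("IN","IS","NI","SI","NS","SN")),
              delta_RA = runif(1), delta_chemo = runif(1),
              delta_diff = runif(1), delta_BDNF = runif(1),
              delta_trkNGF = runif(1))
    m <- do.call(neuroblastoma_full_model, p)
    x <- runif(3, 0, 2); u <- runif(4)
    expect_equal(model_rhs(m, x, u), nb_full_rhs_scalar(p, x, u),
                 tolerance = 1e-12)
  }
})

test_that("full model degenerates as the pathway structure dictates", {
  k0 <- stats::setNames(rep(0, 6), c("IN", "IS", "NI", "SI", "NS", "SN"))
  m <- neuroblastoma_full_model(0.3, 0.2, 0.1, k0, 0, 0, 0, 0, 0)
  # no interconversion, no drug effects: pure exponential proliferation
  x <- c(1, 2, 3)
  expect_equal(model_rhs(m, x, runif(4)), c(0.3, 0.4, 0.3),
               tolerance = 1e-12)
  # full trk inhibition silences every (1 - u_trk) pathway
  p <- list(lambda_I = 0, lambda_N = 0, lambda_S = 0, k = k0,
            delta_RA = 0, delta_chemo = 0, delta_diff = 0.4,
            delta_BDNF = 0.3, delta_trkNGF = 0.2)
  m2 <- do.call(neuroblastoma_full_model, p)
  for (ungf in c(0, 0.5, 1)) {
    expect_equal(model_rhs(m2, c(1, 1, 1), c(0, 0, 1, ungf)), c(0, 0, 0),
                 tolerance = 1e-12)
  }
})

test_that("reduced model prints the three-parameter matrices", {
  red <- neuroblastoma_reduced_model(lambda = 0.2, delta = 0.1,
                                     delta_apop = 0.3)
  expect_equal(red$A[2, 2], -2 - 2 * 0.1 - 0.3)
  expect_equal(red$A[1, 1], 0.2 - 2)
  expect_equal(red$A[1, 2], 1.1)
  expect_equal(red$C[[1]][1, 2], -2 * 0.2)   # chemo column, delta_chemo = 2 lambda
  expect_equal(red$C[[2]][2, 3], 0.3 + 2 * 0.1)
  # the u_trk * u_NGF coefficient of D^{NN} is -delta_apop (stored in the
  # canonical lower slot, row NGF, column trk)
  expect_equal(red$D[[2]][[2]][4, 3], -0.3)
  expect_equal(red$D[[1]][[1]], -red$D[[1]][[2]])
  expect_true(validate_model(red)$ok)
})

test_that("reduced model equals the full model under the reduction ties", {
  set.seed(34)
  for (rep in 1:100) {
    lam <- runif(1, 0.05, 0.5); del <- runif(1, 0.05, 0.5)
    dap <- runif(1, 0.05, 0.5); k <- runif(1, 0.5, 2)
    full <- rescale_model(neuroblastoma_full_model(
      lambda_I = lam * k, lambda_N = 0, lambda_S = 0,
      k = stats::setNames(rep(k, 6), c("IN","IS","NI","SI","NS","SN")),
      delta_RA = del * k, delta_chemo = 2 * lam * k, delta_diff = del * k,
      delta_BDNF = del * k, delta_trkNGF = dap * k), k)
    red <- neuroblastoma_reduced_model(lam, del, dap)
    expect_equal(full$A, red$A, tolerance = 1e-12)
    for (i in 1:3) expect_equal(full$C[[i]], red$C[[i]], tolerance = 1e-12)
    for (i in 1:3) for (j in 1:3) {
      expect_equal(full$D[[i]][[j]], red$D[[i]][[j]], tolerance = 1e-12)
    }
  }
})

test_that("reduced rhs matches its scalar transcription", {
  set.seed(35)
  for (rep in 1:20) {
    lam <- runif(1, 0.05, 0.5); del <- runif(1, 0.05, 0.5)
    dap <- runif(1, 0.05, 0.5)
    red <- neuroblastoma_reduced_model(lam, del, dap)
    x <- runif(3, 0, 2); u <- runif(4)
    expect_equal(model_rhs(red, x, u),
                 nb_reduced_rhs_scalar(lam, del, dap, x, u),
                 tolerance = 1e-12)
  }
})

test_that("default problem uses the standard one-week course settings", {
  m <- two_population_model(0.2, 0.2)
  prob <- default_problem(m)
  expect_equal(prob$cost$T, 7)
  expect_equal(prob$x0, c(1, 1))
  expect_equal(cost_Q <- octherapy:::cost_Q(prob$cost), diag(2))
  expect_equal(octherapy:::cost_R(prob$cost), diag(0.1, 2))
  expect_true(all(prob$cost$M == 0))
  nb <- default_problem(neuroblastoma_reduced_model(0.2, 0.2, 0.2))
  expect_equal(nb$x0, c(1, 1, 1))
  expect_equal(octherapy:::cost_R(nb$cost), diag(0.1, 4))
})

test_that("toxicity path starts at the high-beta corner", {
  ab <- toxicity_path(0)
  expect_equal(unname(ab[1, ]), c(0.05, 0.45))
  # walking the arc raises the cisplatin kill rate and lowers paclitaxel's
  ab_end <- toxicity_path(2 * pi / 9)
  expect_gt(ab_end[1, "alpha"], ab[1, "alpha"])
  expect_lt(ab_end[1, "beta"], ab[1, "beta"])
})
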