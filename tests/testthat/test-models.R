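test_that("afree solves the sequestration equilibrium", {
  expect_equal(afree(1, 0), 1)                  # no repressor: all free
  expect_equal(afree(2, 1), sqrt(2))            # complex C solves (2-C)(1-C)=C
  # repressor in large excess: value from the quadratic, residual tiny
  x <- afree(1000, 1000)
  expect_equal(x, 31.12673, tolerance = 1e-6)
  resid <- x * (1000 - 1000 + x) - (1000 - x)
  expect_lt(abs(resid), 1e-10)
})

test_that("afree equilibrium residual is tiny over the whole domain", {
  set.seed(42)
  A_T <- runif(1e6, 0, 1e4)
  P <- runif(1e6, 0, 1e4)
  Af <- afree(A_T, P)
  # complex C = A_T - A_free must satisfy C = A_free * P_free (K_d = 1)
  C <- A_T - Af
  resid <- Af * (P - C) - C
  expect_lt(max(abs(resid)) / 1e4, 1e-10)       # relative to the scale
  expect_true(all(Af >= 0 & Af <= A_T + 1e-12))
})

test_that("afree is monotone in both arguments", {
  set.seed(7)
  A_T <- runif(500, 0, 100)
  P <- runif(500, 0, 100)
  dP <- runif(500, 0, 10)
  expect_true(all(afree(A_T, P + dP) <= afree(A_T, P) + 1e-12))
  dA <- runif(500, 0, 10)
  expect_true(all(afree(A_T + dA, P) >= afree(A_T, P) - 1e-12))
})

test_that("afree rejects negative input", {
  expect_error(afree(-1, 0), "non-negative")
  expect_error(afree(1, -2), "non-negative")
})

test_that("transcription rate laws behave and agree in the K_A -> 0 limit", {
  expect_equal(transcription_rate(1000, 1000, 20, "law0"), 20)
  expect_equal(transcription_rate(500, 1000, 20000, "law0"), 10000)
  expect_error(transcription_rate(0, 0, 1, "law0"), "undefined")
  # law1 with K_A = 0 is exactly law0
  Af <- seq(0.1, 50, length.out = 40)
  expect_equal(transcription_rate(Af, 50, 7, "law1", K_A = 0),
               transcription_rate(Af, 50, 7, "law0"))
  # and converges as K_A -> 0
  d <- max(abs(transcription_rate(Af, 50, 7, "law1", K_A = 1e-9) -
               transcription_rate(Af, 50, 7, "law0")))
  expect_lt(d, 1e-8)
})

test_that("degradation laws: half-saturation and the linear limit", {
  expect_equal(degradation_rate(0, "linear"), 0)
  expect_equal(degradation_rate(0, "michaelian", 5, 2), 0)
  expect_equal(degradation_rate(2, "michaelian", beta_max = 5, K_m = 2), 2.5)
  # K_m -> Inf with beta_max = K_m recovers the linear law
  P <- seq(0, 100, length.out = 21)
  err <- max(abs(degradation_rate(P, "michaelian", 1e8, 1e8) - P))
  expect_lt(err, 1e-4)
})

test_that("clock_rhs matches the forced values at the origin", {
  spec <- clock_model("SNF", "law1", "michaelian", 8)
  p <- clock_params(spec, alpha = 50, A_T = 20, beta_max = 5, K_m = 5.5,
                    K_A = 20)
  d <- clock_rhs(setNames(numeric(8), species_names(spec)), p, spec)
  expect_equal(unname(d[1]), 50 * 20 / (20 + 20))  # A_free = A_T at P = 0
  expect_equal(unname(d[-1]), rep(0, 7))
})

test_that("clock_rhs vanishes at the analytic SNF(0L3) steady state", {
  pre <- clock_preset("fig3")
  ss <- steady_state(pre$spec, pre$params)
  expect_lt(max(abs(clock_rhs(ss, pre$params, pre$spec))), 1e-8)
})

test_that("NNF activator equation approaches full repression as V grows", {
  spec <- clock_model("NNF", "law1", "michaelian", 8)
  p <- clock_params(spec, alpha = 30, A_T = 30, beta_max = 4.5, K_m = 2.5,
                    K_A = 3.7, V_MAX = 22, delta = 0.17)
  y <- setNames(c(rep(1, 8), 10, 1e9), species_names(spec))
  d <- clock_rhs(y, p, spec)
  expect_equal(unname(d[["AT"]]), -0.17 * 10, tolerance = 1e-6)
})

test_that("compiled and R right-hand sides integrate identically", {
  for (nm in c("fig5", "fig8", "fig9")) {
    pre <- clock_preset(nm)
    rfun <- function(t, y, parms) list(clock_rhs(y, pre$params, pre$spec))
    times <- seq(0, 30, by = 0.1)
    y0 <- initial_state(pre$spec, pre$params)
    solR <- deSolve::ode(y0, times, rfun, NULL, method = "lsoda",
                         rtol = 1e-10, atol = 1e-12)
    solC <- clock_integrate(pre$spec, pre$params, t_end = 30, n_out = 300,
                            rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(solR[, -1]), solC$states, tolerance = 1e-6)
  }
})

test_that("trajectories stay non-negative from non-negative starts", {
  set.seed(11)
  for (nm in c("fig3", "fig5", "fig9")) {
    pre <- clock_preset(nm)
    y0 <- initial_state(pre$spec, pre$params) +
      runif(pre$spec$N + 2 * (pre$spec$family != "SNF"), 0, 5)
    traj <- clock_integrate(pre$spec, pre$params, t_end = 200, n_out = 4000,
                            y0 = y0)
    expect_gt(min(traj$states), -1e-9)
  }
})

test_that("nondimensionalization scales and round-trips correctly", {
  expect_equal(nondimensionalize(c(2, 3, 4), beta_hat = 2,
                                 Kd_hat = 3, A_T_hat = 1)$alpha, 1)
  nd <- nondimensionalize(c(1, 1, 1), beta_hat = 1, Kd_hat = 0.04,
                          A_T_hat = 40)
  expect_equal(nd$A_T, 1000)
  nd2 <- nondimensionalize(c(5, 2, 2), beta_hat = 2, Kd_hat = 0.5,
                           A_T_hat = 7, K_m_hat = 3, beta_max_hat = 4,
                           delta_hat = 1)
  dim2 <- dimensionalize(nd2, beta_hat = 2, Kd_hat = 0.5, N = 3)
  expect_equal(dim2$A_T_hat, 7)
  expect_equal(dim2$K_m_hat, 3)
  expect_equal(dim2$beta_max_hat, 4)
  expect_equal(dim2$delta_hat, 1)
  expect_equal(prod(dim2$alpha_hat), prod(c(5, 2, 2)))
  expect_error(nondimensionalize(1, beta_hat = 0, Kd_hat = 1, A_T_hat = 1),
               "positive")
})

test_that("parameter validation enforces the model-variant contract", {
  snf <- clock_model("SNF", "law0", "linear", 3)
  expect_error(clock_params(snf, alpha = -1, A_T = 1), "positive")
  expect_error(clock_params(snf, alpha = 1, A_T = 1, K_A = 2), "law 1")
  expect_error(clock_params(snf, alpha = 1, A_T = 1, beta_max = 2, K_m = 1),
               "michaelian")
  pnf <- clock_model("PNF", "law1", "michaelian", 8)
  expect_error(clock_params(pnf, alpha = 1, A_T = 1, beta_max = 1, K_m = 1,
                            K_A = 1, R_MAX = 1, delta = 1, epsilon = 1.5),
               "epsilon")
  expect_error(clock_model("SNF", N = 2), "N must be")
  expect_silent(clock_params(pnf, alpha = 1, A_T = 1, beta_max = 1, K_m = 1,
                             K_A = 1, R_MAX = 1, delta = 1, epsilon = 0.01))
})

test_that("presets reproduce their documented parameter values", {
  p7 <- clock_preset("fig7")
  expect_equal(p7$params$K_A, 20)
  expect_equal(p7$spec$N, 8)
  expect_equal(p7$beta_hat, 1.125)
  p9 <- clock_preset("fig9")
  expect_equal(p9$params$epsilon, 3e-4)
  expect_equal(p9$spec$family, "PNF")
})
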