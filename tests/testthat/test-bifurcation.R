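test_that("secant factor: exact small-N values and monotone decay to 1", {
  expect_equal(secant_factor(3), 8)
  expect_equal(secant_factor(4), 4)
  expect_equal(secant_factor(8), 1.8839841, tolerance = 1e-7)
  s <- secant_factor(3:50)
  expect_true(all(diff(s) < 0))
  expect_lt(secant_factor(2000) - 1, 0.01)
  expect_error(secant_factor(2), ">= 3")
})

test_that("Hopf quadratic reduces to the classical N = 3 coefficients", {
  A_T <- c(10, 500, 1000)
  cf <- hopf_quadratic_coeffs(3, A_T)
  expect_equal(cf$Phi, rep(49, 3))
  expect_equal(cf$Psi, 8 * (A_T^2 - 30 * A_T + 1))
  expect_equal(cf$Omega, 64 * A_T * (A_T + 1)^2)
  # law1 with K_A = 0 reproduces law0
  cf1 <- hopf_quadratic_coeffs(3, A_T, K_A = 0, law = "law1")
  expect_equal(cf1, cf)
})

test_that("quadratic roots at A_T = 1000 match the frozen reference values", {
  r <- hopf_roots(3, 1000)
  # roots of 49 a^2 - 7760008 a + 64128064000 = 0
  expect_equal(r$alpha_lower, 8747.04, tolerance = 1e-5)
  expect_equal(r$alpha_upper, 149620.5, tolerance = 1e-5)
  # negative discriminant means no Hopf at that A_T
  expect_true(all(is.na(hopf_roots(3, c(5, 100))$alpha_lower)))
})

test_that("closed-form steady state satisfies its defining equations", {
  pre <- clock_preset("fig3")
  ss <- steady_state(pre$spec, pre$params)
  expect_equal(unname(ss[["P"]]), 971.046, tolerance = 1e-5)
  expect_lt(max(abs(clock_rhs(ss, pre$params, pre$spec))), 1e-9 * 1000)
  # vanishing production gives a vanishing steady state
  spec <- clock_model("SNF", "law0", "linear", 3)
  p0 <- clock_params(spec, alpha = 1e-10, A_T = 1000)
  expect_lt(max(steady_state(spec, p0)), 1e-9)
})

test_that("on the N = 3 locus the sequestration loop gain equals 8 exactly", {
  # Hopf condition: (alpha / A_T) |dA_free/dP| at steady state equals S_3
  spec <- clock_model("SNF", "law0", "linear", 3)
  for (A_T in c(600, 1000, 4000)) {
    r <- hopf_roots(3, A_T)
    for (alpha in c(r$alpha_lower, r$alpha_upper)) {
      Pss <- steady_state(spec, clock_params(spec, alpha = alpha,
                                             A_T = A_T))[["P"]]
      b <- A_T - Pss - 1
      gain <- alpha / (2 * A_T) * (1 + b / sqrt(b * b + 4 * A_T))
      expect_lt(abs(gain - 8), 1e-8)
    }
  }
})

test_that("steady states solve every family, including NNF and PNF", {
  for (nm in c("fig5", "fig7", "fig8", "fig9")) {
    pre <- clock_preset(nm)
    ss <- steady_state(pre$spec, pre$params)
    expect_lt(max(abs(clock_rhs(ss, pre$params, pre$spec))),
              1e-9 * max(1, max(ss)))
  }
})

test_that("the eigenvalue oracle confirms the analytic locus", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  for (A_T in c(500, 2000)) {
    r <- hopf_roots(3, A_T)
    for (alpha in c(r$alpha_lower, r$alpha_upper)) {
      cross <- hopf_crossing_alpha(
        spec, function(a) clock_params(spec, alpha = a, A_T = A_T),
        c(alpha * 0.9, alpha * 1.1))
      expect_lt(abs(cross / alpha - 1), 1e-4)
      lam <- leading_eigenvalue(spec, clock_params(spec, alpha = cross,
                                                   A_T = A_T))
      expect_lt(abs(Re(lam)), 1e-6)
      expect_gt(abs(Im(lam)), 0.1)          # genuine Hopf, not a fold
    }
    # midway between the branches the steady state is unstable
    mid <- sqrt(r$alpha_lower * r$alpha_upper)
    expect_gt(Re(leading_eigenvalue(
      spec, clock_params(spec, alpha = mid, A_T = A_T))), 0)
  }
  # pure decay in the no-production limit
  lam0 <- leading_eigenvalue(
    spec, clock_params(spec, alpha = 1e-10, A_T = 1000))
  expect_equal(Re(lam0), -1, tolerance = 1e-3)
})

test_that("crossing the locus switches simulated dynamics", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  set.seed(5)
  for (i in 1:4) {
    A_T <- 10^runif(1, 2.8, 3.5)
    r <- hopf_roots(3, A_T)
    inside <- classify_point(
      spec, clock_params(spec, alpha = r$alpha_lower * 1.3, A_T = A_T),
      method = "simulate", t_end = 400, n_out = 8000)$oscillatory
    outside <- classify_point(
      spec, clock_params(spec, alpha = r$alpha_lower * 0.7, A_T = A_T),
      method = "simulate", t_end = 400, n_out = 8000)$oscillatory
    expect_true(inside)
    expect_false(outside)
  }
})

test_that("domain scans agree with the analytic band for linear models", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  base <- clock_params(spec, alpha = 2e4, A_T = 1e3)
  x <- 10^seq(3.5, 5.5, length.out = 9)
  sc <- domain_scan(spec, base, "alpha", "A_T", x, c(600, 1000, 3000),
                    method = "eigen")
  r <- hopf_roots(3, c(600, 1000, 3000))
  expected <- outer(seq_along(x), seq_len(3), Vectorize(function(i, j)
    !is.na(r$alpha_lower[j]) && x[i] > r$alpha_lower[j] &&
      x[i] < r$alpha_upper[j]))
  expect_equal(sc$mask, expected)
})

test_that("boundary refinement brackets the analytic crossing", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  base <- clock_params(spec, alpha = 2e4, A_T = 1e3)
  r <- hopf_roots(3, 1000)
  x <- c(r$alpha_lower * 0.8, r$alpha_lower * 1.4)
  sc <- domain_scan(spec, base, "alpha", "A_T", x, 1000,
                    method = "eigen", refine_boundary = TRUE)
  expect_equal(sc$boundaries$x, r$alpha_lower,
               tolerance = 0.01)
})

test_that("empty grids give empty scans", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  base <- clock_params(spec, alpha = 2e4, A_T = 1e3)
  sc <- domain_scan(spec, base, "alpha", "A_T", numeric(0), numeric(0))
  expect_equal(dim(sc$mask), c(0, 0))
})

test_that("the five-point criterion passes at the SNF(0L3) wild type", {
  pre <- clock_preset("fig3")
  fp <- five_point(pre$spec, pre$params)
  expect_true(fp$pass)
  expect_length(fp$verdicts, 5)
  # a fragile point just inside the lower branch fails on halving alpha
  r <- hopf_roots(3, 1000)
  frail <- clock_params(pre$spec, alpha = r$alpha_lower * 1.1, A_T = 1000)
  fp2 <- five_point(pre$spec, frail)
  expect_false(fp2$pass)
  expect_false(fp2$verdicts[["half_alpha"]])
})

test_that("circadian area behaves under window and timescale changes", {
  # build a synthetic scan: constant period 24 on a known sub-rectangle
  sc <- structure(list(
    x_name = "alpha", y_name = "A_T",
    x_grid = seq(1, 2, length.out = 11), y_grid = seq(1, 2, length.out = 11),
    mask = matrix(TRUE, 11, 11),
    period = matrix(24, 11, 11)), class = "domain_scan")
  expect_equal(circadian_area(sc, beta_hat = 1, WT = c(1, 1),
                              window_hours = c(22, 26)), 1)
  # a window that excludes all periods gives zero area
  expect_equal(circadian_area(sc, beta_hat = 1, WT = c(1, 1),
                              window_hours = c(2, 3)), 0)
  # doubling beta_hat halves the period in hours, moving it out of window
  expect_equal(circadian_area(sc, beta_hat = 2, WT = c(1, 1),
                              window_hours = c(22, 26)), 0)
  expect_equal(circadian_area(sc, beta_hat = 2, WT = c(1, 1),
                              window_hours = c(11, 13)), 1)
})

test_that("period sensitivity: spread statistic and degenerate sweeps", {
  pre <- clock_preset("fig5")
  ps <- period_sensitivity(pre$spec, pre$params, "A_T",
                           fold_range = c(0.8, 1.25), n_points = 3,
                           t_end = 300, n_out = 6000)
  expect_gte(ps$Delta, 0)
  expect_equal(ps$DeltaT_hours, ps$Delta * 24)
  ps1 <- period_sensitivity(pre$spec, pre$params, "alpha",
                            fold_range = c(1, 1), n_points = 1,
                            t_end = 300, n_out = 6000)
  expect_equal(ps1$Delta, 0)
})
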