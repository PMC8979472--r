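test_that("the wild-type SNF(0L3) point oscillates and is summarised", {
  r <- preset_run("fig3")
  s <- r$summary
  expect_true(s$oscillatory)
  expect_gt(s$n_cycles, 5)
  expect_true(all(s$rel_amplitude >= 0 & s$rel_amplitude <= 1))
  expect_lte(s$max_P_protein, s$max_P_tot + 1e-12)
  expect_gt(s$period, 0)
})

test_that("period is a property of the attractor, not the start", {
  pre <- clock_preset("fig5")
  set.seed(3)
  periods <- replicate(3, {
    y0 <- runif(8, 0.1, 20)
    s <- summarize_oscillation(
      clock_integrate(pre$spec, pre$params, y0 = y0))
    s$period
  })
  expect_lt(diff(range(periods)) / mean(periods), 1e-3)
})

test_that("mean-crossing and peak-to-peak period estimates agree", {
  r <- preset_run("fig3")
  traj <- r$trajectory
  keep <- traj$times >= 360
  t <- traj$times[keep]
  P <- traj$states[keep, match("P", traj$species)]
  peaks <- which(diff(sign(diff(P))) == -2) + 1
  p2p <- mean(diff(t[peaks]))
  expect_lt(abs(p2p / r$summary$period - 1), 0.005)
})

test_that("a point below the lower Hopf branch damps to steady state", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  lower <- hopf_roots(3, 1000)$alpha_lower
  p <- clock_params(spec, alpha = lower * 0.9, A_T = 1000)
  s <- simulate_clock(spec, p, max_extend = 0)$summary
  expect_false(s$oscillatory)
  expect_lt(s$rel_amp_P_tot, 1e-3)
})

test_that("production shutdown decays every species to zero", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  p <- clock_params(spec, alpha = 1e-9, A_T = 1000)
  traj <- clock_integrate(spec, p, t_end = 100, n_out = 1000,
                          y0 = c(M = 5, P1 = 5, P = 5))
  expect_lt(max(traj$states[nrow(traj$states), ]), 1e-6)
})

test_that("skewness: symmetric waves score zero, one-sided profiles positive", {
  t <- seq(0, 10 * 2 * pi, length.out = 10001)[-10001]
  expect_lt(abs(series_skewness(sin(t))), 1e-10)
  pulse <- exp(-5 * ((t / (2 * pi)) %% 1))      # sawtooth-like exponential
  expect_gt(series_skewness(pulse), 0)
  expect_error(series_skewness(rep(1, 10)), "constant")
})

test_that("phase-dispersed averaging preserves the mean but softens skew", {
  traj <- preset_run("fig3")$trajectory
  single <- preset_run("fig3")$summary$skewness_M

  pa0 <- population_average(traj, phase_sd = 0, n_cells = 10, seed = 1)
  expect_equal(pa0$skewness_M, single, tolerance = 0.02)

  pa <- population_average(traj, phase_sd = 0.5, n_cells = 100, seed = 1)
  expect_lt(pa$skewness_M, single)              # dephasing symmetrises

  # near-total dephasing flattens the average
  pa_flat <- population_average(traj, phase_sd = 20, n_cells = 200, seed = 1)
  M <- pa_flat$states[, 1]
  expect_lt((max(M) - min(M)) / (max(M) + min(M)), 0.05)

  # deterministic given the seed
  pb <- population_average(traj, phase_sd = 0.5, n_cells = 100, seed = 1)
  expect_identical(pa$skewness_M, pb$skewness_M)
})

test_that("population averaging refuses non-oscillatory input", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  p <- clock_params(spec, alpha = 100, A_T = 1000)   # far below the band
  traj <- clock_integrate(spec, p, t_end = 200, n_out = 2000)
  expect_error(population_average(traj), "oscillatory")
})

test_that("simulation and eigenvalue classification agree for linear models", {
  spec <- clock_model("SNF", "law0", "linear", 3)
  set.seed(99)
  n_pts <- 60
  agree <- vapply(seq_len(n_pts), function(i) {
    A_T <- 10^runif(1, 2.5, 3.7)
    alpha <- 10^runif(1, 3.5, 5.5)
    p <- clock_params(spec, alpha = alpha, A_T = A_T)
    eig <- classify_point(spec, p, method = "eigen")$oscillatory
    sim <- classify_point(spec, p, method = "simulate",
                          t_end = 300, n_out = 6000,
                          rtol = 1e-8, atol = 1e-10)$oscillatory
    # near-boundary points are legitimately ambiguous for the amplitude rule
    lam <- Re(leading_eigenvalue(spec, p))
    if (abs(lam) < 5e-3) TRUE else eig == sim
  }, logical(1))
  expect_true(all(agree))
})
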