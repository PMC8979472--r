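#' Integrate a clock model
#'
#' Solves the dimensionless ODEs with the stiff-capable `lsoda` solver
#' (compiled right-hand side).  Output is dense enough to resolve the
#' waveform: `n_out` equally spaced points over `[0, t_end]`.
#'
#' @param spec a [clock_model()].
#' @param params a [clock_params()].
#' @param t_end final dimensionless time (default 600).
#' @param n_out number of output intervals (default 24000, i.e. step 0.025
#'   at the default `t_end`).
#' @param y0 initial state; defaults to [initial_state()].
#' @param rtol,atol solver tolerances.  The defaults (1e-8, 1e-10) are
#'   tight because NNF/PNF trajectories have near-zero plateaus.
#' @return a `clock_trajectory`: list with `times`, `states` (matrix, one
#'   column per species), `spec`, `params`.
#' @examples
#' pre <- clock_preset("fig3")
#' traj <- clock_integrate(pre$spec, pre$params, t_end = 60)
#' @export
clock_integrate <- function(spec, params, t_end = 600, n_out = 24000,
                            y0 = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "clock_model"), inherits(params, "clock_params"))
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(y0)) y0 <- initial_state(spec, params)
  nm <- species_names(spec)
  if (length(y0) != length(nm))
    stop("y0 has length ", length(y0), ", expected ", length(nm))
  times <- seq(0, t_end, length.out = n_out + 1)
  sol <- deSolve::ode(y = setNames(as.numeric(y0), nm), times = times,
                      func = "circlock_derivs", parms = compiled_parms(spec, params),
                      dllname = "circlock", initfunc = "circlock_init",
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("solver failure for ", spec$family, " model with alpha=",
         params$alpha, ", A_T=", params$A_T)
  structure(
    list(times = sol[, 1], states = unname(sol[, -1, drop = FALSE]),
         species = nm, spec = spec, params = params),
    class = "clock_trajectory"
  )
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("<clock_trajectory> ", length(x$times), " time points, species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

trajectory_column <- function(traj, name) {
  i <- match(name, traj$species)
  if (is.na(i)) stop("no species named '", name, "'")
  traj$states[, i]
}

# upward crossings of `level` by linear interpolation; returns crossing times
upward_crossings <- function(t, x, level) {
  below <- x[-length(x)] < level & x[-1] >= level
  i <- which(below)
  if (!length(i)) return(numeric(0))
  frac <- (level - x[i]) / (x[i + 1] - x[i])
  t[i] + frac * (t[i + 1] - t[i])
}

#' Summarise an oscillation
#'
#' Discards an initial transient, then classifies the trajectory as
#' oscillatory or not and extracts the cycle statistics: period (mean
#' spacing of upward mean-crossings of nuclear PER), per-species relative
#' amplitudes `(max - min)/(max + min)`, the peak of total PER
#' `P_tot = P + sum(P_j)` (mRNA M excluded), the peak of the
#' protein-only total (additionally excluding the first `n_mrna` chain
#' species, which stand for mRNA processing steps), the one-period time
#' average of A_T, and the skewness of M.
#'
#' A trajectory counts as oscillatory when the post-transient relative
#' amplitude of P exceeds `amp_tol` and the spacing of at least 5
#' mean-crossings is stable to 0.1%.
#'
#' @param traj a `clock_trajectory`.
#' @param transient_fraction fraction of the run discarded (default 0.6).
#' @param n_mrna chain species counted as mRNA-like when computing the
#'   protein-only peak; default 2 for loops with N >= 8, else 0.
#' @param amp_tol relative-amplitude threshold separating limit cycles from
#'   slowly damped spirals (default 1e-3).
#' @return an `osc_summary` list: `oscillatory`, `period`, `inconclusive`,
#'   `max`, `min`, `rel_amplitude` (named per species), `max_P_tot`,
#'   `min_P_tot`, `rel_amp_P_tot`, `max_P_protein`, `avg_A_T`,
#'   `skewness_M`, `n_cycles`.
#' @export
summarize_oscillation <- function(traj, transient_fraction = 0.6,
                                  n_mrna = NULL, amp_tol = 1e-3) {
  stopifnot(inherits(traj, "clock_trajectory"))
  spec <- traj$spec
  if (is.null(n_mrna)) n_mrna <- if (spec$N >= 8) 2L else 0L
  keep <- traj$times >= transient_fraction * traj$times[length(traj$times)]
  t <- traj$times[keep]
  S <- traj$states[keep, , drop = FALSE]
  colnames(S) <- traj$species

  mx <- apply(S, 2, max)
  mn <- apply(S, 2, min)
  rel <- ifelse(mx + mn > 0, (mx - mn) / (mx + mn), 0)

  P <- S[, "P"]
  out <- list(oscillatory = FALSE, period = NA_real_, inconclusive = FALSE,
              max = mx, min = mn, rel_amplitude = rel,
              max_P_tot = NA_real_, min_P_tot = NA_real_,
              rel_amp_P_tot = NA_real_, max_P_protein = NA_real_,
              avg_A_T = NA_real_, skewness_M = NA_real_, n_cycles = 0L)
  class(out) <- "osc_summary"

  if (rel[["P"]] <= amp_tol) {
    # steady (or numerically flat): report extrema over the window
    chain <- paste0("P", seq_len(spec$J))
    pt <- rowSums(S[, c(chain, "P"), drop = FALSE])
    out$max_P_tot <- max(pt)
    out$min_P_tot <- min(pt)
    out$rel_amp_P_tot <- if (max(pt) + min(pt) > 0)
      (max(pt) - min(pt)) / (max(pt) + min(pt)) else 0
    prot <- c(if (spec$J > n_mrna) chain[(n_mrna + 1):spec$J], "P")
    out$max_P_protein <- max(rowSums(S[, prot, drop = FALSE]))
    if ("AT" %in% colnames(S)) out$avg_A_T <- mean(S[, "AT"])
    return(out)
  }

  cross <- upward_crossings(t, P, mean(P))
  if (length(cross) < 6) {            # < 5 full cycles: cannot certify
    out$inconclusive <- TRUE
    return(out)
  }
  gaps <- diff(cross)
  period <- mean(gaps)
  stable <- (max(gaps) - min(gaps)) / period < 1e-3
  # per-cycle amplitude trend separates limit cycles from slow spirals:
  # decaying peaks mean damped, growing peaks mean not yet converged
  cyc_amp <- vapply(seq_len(length(cross) - 1), function(k) {
    seg <- P[t >= cross[k] & t <= cross[k + 1]]
    max(seg) - min(seg)
  }, numeric(1))
  trend <- cyc_amp[length(cyc_amp)] / cyc_amp[1]
  out$n_cycles <- length(gaps)
  out$period <- period
  # a drifting envelope (either direction) means the attractor has not been
  # reached: damped spirals keep shrinking until they fall below amp_tol,
  # while cycles approached from outside settle to trend ~ 1
  out$oscillatory <- stable && trend >= 0.98 && trend <= 1.02
  out$inconclusive <- !out$oscillatory

  # statistics over the integer-period window between first and last crossing
  win <- t >= cross[1] & t <= cross[length(cross)]
  W <- S[win, , drop = FALSE]
  chain <- paste0("P", seq_len(spec$J))
  out$max <- apply(W, 2, max)
  out$min <- apply(W, 2, min)
  out$rel_amplitude <- ifelse(out$max + out$min > 0,
                              (out$max - out$min) / (out$max + out$min), 0)
  pt <- rowSums(W[, c(chain, "P"), drop = FALSE])
  out$max_P_tot <- max(pt)
  out$min_P_tot <- min(pt)
  out$rel_amp_P_tot <- (max(pt) - min(pt)) / (max(pt) + min(pt))
  prot <- c(if (spec$J > n_mrna) chain[(n_mrna + 1):spec$J], "P")
  out$max_P_protein <- max(rowSums(W[, prot, drop = FALSE]))
  if ("AT" %in% colnames(S)) {
    one <- t >= cross[length(cross)] - period & t <= cross[length(cross)]
    out$avg_A_T <- mean(S[one, "AT"])
  }
  out$skewness_M <- series_skewness(W[, "M"])
  out
}

#' @export
print.osc_summary <- function(x, ...) {
  if (x$oscillatory)
    cat(sprintf("<osc_summary> oscillatory, period = %.4g over %d cycles\n",
                x$period, x$n_cycles))
  else if (x$inconclusive)
    cat("<osc_summary> inconclusive (run too short or period unstable)\n")
  else
    cat("<osc_summary> non-oscillatory\n")
  cat(sprintf("  max P_tot = %.4g, max P_protein = %.4g\n",
              x$max_P_tot, x$max_P_protein))
  if (is.finite(x$avg_A_T)) cat(sprintf("  avg A_T = %.4g\n", x$avg_A_T))
  invisible(x)
}

#' Integrate and summarise, extending the run until the period stabilises
#'
#' Convenience wrapper: integrates to `t_end`, summarises, and doubles
#' `t_end` (at most `max_extend` times) while the classification is
#' inconclusive -- convergence onto the limit cycle is slow near Hopf
#' boundaries.
#'
#' @inheritParams clock_integrate
#' @inheritParams summarize_oscillation
#' @param max_extend maximum number of doublings (default 3).
#' @return list with `trajectory` and `summary`.
#' @export
simulate_clock <- function(spec, params, t_end = 600, n_out = 24000,
                           rtol = 1e-8, atol = 1e-10,
                           transient_fraction = 0.6, n_mrna = NULL,
                           amp_tol = 1e-3, max_extend = 3) {
  for (k in 0:max_extend) {
    traj <- clock_integrate(spec, params, t_end = t_end, n_out = n_out,
                            rtol = rtol, atol = atol)
    s <- summarize_oscillation(traj, transient_fraction = transient_fraction,
                               n_mrna = n_mrna, amp_tol = amp_tol)
    if (!s$inconclusive) break
    t_end <- 2 * t_end
    n_out <- 2 * n_out
  }
  list(trajectory = traj, summary = s)
}

#' Skewness of a uniformly sampled periodic series
#'
#' Third standardised moment, `mean((x - m)^3) / mean((x - m)^2)^(3/2)`,
#' intended for series covering an integer number of periods on a uniform
#' time grid (otherwise partial cycles bias the moments).
#'
#' @param x numeric series.
#' @return skewness.
#' @export
series_skewness <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) stop("skewness undefined for a constant series")
  mean((x - m)^3) / v^1.5
}

#' Phase-dispersed population average of a limit cycle
#'
#' Emulates a bulk measurement over a population of unsynchronised cells:
#' each cell runs the same limit cycle, time-shifted by a Normal(0,
#' `phase_sd`) draw (wrapped periodically), and the traces are averaged.
#' Dephasing attenuates harmonics, so an asymmetric single-cell waveform
#' averages to a more nearly sinusoidal (less skewed) population trace.
#'
#' @param traj an oscillatory `clock_trajectory`.
#' @param phase_sd standard deviation of the phase shifts, in dimensionless
#'   time units.
#' @param n_cells number of cells averaged.
#' @param seed RNG seed (the only source of randomness).
#' @param n_periods number of periods covered by the returned average.
#' @param transient_fraction passed to [summarize_oscillation()] to locate
#'   the limit cycle.
#' @return list with `times`, `states` (averaged over cells, one column per
#'   species), `species`, `period`, `skewness_M`.
#' @export
population_average <- function(traj, phase_sd = 0.5, n_cells = 100,
                               seed = 1, n_periods = 3,
                               transient_fraction = 0.6) {
  stopifnot(inherits(traj, "clock_trajectory"), phase_sd >= 0, n_cells >= 1)
  s <- summarize_oscillation(traj, transient_fraction = transient_fraction)
  if (!s$oscillatory)
    stop("population_average() needs an oscillatory trajectory")
  period <- s$period

  # one period of the limit cycle, as a periodic interpolant per species
  t_last <- traj$times[length(traj$times)]
  t0 <- t_last - period * floor((t_last - transient_fraction * t_last) / period)
  grid <- seq(0, period, length.out = 2049)[-2049]
  base <- sapply(seq_along(traj$species), function(j)
    approx(traj$times, traj$states[, j], xout = t0 + grid)$y)

  set.seed(seed)
  shifts <- rnorm(n_cells, 0, phase_sd) %% period
  ng <- length(grid)
  times <- seq(0, n_periods * period, length.out = n_periods * ng + 1)
  idx0 <- (seq_along(times) - 1) %% ng           # position within the cycle
  acc <- matrix(0, length(times), ncol(base))
  for (i in seq_len(n_cells)) {
    off <- (idx0 + round(shifts[i] / period * ng)) %% ng + 1
    acc <- acc + base[off, , drop = FALSE]
  }
  avg <- acc / n_cells
  list(times = times, states = avg, species = traj$species,
       period = period, skewness_M = series_skewness(avg[, 1]))
}
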