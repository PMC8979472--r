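#' Constrained parameter-search problem
#'
#' Defines the box bounds, the hard constraints and the objective of the
#' search for parameter sets that oscillate with the smallest possible
#' peak of total PER -- equivalently, that tolerate the largest physical
#' dissociation constant K_d (which scales as 1 / max P_tot).
#'
#' Default bounds per family (all searched on a log scale):
#' \itemize{
#'   \item SNF law1: alpha in \[1e-2, 1e3\], A_T in \[1e-2, 1e2\],
#'     beta_max in \[1e-2, 1e3\], K_m in \[1, 1e2\], K_A in \[1, 1e2\].
#'   \item SNF law0 (no K_A): the remaining four.
#'   \item NNF: as SNF law1 with A_MAX in \[1e-2, 1e3\] plus
#'     V_MAX in \[1e-2, 1e2\], delta in \[1e-2, 1e2\].
#'   \item PNF: as NNF with R_MAX in place of V_MAX and additionally
#'     epsilon in \[1e-4, 1e-1\].
#' }
#'
#' Hard constraints (all families): sustained oscillation and relative
#' amplitude of P_tot above 0.5.  NNF adds relative amplitude of A_T above
#' 0.2 and max V below 10; PNF adds relative amplitude of A_T above 0.2
#' and max R below 5.  NNF/PNF additionally carry the soft criterion that
#' the ratio max A_T / max P_tot be close to 1.
#'
#' @param spec a [clock_model()] with michaelian degradation.
#' @param bounds optional named list of `c(lo, hi)` overriding defaults.
#' @return a `search_problem` list with `spec`, `bounds`, `param_names`.
#' @export
search_problem <- function(spec, bounds = NULL) {
  stopifnot(inherits(spec, "clock_model"))
  b <- list(alpha = c(1e-2, 1e3),
            A_T = c(1e-2, if (spec$family == "SNF") 1e2 else 1e3),
            beta_max = c(1e-2, 1e3),
            K_m = c(1, 1e2))
  if (spec$law == "law1") b$K_A <- c(1, 1e2)
  if (spec$family == "NNF") {
    b$V_MAX <- c(1e-2, 1e2)
    b$delta <- c(1e-2, 1e2)
  }
  if (spec$family == "PNF") {
    b$R_MAX <- c(1e-2, 1e2)
    b$delta <- c(1e-2, 1e2)
    b$epsilon <- c(1e-4, 1e-1)
  }
  if (!is.null(bounds)) b <- modifyList(b, bounds)
  structure(list(spec = spec, bounds = b, param_names = names(b)),
            class = "search_problem")
}

params_from_vector <- function(problem, x) {
  do.call(clock_params,
          c(list(spec = problem$spec), as.list(setNames(x, problem$param_names))))
}

#' Evaluate a candidate parameter set
#'
#' Simulates the candidate and reports the objective (peak total PER) and
#' every constraint.  Non-oscillatory candidates are infeasible.  The
#' penalised cost adds the exact penalty `w * violation` (w = 1e3) per
#' violated hard constraint and, for NNF/PNF, the soft term
#' `w * log(ratio)^2` on the peak-BMAL1 to peak-PER ratio.
#'
#' @param problem a [search_problem()].
#' @param x numeric vector of parameter values in `problem$param_names`
#'   order (or a [clock_params()]).
#' @param t_end,n_out,rtol,atol solver settings for candidate evaluation
#'   (defaults trade some accuracy for speed).
#' @param penalty_weight weight of the quadratic penalty terms.
#' @return list: `feasible`, `objective` (max P_tot, `NA` if the candidate
#'   does not oscillate), `cost` (penalised), `period`, `constraints`
#'   (named list of measured values), `violations` (named numeric).
#' @export
evaluate_candidate <- function(problem, x, t_end = 300, n_out = 6000,
                               rtol = 1e-6, atol = 1e-8,
                               penalty_weight = 1e3) {
  params <- if (inherits(x, "clock_params")) x else params_from_vector(problem, x)
  spec <- problem$spec
  s <- tryCatch(
    simulate_clock(spec, params, t_end = t_end, n_out = n_out,
                   rtol = rtol, atol = atol, max_extend = 1)$summary,
    error = function(e) NULL)
  if (is.null(s)) {
    return(list(feasible = FALSE, objective = NA_real_, cost = 1e6,
                period = NA_real_, constraints = list(),
                violations = c(oscillatory = 1)))
  }
  if (!isTRUE(s$oscillatory)) {
    # graded infeasible cost: larger residual amplitude means closer to the
    # oscillatory domain, which gives the annealer a slope to follow
    amp <- min(1, s$rel_amplitude[["P"]])
    return(list(feasible = FALSE, objective = NA_real_,
                cost = 1e4 + penalty_weight * (1 - amp),
                period = NA_real_, constraints = list(),
                violations = c(oscillatory = 1)))
  }
  amp_ptot <- s$rel_amp_P_tot
  viol <- c()
  cons <- list(rel_amp_P_tot = amp_ptot, max_P_tot = s$max_P_tot,
               period = s$period)
  viol["rel_amp_P_tot"] <- max(0, 0.5 - amp_ptot)
  soft <- 0
  if (spec$family != "SNF") {
    amp_A <- s$rel_amplitude[["AT"]]
    cons$rel_amp_A_T <- amp_A
    viol["rel_amp_A_T"] <- max(0, 0.2 - amp_A)
    ratio <- s$max[["AT"]] / s$max_P_tot
    cons$peak_ratio <- ratio
    soft <- penalty_weight * log(ratio)^2
    if (spec$family == "NNF") {
      cons$max_V <- s$max[["V"]]
      viol["max_V"] <- max(0, s$max[["V"]] - 10)
    } else {
      cons$max_R <- s$max[["R"]]
      viol["max_R"] <- max(0, s$max[["R"]] - 5)
    }
  }
  # exact (linear) penalty: with a quadratic penalty the penalised optimum
  # sits strictly inside the infeasible side of the amplitude constraint
  # (zero gradient at zero violation), so runs would converge just below
  # the threshold; the linear form makes the constrained optimum the
  # penalised optimum for any weight above the active multiplier
  cost <- s$max_P_tot + penalty_weight * sum(viol) + soft
  list(feasible = all(viol == 0), objective = s$max_P_tot, cost = cost,
       period = s$period, constraints = cons, violations = viol)
}

#' Simulated-annealing search for minimal peak PER
#'
#' Stochastic search over the log-scaled bounded box of
#' [search_problem()]: proposals perturb each parameter multiplicatively,
#' acceptance follows the Metropolis rule, and the temperature cools
#' geometrically (factor 0.95 per 50 accepted moves).  Each restart runs
#' independently from a random feasible-or-not start; elitism keeps the
#' best candidate seen.  With several restarts the run doubles as a batch
#' experiment: the returned summary gives mean and standard deviation of
#' the objective and period over the per-restart best feasible candidates.
#'
#' @param problem a [search_problem()].
#' @param iterations proposals per restart.
#' @param restarts independent restarts.
#' @param seed RNG seed; identical seeds give identical output.
#' @param step initial proposal size in log10 units; the proposal standard
#'   deviation shrinks geometrically to 5% of `step` over the run.
#' @param T0 initial temperature (cost units).
#' @param polish greedy feasible-only refinement steps appended to each
#'   restart (small downhill moves from the best feasible point).
#' @param ... passed to [evaluate_candidate()].
#' @return an `anneal_result` list: `best` (parameters, objective, period),
#'   `batch` (data.frame, one row per restart with a feasible best),
#'   `summary` (mean/sd of objective and period), `n_feasible`.
#' @export
anneal <- function(problem, iterations = 300, restarts = 20, seed = 1,
                   step = 0.25, T0 = 50, polish = 150, ...) {
  stopifnot(iterations >= 1, restarts >= 1)
  set.seed(seed)
  b <- problem$bounds
  lo <- log10(vapply(b, `[`, numeric(1), 1))
  hi <- log10(vapply(b, `[`, numeric(1), 2))
  np <- length(lo)

  run_once <- function() {
    # start each walk at an oscillatory point when one can be found
    # quickly: random starts are almost surely non-oscillatory, and the
    # search is only meaningful inside the oscillatory domain
    z <- runif(np, lo, hi)                      # log10 coordinates
    ev <- evaluate_candidate(problem, 10^z, ...)
    tries <- 0
    while (is.na(ev$objective) && tries < 30) {
      z2 <- runif(np, lo, hi)
      ev2 <- evaluate_candidate(problem, 10^z2, ...)
      if (!is.na(ev2$objective) || ev2$cost < ev$cost) {
        z <- z2; ev <- ev2
      }
      tries <- tries + 1
    }
    best <- list(z = z, ev = ev)
    bestf <- if (ev$feasible) best else NULL
    Temp <- T0
    accepted <- 0
    for (it in seq_len(iterations)) {
      # proposal size shrinks geometrically so late iterations refine
      sd_it <- step * (0.05 / 1)^((it - 1) / (iterations - 1))
      zp <- pmin(pmax(z + rnorm(np, 0, sd_it), lo), hi)
      evp <- evaluate_candidate(problem, 10^zp, ...)
      if (evp$cost < ev$cost ||
          runif(1) < exp((ev$cost - evp$cost) / Temp)) {
        z <- zp; ev <- evp
        accepted <- accepted + 1
        Temp <- T0 * 0.95^(accepted %/% 50)
      }
      if ((ev$feasible && !best$ev$feasible) ||
          (ev$feasible == best$ev$feasible && ev$cost < best$ev$cost))
        best <- list(z = z, ev = ev)
      if (ev$feasible &&
          (is.null(bestf) || ev$objective < bestf$ev$objective))
        bestf <- list(z = z, ev = ev)
    }
    # greedy polish of the best feasible point: small feasible-only
    # downhill moves, emulating a fully converged annealing run
    if (!is.null(bestf)) {
      z <- bestf$z
      ev <- bestf$ev
      for (it in seq_len(polish)) {
        sd_it <- 0.05 * (0.2)^((it - 1) / max(1, polish - 1))
        zp <- pmin(pmax(z + rnorm(np, 0, sd_it), lo), hi)
        evp <- evaluate_candidate(problem, 10^zp, ...)
        if (evp$feasible && evp$objective < ev$objective) {
          z <- zp; ev <- evp
        }
      }
      bestf <- list(z = z, ev = ev)
    }
    list(best = best, bestf = bestf)
  }

  runs <- lapply(seq_len(restarts), function(i) run_once())
  feas <- Filter(Negate(is.null), lapply(runs, `[[`, "bestf"))
  batch <- if (length(feas)) {
    do.call(rbind, lapply(feas, function(r)
      data.frame(objective = r$ev$objective, period = r$ev$period,
                 t(setNames(10^r$z, problem$param_names)))))
  } else NULL
  allbest <- lapply(runs, `[[`, "best")
  best <- allbest[[which.min(vapply(allbest, function(r)
    r$ev$cost + if (r$ev$feasible) 0 else 1e9, numeric(1)))]]
  res <- list(
    best = list(params = params_from_vector(problem, 10^best$z),
                objective = best$ev$objective, period = best$ev$period,
                feasible = best$ev$feasible, constraints = best$ev$constraints),
    batch = batch,
    summary = if (!is.null(batch)) list(
      objective_mean = mean(batch$objective), objective_sd = sd(batch$objective),
      period_mean = mean(batch$period), period_sd = sd(batch$period)) else NULL,
    n_feasible = length(feas))
  class(res) <- "anneal_result"
  res
}

#' @export
print.anneal_result <- function(x, ...) {
  cat("<anneal_result> ", x$n_feasible, " feasible restart(s)\n", sep = "")
  if (!is.null(x$summary))
    cat(sprintf("  max P_tot = %.3g +/- %.2g, period = %.3g +/- %.2g\n",
                x$summary$objective_mean, x$summary$objective_sd,
                x$summary$period_mean, x$summary$period_sd))
  if (!is.null(x$best$objective) && !is.na(x$best$objective))
    cat(sprintf("  best objective %.4g (period %.4g)\n",
                x$best$objective, x$best$period))
  invisible(x)
}
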