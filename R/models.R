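#' Define a clock model variant
#'
#' A model variant is identified by its feedback architecture, the *Per*
#' transcription rate law, the nuclear PER degradation rate law, and the
#' length of the core negative-feedback loop.
#'
#' The core loop consists of *Per* mRNA (M), a chain of `J = N - 2`
#' intermediates (mRNA processing, translation, phosphorylation, nuclear
#' import), and nuclear PER (P), which sequesters the BMAL1:CLOCK activator
#' by stoichiometric binding.  `family = "NNF"` adds REV-ERB repression of
#' *Bmal1* (state variables A_T and V); `family = "PNF"` adds ROR activation
#' of *Bmal1* (state variables A_T and R).
#'
#' The shorthand used throughout ("SNF(0L3)", "NNF(1M8)", ...) reads:
#' family, transcription law (0 or 1), degradation law (L linear,
#' M Michaelian), loop length N.
#'
#' @param family one of "SNF", "NNF", "PNF".
#' @param law transcription rate law: "law0" (rate proportional to
#'   A_free/A_T) or "law1" (proportional to A_free/(K_A + A_T)).
#' @param degradation nuclear PER removal: "linear" or "michaelian".
#' @param N total loop length (>= 3); the number of chain intermediates is
#'   `J = N - 2`.
#' @return an object of class `clock_model`.
#' @examples
#' clock_model("SNF", "law0", "linear", N = 3)   # the original 0L3 model
#' clock_model("PNF", "law1", "michaelian", N = 8)
#' @export
clock_model <- function(family = c("SNF", "NNF", "PNF"),
                        law = c("law0", "law1"),
                        degradation = c("linear", "michaelian"),
                        N = 3) {
  family <- match.arg(family)
  law <- match.arg(law)
  degradation <- match.arg(degradation)
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N < 3)
    stop("N must be a single integer >= 3")
  structure(
    list(family = family, law = law, degradation = degradation,
         N = as.integer(N), J = as.integer(N) - 2L),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  code <- paste0(x$family, "(",
                 if (x$law == "law0") "0" else "1",
                 if (x$degradation == "linear") "L" else "M",
                 x$N, ")")
  cat("<clock_model> ", code, "  [", x$J, " chain intermediate",
      if (x$J > 1) "s", "]\n", sep = "")
  invisible(x)
}

#' Dimensionless parameter set for a clock model
#'
#' All parameters are dimensionless: concentrations are scaled by the
#' PER:BMAL1 dissociation constant (so K_d = 1 by construction) and time by
#' the common first-order decay rate.  Only the fields relevant to the given
#' model variant may be supplied; irrelevant fields must be left `NULL`.
#'
#' @param spec a [clock_model()].
#' @param alpha maximal *Per* transcription strength (> 0).
#' @param A_T total activator concentration: the constant A_T for SNF, or
#'   A_MAX (the maximal *Bmal1* expression level) for NNF/PNF.
#' @param beta_max maximal Michaelian degradation rate (michaelian only).
#' @param K_m Michaelis constant of nuclear PER degradation (michaelian
#'   only).
#' @param K_A activator/E-box dissociation constant (law1 only; `K_A = 0`
#'   recovers law 0).
#' @param V_MAX maximal REV-ERB level (NNF only).
#' @param R_MAX maximal ROR level (PNF only).
#' @param delta relaxation rate of the *Bmal1* arm (NNF/PNF).
#' @param epsilon basal *Bmal1* expression fraction in (0, 1) (PNF only).
#' @return an object of class `clock_params` (a named list).
#' @export
clock_params <- function(spec, alpha, A_T, beta_max = NULL, K_m = NULL,
                         K_A = NULL, V_MAX = NULL, R_MAX = NULL,
                         delta = NULL, epsilon = NULL) {
  stopifnot(inherits(spec, "clock_model"))
  chk_pos <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      stop(nm, " must be a single positive number")
    x
  }
  p <- list(alpha = chk_pos(alpha, "alpha"), A_T = chk_pos(A_T, "A_T"))

  if (spec$degradation == "michaelian") {
    p$beta_max <- chk_pos(beta_max, "beta_max")
    p$K_m <- chk_pos(K_m, "K_m")
  } else if (!is.null(beta_max) || !is.null(K_m)) {
    stop("beta_max/K_m only apply to michaelian degradation")
  }
  if (spec$law == "law1") {
    if (is.null(K_A) || length(K_A) != 1L || !is.finite(K_A) || K_A < 0)
      stop("K_A must be a single number >= 0 for rate law 1")
    p$K_A <- K_A
  } else if (!is.null(K_A)) {
    stop("K_A only applies to rate law 1")
  }
  if (spec$family == "NNF") {
    p$V_MAX <- chk_pos(V_MAX, "V_MAX")
    p$delta <- chk_pos(delta, "delta")
  } else if (!is.null(V_MAX)) {
    stop("V_MAX only applies to the NNF family")
  }
  if (spec$family == "PNF") {
    p$R_MAX <- chk_pos(R_MAX, "R_MAX")
    p$delta <- chk_pos(delta, "delta")
    if (is.null(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
        epsilon <= 0 || epsilon >= 1)
      stop("epsilon must be a single number in (0, 1)")
    p$epsilon <- epsilon
  } else if (!is.null(R_MAX) || !is.null(epsilon)) {
    stop("R_MAX/epsilon only apply to the PNF family")
  }
  if (spec$family == "SNF" && !is.null(delta))
    stop("delta only applies to the NNF/PNF families")
  structure(p, class = "clock_params")
}

#' @export
print.clock_params <- function(x, ...) {
  cat("<clock_params>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Free activator concentration under stoichiometric sequestration
#'
#' Solves the equilibrium-binding quadratic for the concentration of
#' activator (BMAL1:CLOCK) not bound by repressor (PER:CRY), with the
#' dimensionless dissociation constant equal to 1:
#' `A_free = (A_T - P - 1 + sqrt((A_T - P - 1)^2 + 4 A_T)) / 2`.
#'
#' When `A_T - P - 1 < 0` the root is evaluated in the algebraically
#' equivalent form `2 A_T / (P + 1 - A_T + sqrt(...))`, which avoids
#' catastrophic cancellation when the repressor is in large excess --
#' exactly the regime oscillations drive the system into.
#'
#' @param A_T total activator (>= 0); recycled against `P`.
#' @param P nuclear repressor (>= 0).
#' @return free activator, in `[0, A_T]`.
#' @examples
#' afree(1, 0)    # no repressor: all activator free
#' afree(2, 1)    # sqrt(2)
#' @export
afree <- function(A_T, P) {
  if (any(!is.finite(A_T)) || any(!is.finite(P)) || any(A_T < 0) || any(P < 0))
    stop("afree() requires finite non-negative A_T and P")
  b <- A_T - P - 1
  s <- sqrt(b * b + 4 * A_T)
  ifelse(b >= 0, (b + s) / 2, 2 * A_T / (s - b))
}

#' Per transcription rate
#'
#' Rate law 0 takes the transcription rate proportional to the fraction of
#' unsequestered activator, `alpha * A_free / A_T` (activator assumed to
#' saturate the E-boxes).  Rate law 1, `alpha * A_free / (K_A + A_T)`,
#' relaxes that saturation assumption; `K_A = 0` recovers law 0.
#'
#' @param A_free free activator.
#' @param A_T total activator.
#' @param alpha transcription strength.
#' @param law "law0" or "law1".
#' @param K_A E-box dissociation constant (law1).
#' @return synthesis rate of M.
#' @export
transcription_rate <- function(A_free, A_T, alpha, law = c("law0", "law1"),
                               K_A = 0) {
  law <- match.arg(law)
  if (law == "law0") {
    if (any(A_T <= 0))
      stop("rate law 0 is undefined at A_T = 0")
    alpha * A_free / A_T
  } else {
    if (any(K_A < 0)) stop("K_A must be >= 0")
    alpha * A_free / (K_A + A_T)
  }
}

#' Nuclear PER removal rate
#'
#' Linear kinetics return `P`; the Michaelis-Menten law returns
#' `beta_max * P / (K_m + P)`, which saturates at `beta_max` -- the feature
#' that slows the response of nuclear PER to production changes and thereby
#' boosts oscillatory robustness.
#'
#' @param P nuclear PER (>= 0).
#' @param degradation "linear" or "michaelian".
#' @param beta_max,K_m Michaelian parameters.
#' @return removal rate of P.
#' @export
degradation_rate <- function(P, degradation = c("linear", "michaelian"),
                             beta_max = NULL, K_m = NULL) {
  degradation <- match.arg(degradation)
  if (any(P < 0)) stop("P must be >= 0")
  if (degradation == "linear") P else beta_max * P / (K_m + P)
}

#' Species names for a model variant
#'
#' @param spec a [clock_model()].
#' @return character vector: `M`, `P1`..`PJ`, `P`, then `AT` and `V` (NNF)
#'   or `R` (PNF).
#' @export
species_names <- function(spec) {
  nm <- c("M", paste0("P", seq_len(spec$J)), "P")
  if (spec$family == "NNF") nm <- c(nm, "AT", "V")
  if (spec$family == "PNF") nm <- c(nm, "AT", "R")
  nm
}

#' Default initial conditions
#'
#' All core species start at zero; for NNF/PNF the activator starts at half
#' its maximal level and the auxiliary protein at zero.  Any positive start
#' converges to the same attractor; a fixed choice keeps runs reproducible.
#'
#' @param spec a [clock_model()].
#' @param params a [clock_params()].
#' @return named numeric state vector.
#' @export
initial_state <- function(spec, params) {
  y <- setNames(numeric(spec$N), c("M", paste0("P", seq_len(spec$J)), "P"))
  if (spec$family == "NNF") y <- c(y, AT = params$A_T / 2, V = 0)
  if (spec$family == "PNF") y <- c(y, AT = params$A_T / 2, R = 0)
  y
}

#' Time derivative of the model state
#'
#' Pure-R reference implementation of the dimensionless ODE right-hand
#' side.  The compiled equivalent in src/ is what the integrator calls; this
#' function is the readable single source of the equations and is tested
#' against the compiled code.
#'
#' The core loop is `dM/dt = alpha F(A_free) - M`, `dP1/dt = M - P1`,
#' `dPj/dt = P(j-1) - Pj`, `dP/dt = PJ - G(P)`.  NNF adds
#' `dAT/dt = delta (A_MAX/(V+1) - AT)`, `dV/dt = delta (V_MAX F - V)`;
#' PNF adds `dAT/dt = delta (A_MAX (eps+R)/(R+1) - AT)`,
#' `dR/dt = delta (R_MAX F - R)`.  F uses the instantaneous A_T.
#'
#' @param state named state vector matching [species_names()].
#' @param params a [clock_params()].
#' @param spec a [clock_model()].
#' @return named derivative vector.
#' @export
clock_rhs <- function(state, params, spec) {
  nm <- species_names(spec)
  if (length(state) != length(nm))
    stop("state has length ", length(state), ", expected ", length(nm))
  J <- spec$J
  M <- state[[1]]
  P <- state[[J + 2]]
  A_T <- if (spec$family == "SNF") params$A_T else state[[J + 3]]
  Af <- afree(A_T, P)
  FF <- if (spec$law == "law0") Af / A_T else Af / (params$K_A + A_T)
  G <- if (spec$degradation == "linear") P else
    params$beta_max * P / (params$K_m + P)
  chain <- state[2:(J + 1)]
  d <- c(params$alpha * FF - M,
         c(M, chain[-J])[seq_len(J)] - chain,
         chain[J] - G)
  if (spec$family == "NNF") {
    V <- state[[J + 4]]
    d <- c(d,
           params$delta * (params$A_T / (V + 1) - A_T),
           params$delta * (params$V_MAX * FF - V))
  } else if (spec$family == "PNF") {
    R <- state[[J + 4]]
    d <- c(d,
           params$delta * (params$A_T * (params$epsilon + R) / (R + 1) - A_T),
           params$delta * (params$R_MAX * FF - R))
  }
  setNames(d, nm)
}

# parameter vector handed to the compiled derivs routine
compiled_parms <- function(spec, params) {
  c(law = if (spec$law == "law0") 0 else 1,
    deg = if (spec$degradation == "linear") 0 else 1,
    J = spec$J,
    fam = match(spec$family, c("SNF", "NNF", "PNF")) - 1,
    alpha = params$alpha,
    AT = params$A_T,
    beta_max = params$beta_max %||% 0,
    Km = params$K_m %||% 1,
    KA = params$K_A %||% 0,
    VRmax = params$V_MAX %||% params$R_MAX %||% 0,
    delta = params$delta %||% 0,
    eps = params$epsilon %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert dimensional rate constants to the dimensionless parameter set
#'
#' Concentrations are scaled by the dissociation constant `Kd_hat` of the
#' PER:BMAL1 complex and time by the common decay rate `beta_hat`; the
#' composite transcription strength is
#' `alpha = prod(alpha_hat) / (beta_hat^N * Kd_hat)` for a loop of length
#' `N` (the production rates of the chain steps are assumed equal to
#' `beta_hat`, so extra steps contribute cancelling factors).
#'
#' @param alpha_hat vector of the N production-rate constants around the
#'   loop (transcription first), units nM/h then 1/h.
#' @param beta_hat common decay rate, 1/h.
#' @param Kd_hat PER:BMAL1 dissociation constant, nM.
#' @param A_T_hat total activator, nM.
#' @param K_m_hat,beta_max_hat Michaelian degradation constants (nM, nM/h).
#' @param delta_hat Bmal1-arm relaxation rate, 1/h.
#' @return named list of dimensionless parameters (`alpha`, `A_T`, and any
#'   of `K_m`, `beta_max`, `delta` supplied).
#' @examples
#' nondimensionalize(c(2, 1, 1), beta_hat = 1, Kd_hat = 2,
#'                   A_T_hat = 40)$alpha   # 1
#' @export
nondimensionalize <- function(alpha_hat, beta_hat, Kd_hat, A_T_hat,
                              K_m_hat = NULL, beta_max_hat = NULL,
                              delta_hat = NULL) {
  if (beta_hat <= 0 || Kd_hat <= 0)
    stop("beta_hat and Kd_hat must be positive")
  if (any(alpha_hat <= 0) || A_T_hat <= 0)
    stop("all dimensional rates must be positive")
  out <- list(
    alpha = prod(alpha_hat) / (beta_hat^length(alpha_hat) * Kd_hat),
    A_T = A_T_hat / Kd_hat)
  if (!is.null(K_m_hat)) out$K_m <- K_m_hat / Kd_hat
  if (!is.null(beta_max_hat)) out$beta_max <- beta_max_hat / (beta_hat * Kd_hat)
  if (!is.null(delta_hat)) out$delta <- delta_hat / beta_hat
  out
}

#' Recover dimensional constants from a dimensionless parameter set
#'
#' Inverse of [nondimensionalize()] under the equal-rate convention: the
#' chain production rates are taken equal to `beta_hat` except the first,
#' which absorbs `alpha`.
#'
#' @param params named list with at least `alpha` and `A_T` (as returned by
#'   [nondimensionalize()]).
#' @param beta_hat decay rate, 1/h.
#' @param Kd_hat dissociation constant, nM.
#' @param N loop length used for the forward conversion.
#' @return named list of dimensional constants.
#' @export
dimensionalize <- function(params, beta_hat, Kd_hat, N = 3) {
  if (beta_hat <= 0 || Kd_hat <= 0)
    stop("beta_hat and Kd_hat must be positive")
  out <- list(
    alpha_hat = c(params$alpha * beta_hat * Kd_hat, rep(beta_hat, N - 1)),
    A_T_hat = params$A_T * Kd_hat)
  if (!is.null(params$K_m)) out$K_m_hat <- params$K_m * Kd_hat
  if (!is.null(params$beta_max))
    out$beta_max_hat <- params$beta_max * beta_hat * Kd_hat
  if (!is.null(params$delta)) out$delta_hat <- params$delta * beta_hat
  out
}

#' Built-in wild-type presets
#'
#' Returns the model variant, parameter set and (where used for unit
#' conversion) the timescale `beta_hat` for the documented wild-type
#' operating points of each model family.
#'
#' Available presets:
#' \describe{
#'   \item{fig3}{SNF(0L3), A_T = 1000, alpha = 20000 (beta_hat = 0.16/h).}
#'   \item{fig4c}{SNF(0L8), A_T = 40, alpha = 200.}
#'   \item{fig5}{SNF(0M8), beta_max = 3.8, K_m = 1, A_T = 16, alpha = 20.}
#'   \item{fig7}{SNF(1M8), beta_max = 5, K_m = 5.5, K_A = 20, A_T = 20,
#'     alpha = 50 (beta_hat = 1.125/h).}
#'   \item{fig8}{NNF(1M8), beta_max = 4.5, K_m = 2.5, K_A = 3.7,
#'     V_MAX = 22, delta = 0.17, A_MAX = 30, alpha = 30 (beta_hat = 1/h).}
#'   \item{fig9}{PNF(1M8), beta_max = 1.85, K_m = 8.5, K_A = 35,
#'     R_MAX = 6.2, epsilon = 3e-4, delta = 8, A_MAX = 15, alpha = 10
#'     (beta_hat = 1.3/h).}
#' }
#'
#' @param name preset name.
#' @return list with elements `spec`, `params`, `beta_hat` (or `NA`).
#' @examples
#' clock_preset("fig3")$params$alpha
#' @export
clock_preset <- function(name = c("fig3", "fig4c", "fig5", "fig7", "fig8",
                                  "fig9")) {
  name <- match.arg(name)
  switch(name,
    fig3 = {
      spec <- clock_model("SNF", "law0", "linear", N = 3)
      list(spec = spec,
           params = clock_params(spec, alpha = 2e4, A_T = 1e3),
           beta_hat = 0.16)
    },
    fig4c = {
      spec <- clock_model("SNF", "law0", "linear", N = 8)
      list(spec = spec,
           params = clock_params(spec, alpha = 200, A_T = 40),
           beta_hat = NA_real_)
    },
    fig5 = {
      spec <- clock_model("SNF", "law0", "michaelian", N = 8)
      list(spec = spec,
           params = clock_params(spec, alpha = 20, A_T = 16,
                                 beta_max = 3.8, K_m = 1),
           beta_hat = NA_real_)
    },
    fig7 = {
      spec <- clock_model("SNF", "law1", "michaelian", N = 8)
      list(spec = spec,
           params = clock_params(spec, alpha = 50, A_T = 20,
                                 beta_max = 5, K_m = 5.5, K_A = 20),
           beta_hat = 1.125)
    },
    fig8 = {
      spec <- clock_model("NNF", "law1", "michaelian", N = 8)
      list(spec = spec,
           params = clock_params(spec, alpha = 30, A_T = 30,
                                 beta_max = 4.5, K_m = 2.5, K_A = 3.7,
                                 V_MAX = 22, delta = 0.17),
           beta_hat = 1)
    },
    fig9 = {
      spec <- clock_model("PNF", "law1", "michaelian", N = 8)
      list(spec = spec,
           params = clock_params(spec, alpha = 10, A_T = 15,
                                 beta_max = 1.85, K_m = 8.5, K_A = 35,
                                 R_MAX = 6.2, delta = 8, epsilon = 3e-4),
           beta_hat = 1.3)
    })
}
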