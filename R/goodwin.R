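#' Goodwin oscillator parameters
#'
#' The classical negative-feedback chain used as a baseline for
#' comparison: the end product Z of an N-stage chain represses the first
#' stage through a Hill function with exponent `p`, and every stage decays
#' at unit rate (the dimensionless convention shared with the clock
#' models).
#'
#' @param alpha1 maximal transcription rate (> 0).
#' @param K repression threshold (> 0).
#' @param p Hill exponent (>= 1).
#' @param N chain length (integer >= 3).
#' @return a `goodwin_params` list.
#' @export
goodwin_params <- function(alpha1, K = 1, p, N = 3) {
  stopifnot(alpha1 > 0, K > 0, p >= 1, N == round(N), N >= 3)
  structure(list(alpha1 = alpha1, K = K, p = p, N = as.integer(N)),
            class = "goodwin_params")
}

#' Goodwin chain right-hand side
#'
#' `dX1/dt = alpha1 K^p / (K^p + Z^p) - X1`, `dXj/dt = X(j-1) - Xj`, with
#' `Z = XN`.
#'
#' @param state numeric state vector of length N.
#' @param params a [goodwin_params()].
#' @return derivative vector.
#' @export
goodwin_rhs <- function(state, params) {
  N <- params$N
  if (length(state) != N) stop("state must have length N = ", N)
  Z <- state[N]
  prod1 <- params$alpha1 * params$K^params$p / (params$K^params$p + Z^params$p)
  c(prod1, state[-N]) - state
}

#' Goodwin steady state
#'
#' At equilibrium all stages are equal to Z, which solves
#' `Z (K^p + Z^p) = alpha1 K^p`; the left side is strictly increasing so
#' the root is unique.
#'
#' @param params a [goodwin_params()].
#' @return steady-state vector (all entries equal).
#' @export
goodwin_steady_state <- function(params) {
  f <- function(Z) Z * (params$K^params$p + Z^params$p) -
    params$alpha1 * params$K^params$p
  hi <- max(params$alpha1, params$K, 1)
  while (f(hi) < 0) hi <- hi * 2
  Z <- uniroot(f, c(0, hi), tol = 1e-13 * hi)$root
  rep(Z, params$N)
}

#' Leading eigenvalue of the Goodwin chain at steady state
#'
#' The Jacobian is the unit-rate chain plus the repression gain
#' `f'(Z) = -alpha1 p K^p Z^(p-1) / (K^p + Z^p)^2` in the corner.
#'
#' @param params a [goodwin_params()].
#' @return complex scalar with the largest real part.
#' @export
goodwin_leading_eigenvalue <- function(params) {
  N <- params$N
  Z <- goodwin_steady_state(params)[1]
  Kp <- params$K^params$p
  gain <- -params$alpha1 * params$p * Kp * Z^(params$p - 1) / (Kp + Z^params$p)^2
  Jm <- diag(-1, N)
  for (j in 2:N) Jm[j, j - 1] <- 1
  Jm[1, N] <- gain
  ev <- eigen(Jm, only.values = TRUE)$values
  ev[which.max(Re(ev))]
}

#' Does a Goodwin chain admit a Hopf bifurcation at this Hill exponent?
#'
#' Sweeps the transcription rate `alpha1` over a log grid and reports
#' whether the steady state is unstable anywhere (i.e. a Hopf crossing
#' exists along the sweep).
#'
#' @param p Hill exponent.
#' @param N chain length.
#' @param K repression threshold.
#' @param alpha1_range sweep limits.
#' @param n_sweep sweep resolution.
#' @return logical.
#' @export
goodwin_hopf_exists <- function(p, N = 3, K = 1,
                                alpha1_range = c(1e-2, 1e6), n_sweep = 121) {
  grid <- exp(seq(log(alpha1_range[1]), log(alpha1_range[2]),
                  length.out = n_sweep))
  for (a in grid) {
    lam <- goodwin_leading_eigenvalue(goodwin_params(a, K, p, N))
    if (Re(lam) > 0) return(TRUE)
  }
  FALSE
}

#' Minimal Hill exponent for Goodwin oscillations
#'
#' For equal degradation rates, a length-N Goodwin chain can oscillate
#' only if the Hill exponent exceeds the secant factor
#' `S_N = sec(pi/N)^N` -- the famous (and biologically implausible)
#' `p > 8` at N = 3.
#'
#' @param N chain length (integer >= 3).
#' @return the exponent bound.
#' @examples
#' min_hill_exponent(3)  # 8
#' @export
min_hill_exponent <- function(N) secant_factor(N)
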