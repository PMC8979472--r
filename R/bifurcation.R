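#' Secant factor of a delay chain
#'
#' `S_N = sec(pi/N)^N` is the minimal loop gain at which a chain of N
#' first-order stages with equal decay rates can undergo a Hopf
#' bifurcation.  It equals 8 at N = 3, decreases with N, and tends to 1:
#' longer chains oscillate at lower gain.
#'
#' @param N loop length (integer >= 3).
#' @return the secant factor.
#' @examples
#' secant_factor(3)  # 8
#' secant_factor(4)  # 4
#' @export
secant_factor <- function(N) {
  if (any(N != round(N)) || any(N < 3)) stop("N must be an integer >= 3")
  (1 / cos(pi / N))^N
}

#' Coefficients of the Hopf-locus quadratic
#'
#' For linear-degradation models the Hopf bifurcation locus in the
#' (alpha, A_T) plane is the solution set of
#' `Phi alpha^2 - Psi(A_T) alpha + Omega(A_T) = 0` with, for rate law 0,
#' `Phi = (S_N - 1)^2`, `Psi = S_N ((A_T+1)^2 - 4 S_N A_T)`,
#' `Omega = S_N^2 A_T (A_T+1)^2`; rate law 1 multiplies `Psi` by
#' `(A_T+K_A)/A_T` and `Omega` by `(A_T+K_A)^2/A_T^2`.  `K_A = 0`
#' recovers law 0; N = 3 with law 0 gives the classical
#' `Phi = 49`, `Psi = 8(A_T^2 - 30 A_T + 1)`, `Omega = 64 A_T (A_T+1)^2`.
#'
#' @param N loop length.
#' @param A_T total activator (vectorised).
#' @param K_A E-box dissociation constant (law1).
#' @param law "law0" or "law1".
#' @return list of vectors `Phi`, `Psi`, `Omega`.
#' @export
hopf_quadratic_coeffs <- function(N, A_T, K_A = 0, law = c("law0", "law1")) {
  law <- match.arg(law)
  if (any(A_T <= 0)) stop("A_T must be positive")
  if (law == "law1" && any(K_A < 0)) stop("K_A must be >= 0")
  if (law == "law0") K_A <- 0
  S <- secant_factor(N)
  f <- (A_T + K_A) / A_T
  list(Phi = rep((S - 1)^2, length(A_T)),
       Psi = S * f * ((A_T + 1)^2 - 4 * S * A_T),
       Omega = S^2 * f^2 * A_T * (A_T + 1)^2)
}

#' Roots of the Hopf quadratic
#'
#' Solves the quadratic of [hopf_quadratic_coeffs()] for alpha at each
#' `A_T`.  Where the discriminant is negative there is no Hopf bifurcation
#' at that `A_T` and both roots are returned as `NA`.  The smaller root is
#' computed as `2 Omega / (Psi + sqrt(disc))` to avoid cancellation.
#'
#' @inheritParams hopf_quadratic_coeffs
#' @return data.frame with columns `A_T`, `alpha_lower`, `alpha_upper`.
#' @export
hopf_roots <- function(N, A_T, K_A = 0, law = c("law0", "law1")) {
  law <- match.arg(law)
  cf <- hopf_quadratic_coeffs(N, A_T, K_A, law)
  disc <- cf$Psi^2 - 4 * cf$Phi * cf$Omega
  ok <- disc >= 0 & cf$Psi > 0
  sq <- sqrt(pmax(disc, 0))
  lower <- ifelse(ok, 2 * cf$Omega / (cf$Psi + sq), NA_real_)
  upper <- ifelse(ok, (cf$Psi + sq) / (2 * cf$Phi), NA_real_)
  data.frame(A_T = A_T, alpha_lower = lower, alpha_upper = upper)
}

#' Analytic Hopf bifurcation locus
#'
#' Tabulates the two branches of the Hopf locus over a grid of `A_T`
#' values for a linear-degradation model.  Oscillations occur for alpha
#' strictly between the branches.
#'
#' @param N loop length.
#' @param A_T_grid grid of total-activator values.
#' @param K_A E-box dissociation constant (law1 models).
#' @param law transcription rate law.
#' @return a `hopf_locus` data.frame (columns `A_T`, `alpha_lower`,
#'   `alpha_upper`) with attributes `N`, `K_A`, `law`.
#' @export
hopf_locus <- function(N, A_T_grid, K_A = 0, law = c("law0", "law1")) {
  law <- match.arg(law)
  out <- hopf_roots(N, A_T_grid, K_A, law)
  structure(out, N = N, K_A = K_A, law = law,
            class = c("hopf_locus", "data.frame"))
}

#' Steady state of a clock model
#'
#' For SNF models with linear degradation and rate law 0 the closed form
#' `P_ss = alpha (A_T - 1) / (2 (alpha + A_T)) *
#' (1 + sqrt(1 + 4 (alpha + A_T)/(A_T - 1)^2))` is used; all other
#' variants reduce to nested scalar root-finding: the production/removal
#' balance `alpha F(A_free(P)) = G(P)` is monotone in P, and for NNF/PNF
#' the Bmal1-arm equilibrium `A_T(P)` is resolved by an inner root-find.
#'
#' @param spec a [clock_model()].
#' @param params a [clock_params()].
#' @param tol relative root-finding tolerance.
#' @return named steady-state vector (same layout as [initial_state()]).
#'   If several equilibria are detected (possible with the PNF positive
#'   feedback) a warning is issued and the one with the largest P is
#'   returned.
#' @export
steady_state <- function(spec, params, tol = 1e-12) {
  alpha <- params$alpha
  nm <- species_names(spec)

  if (spec$family == "SNF") {
    gbal <- function(P) {
      Af <- afree(params$A_T, P)
      FF <- Af / (if (spec$law == "law0") params$A_T else
                    params$K_A + params$A_T)
      G <- if (spec$degradation == "linear") P else
        params$beta_max * P / (params$K_m + P)
      alpha * FF - G
    }
    if (spec$degradation == "linear" && spec$law == "law0" &&
        params$A_T != 1) {
      A_T <- params$A_T
      Pss <- alpha * (A_T - 1) / (2 * (alpha + A_T)) *
        (1 + sqrt(1 + 4 * (alpha + A_T) / (A_T - 1)^2))
    } else {
      hi <- 1
      while (gbal(hi) > 0) {
        hi <- hi * 4
        if (hi > 1e18) stop("steady_state: no finite balance point found")
      }
      Pss <- uniroot(gbal, c(0, hi), tol = tol * max(1, hi))$root
    }
    Af <- afree(params$A_T, Pss)
    FF <- Af / (if (spec$law == "law0") params$A_T else
                  params$K_A + params$A_T)
    flux <- alpha * FF
    y <- setNames(c(flux, rep(flux, spec$J), Pss), nm)
    res <- max(abs(clock_rhs(y, params, spec)))
    if (res > 1e-6 * max(1, flux))
      stop("steady_state did not converge (residual ", signif(res, 3), ")")
    return(y)
  }

  # NNF/PNF: the activator arm feeds back on itself, so the algebraic
  # system can be multi-branched; solve by damped Newton from many starts
  newton <- function(y0) {
    y <- y0
    r <- clock_rhs(y, params, spec)
    for (it in seq_len(100)) {
      nr <- max(abs(r))
      if (nr < 1e-11 * max(1, max(abs(y)))) return(y)
      Jm <- clock_jacobian(spec, params, y)
      step <- tryCatch(solve(Jm, r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        y2 <- pmax(y - lam * step, 1e-300)
        r2 <- clock_rhs(y2, params, spec)
        if (max(abs(r2)) < nr || lam < 1e-8) break
        lam <- lam / 2
      }
      if (max(abs(r2)) >= nr) return(NULL)
      y <- y2
      r <- r2
    }
    NULL
  }

  AMAX <- params$A_T
  roots <- list()
  for (Pg in 10^seq(-3, 3, length.out = 9)) {
    for (ATfrac in c(0.9, 0.1, 0.001)) {
      ATg <- AMAX * ATfrac
      Af <- afree(ATg, Pg)
      FF <- Af / (params$K_A + ATg)
      flux <- alpha * FF
      y0 <- setNames(c(rep(flux, spec$J + 1), Pg, ATg,
                       (params$V_MAX %||% params$R_MAX) * FF), nm)
      y <- newton(y0)
      if (!is.null(y) &&
          !any(vapply(roots, function(r) max(abs(r - y)) <
                        1e-6 * max(1, max(abs(y))), logical(1))))
        roots[[length(roots) + 1]] <- y
    }
  }
  if (!length(roots))
    stop("steady_state did not converge for the ", spec$family, " model")
  if (length(roots) > 1)
    warning("multiple equilibria detected (", length(roots),
            "); returning the one with largest P")
  roots[[which.max(vapply(roots, function(r) r[[spec$J + 2]], numeric(1)))]]
}

# partial derivatives of the free-activator root and the transcription input
afree_partials <- function(A_T, P) {
  b <- A_T - P - 1
  s <- sqrt(b * b + 4 * A_T)
  Af <- afree(A_T, P)
  list(Af = Af, dP = -Af / s, dAT = (Af + 1) / s)
}

#' Jacobian of the model equations at a state
#'
#' Assembled analytically from the structure of the right-hand side: the
#' bidiagonal chain, the sequestration partials of A_free, the degradation
#' slope, and (for NNF/PNF) the Bmal1-arm rows.
#'
#' @param spec a [clock_model()].
#' @param params a [clock_params()].
#' @param state state at which to linearise (typically a steady state).
#' @return square numeric matrix.
#' @export
clock_jacobian <- function(spec, params, state) {
  J <- spec$J
  n <- length(species_names(spec))
  P <- state[[J + 2]]
  A_T <- if (spec$family == "SNF") params$A_T else state[[J + 3]]
  ap <- afree_partials(A_T, P)
  D <- if (spec$law == "law0") A_T else params$K_A + A_T
  FF <- ap$Af / D
  dF_dP <- ap$dP / D
  dF_dAT <- ap$dAT / D - ap$Af / D^2

  M <- matrix(0, n, n)
  M[1, 1] <- -1
  M[1, J + 2] <- params$alpha * dF_dP
  for (j in seq_len(J)) {
    M[1 + j, j] <- 1
    M[1 + j, 1 + j] <- -1
  }
  Gp <- if (spec$degradation == "linear") 1 else
    params$beta_max * params$K_m / (params$K_m + P)^2
  M[J + 2, J + 1] <- 1
  M[J + 2, J + 2] <- -Gp

  if (spec$family != "SNF") {
    del <- params$delta
    M[1, J + 3] <- params$alpha * dF_dAT
    aux <- state[[J + 4]]                 # V or R
    if (spec$family == "NNF") {
      M[J + 3, J + 3] <- -del
      M[J + 3, J + 4] <- -del * params$A_T / (aux + 1)^2
      M[J + 4, J + 2] <- del * params$V_MAX * dF_dP
      M[J + 4, J + 3] <- del * params$V_MAX * dF_dAT
      M[J + 4, J + 4] <- -del
    } else {
      M[J + 3, J + 3] <- -del
      M[J + 3, J + 4] <- del * params$A_T * (1 - params$epsilon) / (aux + 1)^2
      M[J + 4, J + 2] <- del * params$R_MAX * dF_dP
      M[J + 4, J + 3] <- del * params$R_MAX * dF_dAT
      M[J + 4, J + 4] <- -del
    }
  }
  M
}

#' Leading eigenvalue at the steady state
#'
#' Eigenvalue of the analytic Jacobian with the largest real part.  A Hopf
#' bifurcation occurs where its real part crosses zero with nonzero
#' imaginary part.
#'
#' @inheritParams clock_jacobian
#' @param state optional precomputed steady state.
#' @return a complex scalar.
#' @export
leading_eigenvalue <- function(spec, params, state = NULL) {
  if (is.null(state)) state <- steady_state(spec, params)
  ev <- eigen(clock_jacobian(spec, params, state), only.values = TRUE)$values
  ev[which.max(Re(ev))]
}

#' Classify a parameter point as oscillatory or not
#'
#' Linear-degradation SNF models are classified by the sign of the leading
#' Jacobian eigenvalue (fast and exact); Michaelian and NNF/PNF models by
#' simulation with the relative-amplitude rule, matching how their
#' oscillatory domains must be found numerically.
#'
#' @inheritParams clock_jacobian
#' @param method "auto" (rule above), "eigen", or "simulate".
#' @param ... passed to [simulate_clock()] when simulating.
#' @return list with `oscillatory` (logical) and `period` (dimensionless,
#'   `NA` under the eigenvalue test or when not oscillatory).
#' @export
classify_point <- function(spec, params, method = c("auto", "eigen",
                                                    "simulate"), ...) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (spec$family == "SNF" && spec$degradation == "linear")
      "eigen" else "simulate"
  if (method == "eigen") {
    lam <- leading_eigenvalue(spec, params)
    list(oscillatory = Re(lam) > 0 && abs(Im(lam)) > 0,
         period = NA_real_, method = "eigen")
  } else {
    s <- simulate_clock(spec, params, ...)$summary
    list(oscillatory = isTRUE(s$oscillatory), period = s$period,
         method = "simulate")
  }
}

#' Locate a Hopf crossing numerically (eigenvalue oracle)
#'
#' Bisects on alpha for the zero of the real part of the leading
#' eigenvalue inside a bracket.  Used to cross-check the analytic locus.
#'
#' @param spec a [clock_model()] (linear degradation).
#' @param params_at function of alpha returning a [clock_params()].
#' @param bracket alpha interval containing exactly one crossing.
#' @param tol relative tolerance on alpha.
#' @return the crossing alpha.
#' @export
hopf_crossing_alpha <- function(spec, params_at, bracket, tol = 1e-6) {
  f <- function(a) Re(leading_eigenvalue(spec, params_at(a)))
  uniroot(f, bracket, tol = tol * mean(bracket))$root
}

#' Two-parameter oscillatory-domain scan
#'
#' Classifies every point of an (x, y) parameter grid and records the
#' dimensionless period where oscillatory.  Optionally refines the
#' domain boundary along each grid row by bisection.
#'
#' @param spec a [clock_model()].
#' @param base_params a [clock_params()]; the scanned entries are
#'   overwritten point by point.
#' @param x_name,y_name names of the scanned parameters (e.g. "alpha",
#'   "A_T").
#' @param x_grid,y_grid positive grids.
#' @param method classification method, see [classify_point()].
#' @param refine_boundary logical; bisect mask transitions along x.
#' @param refine_iter bisection depth per edge crossing (default 12, about
#'   1% of the cell width).
#' @param ... passed to [classify_point()] (solver settings).
#' @return a `domain_scan` list: `x_name`, `y_name`, `x_grid`, `y_grid`,
#'   `mask` (logical matrix, rows = x), `period` (matrix, `NA` where not
#'   oscillatory), `boundaries` (data.frame when refined).
#' @export
domain_scan <- function(spec, base_params, x_name, y_name, x_grid, y_grid,
                        method = "auto", refine_boundary = FALSE,
                        refine_iter = 12, ...) {
  stopifnot(all(x_grid > 0), all(y_grid > 0))
  point <- function(x, y) {
    p <- base_params
    p[[x_name]] <- x
    p[[y_name]] <- y
    classify_point(spec, p, method = method, ...)
  }
  nx <- length(x_grid); ny <- length(y_grid)
  mask <- matrix(FALSE, nx, ny)
  period <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    r <- point(x_grid[i], y_grid[j])
    mask[i, j] <- r$oscillatory
    if (r$oscillatory) period[i, j] <- r$period
  }
  boundaries <- NULL
  if (refine_boundary && nx > 1) {
    rows <- list()
    for (j in seq_len(ny)) for (i in seq_len(nx - 1)) {
      if (mask[i, j] != mask[i + 1, j]) {
        lo <- x_grid[i]; hi <- x_grid[i + 1]
        lo_osc <- mask[i, j]
        for (k in seq_len(refine_iter)) {
          mid <- (lo + hi) / 2
          if (point(mid, y_grid[j])$oscillatory == lo_osc) lo <- mid else hi <- mid
        }
        rows[[length(rows) + 1]] <-
          data.frame(x = (lo + hi) / 2, y = y_grid[j])
      }
    }
    if (length(rows)) boundaries <- do.call(rbind, rows)
  }
  structure(list(spec = spec, base_params = base_params,
                 x_name = x_name, y_name = y_name,
                 x_grid = x_grid, y_grid = y_grid,
                 mask = mask, period = period, boundaries = boundaries),
            class = "domain_scan")
}

#' @export
print.domain_scan <- function(x, ...) {
  cat(sprintf("<domain_scan> %s x %s, %d x %d grid, %d oscillatory point(s)\n",
              x$x_name, x$y_name, length(x$x_grid), length(x$y_grid),
              sum(x$mask)))
  invisible(x)
}

#' Five-point robustness criterion
#'
#' A wild-type operating point passes when it and the four points obtained
#' by separately halving and doubling alpha and A_T (or A_MAX) all
#' oscillate -- reflecting rhythmic heterozygote and overexpression
#' phenotypes.
#'
#' @inheritParams classify_point
#' @return list with `pass` (logical) and `verdicts` (named logical vector
#'   over WT, half_alpha, double_alpha, half_AT, double_AT).
#' @export
five_point <- function(spec, params, method = "auto", ...) {
  pts <- list(
    WT = c(1, 1), half_alpha = c(0.5, 1), double_alpha = c(2, 1),
    half_AT = c(1, 0.5), double_AT = c(1, 2))
  verdicts <- vapply(pts, function(fk) {
    p <- params
    p$alpha <- params$alpha * fk[1]
    p$A_T <- params$A_T * fk[2]
    classify_point(spec, p, method = method, ...)$oscillatory
  }, logical(1))
  list(pass = all(verdicts), verdicts = verdicts)
}

#' Area of the circadian-oscillation domain
#'
#' Integrates the indicator of "period in hours inside `window_hours`"
#' over the scanned rectangle, with both axes measured as fold changes of
#' the wild-type point, by the trapezoidal rule on the grid nodes.
#' Dimensionless periods convert to hours as `tau / beta_hat`.
#'
#' @param scan a [domain_scan()] carrying periods.
#' @param beta_hat timescale in 1/h.
#' @param WT wild-type values `c(x, y)` used to normalise the axes.
#' @param window_hours circadian window (default 22 to 26 h).
#' @return area in WT-fold-change units squared.
#' @export
circadian_area <- function(scan, beta_hat, WT,
                           window_hours = c(22, 26)) {
  stopifnot(inherits(scan, "domain_scan"), beta_hat > 0)
  hours <- scan$period / beta_hat
  ind <- !is.na(hours) & hours >= window_hours[1] & hours <= window_hours[2]
  u <- scan$x_grid / WT[1]
  v <- scan$y_grid / WT[2]
  # trapezoidal weights along each axis
  wts <- function(g) {
    n <- length(g)
    w <- numeric(n)
    w[1] <- (g[2] - g[1]) / 2
    w[n] <- (g[n] - g[n - 1]) / 2
    if (n > 2) w[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / 2
    w
  }
  sum(outer(wts(u), wts(v)) * ind)
}

#' Period sensitivity to a single parameter
#'
#' Sweeps one parameter across a fold-change range of its wild-type value,
#' records the period wherever the model oscillates, and reports the
#' relative spread `Delta = (Tmax - Tmin) / ((Tmax + Tmin)/2)` together
#' with `DeltaT = Delta * 24 h` (the spread mapped onto a 24-h clock).
#'
#' @inheritParams classify_point
#' @param which_param parameter swept ("A_T" or "alpha").
#' @param fold_range fold-change limits relative to WT (default 1/4 to 4).
#' @param n_points sweep resolution.
#' @return list with `folds`, `periods`, `Delta`, `DeltaT_hours`.
#' @export
period_sensitivity <- function(spec, params, which_param = c("A_T", "alpha"),
                               fold_range = c(0.25, 4), n_points = 13, ...) {
  which_param <- match.arg(which_param)
  folds <- exp(seq(log(fold_range[1]), log(fold_range[2]),
                   length.out = n_points))
  periods <- vapply(folds, function(f) {
    p <- params
    p[[which_param]] <- params[[which_param]] * f
    r <- classify_point(spec, p, method = "simulate", ...)
    if (r$oscillatory) r$period else NA_real_
  }, numeric(1))
  ok <- periods[!is.na(periods)]
  if (!length(ok)) stop("no oscillatory point in the sweep")
  Delta <- if (length(ok) == 1) 0 else
    (max(ok) - min(ok)) / ((max(ok) + min(ok)) / 2)
  list(folds = folds, periods = periods, Delta = Delta,
       DeltaT_hours = Delta * 24)
}
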