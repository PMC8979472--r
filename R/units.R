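#' Unit system for converting dimensionless results to physical units
#'
#' Holds the handful of physical constants every unit conversion flows
#' through: the cell-biological PER budget (default 30,000 molecules per
#' cell), the nuclear volume (default 500 fL), and the Avogadro-derived
#' conversion 0.602 molecules per (nM * fL).  At the defaults the
#' molecule budget corresponds to a concentration scale of
#' `30000 / (500 * 0.602) = 99.7 nM` (quoted as "100 nM" to the precision
#' these estimates carry).
#'
#' @param nucleus_volume nuclear volume in fL.
#' @param per_molecule_budget maximal PER molecules per cell.
#' @param molecules_per_nM_fL molecules per nM per fL.
#' @return a `unit_system` list.
#' @export
unit_system <- function(nucleus_volume = 500, per_molecule_budget = 3e4,
                        molecules_per_nM_fL = 0.602) {
  stopifnot(nucleus_volume > 0, per_molecule_budget > 0,
            molecules_per_nM_fL > 0)
  structure(list(nucleus_volume = nucleus_volume,
                 per_molecule_budget = per_molecule_budget,
                 molecules_per_nM_fL = molecules_per_nM_fL),
            class = "unit_system")
}

#' Estimate the PER:BMAL1 dissociation constant from oscillation amplitude
#'
#' Because concentrations are scaled by the dissociation constant, the
#' dimensionless peak of total PER fixes the physical K_d: the peak
#' corresponds to the whole PER budget, so
#' `K_d = (budget / (volume * 0.602)) / max_P_tot`, i.e. about
#' `100 nM / max_P_tot` at the defaults.  Larger oscillation amplitudes
#' therefore force tighter (smaller) binding constants.
#'
#' @param max_P_tot dimensionless peak of total PER (> 0); vectorised.
#' @param units a [unit_system()].
#' @return K_d in nM.
#' @examples
#' kd_estimate(2500)  # ~0.04 nM
#' kd_estimate(50)    # ~2 nM
#' @export
kd_estimate <- function(max_P_tot, units = unit_system()) {
  if (any(!is.finite(max_P_tot)) || any(max_P_tot <= 0))
    stop("max_P_tot must be positive")
  budget_nM <- units$per_molecule_budget /
    (units$nucleus_volume * units$molecules_per_nM_fL)
  budget_nM / max_P_tot
}

#' Molecule count for a concentration in a compartment
#'
#' @param conc_nM concentration in nM.
#' @param volume_fL compartment volume in fL.
#' @param units a [unit_system()].
#' @return molecule count (rounded).
#' @examples
#' molecules(30, 500)   # ~9000
#' @export
molecules <- function(conc_nM, volume_fL = 500, units = unit_system()) {
  if (any(conc_nM < 0) || any(volume_fL < 0)) stop("inputs must be >= 0")
  round(conc_nM * volume_fL * units$molecules_per_nM_fL)
}

#' Convert a dimensionless period to hours
#'
#' @param tau dimensionless period.
#' @param beta_hat timescale in 1/h.
#' @return period in hours, `tau / beta_hat`.
#' @examples
#' period_hours(3.8, 0.16)   # ~24 h
#' @export
period_hours <- function(tau, beta_hat) {
  if (any(beta_hat <= 0)) stop("beta_hat must be positive")
  tau / beta_hat
}

#' Timescale that maps a dimensionless period onto a target clock period
#'
#' Inverse of [period_hours()]: `beta_hat = tau / target_hours`.
#'
#' @param tau dimensionless period.
#' @param target_hours desired period in hours (default 24).
#' @return beta_hat in 1/h.
#' @export
calibrate_beta <- function(tau, target_hours = 24) {
  if (any(tau <= 0) || any(target_hours <= 0))
    stop("tau and target_hours must be positive")
  tau / target_hours
}

#' Full calibration report for a model operating point
#'
#' Simulates the model, then converts the dimensionless oscillation into
#' physical units: K_d from the total-PER peak (and the protein-only
#' variant that discounts mRNA-like chain species), the activator
#' concentration and molecule count, the timescale, and the period in
#' hours.
#'
#' @param spec a [clock_model()].
#' @param params a [clock_params()].
#' @param beta_hat timescale in 1/h; if `NULL`, calibrated so the period is
#'   `target_hours`.
#' @param target_hours target period used when calibrating `beta_hat`.
#' @param units a [unit_system()].
#' @param ... passed to [simulate_clock()].
#' @return list: `period`, `period_h`, `beta_hat`, `Kd_nM_total`,
#'   `Kd_nM_protein`, `AT_nM`, `BMAL1_molecules`, `max_P_tot`,
#'   `max_P_protein`.
#' @export
calibration_report <- function(spec, params, beta_hat = NULL,
                               target_hours = 24, units = unit_system(),
                               ...) {
  s <- simulate_clock(spec, params, ...)$summary
  if (!s$oscillatory)
    stop("calibration requires an oscillatory operating point")
  if (is.null(beta_hat)) beta_hat <- calibrate_beta(s$period, target_hours)
  kd_prot <- kd_estimate(s$max_P_protein, units)
  # representative activator level: static A_T for SNF, cycle average else
  at_dimless <- if (spec$family == "SNF") params$A_T else s$avg_A_T
  at_nM <- at_dimless * kd_prot
  list(period = s$period,
       period_h = period_hours(s$period, beta_hat),
       beta_hat = beta_hat,
       Kd_nM_total = kd_estimate(s$max_P_tot, units),
       Kd_nM_protein = kd_prot,
       AT_nM = at_nM,
       BMAL1_molecules = molecules(at_nM, units$nucleus_volume, units),
       max_P_tot = s$max_P_tot,
       max_P_protein = s$max_P_protein)
}
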