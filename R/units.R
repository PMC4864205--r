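#' Physical/lattice unit system
#'
#' Links the dimensionless lattice system to SI through the discrete space
#' interval \eqn{\delta x} (m per node spacing) and time step \eqn{\delta t}
#' (s per step). Conversions follow
#' \eqn{u_{LB} = u \,\delta t/\delta x},
#' \eqn{\nu_{LB} = \nu \,\delta t/\delta x^2}, and the relaxation time is
#' \eqn{\tau = 3 \nu_{LB} + 1/2}. Lattice density 1 corresponds to the
#' physical fluid density `rho_phys`, so gauge pressure converts with the
#' factor \eqn{\rho_{phys} (\delta x/\delta t)^2}.
#'
#' @param dx physical grid spacing (m).
#' @param dt physical time step (s).
#' @param rho_phys physical fluid density (kg/m^3); arterial blood is
#'   1060 kg/m^3.
#' @param nu_phys physical kinematic viscosity (m^2/s); blood plasma-scale
#'   value 3.7037e-6 m^2/s.
#' @param L_ref optional reference length (m), informational.
#' @param N optional resolution (cells per reference length), informational.
#' @return object of class `unit_system`.
#' @examples
#' sys <- unit_system(dx = 0.000156563, dt = 0.00005,
#'                    rho_phys = 1060, nu_phys = 3.7037e-6)
#' to_lattice(0.1, "velocity", sys)    # 0.0319361
#' lattice_tau(sys)                    # 0.52266
#' @export
unit_system <- function(dx, dt, rho_phys = 1060, nu_phys = 3.7037e-6,
                        L_ref = NULL, N = NULL) {
  if (!is.finite(dx) || dx <= 0) lbm_invalid_state("dx must be positive")
  if (!is.finite(dt) || dt <= 0) lbm_invalid_state("dt must be positive")
  if (rho_phys <= 0 || nu_phys <= 0)
    lbm_invalid_state("physical density and viscosity must be positive")
  sys <- structure(list(dx = dx, dt = dt, rho_phys = rho_phys,
                        nu_phys = nu_phys, L_ref = L_ref, N = N),
                   class = "unit_system")
  if (lattice_tau(sys) <= 0.5)
    lbm_invalid_state("derived tau must exceed 0.5")  # unreachable for nu>0
  sys
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf(paste0("unit_system: dx = %g m, dt = %g s, rho = %g kg/m^3, ",
                     "nu = %g m^2/s\n  nu_LB = %g, tau = %g\n"),
              x$dx, x$dt, x$rho_phys, x$nu_phys,
              to_lattice(x$nu_phys, "viscosity", x), lattice_tau(x)))
  invisible(x)
}

.unit_factor <- function(kind, sys) {
  switch(kind,
         velocity  = sys$dt / sys$dx,
         viscosity = sys$dt / sys$dx^2,
         time      = 1 / sys$dt,
         length    = 1 / sys$dx,
         pressure  = 1 / (sys$rho_phys * (sys$dx / sys$dt)^2),
         stop(sprintf("unknown quantity kind '%s'", kind)))
}

#' Convert a physical quantity to lattice units
#'
#' @param q physical value(s): velocity (m/s), kinematic viscosity (m^2/s),
#'   time (s), length (m) or gauge pressure (Pa).
#' @param kind one of `"velocity"`, `"viscosity"`, `"time"`, `"length"`,
#'   `"pressure"`.
#' @param sys a [unit_system()].
#' @return the value in lattice units (for pressure: \eqn{c_s^2 \delta\rho}).
#' @export
to_lattice <- function(q, kind = c("velocity", "viscosity", "time", "length",
                                   "pressure"), sys) {
  kind <- match.arg(kind)
  q * .unit_factor(kind, sys)
}

#' Convert a lattice quantity to physical units
#'
#' Exact inverse of [to_lattice()]. For pressure the input is the lattice
#' gauge pressure \eqn{c_s^2(\rho - \rho_{ref})}; the result is
#' \eqn{c_s^2(\rho - \rho_{ref})\, \rho_{phys} (\delta x/\delta t)^2} in Pa.
#'
#' @inheritParams to_lattice
#' @export
to_physical <- function(q, kind = c("velocity", "viscosity", "time", "length",
                                    "pressure"), sys) {
  kind <- match.arg(kind)
  q / .unit_factor(kind, sys)
}

#' Relaxation time implied by a unit system
#'
#' \eqn{\tau = 3\,\nu_{LB} + 1/2}.
#'
#' @param sys a [unit_system()].
#' @export
lattice_tau <- function(sys) {
  3 * to_lattice(sys$nu_phys, "viscosity", sys) + 0.5
}

#' Reynolds number
#'
#' \eqn{Re = u L / \nu}; dimensionless, so valid in either unit system as
#' long as all three arguments share the system. The physical and lattice
#' values agree under consistent conversion (the first principle of the
#' lattice scaling).
#'
#' @param u characteristic speed.
#' @param L characteristic length (e.g. inlet diameter).
#' @param nu kinematic viscosity (> 0).
#' @export
reynolds_number <- function(u, L, nu) {
  if (any(nu <= 0)) lbm_invalid_state("viscosity must be positive")
  u * L / nu
}
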