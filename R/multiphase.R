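#' Shan-Chen pseudopotential parameters
#'
#' Single-component multiphase interaction. The non-ideal equation of state
#' enters through the effective mass
#' \eqn{\psi(\rho) = \rho_0 [1 - \exp(-\rho/\rho_0)]}, and the interaction
#' amplitude `G` sets the "temperature": with the lattice-weighted
#' nearest-neighbour force the bulk pressure is
#' \eqn{p = c_s^2 \rho + \tfrac{1}{2} c_s^2 G \psi^2}, which loses
#' monotonicity (phase coexistence appears) for \eqn{G < -4} at
#' \eqn{\rho_0 = 1}. Negative `G` is the cohesive (separating) sign under
#' this convention.
#'
#' @param G interaction amplitude.
#' @param rho0 EOS reference density (> 0).
#' @param weighted use the D3Q19 lattice weights in the neighbour sum
#'   (isotropic, default) instead of the uniform "corral" sum.
#' @param psi_wall effective mass assigned to solid neighbours (wetting
#'   control; 0 = neutral dry wall).
#' @return object of class `shan_chen_params`.
#' @export
shan_chen_params <- function(G, rho0 = 1, weighted = TRUE, psi_wall = 0) {
  if (rho0 <= 0) lbm_invalid_state("rho0 must be positive")
  structure(list(G = G, rho0 = rho0, weighted = weighted,
                 psi_wall = psi_wall),
            class = "shan_chen_params")
}

#' Shan-Chen effective mass
#'
#' \eqn{\psi(\rho) = \rho_0[1 - \exp(-\rho/\rho_0)]}: monotone increasing,
#' \eqn{\psi(0) = 0}, bounded above by \eqn{\rho_0}.
#'
#' @param rho densities (>= 0).
#' @param params a [shan_chen_params()].
#' @export
effective_mass_psi <- function(rho, params) {
  if (any(rho < 0)) lbm_invalid_state("density must be non-negative")
  params$rho0 * (1 - exp(-rho / params$rho0))
}

#' Shan-Chen interaction force field
#'
#' Nearest-neighbour pseudopotential force
#' \deqn{F(x) = -G\,\psi(x) \sum_i w_i\, \psi(x + e_i)\, e_i}
#' over the 18 moving directions, with periodic wrap on periodic axes and
#' `psi_wall` substituted at solid neighbours. A uniform density field gives
#' exactly zero force, and the sum of the force over a fully periodic
#' domain vanishes to round-off (global momentum conservation).
#'
#' @param rho_field density array (Nx, Ny, Nz) or an `lbm_state`'s density.
#' @param params a [shan_chen_params()].
#' @param flags optional flag array; solid nodes contribute `psi_wall`.
#' @param lattice a [lattice_d3q19()] object.
#' @return (Nx, Ny, Nz, 3) array of force density.
#' @export
interaction_force <- function(rho_field, params, flags = NULL,
                              lattice = lattice_d3q19()) {
  n <- dim(rho_field)
  psi <- effective_mass_psi(rho_field, params)
  if (!is.null(flags)) psi[flags == FLAG_SOLID] <- params$psi_wall
  acc <- array(0, dim = c(n, 3))
  for (i in 2:19) {
    e <- lattice$e[i, ]
    ix <- ((seq_len(n[1]) - 1 + e[1]) %% n[1]) + 1
    iy <- ((seq_len(n[2]) - 1 + e[2]) %% n[2]) + 1
    iz <- ((seq_len(n[3]) - 1 + e[3]) %% n[3]) + 1
    pn <- psi[ix, iy, iz]
    wt <- if (params$weighted) lattice$w[i] else 1
    for (a in 1:3) if (e[a] != 0)
      acc[, , , a] <- acc[, , , a] + wt * e[a] * pn
  }
  F <- array(0, dim = c(n, 3))
  for (a in 1:3) F[, , , a] <- -params$G * psi * acc[, , , a]
  if (!is.null(flags)) {
    sol <- flags == FLAG_SOLID
    for (a in 1:3) {
      Fa <- F[, , , a]; Fa[sol] <- 0; F[, , , a] <- Fa
    }
  }
  F
}

#' Velocity-shift forcing
#'
#' Implements the classic Shan-Chen coupling: the equilibrium distribution
#' inside the collision is evaluated at \eqn{u^{(eq)} = u + \tau F / \rho},
#' and the physically reported momentum (the average of the pre- and
#' post-collision values) is \eqn{\rho u + F/2}.
#'
#' @param f populations at one node (19-vector) or n x 19 matrix.
#' @param F force density, 3-vector or n x 3 matrix.
#' @param params a [collision_params()].
#' @param lattice a [lattice_d3q19()] object.
#' @return list with `u_eq` (velocity to use in the equilibrium), `momentum`
#'   (reported momentum \eqn{\rho u + F/2}) and `rho`.
#' @export
apply_force_shift <- function(f, F, params, lattice = lattice_d3q19()) {
  fm <- .as_f_matrix(f)
  mom <- macroscopic_moments(fm, lattice = lattice)
  Fm <- if (is.null(dim(F))) matrix(F, nrow(fm), 3, byrow = TRUE) else F
  u_eq <- mom$u + params$tau * Fm / mom$rho
  momentum <- mom$rho * mom$u + Fm / 2
  list(u_eq = u_eq, momentum = momentum, rho = mom$rho)
}
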