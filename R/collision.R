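#' Collision parameters
#'
#' Bundles the relaxation settings shared by all four collision operators.
#' The kinematic viscosity implied by the relaxation time is
#' \eqn{\nu_{LB} = c_s^2 (\tau - 1/2)}, so stability requires \eqn{\tau > 1/2}.
#'
#' @param tau relaxation time in lattice units (> 0.5).
#' @param rho0 reference density for the incompressible model.
#' @param mrt_rates optional vector of 19 per-moment relaxation rates for the
#'   MRT operator; defaults to [mrt_default_rates()] at this `tau`.
#' @return object of class `collision_params`.
#' @export
collision_params <- function(tau, rho0 = 1, mrt_rates = NULL) {
  if (!is.finite(tau) || tau <= 0.5)
    lbm_invalid_state("tau must exceed 0.5 (positive viscosity)")
  if (rho0 <= 0) lbm_invalid_state("rho0 must be positive")
  if (is.null(mrt_rates)) mrt_rates <- mrt_default_rates(tau)
  if (length(mrt_rates) != 19L) stop("mrt_rates must have length 19")
  structure(list(tau = tau, omega = 1 / tau, rho0 = rho0,
                 mrt_rates = mrt_rates),
            class = "collision_params")
}

#' @export
print.collision_params <- function(x, ...) {
  cat(sprintf("collision_params: tau = %g (nu_LB = %g), rho0 = %g\n",
              x$tau, (x$tau - 0.5) / 3, x$rho0))
  invisible(x)
}

#' Orthogonal moment basis for D3Q19 MRT collision
#'
#' The standard d'Humieres moment set: density, kinetic energy and its
#' square, momentum and energy fluxes, the five second-order (shear) moments
#' with their fourth-order partners, and three third-order "ghost" moments.
#' Rows are mutually orthogonal under the uniform inner product, so the
#' inverse is the scaled transpose.
#'
#' @param lattice a [lattice_d3q19()] object.
#' @return list with the 19 x 19 transformation matrix `M`, its inverse
#'   `Minv`, and `shear_idx`, the (1-based) rows whose relaxation rate sets
#'   the shear viscosity.
#' @export
mrt_matrix <- function(lattice = lattice_d3q19()) {
  e <- lattice$e
  ex <- e[, 1]; ey <- e[, 2]; ez <- e[, 3]
  e2 <- ex^2 + ey^2 + ez^2
  M <- rbind(
    rep(1, 19),                       #  1 density
    19 * e2 - 30,                     #  2 kinetic energy
    (21 * e2^2 - 53 * e2 + 24) / 2,   #  3 energy squared
    ex,                               #  4 momentum x
    (5 * e2 - 9) * ex,                #  5 energy flux x
    ey,                               #  6 momentum y
    (5 * e2 - 9) * ey,                #  7 energy flux y
    ez,                               #  8 momentum z
    (5 * e2 - 9) * ez,                #  9 energy flux z
    3 * ex^2 - e2,                    # 10 p_xx (shear)
    (3 * e2 - 5) * (3 * ex^2 - e2),   # 11 pi_xx
    ey^2 - ez^2,                      # 12 p_ww (shear)
    (3 * e2 - 5) * (ey^2 - ez^2),     # 13 pi_ww
    ex * ey,                          # 14 p_xy (shear)
    ey * ez,                          # 15 p_yz (shear)
    ex * ez,                          # 16 p_xz (shear)
    (ey^2 - ez^2) * ex,               # 17 ghost m_x
    (ez^2 - ex^2) * ey,               # 18 ghost m_y
    (ex^2 - ey^2) * ez                # 19 ghost m_z
  )
  Minv <- t(M / rowSums(M^2))
  list(M = M, Minv = Minv, shear_idx = c(10L, 12L, 14L, 15L, 16L),
       conserved_idx = c(1L, 4L, 6L, 8L))
}

#' Default MRT relaxation rates
#'
#' The five shear moments relax at \eqn{1/\tau} so the kinematic viscosity
#' matches the single-relaxation-time operators; all remaining non-conserved
#' ("ghost" and energy) moments relax at 1. Rates attached to the conserved
#' moments (density, momentum) have no effect and are set to 0.
#'
#' @param tau relaxation time.
#' @return numeric vector of 19 rates.
#' @export
mrt_default_rates <- function(tau) {
  basis <- mrt_matrix()
  s <- rep(1, 19)
  s[basis$shear_idx] <- 1 / tau
  s[basis$conserved_idx] <- 0
  s
}

.collide_prep <- function(f, params, model, lattice) {
  fm <- .as_f_matrix(f)
  mom <- macroscopic_moments(fm, model = model, rho0 = params$rho0,
                             lattice = lattice)
  list(fm = fm, rho = mom$rho, u = mom$u)
}

.collide_return <- function(out, f) {
  if (is.null(dim(f))) drop(out) else {
    dim(out) <- dim(f)
    out
  }
}

#' BGK single-relaxation-time collision
#'
#' \eqn{f' = f + \frac{1}{\tau}(f^{eq} - f)} with the equilibrium evaluated
#' at the node's own moments. Density and momentum are conserved to
#' round-off; at \eqn{\tau = 1} the output is exactly the equilibrium.
#'
#' @param f populations: 19-vector or n x 19 matrix (one row per node).
#' @param params a [collision_params()] object.
#' @param lattice a [lattice_d3q19()] object.
#' @return post-collision populations, same shape as `f`.
#' @export
collide_bgk <- function(f, params, lattice = lattice_d3q19()) {
  p <- .collide_prep(f, params, "bgk", lattice)
  feq <- equilibrium_bgk(p$rho, p$u, lattice)
  if (is.null(dim(feq))) feq <- matrix(feq, nrow = 1)
  .collide_return(p$fm - params$omega * (p$fm - feq), f)
}

#' Incompressible BGK collision
#'
#' BGK relaxation toward [equilibrium_incompressible()], with the velocity
#' computed as momentum divided by the constant reference density `rho0`.
#' Coincides with [collide_bgk()] wherever \eqn{\rho = \rho_0}.
#'
#' @inheritParams collide_bgk
#' @export
collide_incompressible <- function(f, params, lattice = lattice_d3q19()) {
  p <- .collide_prep(f, params, "incompressible", lattice)
  feq <- equilibrium_incompressible(p$rho, params$rho0, p$u, lattice)
  if (is.null(dim(feq))) feq <- matrix(feq, nrow = 1)
  .collide_return(p$fm - params$omega * (p$fm - feq), f)
}

#' Regularized BGK collision
#'
#' Before relaxing, the non-equilibrium part is replaced by its projection on
#' the second-order moment space: with
#' \eqn{\Pi^{neq}_{\alpha\beta} = \sum_i (f_i - f_i^{eq}) e_{i\alpha} e_{i\beta}}
#' and \eqn{Q_{i\alpha\beta} = e_{i\alpha} e_{i\beta} - c_s^2
#' \delta_{\alpha\beta}}, the regularized non-equilibrium is
#' \eqn{\hat f_i^{neq} = \frac{w_i}{2 c_s^4} Q_{i\alpha\beta}
#' \Pi^{neq}_{\alpha\beta}} and \eqn{f' = f^{eq} + (1 - 1/\tau)\hat f^{neq}}.
#' Discards higher-order ("ghost") non-hydrodynamic content, improving
#' stability at low \eqn{\tau} while leaving the conserved moments and the
#' stress tensor of \eqn{f^{neq}} unchanged.
#'
#' @inheritParams collide_bgk
#' @export
collide_regularized <- function(f, params, lattice = lattice_d3q19()) {
  p <- .collide_prep(f, params, "regularized", lattice)
  feq <- equilibrium_bgk(p$rho, p$u, lattice)
  if (is.null(dim(feq))) feq <- matrix(feq, nrow = 1)
  fneq <- p$fm - feq
  e <- lattice$e
  # six independent components of Pi^neq, n x 6
  pxx <- fneq %*% (e[, 1] * e[, 1])
  pyy <- fneq %*% (e[, 2] * e[, 2])
  pzz <- fneq %*% (e[, 3] * e[, 3])
  pxy <- fneq %*% (e[, 1] * e[, 2])
  pxz <- fneq %*% (e[, 1] * e[, 3])
  pyz <- fneq %*% (e[, 2] * e[, 3])
  tr <- pxx + pyy + pzz
  n <- nrow(fneq)
  qpp <- pxx %*% t(e[, 1]^2) + pyy %*% t(e[, 2]^2) + pzz %*% t(e[, 3]^2) +
    2 * (pxy %*% t(e[, 1] * e[, 2]) + pxz %*% t(e[, 1] * e[, 3]) +
           pyz %*% t(e[, 2] * e[, 3])) -
    lattice$cs2 * (tr %*% t(rep(1, 19)))
  freg <- qpp * rep(lattice$w, each = n) / (2 * lattice$cs2^2)
  .collide_return(feq + (1 - params$omega) * freg, f)
}

#' Multiple-relaxation-time (MRT) collision
#'
#' Transforms the populations to the moment space of [mrt_matrix()], relaxes
#' each moment toward its equilibrium value (the moments of the BGK
#' equilibrium at the node's density and velocity) at its own rate, and
#' transforms back. Density and momentum are exactly conserved regardless of
#' the rates; when every rate equals \eqn{1/\tau} the operator degenerates to
#' [collide_bgk()].
#'
#' @inheritParams collide_bgk
#' @export
collide_mrt <- function(f, params, lattice = lattice_d3q19()) {
  p <- .collide_prep(f, params, "mrt", lattice)
  feq <- equilibrium_bgk(p$rho, p$u, lattice)
  if (is.null(dim(feq))) feq <- matrix(feq, nrow = 1)
  basis <- mrt_matrix(lattice)
  m <- p$fm %*% t(basis$M)
  meq <- feq %*% t(basis$M)
  s <- params$mrt_rates
  mpost <- m - (m - meq) * rep(s, each = nrow(m))
  .collide_return(mpost %*% t(basis$Minv), f)
}

#' Collision operator by name
#'
#' @param model one of `"bgk"`, `"incompressible"`, `"regularized"`, `"mrt"`.
#' @return the corresponding `collide_*` function.
#' @export
collision_operator <- function(model) {
  switch(match.arg(model, c("bgk", "incompressible", "regularized", "mrt")),
         bgk = collide_bgk,
         incompressible = collide_incompressible,
         regularized = collide_regularized,
         mrt = collide_mrt)
}
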