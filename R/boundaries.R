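#' Parabolic inlet description
#'
#' A laminar (Poiseuille) inflow disc: the prescribed axial speed at radial
#' distance r from the disc center is \eqn{u(r) = 2 u_{avg} [1 - (r/R)^2]},
#' so the centreline speed is twice the cross-sectional average.
#'
#' @param axis flow axis, 1 (x), 2 (y) or 3 (z); flow enters along the
#'   positive axis direction.
#' @param center disc center in lattice coordinates (the two transverse
#'   coordinates, or a full 3-vector from which they are taken).
#' @param R disc radius in lattice units (> 0).
#' @param u_avg mean speed in lattice units (>= 0).
#' @return object of class `inlet_spec`.
#' @export
inlet_spec <- function(axis, center, R, u_avg) {
  if (R <= 0) lbm_invalid_state("inlet radius must be positive")
  if (u_avg < 0) lbm_invalid_state("inlet mean speed must be >= 0")
  axis <- as.integer(axis)
  if (length(center) == 3) center <- center[setdiff(1:3, axis)]
  structure(list(axis = axis, center = center, R = R, u_avg = u_avg),
            class = "inlet_spec")
}

#' Parabolic inlet speed profile
#'
#' @param r radial distances from the disc center (lattice units).
#' @param spec an [inlet_spec()].
#' @return axial speeds; 0 beyond the disc radius.
#' @export
inlet_profile <- function(r, spec) {
  u <- 2 * spec$u_avg * (1 - (r / spec$R)^2)
  u[r > spec$R] <- 0
  u
}

.neighbor_flag <- function(flags, idx, e) {
  n <- dim(flags)
  nb <- sweep(idx, 2, e, "+")
  wrap <- function(v, k) ((v - 1) %% k) + 1
  for (a in 1:3) nb[, a] <- wrap(nb[, a], n[a])
  flags[nb]
}

#' Halfway bounce-back at solid walls
#'
#' Applied after a periodic [stream_step()]: every population that streamed
#' into a solid node is returned to its originating fluid node with reversed
#' direction, which places the effective no-slip plane halfway between the
#' fluid and solid node centers and gives zero net mass flux through the
#' wall.
#'
#' @param f post-streaming populations, (Nx, Ny, Nz, 19) array.
#' @param flags integer array of cell flags (same grid).
#' @param lattice a [lattice_d3q19()] object.
#' @return corrected populations.
#' @export
apply_bounce_back <- function(f, flags, lattice = lattice_d3q19()) {
  n <- dim(flags)
  open_idx <- which(flags != FLAG_SOLID, arr.ind = TRUE)
  wrap <- function(v, k) ((v - 1) %% k) + 1
  for (i in 2:19) {
    e <- lattice$e[i, ]
    nb <- open_idx
    for (a in 1:3) nb[, a] <- wrap(nb[, a] + e[a], n[a])
    hit <- flags[nb] == FLAG_SOLID
    if (!any(hit)) next
    src <- open_idx[hit, , drop = FALSE]
    tgt <- nb[hit, , drop = FALSE]
    f[cbind(src, lattice$opp[i])] <- f[cbind(tgt, i)]
  }
  f
}

.boundary_nodes <- function(flags, what) {
  which(flags == what, arr.ind = TRUE)
}

# interior neighbour of a boundary node: the face-adjacent fluid node,
# preferring the given axis direction
.interior_neighbor <- function(flags, idx, axis = NULL, dir = 1L) {
  n <- dim(flags)
  cand <- if (is.null(axis)) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    e <- c(0, 0, 0); e[axis] <- dir
    e2 <- rbind(e, -e,
                c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
    unique(e2)
  }
  out <- matrix(NA_integer_, nrow(idx), 3)
  for (k in seq_len(nrow(cand))) {
    nb <- sweep(idx, 2, cand[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] & nb[, 2] >= 1 & nb[, 2] <= n[2] &
      nb[, 3] >= 1 & nb[, 3] <= n[3]
    ok[ok] <- flags[nb[ok, , drop = FALSE]] == FLAG_FLUID
    fill <- ok & is.na(out[, 1])
    out[fill, ] <- nb[fill, , drop = FALSE]
  }
  out
}

.reconstruct_eq_neq <- function(f, idx, nbr, rho_target, u_target, model,
                                rho0, lattice) {
  # equilibrium at the target state + non-equilibrium copied from the
  # interior neighbour
  fget <- function(ind) {
    out <- matrix(NA_real_, nrow(ind), 19)
    for (i in 1:19) out[, i] <- f[cbind(ind, i)]
    out
  }
  fn <- fget(nbr)
  mom <- macroscopic_moments(fn, model = model, rho0 = rho0, lattice = lattice)
  feq_at <- function(rho, u) {
    if (model == "incompressible")
      equilibrium_incompressible(rho, rho0, u, lattice)
    else equilibrium_bgk(rho, u, lattice)
  }
  fneq <- fn - feq_at(mom$rho, mom$u)
  fnew <- feq_at(rho_target, u_target) + fneq
  if (is.null(dim(fnew))) fnew <- matrix(fnew, nrow = 1)
  for (i in 1:19) f[cbind(idx, i)] <- fnew[, i]
  f
}

#' Impose a parabolic velocity profile on the inlet disc
#'
#' Inlet nodes receive the equilibrium at the local density (extrapolated
#' from the interior neighbour, which anchors the imposed velocity — a free
#' inlet density can otherwise drift to cancel it) and the prescribed
#' profile velocity, plus the non-equilibrium part copied from the interior
#' neighbour. Nodes flagged inlet but lying outside the disc radius are
#' treated as wall (zero velocity); this is signalled once per call via a
#' warning.
#'
#' @param f populations, (Nx, Ny, Nz, 19) array (post-collision).
#' @param flags cell-flag array.
#' @param spec an [inlet_spec()].
#' @param model collision model name (controls the equilibrium family).
#' @param rho0 reference density for the incompressible model.
#' @param lattice a [lattice_d3q19()] object.
#' @return populations with inlet nodes reconstructed.
#' @export
apply_inlet_parabolic <- function(f, flags, spec, model = "bgk", rho0 = 1,
                                  lattice = lattice_d3q19()) {
  idx <- .boundary_nodes(flags, FLAG_INLET)
  if (nrow(idx) == 0L) return(f)
  tv <- setdiff(1:3, spec$axis)
  r <- sqrt((idx[, tv[1]] - spec$center[1])^2 +
              (idx[, tv[2]] - spec$center[2])^2)
  if (any(r > spec$R))
    warning(sprintf("%d inlet node(s) outside the disc radius treated as wall",
                    sum(r > spec$R)))
  speed <- inlet_profile(r, spec)
  u <- matrix(0, nrow(idx), 3)
  u[, spec$axis] <- speed
  nbr <- .interior_neighbor(flags, idx, axis = spec$axis, dir = 1L)
  if (any(is.na(nbr[, 1])))
    lbm_invalid_state("inlet node with no interior fluid neighbour")
  n <- dim(flags)
  cell <- (nbr[, 3] - 1) * n[1] * n[2] + (nbr[, 2] - 1) * n[1] + nbr[, 1]
  fm <- .as_f_matrix(f)
  rho_loc <- rowSums(fm[cell, , drop = FALSE])  # density from the neighbour
  .reconstruct_eq_neq(f, idx, nbr, rho_loc, u, model, rho0, lattice)
}

#' Pin the outlet density (zero gauge pressure)
#'
#' Outlet nodes are rebuilt with density `rho_ref` (gauge pressure zero) and
#' the velocity extrapolated from the adjacent interior fluid node, as the
#' equilibrium at that state plus the neighbour's non-equilibrium part.
#'
#' @inheritParams apply_inlet_parabolic
#' @param rho_ref outlet lattice density (1 = zero gauge pressure).
#' @export
apply_outlet_pressure <- function(f, flags, rho_ref = 1, model = "bgk",
                                  rho0 = 1, lattice = lattice_d3q19()) {
  idx <- .boundary_nodes(flags, FLAG_OUTLET)
  if (nrow(idx) == 0L) return(f)
  nbr <- .interior_neighbor(flags, idx)
  if (any(is.na(nbr[, 1])))
    lbm_invalid_state("outlet node with no interior fluid neighbour")
  fget <- matrix(NA_real_, nrow(nbr), 19)
  for (i in 1:19) fget[, i] <- f[cbind(nbr, i)]
  mom <- macroscopic_moments(fget, model = model, rho0 = rho0,
                             lattice = lattice)
  .reconstruct_eq_neq(f, idx, nbr, rep(rho_ref, nrow(idx)), mom$u, model,
                      rho0, lattice)
}
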