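#' D3Q19 lattice constants
#'
#' The standard three-dimensional, 19-velocity lattice: one rest direction,
#' six axis directions (weight 1/18) and twelve face-diagonal directions
#' (weight 1/36), with speed of sound squared \eqn{c_s^2 = 1/3}.
#'
#' @return An object of class `d3q19`: a list with
#'   \describe{
#'     \item{e}{19 x 3 integer matrix of lattice directions \eqn{e_i}.}
#'     \item{w}{numeric vector of 19 weights summing to 1.}
#'     \item{cs2}{speed of sound squared, 1/3.}
#'     \item{opp}{integer vector with `e[opp[i], ] == -e[i, ]`; an involution
#'       fixing the rest direction.}
#'   }
#' @examples
#' lat <- lattice_d3q19()
#' sum(lat$w)                         # exactly 1
#' lat$e[lat$opp[2], ] + lat$e[2, ]   # zero vector
#' @export
lattice_d3q19 <- function() {
  e <- rbind(
    c(0, 0, 0),
    c(1, 0, 0), c(-1, 0, 0),
    c(0, 1, 0), c(0, -1, 0),
    c(0, 0, 1), c(0, 0, -1),
    c(1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0),
    c(1, 0, 1), c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1),
    c(0, 1, 1), c(0, -1, -1), c(0, 1, -1), c(0, -1, 1)
  )
  storage.mode(e) <- "integer"
  w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  opp <- integer(19)
  for (i in 1:19) {
    opp[i] <- which(e[, 1] == -e[i, 1] & e[, 2] == -e[i, 2] & e[, 3] == -e[i, 3])
  }
  structure(list(e = e, w = w, cs2 = 1 / 3, opp = opp), class = "d3q19")
}

#' @export
print.d3q19 <- function(x, ...) {
  cat("D3Q19 lattice: 19 velocities (1 rest + 6 axis + 12 diagonal),",
      "cs2 = 1/3\n")
  invisible(x)
}

.as_u_matrix <- function(u, n) {
  if (is.null(dim(u))) {
    if (length(u) != 3L) stop("velocity must be a 3-vector or an n x 3 matrix")
    u <- matrix(u, nrow = n, ncol = 3, byrow = TRUE)
  }
  if (nrow(u) != n) stop("velocity rows must match length(rho)")
  u
}

lbm_invalid_state <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("lbm_invalid_state", "error")))
}

lbm_divergence <- function(msg, node = NA_integer_) {
  stop(errorCondition(msg, node = node,
                      class = c("lbm_divergence", "error")))
}

#' BGK (Maxwell-Boltzmann) equilibrium distribution
#'
#' Second-order expansion of the Maxwellian on the D3Q19 lattice:
#' \deqn{f_i^{eq} = w_i \rho \left[1 + 3 (e_i \cdot u) +
#'   \tfrac{9}{2} (e_i \cdot u)^2 - \tfrac{3}{2} u \cdot u\right].}
#' Its moments reproduce \eqn{(\rho, \rho u)} exactly.
#'
#' @param rho densities (length n, all > 0), lattice units.
#' @param u lattice velocity: a 3-vector or an n x 3 matrix.
#' @param lattice a [lattice_d3q19()] object.
#' @return n x 19 matrix of equilibrium values (a 19-vector drops to a vector
#'   when `rho` has length 1).
#' @export
equilibrium_bgk <- function(rho, u, lattice = lattice_d3q19()) {
  if (any(!is.finite(rho)) || any(rho <= 0))
    lbm_invalid_state("equilibrium_bgk: density must be positive and finite")
  n <- length(rho)
  u <- .as_u_matrix(u, n)
  eu <- u %*% t(lattice$e)                       # n x 19
  usq <- rowSums(u * u)
  out <- (rho * (1 + 3 * eu + 4.5 * eu^2 - 1.5 * usq)) *
    rep(lattice$w, each = n)
  if (n == 1L) drop(out) else out
}

#' Incompressible BGK equilibrium distribution
#'
#' Variant in which all velocity terms are multiplied by a constant reference
#' density \eqn{\rho_0} instead of the local \eqn{\rho}:
#' \deqn{f_i^{eq} = w_i\left[\rho + \rho_0\left(3 (e_i\cdot u) +
#'   \tfrac92 (e_i\cdot u)^2 - \tfrac32 u\cdot u\right)\right].}
#' The zeroth moment is \eqn{\rho}; the first moment is \eqn{\rho_0 u}, so the
#' matching velocity definition is momentum divided by \eqn{\rho_0}. This
#' removes the division by the fluctuating density and reduces
#' compressibility error.
#'
#' @inheritParams equilibrium_bgk
#' @param rho0 constant reference density (> 0).
#' @export
equilibrium_incompressible <- function(rho, rho0, u,
                                       lattice = lattice_d3q19()) {
  if (!is.finite(rho0) || rho0 <= 0)
    lbm_invalid_state("equilibrium_incompressible: rho0 must be positive")
  n <- length(rho)
  u <- .as_u_matrix(u, n)
  eu <- u %*% t(lattice$e)
  usq <- rowSums(u * u)
  out <- (rho + rho0 * (3 * eu + 4.5 * eu^2 - 1.5 * usq)) *
    rep(lattice$w, each = n)
  if (n == 1L) drop(out) else out
}

.as_f_matrix <- function(f) {
  if (is.null(dim(f))) {
    if (length(f) != 19L) stop("f must have 19 populations per node")
    return(matrix(f, nrow = 1))
  }
  d <- dim(f)
  if (d[length(d)] != 19L) stop("last extent of f must be 19")
  dim(f) <- c(prod(d[-length(d)]), 19L)
  f
}

#' Macroscopic density and velocity from populations
#'
#' Zeroth and first moments of the distribution:
#' \eqn{\rho = \sum_i f_i}, \eqn{u = \sum_i f_i e_i / \rho}. For the
#' incompressible model the contract velocity is momentum divided by the
#' constant `rho0`, matching [equilibrium_incompressible()].
#'
#' @param f populations: a 19-vector, an n x 19 matrix, or an
#'   (Nx, Ny, Nz, 19) array.
#' @param model one of `"bgk"`, `"incompressible"`, `"regularized"`, `"mrt"`.
#' @param rho0 reference density, used only for `model = "incompressible"`.
#' @param lattice a [lattice_d3q19()] object.
#' @return list with `rho` (length n) and `u` (n x 3 matrix).
#' @export
macroscopic_moments <- function(f, model = "bgk", rho0 = 1,
                                lattice = lattice_d3q19()) {
  model <- match.arg(model, c("bgk", "incompressible", "regularized", "mrt"))
  fm <- .as_f_matrix(f)
  rho <- rowSums(fm)
  bad <- which(!is.finite(rho) | rho <= 0)
  if (length(bad))
    lbm_divergence(sprintf("non-positive density at node %d", bad[1]),
                   node = bad[1])
  mom <- fm %*% lattice$e
  u <- mom / if (model == "incompressible") rho0 else rho
  list(rho = rho, u = u)
}

#' Streaming step on a periodic grid
#'
#' Advects each population one node along its own direction,
#' \eqn{f_i(x + e_i) \leftarrow f_i(x)}, with periodic wrap at every face.
#' This is a pure permutation of values: total mass (and, on a fully periodic
#' domain, momentum) is conserved exactly. Wall/inlet/outlet handling is a
#' separate concern (see [apply_bounce_back()]).
#'
#' @param f populations as an (Nx, Ny, Nz, 19) array.
#' @param lattice a [lattice_d3q19()] object.
#' @return array of the same shape, post-streaming.
#' @export
stream_step <- function(f, lattice = lattice_d3q19()) {
  d <- dim(f)
  if (length(d) != 4L || d[4] != 19L)
    stop("f must be an (Nx, Ny, Nz, 19) array")
  out <- f
  for (i in 1:19) {
    e <- lattice$e[i, ]
    sl <- f[, , , i, drop = FALSE]
    # shift by +e with periodic wrap: destination index = source + e
    ix <- ((seq_len(d[1]) - 1 - e[1]) %% d[1]) + 1
    iy <- ((seq_len(d[2]) - 1 - e[2]) %% d[2]) + 1
    iz <- ((seq_len(d[3]) - 1 - e[3]) %% d[3]) + 1
    out[, , , i] <- sl[ix, iy, iz, , drop = FALSE]
  }
  out
}
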