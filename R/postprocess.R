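#' Gauge pressure field in Pa
#'
#' Lattice pressure is \eqn{p_{LB} = c_s^2 (\rho - \rho_{ref})}; the
#' physical gauge pressure follows from the unit system as
#' \eqn{p = p_{LB}\, \rho_{phys} (\delta x / \delta t)^2}. With the outlet
#' density pinned at `rho_ref`, pressure is zero at the outlets and the
#' reported values are relative to them.
#'
#' @param state an `lbm_state` (or a density array).
#' @param sys a [unit_system()]; taken from the state when available.
#' @param rho_ref reference (outlet) density.
#' @return array of gauge pressures (Pa), `NA` on solid nodes.
#' @export
compute_pressure <- function(state, sys = NULL, rho_ref = 1) {
  rho <- if (inherits(state, "lbm_state")) state$rho else state
  if (is.null(sys) && inherits(state, "lbm_state")) sys <- state$sys
  p_lat <- (rho - rho_ref) / 3
  if (is.null(sys)) p_lat else to_physical(p_lat, "pressure", sys)
}

# speed magnitude with the grid shape kept even when an extent is 1
.speed_field <- function(state) {
  n <- dim(state$geom$flags)
  comp <- function(a) {
    v <- state$u[, , , a, drop = FALSE]
    dim(v) <- n
    v
  }
  sqrt(comp(1)^2 + comp(2)^2 + comp(3)^2)
}

# outward wall normals from the smoothed solid indicator (3^3 box filter),
# evaluated at the given fluid nodes; returns unit vectors, NA when the
# local gradient vanishes (isolated voxel)
.wall_normals <- function(flags, idx, periodic = c(FALSE, FALSE, FALSE)) {
  n <- dim(flags)
  s <- (flags == FLAG_SOLID) * 1
  sh <- function(a, ax, by) {
    i <- seq_len(n[ax]) + by
    i <- if (periodic[ax]) ((i - 1) %% n[ax]) + 1 else pmin(pmax(i, 1L), n[ax])
    switch(ax, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  sm <- s
  for (ax in 1:3) sm <- (sh(sm, ax, -1L) + sm + sh(sm, ax, 1L)) / 3
  g <- lapply(1:3, function(ax) (sh(sm, ax, 1L) - sh(sm, ax, -1L)) / 2)
  nm <- cbind(g[[1]][idx], g[[2]][idx], g[[3]][idx])
  len <- sqrt(rowSums(nm^2))
  ok <- len > 1e-12
  nm[ok, ] <- nm[ok, , drop = FALSE] / len[ok]
  nm[!ok, ] <- NA_real_
  nm
}

#' Wall shear stress from the non-equilibrium stress tensor
#'
#' At every fluid node adjacent to a wall, the deviatoric stress is
#' recovered locally from the non-equilibrium populations,
#' \deqn{\sigma_{\alpha\beta} = \left(1 - \frac{1}{2\tau}\right)
#'   \sum_i f_i^{neq} e_{i\alpha} e_{i\beta},}
#' the wall traction is \eqn{t = \sigma n} with `n` the outward normal
#' estimated from the smoothed solid indicator, and the WSS is the
#' magnitude of the tangential traction \eqn{|t - (t \cdot n) n|},
#' converted to Pa. Wall cells with an undefined normal are excluded and
#' counted.
#'
#' @param state an `lbm_state`.
#' @param sys a [unit_system()]; taken from the state when available
#'   (without one, values stay in lattice units).
#' @param normals optional analytic outward normals for parametric
#'   geometries: a function taking an n x 3 matrix of 1-based node
#'   coordinates and returning n x 3 unit vectors. Defaults to normals
#'   estimated from the box-smoothed solid indicator.
#' @return object of class `wss_field`: data frame with node indices,
#'   physical positions (m), outward unit normals and `wss` (Pa), plus an
#'   `excluded` attribute.
#' @export
compute_wss <- function(state, sys = NULL, normals = NULL) {
  stopifnot(inherits(state, "lbm_state"))
  if (is.null(sys)) sys <- state$sys
  lattice <- lattice_d3q19()
  flags <- state$geom$flags
  n <- dim(flags)
  # wall cells: fluid nodes with a solid link neighbour
  fluid <- flags == FLAG_FLUID
  solid <- flags == FLAG_SOLID
  near <- array(FALSE, n)
  for (i in 2:19) {
    e <- lattice$e[i, ]
    ix <- pmin(pmax(seq_len(n[1]) + e[1], 1L), n[1])
    iy <- pmin(pmax(seq_len(n[2]) + e[2], 1L), n[2])
    iz <- pmin(pmax(seq_len(n[3]) + e[3], 1L), n[3])
    near <- near | solid[ix, iy, iz, drop = FALSE]
  }
  idx <- which(fluid & near, arr.ind = TRUE)
  lin <- which(fluid & near)
  if (nrow(idx) == 0L) stop("no wall-adjacent fluid nodes")
  fm <- state$f
  dim(fm) <- c(prod(n), 19)
  fw <- fm[lin, , drop = FALSE]
  mom <- macroscopic_moments(fw, model = state$model,
                             rho0 = state$params$rho0, lattice = lattice)
  feq <- if (state$model == "incompressible")
    equilibrium_incompressible(mom$rho, state$params$rho0, mom$u, lattice)
  else equilibrium_bgk(mom$rho, mom$u, lattice)
  fneq <- fw - feq
  e <- lattice$e
  pref <- 1 - 1 / (2 * state$params$tau)
  sxx <- pref * (fneq %*% (e[, 1]^2))
  syy <- pref * (fneq %*% (e[, 2]^2))
  szz <- pref * (fneq %*% (e[, 3]^2))
  sxy <- pref * (fneq %*% (e[, 1] * e[, 2]))
  sxz <- pref * (fneq %*% (e[, 1] * e[, 3]))
  syz <- pref * (fneq %*% (e[, 2] * e[, 3]))
  # remove the isotropic part: only the deviator carries shear
  tr3 <- (sxx + syy + szz) / 3
  sxx <- sxx - tr3; syy <- syy - tr3; szz <- szz - tr3
  nm <- if (is.null(normals)) .wall_normals(flags, idx, state$geom$periodic)
  else {
    v <- normals(idx)
    v / sqrt(rowSums(v^2))
  }
  ok <- !is.na(nm[, 1])
  tx <- sxx * nm[, 1] + sxy * nm[, 2] + sxz * nm[, 3]
  ty <- sxy * nm[, 1] + syy * nm[, 2] + syz * nm[, 3]
  tz <- sxz * nm[, 1] + syz * nm[, 2] + szz * nm[, 3]
  tn <- tx * nm[, 1] + ty * nm[, 2] + tz * nm[, 3]
  wss <- sqrt(pmax((tx - tn * nm[, 1])^2 + (ty - tn * nm[, 2])^2 +
                     (tz - tn * nm[, 3])^2, 0))
  # lattice stress converts to Pa with the same rho_phys (dx/dt)^2 scale as
  # pressure
  if (!is.null(sys)) wss <- to_physical(wss, "pressure", sys)
  dx <- if (!is.null(sys)) sys$dx else state$geom$dx
  pos <- sweep((idx - 1) * dx, 2, state$geom$origin, "+")
  out <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    nx = nm[, 1], ny = nm[, 2], nz = nm[, 3],
                    wss = as.vector(wss))
  out <- out[ok, , drop = FALSE]
  attr(out, "excluded") <- sum(!ok)
  class(out) <- c("wss_field", class(out))
  out
}

#' Trilinear probe extraction
#'
#' Samples density, velocity and gauge pressure at arbitrary physical
#' positions by trilinear interpolation from the 8 enclosing nodes. A probe
#' whose enclosing nodes are not all fluid (or inlet/outlet) is rejected,
#' naming the probe index.
#'
#' @param state an `lbm_state`.
#' @param probes n x 3 matrix of physical positions (m).
#' @param sys a [unit_system()]; taken from the state when available.
#' @param rho_ref reference density for the gauge pressure.
#' @return data frame: probe index, position, `rho`, velocity components and
#'   `speed_m_s`, `pressure_pa` (lattice units when no unit system is
#'   attached).
#' @export
extract_probes <- function(state, probes, sys = NULL, rho_ref = 1) {
  stopifnot(inherits(state, "lbm_state"))
  if (is.null(sys)) sys <- state$sys
  if (is.null(dim(probes))) probes <- matrix(probes, ncol = 3)
  dx <- if (!is.null(sys)) sys$dx else state$geom$dx
  n <- dim(state$geom$flags)
  gpos <- sweep(probes, 2, state$geom$origin) / dx    # 0-based grid coords
  i0 <- floor(gpos)
  fr <- gpos - i0
  interp_one <- function(field3, k) {
    v <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wgt <- prod(ifelse(c(cx, cy, cz) == 1, fr[k, ], 1 - fr[k, ]))
      v <- v + wgt * field3[i0[k, 1] + 1 + cx, i0[k, 2] + 1 + cy,
                            i0[k, 3] + 1 + cz]
    }
    v
  }
  flags <- state$geom$flags
  out <- data.frame(probe = seq_len(nrow(probes)), x = probes[, 1],
                    y = probes[, 2], z = probes[, 3], rho = NA_real_,
                    ux = NA_real_, uy = NA_real_, uz = NA_real_)
  for (k in seq_len(nrow(probes))) {
    if (any(i0[k, ] < 0) || any(i0[k, ] + 1 >= n))
      stop(sprintf("probe %d lies outside the grid", k))
    corner_flags <- flags[(i0[k, 1] + 1):(i0[k, 1] + 2),
                          (i0[k, 2] + 1):(i0[k, 2] + 2),
                          (i0[k, 3] + 1):(i0[k, 3] + 2)]
    if (any(corner_flags == FLAG_SOLID))
      stop(sprintf("probe %d lies outside the fluid region", k))
    ucomp <- function(a) {
      v <- state$u[, , , a, drop = FALSE]
      dim(v) <- n
      v
    }
    out$rho[k] <- interp_one(state$rho, k)
    out$ux[k] <- interp_one(ucomp(1), k)
    out$uy[k] <- interp_one(ucomp(2), k)
    out$uz[k] <- interp_one(ucomp(3), k)
  }
  if (!is.null(sys)) {
    for (cc in c("ux", "uy", "uz"))
      out[[cc]] <- to_physical(out[[cc]], "velocity", sys)
  }
  out$speed_m_s <- sqrt(out$ux^2 + out$uy^2 + out$uz^2)
  p_lat <- (out$rho - rho_ref) / 3
  out$pressure_pa <- if (!is.null(sys))
    to_physical(p_lat, "pressure", sys) else p_lat
  out
}

#' Axis-aligned plane slice
#'
#' @param state an `lbm_state`.
#' @param plane `"xy"`, `"yz"` or `"zx"`.
#' @param coord physical coordinate (m) of the plane along its normal axis;
#'   the nearest node layer is used.
#' @param sys optional [unit_system()] for physical units.
#' @param rho_ref reference density for pressure.
#' @return list of 2D matrices: `rho`, `speed`, `pressure`, plus the slice
#'   `index` used.
#' @export
extract_plane <- function(state, plane = c("xy", "yz", "zx"), coord,
                          sys = NULL, rho_ref = 1) {
  plane <- match.arg(plane)
  if (is.null(sys)) sys <- state$sys
  axis <- switch(plane, xy = 3L, yz = 1L, zx = 2L)
  dx <- if (!is.null(sys)) sys$dx else state$geom$dx
  n <- dim(state$geom$flags)
  k <- round((coord - state$geom$origin[axis]) / dx) + 1
  if (k < 1 || k > n[axis]) stop("plane does not intersect the domain")
  slice <- function(a) {
    m <- switch(axis, a[k, , , drop = FALSE], a[, k, , drop = FALSE],
                a[, , k, drop = FALSE])
    dim(m) <- dim(a)[setdiff(1:3, axis)]
    m
  }
  spd <- .speed_field(state)
  if (!is.null(sys)) spd <- to_physical(spd, "velocity", sys)
  list(rho = slice(state$rho), speed = slice(spd),
       pressure = slice(compute_pressure(state, sys, rho_ref)), index = k)
}

#' Pointwise field comparison
#'
#' Percentage differences \eqn{100 (a - b)/b} and absolute changes
#' \eqn{b - a} between a sample and a reference, with summary maxima and
#' means. Points with zero reference are flagged `NA` in the percentage
#' column and excluded from its summary.
#'
#' @param a sampled values.
#' @param b reference values (same length).
#' @return list with `percent`, `abs_change`, and a `summary` list of
#'   max/mean absolute values of both.
#' @export
compare_fields <- function(a, b) {
  stopifnot(length(a) == length(b))
  pct <- ifelse(b == 0, NA_real_, 100 * (a - b) / b)
  ac <- b - a
  list(percent = pct, abs_change = ac,
       summary = list(max_percent = max(abs(pct), na.rm = TRUE),
                      mean_percent = mean(abs(pct), na.rm = TRUE),
                      max_abs = max(abs(ac)), mean_abs = mean(abs(ac))))
}

#' Wall shear stress distribution statistics
#'
#' Histogram of the percentage of wall cells per WSS bin over a fixed
#' range, box-plot quartiles (linear interpolation between order
#' statistics) and 1.5 IQR outliers.
#'
#' @param wss a `wss_field` (or numeric vector of WSS values).
#' @param bin_width bin width in Pa.
#' @param range covered WSS interval in Pa; percentages are relative to the
#'   cells inside the range and sum to 100.
#' @return object of class `dist_stats`: list with `breaks`, `percent`,
#'   `q1`, `median`, `q3`, `iqr`, `outliers`.
#' @export
wss_distribution_stats <- function(wss, bin_width = 0.1,
                                   range = c(0, 2.8)) {
  v <- if (is.data.frame(wss)) wss$wss else as.numeric(wss)
  if (length(v) == 0L) stop("empty WSS field")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  inr <- v[v >= range[1] & v <= range[2]]
  counts <- if (length(inr))
    graphics::hist(inr, breaks = breaks, plot = FALSE,
                   include.lowest = TRUE, right = FALSE)$counts
  else rep(0L, length(breaks) - 1)
  pct <- if (sum(counts)) 100 * counts / sum(counts) else counts * 0
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
  structure(list(breaks = breaks, percent = pct, q1 = q[1], median = q[2],
                 q3 = q[3], iqr = iqr, outliers = out),
            class = "dist_stats")
}

#' @export
print.dist_stats <- function(x, ...) {
  cat(sprintf("WSS distribution: Q1 %.3g, median %.3g, Q3 %.3g (IQR %.3g), %d outlier(s)\n",
              x$q1, x$median, x$q3, x$iqr, length(x$outliers)))
  invisible(x)
}

#' Velocity-threshold visualization mask
#'
#' Marks nodes whose physical speed exceeds `u_min` (m/s), the high-flow
#' rendering used to expose the near-stagnant aneurysm sac (flows above
#' 0.05 m/s visualized, the sac interior largely excluded).
#'
#' @param state an `lbm_state`.
#' @param sys optional [unit_system()]; lattice speeds are used without one.
#' @param u_min threshold speed (m/s).
#' @return logical array over the grid; `FALSE` on solid nodes.
#' @export
threshold_view <- function(state, sys = NULL, u_min = 0.05) {
  if (is.null(sys)) sys <- state$sys
  spd <- .speed_field(state)
  if (!is.null(sys)) spd <- to_physical(spd, "velocity", sys)
  !is.na(spd) & spd > u_min
}
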