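# Cell flag codes used throughout: 0 fluid, 1 solid, 2 inlet, 3 outlet.
FLAG_FLUID <- 0L
FLAG_SOLID <- 1L
FLAG_INLET <- 2L
FLAG_OUTLET <- 3L

#' Parametric bifurcation-aneurysm vessel description
#'
#' A Y-shaped carotid-style bifurcation: a straight inlet trunk that splits
#' at an apex into two branch tubes of smaller caliber, with an optional
#' spherical aneurysm sac attached near the apex. Default diameters follow
#' the carotid bifurcation: inlet 0.63 cm, outlets 0.45 cm and 0.3 cm.
#' Branch angles, segment lengths and sac placement are free parameters (the
#' qualitative shape, not an exact CAD reproduction).
#'
#' @param d_inlet,d_out1,d_out2 tube diameters (m), all > 0.
#' @param angle1,angle2 branch angles from the trunk axis (degrees); the two
#'   branches open on opposite sides when the signs differ.
#' @param trunk_len trunk length from inlet plane to bifurcation apex (m).
#' @param branch_len branch tube length (m); branches are extended so the
#'   outflow caps are truncated by the downstream domain face.
#' @param sac_radius aneurysm sac radius (m); 0 disables the sac.
#' @param sac_offset 3-vector (m), sac center offset from the apex.
#' @return object of class `bifurcation_spec`.
#' @export
bifurcation_spec <- function(d_inlet = 0.0063, d_out1 = 0.0045,
                             d_out2 = 0.003, angle1 = 40, angle2 = -60,
                             trunk_len = 0.018, branch_len = 0.022,
                             sac_radius = 0.0035,
                             sac_offset = c(0.001, 0.0045, 0)) {
  if (any(c(d_inlet, d_out1, d_out2) <= 0))
    lbm_invalid_state("all diameters must be positive")
  if (sac_radius < 0) lbm_invalid_state("sac radius must be >= 0")
  if (trunk_len <= 0 || branch_len <= 0)
    lbm_invalid_state("segment lengths must be positive")
  structure(list(d_inlet = d_inlet, d_out1 = d_out1, d_out2 = d_out2,
                 angle1 = angle1, angle2 = angle2, trunk_len = trunk_len,
                 branch_len = branch_len, sac_radius = sac_radius,
                 sac_offset = sac_offset),
            class = "bifurcation_spec")
}

# inside test for a capped cylinder: base b, unit axis a, length L, radius r
.inside_cylinder <- function(p, b, a, L, r) {
  d <- sweep(p, 2, b)
  t <- d %*% a
  perp2 <- rowSums(d * d) - t^2
  t >= 0 & t <= L & perp2 <= r^2
}

#' Implicit solid for a bifurcation-aneurysm vessel
#'
#' Builds the fluid region as the union of three capped cylinders (trunk and
#' two branches, meeting at the bifurcation apex) and the sac sphere. The
#' trunk runs along +x from the origin; the inlet cap lies in the plane
#' x = 0 and both branch tubes point downstream, so an axis-aligned plane
#' x = const cuts planar outflow discs.
#'
#' @param spec a [bifurcation_spec()].
#' @return object of class `implicit_solid`: a list with `inside` (a
#'   vectorized function taking an n x 3 matrix of points in m), suggested
#'   voxelization `bounds` (2 x 3 matrix), the `apex` position, the inlet
#'   cap description and the downstream cut plane `x_cut`.
#' @export
generate_bifurcation_aneurysm <- function(spec) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  apex <- c(spec$trunk_len, 0, 0)
  a1 <- c(cos(spec$angle1 * pi / 180), sin(spec$angle1 * pi / 180), 0)
  a2 <- c(cos(spec$angle2 * pi / 180), sin(spec$angle2 * pi / 180), 0)
  if (a1[1] <= 0 || a2[1] <= 0)
    lbm_invalid_state("branch angles must stay below 90 degrees from the trunk")
  r0 <- spec$d_inlet / 2; r1 <- spec$d_out1 / 2; r2 <- spec$d_out2 / 2
  # branches start slightly upstream of the apex so the junction is watertight
  b1 <- apex - a1 * r0; b2 <- apex - a2 * r0
  blen <- spec$branch_len + r0
  sac_c <- apex + spec$sac_offset
  sac_r <- spec$sac_radius
  # downstream cut: keep both branch caps inside the tube length
  x_cut <- spec$trunk_len + spec$branch_len * min(a1[1], a2[1]) * 0.85
  inside <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    inb <- .inside_cylinder(p, c(0, 0, 0), c(1, 0, 0), spec$trunk_len, r0) |
      .inside_cylinder(p, b1, a1, blen, r1) |
      .inside_cylinder(p, b2, a2, blen, r2)
    if (sac_r > 0)
      inb <- inb | (rowSums(sweep(p, 2, sac_c)^2) <= sac_r^2)
    # nothing lives upstream of the inlet plane or downstream of the cut
    inb & p[, 1] >= 0 & p[, 1] <= x_cut
  }
  ymax <- max(abs(b1[2]) + blen * abs(a1[2]) + r1,
              abs(b2[2]) + blen * abs(a2[2]) + r2,
              r0, if (sac_r > 0) abs(sac_c[2]) + sac_r else 0)
  zmax <- max(r0, r1, r2, if (sac_r > 0) abs(sac_c[3]) + sac_r else 0)
  bounds <- rbind(c(0, -ymax, -zmax), c(x_cut, ymax, zmax))
  if (spec$trunk_len <= r0)
    lbm_invalid_state("trunk too short: inlet and outlet caps overlap")
  structure(list(inside = inside, bounds = bounds, apex = apex,
                 inlet = list(axis = 1L, center = c(0, 0, 0), R = r0),
                 x_cut = x_cut, sac_center = sac_c, sac_radius = sac_r,
                 spec = spec),
            class = "implicit_solid")
}

#' Voxelize a solid onto a regular lattice
#'
#' Flags every node whose center lies inside the solid as fluid and all
#' others as solid (node centers sit at `origin + index * dx`, 0-based
#' indexing). For an `implicit_solid` vessel the fluid discs on the x = 0
#' face become inlet nodes and those on the far x face become outlet nodes.
#' Fluid pockets not reachable from the inlet (or, lacking an inlet, from
#' the largest component) are removed by flood fill over face adjacency.
#'
#' @param solid an `implicit_solid`, an `stl_mesh` from [read_stl()], or a
#'   plain vectorized inside-function (then `bounds` is required).
#' @param dx lattice spacing (m), > 0.
#' @param bounds optional 2 x 3 matrix (min row, max row) overriding the
#'   solid's own suggested bounds.
#' @param margin solid padding (in nodes) added outside the bounds on the
#'   transverse faces.
#' @return object of class `lbm_geometry`: list with the integer `flags`
#'   array (0 fluid, 1 solid, 2 inlet, 3 outlet), `dx`, `origin`, `periodic`
#'   flags per axis, and inlet/outlet metadata.
#' @export
voxelize <- function(solid, dx, bounds = NULL, margin = 2L) {
  if (!is.finite(dx) || dx <= 0) lbm_invalid_state("dx must be positive")
  caps <- NULL
  meta <- list()
  if (inherits(solid, "stl_mesh")) {
    inside <- .stl_inside_fun(solid)
    if (is.null(bounds)) bounds <- .stl_bounds(solid)
  } else if (inherits(solid, "implicit_solid")) {
    inside <- solid$inside
    if (is.null(bounds)) bounds <- solid$bounds
    caps <- "x"
    meta <- list(apex = solid$apex, sac_center = solid$sac_center,
                 sac_radius = solid$sac_radius, inlet = solid$inlet)
  } else if (is.function(solid)) {
    inside <- solid
    if (is.null(bounds)) stop("bounds must be given for a bare inside-function")
  } else stop("unsupported solid description")

  origin <- c(bounds[1, 1],
              bounds[1, 2] - margin * dx,
              bounds[1, 3] - margin * dx)
  n <- c(floor((bounds[2, 1] - bounds[1, 1]) / dx) + 1L,
         floor((bounds[2, 2] - origin[2]) / dx) + 1L + margin,
         floor((bounds[2, 3] - origin[3]) / dx) + 1L + margin)
  xs <- origin[1] + (seq_len(n[1]) - 1) * dx
  ys <- origin[2] + (seq_len(n[2]) - 1) * dx
  zs <- origin[3] + (seq_len(n[3]) - 1) * dx
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  fl <- inside(pts)
  flags <- array(ifelse(fl, FLAG_FLUID, FLAG_SOLID), dim = n)
  if (!any(flags == FLAG_FLUID))
    lbm_invalid_state("empty solid: voxelization produced no fluid nodes")

  inlet_nodes <- NULL
  if (identical(caps, "x")) {
    # inlet disc on the first x layer, outlet discs on the last
    iin <- which(flags[1, , ] == FLAG_FLUID, arr.ind = TRUE)
    iout <- which(flags[n[1], , ] == FLAG_FLUID, arr.ind = TRUE)
    if (nrow(iin) == 0L || nrow(iout) == 0L)
      lbm_invalid_state("vessel does not reach the inlet/outlet faces")
    flags[cbind(1L, iin)] <- FLAG_INLET
    flags[cbind(n[1], iout)] <- FLAG_OUTLET
    inlet_nodes <- cbind(1L, iin)
  }
  geom <- structure(list(flags = flags, dx = dx, origin = origin,
                         periodic = c(FALSE, FALSE, FALSE), meta = meta),
                    class = "lbm_geometry")
  flood_fill_fluid(geom)
}

#' Remove fluid not connected to the inlet
#'
#' Breadth-first flood fill over face adjacency starting from the inlet
#' nodes (or from the node richest component seed when there is no inlet);
#' unreachable fluid nodes become solid, and inlet/outlet nodes without a
#' face-adjacent fluid node are demoted to solid too.
#'
#' @param geom an `lbm_geometry`.
#' @return the cleaned geometry.
#' @export
flood_fill_fluid <- function(geom) {
  flags <- geom$flags
  n <- dim(flags)
  open <- flags != FLAG_SOLID
  idx <- array(seq_along(flags), dim = n)
  # 6 face-neighbour index arrays (clamped at the hull; hull nodes of a
  # voxelized vessel are solid anyway)
  shift <- function(a, ax, by) {
    i <- pmin(pmax(seq_len(n[ax]) + by, 1L), n[ax])
    switch(ax, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  nbrs <- lapply(list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1)),
                 function(s) shift(idx, s[1], s[2]))
  seed <- which(flags == FLAG_INLET)
  if (length(seed) == 0L) seed <- which(open)[1]
  reached <- logical(length(flags))
  reached[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(nbrs, function(nb) nb[frontier])))
    nxt <- nxt[open[nxt] & !reached[nxt]]
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  flags[open & !array(reached, dim = n)] <- FLAG_SOLID
  # boundary-cap sanity: inlet/outlet must touch fluid
  for (fc in c(FLAG_INLET, FLAG_OUTLET)) {
    cand <- which(flags == fc)
    if (!length(cand)) next
    has_fluid <- Reduce(`|`, lapply(nbrs, function(nb)
      flags[nb[cand]] == FLAG_FLUID))
    flags[cand[!has_fluid]] <- FLAG_SOLID
  }
  geom$flags <- flags
  geom
}

#' Fraction and count of fluid nodes
#' @param geom an `lbm_geometry`.
#' @return list with counts per flag class.
#' @export
geometry_summary <- function(geom) {
  f <- geom$flags
  list(n = dim(f), fluid = sum(f == FLAG_FLUID), solid = sum(f == FLAG_SOLID),
       inlet = sum(f == FLAG_INLET), outlet = sum(f == FLAG_OUTLET))
}

#' @export
print.lbm_geometry <- function(x, ...) {
  s <- geometry_summary(x)
  cat(sprintf(paste0("lbm_geometry: %d x %d x %d grid, dx = %g m\n",
                     "  fluid %d, solid %d, inlet %d, outlet %d\n"),
              s$n[1], s$n[2], s$n[3], x$dx, s$fluid, s$solid, s$inlet,
              s$outlet))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Analytic test geometries (lattice-unit fixtures; dx defaults to 1 m/node so
# lattice and "physical" coordinates coincide unless a unit system is added).

#' Periodic all-fluid box
#' @param nx,ny,nz grid extents.
#' @param dx spacing (m).
#' @return an `lbm_geometry` with all axes periodic.
#' @export
box_geometry <- function(nx, ny = nx, nz = nx, dx = 1) {
  flags <- array(FLAG_FLUID, dim = c(nx, ny, nz))
  structure(list(flags = flags, dx = dx, origin = c(0, 0, 0),
                 periodic = c(TRUE, TRUE, TRUE), meta = list()),
            class = "lbm_geometry")
}

#' Plane channel between two bounce-back walls
#'
#' Walls are the first and last y layers; x and z are periodic. The no-slip
#' planes sit half a node outside the outermost fluid layers, so the
#' effective channel width is `ny - 2` (fluid layers) + 1 node.
#'
#' @param ny total y extent including the two wall layers.
#' @param nx,nz periodic extents.
#' @param dx spacing (m).
#' @export
channel_geometry <- function(ny, nx = 4, nz = 4, dx = 1) {
  flags <- array(FLAG_FLUID, dim = c(nx, ny, nz))
  flags[, c(1, ny), ] <- FLAG_SOLID
  structure(list(flags = flags, dx = dx, origin = c(0, 0, 0),
                 periodic = c(TRUE, FALSE, TRUE), meta = list()),
            class = "lbm_geometry")
}

#' Circular pipe with periodic axis
#'
#' A staircase (voxelized) cylinder of radius `R` nodes along the z axis,
#' driven in tests by a body force. The pipe axis passes through the center
#' of the cross-section; node centers at distance <= R from the axis are
#' fluid.
#'
#' @param R pipe radius in nodes.
#' @param nz axial (periodic) extent.
#' @param dx spacing (m).
#' @export
pipe_geometry <- function(R, nz = 3, dx = 1) {
  nxy <- 2L * ceiling(R) + 3L
  c0 <- (nxy + 1) / 2
  flags <- array(FLAG_SOLID, dim = c(nxy, nxy, nz))
  for (i in seq_len(nxy)) for (j in seq_len(nxy)) {
    if ((i - c0)^2 + (j - c0)^2 <= R^2) flags[i, j, ] <- FLAG_FLUID
  }
  structure(list(flags = flags, dx = dx, origin = c(0, 0, 0),
                 periodic = c(FALSE, FALSE, TRUE),
                 meta = list(axis = 3L, center = c(c0, c0), R = R)),
            class = "lbm_geometry")
}

#' Straight pipe with velocity inlet and pressure outlet
#'
#' Like [pipe_geometry()] but bounded: the first z layer of fluid becomes
#' the inlet disc and the last the outlet disc; the axis is not periodic.
#'
#' @inheritParams pipe_geometry
#' @export
pipe_flow_geometry <- function(R, nz, dx = 1) {
  g <- pipe_geometry(R, nz = nz, dx = dx)
  fl <- g$flags
  in1 <- which(fl[, , 1] == FLAG_FLUID, arr.ind = TRUE)
  fl[cbind(in1, 1L)] <- FLAG_INLET
  out1 <- which(fl[, , nz] == FLAG_FLUID, arr.ind = TRUE)
  fl[cbind(out1, nz)] <- FLAG_OUTLET
  g$flags <- fl
  g$periodic <- c(FALSE, FALSE, FALSE)
  g
}
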