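# Packing a voxel geometry into the dense active-node arrays consumed by the
# C++ stepping kernel: active = all non-solid nodes; src[c, i] holds the
# 0-based active index of the pull source one link upstream of direction i,
# or -1 when the link is blocked (solid neighbour, or domain hull on a
# non-periodic axis) and halfway bounce-back applies.
.pack_geometry <- function(geom, lattice = lattice_d3q19()) {
  flags <- geom$flags
  n <- dim(flags)
  active <- which(flags != FLAG_SOLID)
  na <- length(active)
  if (na == 0L) lbm_invalid_state("geometry has no active nodes")
  amap <- integer(prod(n))
  amap[active] <- seq_len(na)
  ai <- arrayInd(active, n)
  src <- matrix(-1L, na, 19)
  for (i in 1:19) {
    e <- lattice$e[i, ]
    sc <- sweep(ai, 2, e)       # source = x - e_i
    ok <- rep(TRUE, na)
    for (a in 1:3) {
      if (geom$periodic[a]) {
        sc[, a] <- ((sc[, a] - 1) %% n[a]) + 1
      } else {
        ok <- ok & sc[, a] >= 1 & sc[, a] <= n[a]
      }
    }
    lin <- rep(NA_integer_, na)
    lin[ok] <- (sc[ok, 3] - 1) * n[1] * n[2] + (sc[ok, 2] - 1) * n[1] +
      sc[ok, 1]
    hit <- ok & amap[replace(lin, is.na(lin), 1L)] > 0 & !is.na(lin)
    src[hit, i] <- amap[lin[hit]] - 1L
  }
  list(flags = flags, n = n, active = active, amap = amap, ai = ai,
       src = src, na = na)
}

# boundary-node bookkeeping for the kernel: indices are 0-based into the
# active arrays
.pack_boundaries <- function(pack, geom, inlet = NULL) {
  flags <- pack$flags
  inletIdx <- integer(0); inletNbr <- integer(0)
  inletU <- matrix(0, 0, 3)
  if (!is.null(inlet)) {
    idx <- which(flags == FLAG_INLET, arr.ind = TRUE)
    if (nrow(idx)) {
      nbr <- .interior_neighbor(flags, idx, axis = inlet$axis, dir = 1L)
      if (any(is.na(nbr[, 1])))
        lbm_invalid_state("inlet node with no interior fluid neighbour")
      tv <- setdiff(1:3, inlet$axis)
      r <- sqrt((idx[, tv[1]] - inlet$center[1])^2 +
                  (idx[, tv[2]] - inlet$center[2])^2)
      speed <- inlet_profile(r, inlet)
      inletU <- matrix(0, nrow(idx), 3)
      inletU[, inlet$axis] <- speed
      n <- pack$n
      lin <- function(ix) (ix[, 3] - 1) * n[1] * n[2] + (ix[, 2] - 1) * n[1] +
        ix[, 1]
      inletIdx <- pack$amap[lin(idx)] - 1L
      inletNbr <- pack$amap[lin(nbr)] - 1L
    }
  }
  outIdx <- integer(0); outNbr <- integer(0)
  odx <- which(flags == FLAG_OUTLET, arr.ind = TRUE)
  if (nrow(odx)) {
    nbr <- .interior_neighbor(flags, odx)
    if (any(is.na(nbr[, 1])))
      lbm_invalid_state("outlet node with no interior fluid neighbour")
    n <- pack$n
    lin <- function(ix) (ix[, 3] - 1) * n[1] * n[2] + (ix[, 2] - 1) * n[1] +
      ix[, 1]
    outIdx <- pack$amap[lin(odx)] - 1L
    outNbr <- pack$amap[lin(nbr)] - 1L
  }
  list(inletIdx = inletIdx, inletNbr = inletNbr, inletU = inletU,
       outletIdx = outIdx, outletNbr = outNbr)
}

.model_code <- function(model) {
  match(match.arg(model, c("bgk", "incompressible", "regularized", "mrt")),
        c("bgk", "incompressible", "regularized", "mrt")) - 1L
}

.unpack_field <- function(vals, pack, fill = NA_real_) {
  if (is.null(dim(vals))) {
    out <- array(fill, dim = pack$n)
    out[pack$active] <- vals
    return(out)
  }
  k <- ncol(vals)
  out <- array(fill, dim = c(pack$n, k))
  for (j in seq_len(k)) {
    sl <- array(fill, dim = pack$n)
    sl[pack$active] <- vals[, j]
    out[, , , j] <- sl
  }
  out
}

#' Run the lattice Boltzmann loop in lattice units
#'
#' Low-level driver: iterates collide -> inlet/outlet reconstruction ->
#' stream (with halfway bounce-back) on a packed geometry until the
#' relative L2 change of the velocity field over a `check_every`-step window
#' drops below `tol`, or `max_steps` is reached. All quantities are lattice
#' units; use [run_simulation()] for the physical-unit front end.
#'
#' @param geom an `lbm_geometry`.
#' @param params a [collision_params()].
#' @param model collision model name.
#' @param inlet optional [inlet_spec()] (lattice units).
#' @param rho_ref outlet reference density.
#' @param body_force constant force density 3-vector (lattice units).
#' @param multiphase optional [shan_chen_params()] enabling Shan-Chen
#'   forcing.
#' @param f_init initial populations: `NULL` (equilibrium at rest,
#'   `rho_init`), an (Nx, Ny, Nz, 19) array, or a density array of grid
#'   shape (equilibrium at rest at that density).
#' @param rho_init scalar initial density when `f_init` is `NULL`.
#' @param max_steps step budget.
#' @param tol windowed relative L2 velocity-change tolerance; `0` disables
#'   early stopping (runs exactly `max_steps`).
#' @param check_every residual window length in steps.
#' @param ramp_steps linear inlet warm-up length (0 = no ramp).
#' @param budget record total mass and momentum (with the half-force
#'   correction) after every step.
#' @param on_divergence `"error"` aborts with a divergence condition naming
#'   the step and node; `"return"` hands back the partial state.
#' @return object of class `lbm_state`: full-grid arrays `f`, `rho`, `u`
#'   (lattice units, `NA` on solid nodes), the geometry, run metadata,
#'   `residuals`, and a `status` of `"converged"`, `"max_steps"` or
#'   `"diverged"`.
#' @export
run_lbm <- function(geom, params, model = "bgk", inlet = NULL, rho_ref = 1,
                    body_force = c(0, 0, 0), multiphase = NULL,
                    f_init = NULL, rho_init = 1, max_steps = 10000,
                    tol = 1e-6, check_every = 100, ramp_steps = 0,
                    budget = FALSE, on_divergence = c("error", "return")) {
  on_divergence <- match.arg(on_divergence)
  lattice <- lattice_d3q19()
  pack <- .pack_geometry(geom, lattice)
  bnd <- .pack_boundaries(pack, geom, inlet)
  mcode <- .model_code(model)
  basis <- mrt_matrix(lattice)

  if (is.null(f_init)) {
    fp <- matrix(rep(lattice$w * rho_init, each = pack$na), pack$na, 19)
  } else if (length(dim(f_init)) == 4L) {
    fm <- f_init
    dim(fm) <- c(prod(pack$n), 19)
    fp <- fm[pack$active, , drop = FALSE]
  } else if (length(dim(f_init)) == 3L) {
    rhov <- f_init[pack$active]
    fp <- equilibrium_bgk(rhov, matrix(0, pack$na, 3), lattice)
  } else stop("f_init must be a population or density array")

  sc <- multiphase
  res <- lbm_run_cpp(fp, pack$src, integer(pack$na), lattice$e, lattice$w,
                     lattice$opp - 1L, mcode, params$tau, params$rho0,
                     basis$M, basis$Minv, params$mrt_rates,
                     bnd$inletIdx, bnd$inletU, bnd$inletNbr,
                     bnd$outletIdx, bnd$outletNbr, rho_ref,
                     as.numeric(body_force),
                     !is.null(sc), if (is.null(sc)) 0 else sc$G,
                     if (is.null(sc)) 1 else sc$rho0,
                     if (is.null(sc)) TRUE else sc$weighted,
                     if (is.null(sc)) 0 else sc$psi_wall,
                     as.integer(max_steps), as.integer(check_every), tol,
                     as.integer(ramp_steps), budget)
  if (res$diverged && on_divergence == "error")
    lbm_divergence(sprintf("simulation diverged at step %d (active node %d)",
                           res$diverge_step, res$diverge_node),
                   node = res$diverge_node)
  status <- if (res$diverged) "diverged" else if (res$converged)
    "converged" else "max_steps"
  fm <- matrix(NA_real_, prod(pack$n), 19)
  fm[pack$active, ] <- res$f
  dim(fm) <- c(pack$n, 19)
  structure(list(f = fm, rho = .unpack_field(res$rho, pack),
                 u = .unpack_field(res$u, pack),
                 geom = geom, model = model, params = params,
                 inlet = inlet, rho_ref = rho_ref,
                 steps = res$steps, residuals = res$residuals,
                 status = status, converged = res$converged,
                 budget = if (budget) res$budget else NULL),
            class = "lbm_state")
}

#' @export
print.lbm_state <- function(x, ...) {
  cat(sprintf("lbm_state: model %s, %d steps, status %s\n", x$model,
              x$steps, x$status))
  if (length(x$residuals))
    cat(sprintf("  final residual %.3g\n",
                x$residuals[length(x$residuals)]))
  invisible(x)
}

#' Simulation configuration in physical units
#'
#' Collects everything one run needs. Physical quantities are SI; the
#' lattice system is derived internally through [unit_system()]. The
#' configuration (including the seed for multiphase initial noise) fully
#' determines the run: identical configurations reproduce bit-identical
#' results.
#'
#' @param geometry an `lbm_geometry`, a [bifurcation_spec()] (voxelized at
#'   `dx`), or a path to an STL file.
#' @param model collision model name.
#' @param dx,dt discrete space interval (m) and time step (s).
#' @param rho_phys,nu_phys blood density (kg/m^3) and kinematic viscosity
#'   (m^2/s).
#' @param u_avg mean inlet speed (m/s).
#' @param rho_ref outlet lattice density (zero gauge pressure).
#' @param multiphase logical toggle for Shan-Chen forcing.
#' @param G,sc_rho0 Shan-Chen amplitude and EOS reference density.
#' @param noise_amplitude initial density perturbation amplitude
#'   (multiphase).
#' @param seed RNG seed for the initial perturbation.
#' @param max_steps,tol,check_every,ramp_steps driver controls, see
#'   [run_lbm()].
#' @return object of class `run_config`.
#' @export
run_config <- function(geometry, model = "bgk", dx, dt, rho_phys = 1060,
                       nu_phys = 3.7037e-6, u_avg = 0.1, rho_ref = 1,
                       multiphase = FALSE, G = -5, sc_rho0 = 1,
                       noise_amplitude = 0.01, seed = 1,
                       max_steps = 20000, tol = 1e-6, check_every = 100,
                       ramp_steps = 1000) {
  model <- match.arg(model, c("bgk", "incompressible", "regularized", "mrt"))
  sys <- unit_system(dx, dt, rho_phys, nu_phys)
  tau <- lattice_tau(sys)
  if (tau <= 0.5) lbm_invalid_state("derived tau must exceed 0.5")
  u_lb <- to_lattice(u_avg, "velocity", sys)
  if (u_lb > 0.1)
    warning(sprintf("lattice inlet speed %.4f exceeds 0.1: noticeable compressibility error", u_lb))
  structure(list(geometry = geometry, model = model, sys = sys, tau = tau,
                 u_avg = u_avg, rho_ref = rho_ref, multiphase = multiphase,
                 G = G, sc_rho0 = sc_rho0, noise_amplitude = noise_amplitude,
                 seed = seed, max_steps = max_steps, tol = tol,
                 check_every = check_every, ramp_steps = ramp_steps),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file holds the arguments of [run_config()] by name; `geometry` may be
#' `"bifurcation"` (parametric defaults, optionally refined by a
#' `bifurcation:` block) or an STL path.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- y$geometry
  if (identical(geom, "bifurcation") || is.null(geom)) {
    bs <- do.call(bifurcation_spec, if (is.null(y$bifurcation)) list() else
      y$bifurcation)
    geom <- bs
  }
  args <- y[intersect(names(y), names(formals(run_config)))]
  args$geometry <- geom
  do.call(run_config, args)
}

#' Run a configured simulation
#'
#' Voxelizes the geometry if needed, converts the physical boundary values
#' to lattice units, runs the collide-boundary-stream loop to convergence
#' and returns the final state (an `lbm_state` carrying the unit system, so
#' post-processing can report Pa and m/s).
#'
#' @param cfg a [run_config()].
#' @param ... overrides passed to [run_lbm()] (e.g. `budget = TRUE`).
#' @return an `lbm_state` with the `unit_system` attached as `$sys`.
#' @export
run_simulation <- function(cfg, ...) {
  stopifnot(inherits(cfg, "run_config"))
  sys <- cfg$sys
  geom <- cfg$geometry
  if (inherits(geom, "bifurcation_spec"))
    geom <- voxelize(generate_bifurcation_aneurysm(geom), dx = sys$dx)
  else if (is.character(geom))
    geom <- voxelize(read_stl(geom), dx = sys$dx)
  stopifnot(inherits(geom, "lbm_geometry"))

  inlet <- NULL
  if (any(geom$flags == FLAG_INLET)) {
    im <- geom$meta$inlet
    idx <- which(geom$flags == FLAG_INLET, arr.ind = TRUE)
    axis <- if (!is.null(im)) im$axis else 3L
    tv <- setdiff(1:3, axis)
    center <- if (!is.null(im))
      (im$center[tv] - geom$origin[tv]) / geom$dx + 1
    else colMeans(idx[, tv, drop = FALSE])
    R <- if (!is.null(im)) im$R / geom$dx else
      max(sqrt((idx[, tv[1]] - center[1])^2 + (idx[, tv[2]] - center[2])^2)) + 0.5
    inlet <- inlet_spec(axis, center, R,
                        to_lattice(cfg$u_avg, "velocity", sys))
  }
  params <- collision_params(cfg$tau)
  sc <- NULL
  f_init <- NULL
  if (cfg$multiphase) {
    sc <- shan_chen_params(cfg$G, cfg$sc_rho0)
    set.seed(cfg$seed)
    rho <- array(1 + cfg$noise_amplitude * (2 * stats::runif(prod(dim(geom$flags))) - 1),
                 dim = dim(geom$flags))
    f_init <- rho
  }
  st <- run_lbm(geom, params, model = cfg$model, inlet = inlet,
                rho_ref = cfg$rho_ref, multiphase = sc, f_init = f_init,
                max_steps = cfg$max_steps, tol = cfg$tol,
                check_every = cfg$check_every, ramp_steps = cfg$ramp_steps,
                ...)
  st$sys <- sys
  st
}

# ---------------------------------------------------------------------------
# Pure-R reference step, used to cross-check the C++ kernel on small grids.
# Mirrors the kernel exactly: collide -> inlet/outlet reconstruction ->
# pull streaming with halfway bounce-back.
.reference_step <- function(fp, pack, bnd, params, model = "bgk",
                            rho_ref = 1, body_force = c(0, 0, 0),
                            lattice = lattice_d3q19()) {
  collide <- collision_operator(model)
  if (any(body_force != 0)) {
    stopifnot(model == "bgk")   # forced reference path kept minimal
    mom <- macroscopic_moments(fp, lattice = lattice)
    ueq <- mom$u + params$tau * matrix(body_force, pack$na, 3, byrow = TRUE) /
      mom$rho
    feq <- equilibrium_bgk(mom$rho, ueq, lattice)
    fpost <- fp - params$omega * (fp - feq)
  } else {
    fpost <- collide(fp, params, lattice)
  }
  recon <- function(fpost, idx0, nbr0, rho_t, u_t) {
    nb <- nbr0 + 1L
    mom <- macroscopic_moments(fpost[nb, , drop = FALSE], model = model,
                               rho0 = params$rho0, lattice = lattice)
    feq_at <- function(rho, u)
      if (model == "incompressible")
        equilibrium_incompressible(rho, params$rho0, u, lattice)
      else equilibrium_bgk(rho, u, lattice)
    fneq <- fpost[nb, , drop = FALSE] - feq_at(mom$rho, mom$u)
    out <- feq_at(rho_t, u_t) + fneq
    if (is.null(dim(out))) out <- matrix(out, nrow = 1)
    fpost[idx0 + 1L, ] <- out
    fpost
  }
  if (length(bnd$inletIdx)) {
    rho_loc <- rowSums(fpost[bnd$inletNbr + 1L, , drop = FALSE])
    fpost <- recon(fpost, bnd$inletIdx, bnd$inletNbr, rho_loc, bnd$inletU)
  }
  if (length(bnd$outletIdx)) {
    mom <- macroscopic_moments(fpost[bnd$outletNbr + 1L, , drop = FALSE],
                               model = model, rho0 = params$rho0,
                               lattice = lattice)
    fpost <- recon(fpost, bnd$outletIdx, bnd$outletNbr,
                   rep(rho_ref, length(bnd$outletIdx)), mom$u)
  }
  fnew <- fpost
  for (i in 1:19) {
    s <- pack$src[, i]
    hit <- s >= 0
    fnew[hit, i] <- fpost[s[hit] + 1L, i]
    fnew[!hit, i] <- fpost[!hit, lattice$opp[i]]
  }
  fnew
}

# ---------------------------------------------------------------------------
# File output

#' Write fields as a legacy VTK structured-points file
#'
#' ASCII legacy VTK with the grid origin and spacing in physical meters and
#' units embedded in the field names, readable by ParaView and by
#' [read_vtk()].
#'
#' @param fields named list: 3D arrays become SCALARS, 4D arrays with a
#'   trailing extent of 3 become VECTORS. `NA` (solid) entries are written
#'   as 0.
#' @param path output file.
#' @param dx grid spacing (m).
#' @param origin grid origin (m).
#' @return the path, invisibly.
#' @export
write_vtk <- function(fields, path, dx = 1, origin = c(0, 0, 0)) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  n <- dim(fields[[1]])[1:3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hemolbm fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %.17g %.17g %.17g", origin[1], origin[2],
                       origin[3]),
               sprintf("SPACING %.17g %.17g %.17g", dx, dx, dx),
               sprintf("POINT_DATA %d", prod(n))), con)
  for (nm in names(fields)) {
    a <- fields[[nm]]
    a[is.na(a)] <- 0
    if (length(dim(a)) == 3L) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", as.vector(a)), con)
    } else if (length(dim(a)) == 4L && dim(a)[4] == 3L) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      m <- cbind(as.vector(a[, , , 1]), as.vector(a[, , , 2]),
                 as.vector(a[, , , 3]))
      writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
    } else stop("field '", nm, "' must be a 3D scalar or (.,.,.,3) vector array")
  }
  invisible(path)
}

#' Read back a VTK file written by [write_vtk()]
#'
#' @param path file path.
#' @return list with `fields` (named arrays), `dx`, `origin`, `dims`.
#' @export
read_vtk <- function(path) {
  txt <- readLines(path)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", txt, value = TRUE),
                              "\\s+")[[1]][2:4])
  origin <- as.numeric(strsplit(grep("^ORIGIN", txt, value = TRUE),
                                "\\s+")[[1]][2:4])
  dx <- as.numeric(strsplit(grep("^SPACING", txt, value = TRUE),
                            "\\s+")[[1]][2])
  npt <- prod(dims)
  fields <- list()
  i <- grep("^POINT_DATA", txt) + 1L
  while (i <= length(txt)) {
    hdr <- strsplit(txt[i], "\\s+")[[1]]
    if (hdr[1] == "SCALARS") {
      vals <- as.numeric(txt[(i + 2):(i + 1 + npt)])
      fields[[hdr[2]]] <- array(vals, dim = dims)
      i <- i + 2L + npt
    } else if (hdr[1] == "VECTORS") {
      rows <- txt[(i + 1):(i + npt)]
      m <- matrix(as.numeric(unlist(strsplit(rows, "\\s+"))), ncol = 3,
                  byrow = TRUE)
      a <- array(NA_real_, dim = c(dims, 3))
      for (j in 1:3) a[, , , j] <- array(m[, j], dim = dims)
      fields[[hdr[2]]] <- a
      i <- i + 1L + npt
    } else i <- i + 1L
  }
  list(fields = fields, dx = dx, origin = origin, dims = dims)
}

#' Write probe samples as CSV
#'
#' One row per probe with its index, physical position, pressure and
#' velocity magnitude. When `reference` is given (per-model comparison), a
#' percentage-difference and an absolute-change column computed by
#' [compare_fields()] are appended.
#'
#' @param samples data frame from [extract_probes()].
#' @param path output file.
#' @param reference optional numeric vector of reference velocity magnitudes
#'   of the same length.
#' @return the path, invisibly.
#' @export
write_probe_csv <- function(samples, path, reference = NULL) {
  stopifnot(nrow(samples) >= 1)
  if (!is.null(reference)) {
    cmp <- compare_fields(samples$speed_m_s, reference)
    samples$percent_diff <- cmp$percent
    samples$abs_change <- cmp$abs_change
  }
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
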