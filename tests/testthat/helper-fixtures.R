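# Shared fixtures. Long steady-state solutions are computed once per test
# session and cached so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# random but physically valid populations: equilibrium at mildly perturbed
# density/velocity plus a small non-equilibrium admixture
random_valid_f <- function(n = 25, seed = 1) {
  set.seed(seed)
  rho <- runif(n, 0.9, 1.1)
  u <- matrix(runif(3 * n, -0.05, 0.05), n, 3)
  feq <- equilibrium_bgk(rho, u)
  feq * (1 + 0.05 * matrix(runif(n * 19, -1, 1), n, 19))
}

# Body-force-driven periodic pipe, the Poiseuille validation fixture:
# D ~ 48 nodes, tau = 0.8, mean speed targeted at the paper's lattice inlet
# speed 0.0319361.
pipe_fixture <- function(model) {
  key <- paste0("pipe_", model)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  R <- 24.12
  tau <- 0.8
  nu <- (tau - 0.5) / 3
  gf <- 8 * nu * 0.0319361 / R^2
  geom <- pipe_geometry(R, nz = 1)
  st <- run_lbm(geom, collision_params(tau), model = model,
                body_force = c(0, 0, gf), max_steps = 60000, tol = 1e-8,
                check_every = 200)
  c0 <- geom$meta$center
  uz <- st$u[, , 1, 3]
  idx <- which(!is.na(uz), arr.ind = TRUE)
  r <- sqrt((idx[, 1] - c0[1])^2 + (idx[, 2] - c0[2])^2)
  out <- list(state = st, geom = geom, R = R, tau = tau, nu = nu, g = gf,
              r = r, idx = idx, u = uz[idx],
              u_analytic = gf * R^2 / (4 * nu) * (1 - (r / R)^2),
              normals = function(ix) cbind(ix[, 1] - c0[1],
                                           ix[, 2] - c0[2], 0))
  .fixtures[[key]] <- out
  out
}

# Reduced-scale bifurcation-aneurysm steady flow (the paper's lattice
# viscosity, MRT collision, ~80 cells across the 0.05589 m reference length).
aneurysm_fixture <- function() {
  if (!is.null(.fixtures$aneurysm)) return(.fixtures$aneurysm)
  dx <- 0.05589 / 80
  dt <- 0.08 * dx / 0.1           # inlet average 0.1 m/s -> 0.08 lattice
  nu_eff <- 0.00755492 * dx^2 / dt
  cfg <- run_config(bifurcation_spec(), model = "mrt", dx = dx, dt = dt,
                    nu_phys = nu_eff, u_avg = 0.1, max_steps = 60000,
                    tol = 1e-8, ramp_steps = 3000)
  st <- run_simulation(cfg)
  .fixtures$aneurysm <- st
  st
}

rel_l2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  sqrt(sum((a[ok] - b[ok])^2) / sum(b[ok]^2))
}
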