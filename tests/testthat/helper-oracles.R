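# Independent oracles, kept deliberately free of the package's D3Q19 code
# paths.

# Viscosity from the exponential decay of a periodic shear wave
# u_y(x, t) = A exp(-nu k^2 t) sin(k x), measured by sine projection between
# two run lengths (skipping the initial non-equilibrium transient).
shear_wave_nu <- function(model, tau, L = 64, t0 = 100, t1 = 500,
                          amplitude = 0.005) {
  geom <- box_geometry(L, 1, 1)
  x <- 0:(L - 1)
  k <- 2 * pi / L
  f0 <- array(equilibrium_bgk(rep(1, L), cbind(0, amplitude * sin(k * x), 0)),
              dim = c(L, 1, 1, 19))
  amp <- function(st) 2 / L * sum(st$u[, 1, 1, 2] * sin(k * x))
  a0 <- amp(run_lbm(geom, collision_params(tau), model = model, f_init = f0,
                    max_steps = t0, tol = 0, check_every = 0))
  a1 <- amp(run_lbm(geom, collision_params(tau), model = model, f_init = f0,
                    max_steps = t1, tol = 0, check_every = 0))
  -log(a1 / a0) / (k^2 * (t1 - t0))
}

# Brute-force 1D lattice (D1Q3) Shan-Chen flat-interface equilibrium.
# Same speed of sound (1/3) and the same 1D projection of the weighted
# nearest-neighbour force stencil (coefficient 1/6), but an entirely
# separate three-velocity implementation.
d1q3_coexistence <- function(G, tau = 1, Nx = 64, steps = 20000, rho0 = 1,
                             rho_hi = 1.8, rho_lo = 0.25) {
  w <- c(2 / 3, 1 / 6, 1 / 6)
  ev <- c(0, 1, -1)
  rho <- rep(rho_lo, Nx)
  rho[(Nx / 4):(3 * Nx / 4)] <- rho_hi
  feq <- function(r, u)
    sapply(1:3, function(s)
      w[s] * r * (1 + 3 * ev[s] * u + 4.5 * (ev[s] * u)^2 - 1.5 * u^2))
  f <- feq(rho, 0)
  ip <- c(2:Nx, 1)
  im <- c(Nx, 1:(Nx - 1))
  for (t in seq_len(steps)) {
    r <- rowSums(f)
    m <- as.vector(f %*% ev)
    psi <- rho0 * (1 - exp(-r / rho0))
    Fx <- -G * psi * (1 / 6) * (psi[ip] - psi[im])
    u <- m / r
    fe <- feq(r, u)
    fs <- feq(r, u + tau * Fx / r)
    f <- f - (f - fe) / tau + (fs - fe) / tau
    f <- cbind(f[, 1], f[im, 2], f[ip, 3])
  }
  r <- rowSums(f)
  c(liquid = max(r), vapor = min(r))
}
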