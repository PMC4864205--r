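test_that("the effective mass follows the exponential equation of state", {
  sc <- shan_chen_params(G = -5, rho0 = 1)
  expect_identical(effective_mass_psi(0, sc), 0)
  expect_equal(effective_mass_psi(1, sc), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(effective_mass_psi(1, sc), 0.6321206, tolerance = 1e-7)
  expect_lt(abs(effective_mass_psi(50, sc) - 1), 1e-12)  # bounded by rho0
  # monotone increasing
  r <- seq(0, 5, by = 0.1)
  expect_true(all(diff(effective_mass_psi(r, sc)) > 0))
  expect_error(effective_mass_psi(-0.1, sc), class = "lbm_invalid_state")
  # rho0 scales the asymptote
  sc2 <- shan_chen_params(G = -5, rho0 = 2)
  expect_equal(effective_mass_psi(2, sc2), 2 * (1 - exp(-1)),
               tolerance = 1e-12)
})

test_that("the interaction force vanishes identically on uniform density", {
  sc <- shan_chen_params(G = -5)
  F <- interaction_force(array(0.8, dim = c(7, 6, 5)), sc)
  expect_identical(max(abs(F)), 0)
})

test_that("global momentum from the force sums to zero on periodic boxes", {
  sc <- shan_chen_params(G = -5)
  set.seed(9)
  rho <- array(0.7 + 0.2 * runif(8^3), dim = c(8, 8, 8))
  F <- interaction_force(rho, sc)
  for (a in 1:3) expect_lt(abs(sum(F[, , , a])), 1e-12)
  # same for the unweighted "corral" variant
  Fu <- interaction_force(rho, shan_chen_params(G = -5, weighted = FALSE))
  for (a in 1:3) expect_lt(abs(sum(Fu[, , , a])), 1e-12)
})

test_that("a density step yields mirror-opposite interface forces", {
  sc <- shan_chen_params(G = -5)
  nx <- 12
  # symmetric bump: the two interfaces are mirror images, so the force
  # pattern is exactly antisymmetric about the bump center
  rho <- array(0.3, dim = c(nx, 3, 3))
  rho[4:9, , ] <- 1.5
  F <- interaction_force(rho, sc)
  fx <- F[, 2, 2, 1]
  expect_equal(fx, -fx[c(12:1)], tolerance = 1e-14)  # mirror about 6.5
  expect_equal(sum(fx), 0, tolerance = 1e-14)
  # only nodes adjacent to an interface feel a force
  expect_true(all(fx[c(1, 2, 6, 7, 11, 12)] == 0))
  expect_true(all(fx[c(3, 4, 9, 10)] != 0))
})

test_that("the velocity shift reports the averaged momentum rho u + F/2", {
  p <- collision_params(0.9)
  f <- equilibrium_bgk(1.1, c(0.02, 0, 0))
  out0 <- apply_force_shift(f, c(0, 0, 0), p)
  expect_equal(out0$u_eq, matrix(c(0.02, 0, 0), 1), tolerance = 1e-13)
  expect_equal(out0$momentum, matrix(1.1 * c(0.02, 0, 0), 1),
               tolerance = 1e-13)
  Fv <- c(1e-3, 0, -2e-3)
  out <- apply_force_shift(f, Fv, p)
  expect_equal(out$u_eq, matrix(c(0.02, 0, 0) + 0.9 * Fv / 1.1, 1),
               tolerance = 1e-13)
  expect_equal(out$momentum, matrix(1.1 * c(0.02, 0, 0) + Fv / 2, 1),
               tolerance = 1e-13)
})

test_that("a constant body force accelerates a periodic box uniformly", {
  g <- box_geometry(6)
  na <- 6^3
  gf <- 2e-5
  st <- run_lbm(g, collision_params(0.8), body_force = c(gf, 0, 0),
                max_steps = 40, tol = 0, check_every = 0, budget = TRUE)
  # reported momentum (with the half-force) grows by F_total per step
  px <- st$budget$px
  expect_equal(diff(px), rep(na * gf, 39), tolerance = 1e-10)
  expect_equal(px[1], na * gf * 1.5, tolerance = 1e-10)  # one kick + F/2
})

test_that("mass and global momentum are conserved under Shan-Chen forcing", {
  sc <- shan_chen_params(G = -5)
  set.seed(13)
  rho0 <- array(0.693 * (1 + 0.05 * (2 * runif(10^3) - 1)), dim = c(10, 10, 10))
  st <- run_lbm(box_geometry(10), collision_params(1), multiphase = sc,
                f_init = rho0, max_steps = 200, tol = 0, check_every = 0,
                budget = TRUE)
  m0 <- sum(rho0)
  expect_equal(st$budget$mass / m0, rep(1, 200), tolerance = 1e-12)
  expect_lt(max(abs(st$budget$px)), 1e-9)
  expect_lt(max(abs(st$budget$py)), 1e-9)
  expect_lt(max(abs(st$budget$pz)), 1e-9)
})

test_that("phase separation occurs beyond the critical G for one sign only", {
  set.seed(7)
  rho0 <- array(0.693 * (1 + 0.05 * (2 * runif(16^3) - 1)), dim = c(16, 16, 16))
  spread <- function(G) {
    st <- run_lbm(box_geometry(16), collision_params(1),
                  multiphase = shan_chen_params(G), f_init = rho0,
                  max_steps = 3000, tol = 0, check_every = 0,
                  on_divergence = "return")
    diff(range(st$rho))
  }
  s_att <- spread(-5)    # beyond the critical magnitude |G| = 4
  s_rep <- spread(5)
  expect_gt(s_att, 0.5)          # two distinct phases
  expect_lt(s_rep, 0.05)         # relaxes back to uniform
  # below the critical magnitude the perturbation decays for both signs
  expect_lt(spread(-3), 0.05)
})

test_that("flat-interface coexistence matches the 1D brute-force oracle", {
  sc <- shan_chen_params(G = -5)
  nx <- 64
  rho0 <- array(0.25, dim = c(nx, 2, 2))
  rho0[(nx / 4):(3 * nx / 4), , ] <- 1.8
  st <- run_lbm(box_geometry(nx, 2, 2), collision_params(1),
                multiphase = sc, f_init = rho0, max_steps = 20000,
                tol = 1e-10, check_every = 100)
  liq <- max(st$rho)
  vap <- min(st$rho)
  oracle <- d1q3_coexistence(G = -5)
  expect_lt(abs(liq / oracle["liquid"] - 1), 0.01)
  expect_lt(abs(vap / oracle["vapor"] - 1), 0.01)
})
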