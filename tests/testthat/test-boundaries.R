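lat <- lattice_d3q19()

test_that("fluid at rest beside walls is unchanged by a full step", {
  g <- channel_geometry(ny = 8, nx = 3, nz = 3)
  st <- run_lbm(g, collision_params(0.8), max_steps = 5, tol = 0,
                check_every = 0)
  fl <- g$flags
  fm <- st$f
  w_ref <- array(rep(lat$w, each = prod(dim(fl))), dim = c(dim(fl), 19))
  open <- array(rep(fl != 1L, 19), dim = c(dim(fl), 19))
  expect_equal(fm[open], w_ref[open], tolerance = 1e-14)
})

test_that("a population aimed at a wall returns reversed and unchanged", {
  n <- c(3, 5, 3)
  fl <- array(0L, dim = n)
  fl[, 5, ] <- 1L                      # wall at the +y face
  f <- array(0, dim = c(n, 19))
  f[2, 4, 2, 4] <- 0.7                 # direction 4 = (0, 1, 0), into the wall
  fs <- apply_bounce_back(stream_step(f), fl)
  expect_equal(fs[2, 4, 2, lat$opp[4]], 0.7)   # reflected at the origin node
  # nothing survives inside the wall nodes as far as fluid dynamics goes:
  # the reflected population is the only nonzero value on open nodes
  open <- array(rep(fl != 1L, 19), dim = c(n, 19))
  expect_equal(sum(fs[open] != 0), 1L)
})

test_that("closed domains conserve mass to round-off every step", {
  n <- c(6, 6, 6)
  fl <- array(1L, dim = n)
  fl[2:5, 2:5, 2:5] <- 0L              # sealed box of fluid
  g <- structure(list(flags = fl, dx = 1, origin = c(0, 0, 0),
                      periodic = c(FALSE, FALSE, FALSE), meta = list()),
                 class = "lbm_geometry")
  set.seed(31)
  rho0 <- array(runif(prod(n), 0.9, 1.1), dim = n)
  st <- run_lbm(g, collision_params(0.6), f_init = rho0, max_steps = 50,
                tol = 0, check_every = 0, budget = TRUE)
  m0 <- sum(rho0[fl == 0L])
  expect_equal(st$budget$mass / m0, rep(1, 50), tolerance = 1e-13)
})

test_that("body-force plane Poiseuille matches the parabola at 20 nodes", {
  g <- channel_geometry(ny = 22, nx = 3, nz = 3)   # 20 fluid layers
  tau <- 0.9
  nu <- (tau - 0.5) / 3
  gf <- 1e-5
  st <- run_lbm(g, collision_params(tau), body_force = c(0, 0, gf),
                max_steps = 20000, tol = 1e-10, check_every = 100)
  expect_identical(st$status, "converged")
  uz <- st$u[2, 2:21, 2, 3]
  yh <- (2:21) - 1.5                   # distance from the lower no-slip plane
  uan <- gf / (2 * nu) * yh * (20 - yh)
  expect_lt(rel_l2(uz, uan), 0.02)
})

test_that("the imposed inlet profile has the right centreline and average", {
  sp <- inlet_spec(axis = 3, center = c(0, 0), R = 10.5, u_avg = 0.05)
  expect_equal(inlet_profile(0, sp), 0.1)          # centreline = 2 u_avg
  expect_equal(inlet_profile(10.5, sp), 0)         # zero at the rim
  expect_equal(inlet_profile(12, sp), 0)           # beyond the rim: wall
  # discrete average over a disc of >= 20 nodes diameter within 2%
  xy <- expand.grid(i = -12:12, j = -12:12)
  r <- sqrt(xy$i^2 + xy$j^2)
  r <- r[r <= 10.5]
  expect_lt(abs(mean(inlet_profile(r, sp)) / 0.05 - 1), 0.02)
  expect_error(inlet_spec(3, c(0, 0), R = -1, u_avg = 1),
               class = "lbm_invalid_state")
})

test_that("inlet reconstruction imposes the parabolic velocity", {
  g <- pipe_flow_geometry(R = 6.2, nz = 10)
  c0 <- g$meta$center
  sp <- inlet_spec(axis = 3, center = c0, R = 6.2, u_avg = 0.04)
  f <- array(rep(lat$w, each = prod(dim(g$flags))),
             dim = c(dim(g$flags), 19))
  f2 <- apply_inlet_parabolic(f, g$flags, sp)
  idx <- which(g$flags == 2L, arr.ind = TRUE)
  fm <- f2
  dim(fm) <- c(prod(dim(g$flags)), 19)
  lin <- (idx[, 3] - 1) * prod(dim(g$flags)[1:2]) +
    (idx[, 2] - 1) * dim(g$flags)[1] + idx[, 1]
  m <- macroscopic_moments(fm[lin, ])
  r <- sqrt((idx[, 1] - c0[1])^2 + (idx[, 2] - c0[2])^2)
  expect_equal(m$u[, 3], inlet_profile(r, sp), tolerance = 1e-12)
  expect_equal(m$u[, 1], rep(0, nrow(idx)), tolerance = 1e-13)
})

test_that("outlet reconstruction pins the density exactly", {
  g <- pipe_flow_geometry(R = 6.2, nz = 10)
  n <- dim(g$flags)
  set.seed(5)
  rho0 <- array(runif(prod(n), 0.95, 1.05), dim = n)
  f <- array(equilibrium_bgk(as.vector(rho0), matrix(0, prod(n), 3)),
             dim = c(n, 19))
  f2 <- apply_outlet_pressure(f, g$flags, rho_ref = 1)
  idx <- which(g$flags == 3L, arr.ind = TRUE)
  fm <- f2
  dim(fm) <- c(prod(n), 19)
  lin <- (idx[, 3] - 1) * prod(n[1:2]) + (idx[, 2] - 1) * n[1] + idx[, 1]
  expect_equal(rowSums(fm[lin, ]), rep(1, nrow(idx)), tolerance = 1e-13)
  # a uniform state at rho_ref, u = 0 is left untouched
  fu <- array(rep(lat$w, each = prod(n)), dim = c(n, 19))
  expect_equal(apply_outlet_pressure(fu, g$flags, rho_ref = 1), fu,
               tolerance = 1e-14)
})

test_that("a velocity-inlet/pressure-outlet pipe obeys Hagen-Poiseuille", {
  tau <- 0.8
  nu <- (tau - 0.5) / 3
  R <- 14.2
  g <- pipe_flow_geometry(R = R, nz = 50)
  sp <- inlet_spec(axis = 3, center = g$meta$center, R = R, u_avg = 0.01)
  st <- run_lbm(g, collision_params(tau), inlet = sp, max_steps = 30000,
                tol = 1e-9, check_every = 100, ramp_steps = 500)
  expect_identical(st$status, "converged")
  c0 <- g$meta$center
  p <- (st$rho[c0[1], c0[2], ] - 1) / 3
  zr <- 10:45
  dpdz <- unname(stats::coef(stats::lm(p[zr] ~ zr))[2])
  uavg <- mean(st$u[, , 28, 3], na.rm = TRUE)
  expect_lt(abs(dpdz / (-8 * nu * uavg / R^2) - 1), 0.05)
  # gauge pressure runs out at the outlet: the last fluid layer sits within
  # a few node-gradients of zero
  expect_lt(abs(p[49]), 5 * abs(dpdz))
  # steady state is initialization-independent
  st2 <- run_lbm(g, collision_params(tau), inlet = sp, f_init = st$f,
                 max_steps = 30000, tol = 1e-9, check_every = 100)
  expect_lt(rel_l2(st2$u, st$u), 0.001)
})
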