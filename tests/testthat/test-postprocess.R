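lat <- lattice_d3q19()

# hand-built lbm_state over an all-fluid periodic box with a prescribed
# macroscopic field (populations at equilibrium)
synthetic_state <- function(rho, u, geom, model = "bgk", tau = 0.8) {
  n <- dim(geom$flags)
  f <- array(equilibrium_bgk(as.vector(rho), u), dim = c(n, 19))
  structure(list(f = f, rho = rho,
                 u = array(u, dim = c(n, 3)), geom = geom, model = model,
                 params = collision_params(tau), steps = 0L,
                 residuals = numeric(0), status = "converged",
                 converged = TRUE, sys = NULL),
            class = "lbm_state")
}

test_that("pressure is zero at the reference density and scales correctly", {
  g <- box_geometry(4)
  rho <- array(1, dim = c(4, 4, 4))
  st <- synthetic_state(rho, matrix(0, 64, 3), g)
  expect_true(all(compute_pressure(st, rho_ref = 1) == 0))
  sys <- unit_system(dx = 1e-4, dt = 1e-5, rho_phys = 1060,
                     nu_phys = 3.7037e-6)
  rho2 <- array(1.03, dim = c(4, 4, 4))
  st2 <- synthetic_state(rho2, matrix(0, 64, 3), g)
  p <- compute_pressure(st2, sys = sys, rho_ref = 1)
  expect_equal(p[1, 1, 1], 0.01 * 1060 * (1e-4 / 1e-5)^2, tolerance = 1e-10)
})

test_that("WSS is zero on every wall cell of a resting fluid", {
  g <- pipe_geometry(5.2, nz = 4)
  st <- run_lbm(g, collision_params(0.8), max_steps = 3, tol = 0,
                check_every = 0)
  w <- compute_wss(st)
  expect_gt(nrow(w), 0)
  expect_true(all(w$wss < 1e-14))
  expect_true(all(abs(sqrt(w$nx^2 + w$ny^2 + w$nz^2) - 1) < 1e-12))
})

test_that("pipe WSS matches the Poiseuille wall shear within 10 percent", {
  fx <- pipe_fixture("bgk")
  w <- compute_wss(fx$state, normals = fx$normals)
  u_avg <- mean(fx$u)
  wss_an <- 4 * fx$nu * 1 * u_avg / fx$R      # 4 mu u_avg / R, rho = 1
  expect_lt(abs(mean(w$wss) / wss_an - 1), 0.10)
  # the same check expressed in physical units: attach the blood unit system
  sys <- unit_system(dx = 0.0063 / (2 * fx$R), dt = 1e-4, rho_phys = 1060,
                     nu_phys = fx$nu * (0.0063 / (2 * fx$R))^2 / 1e-4)
  fx$state$sys <- sys
  wp <- compute_wss(fx$state, normals = fx$normals)
  mu <- 1060 * sys$nu_phys
  wss_pa <- 4 * mu * to_physical(u_avg, "velocity", sys) / (0.0063 / 2)
  expect_lt(abs(mean(wp$wss) / wss_pa - 1), 0.10)
})

test_that("WSS is invariant under relabeling of the lattice axes", {
  fx <- pipe_fixture("bgk")
  w0 <- compute_wss(fx$state)
  # rotate the whole problem x->y->z->x and rerun
  g2 <- fx$geom
  g2$flags <- aperm(fx$geom$flags, c(3, 1, 2))
  g2$periodic <- fx$geom$periodic[c(3, 1, 2)]
  st2 <- run_lbm(g2, collision_params(fx$tau), body_force = c(fx$g, 0, 0),
                 max_steps = 60000, tol = 1e-8, check_every = 200)
  w2 <- compute_wss(st2)
  expect_equal(sort(w2$wss), sort(w0$wss), tolerance = 1e-6)
})

test_that("probes interpolate trilinearly and reject non-fluid locations", {
  g <- box_geometry(6, dx = 1)
  # linear ramp u_x = 0.01 * x-index
  n <- c(6, 6, 6)
  ij <- arrayInd(1:prod(n), n)
  u <- cbind(0.01 * (ij[, 1] - 1), 0, 0)
  st <- synthetic_state(array(1, n), u, g)
  # at a node center: that node's value
  s1 <- extract_probes(st, c(2, 3, 3))
  expect_equal(s1$ux, 0.01 * 2, tolerance = 1e-12)
  # midpoint of two nodes on a linear field: their mean
  s2 <- extract_probes(st, c(2.5, 3, 3))
  expect_equal(s2$ux, 0.01 * 2.5, tolerance = 1e-12)
  # outside-fluid probe rejected with its index
  g2 <- channel_geometry(ny = 6, nx = 6, nz = 6)
  st2 <- synthetic_state(array(1, n), u * 0, g2)
  expect_error(extract_probes(st2, rbind(c(2, 2, 2), c(2, 0.2, 2))),
               "probe 2")
})

test_that("a plane through the pipe axis shows the parabolic profile", {
  fx <- pipe_fixture("bgk")
  c0 <- fx$geom$meta$center
  sl <- extract_plane(fx$state, "zx", coord = c0[2] - 1)
  prof <- sl$speed[, 1]
  keep <- !is.na(prof)
  x <- which(keep)
  uan <- fx$g * fx$R^2 / (4 * fx$nu) * (1 - ((x - c0[1]) / fx$R)^2)
  expect_lt(rel_l2(prof[keep], uan), 0.03)
})

test_that("field comparison implements percentage and absolute change", {
  cmp <- compare_fields(c(105, 95), c(100, 100))
  expect_equal(cmp$percent, c(5, -5))
  expect_equal(cmp$abs_change, c(-5, 5))
  expect_equal(compare_fields(0.083, 0.1)$abs_change, 0.017)
  # identical fields: zero everywhere; absolute change is antisymmetric
  a <- runif(10)
  expect_true(all(compare_fields(a, a)$percent == 0))
  expect_equal(compare_fields(a, a + 1)$abs_change,
               -compare_fields(a + 1, a)$abs_change)
  # zero reference flagged and excluded from the percentage summary
  cz <- compare_fields(c(1, 2), c(0, 1))
  expect_true(is.na(cz$percent[1]))
  expect_equal(cz$summary$max_percent, 100)
})

test_that("WSS distribution statistics follow box-plot conventions", {
  s <- wss_distribution_stats(1:9, bin_width = 1, range = c(0, 10))
  expect_equal(unname(c(s$q1, s$median, s$q3)), c(3, 5, 7))
  expect_equal(s$iqr, 4)
  expect_length(s$outliers, 0)
  expect_equal(sum(s$percent), 100)
  # all cells equal: a single occupied bin at 100%, no spread
  s2 <- wss_distribution_stats(rep(1.25, 40), bin_width = 0.1,
                               range = c(0, 2.8))
  expect_equal(max(s2$percent), 100)
  expect_equal(sum(s2$percent > 0), 1L)
  expect_equal(s2$iqr, 0)
  expect_length(s2$outliers, 0)
  # an extreme point beyond 1.5 IQR is reported
  s3 <- wss_distribution_stats(c(rep(1, 10), rep(2, 10), 40),
                               bin_width = 0.5, range = c(0, 50))
  expect_true(40 %in% s3$outliers)
  expect_error(wss_distribution_stats(numeric(0)), "empty")
})

test_that("the velocity threshold mask brackets the moving fluid", {
  fx <- pipe_fixture("bgk")
  st <- fx$state
  m0 <- threshold_view(st, u_min = 0)
  # every fluid node of the forced pipe is in motion
  expect_equal(sum(m0), sum(!is.na(st$u[, , , 3])))
  mhi <- threshold_view(st, u_min = 1)
  expect_equal(sum(mhi), 0L)
  mmid <- threshold_view(st, u_min = fx$g * fx$R^2 / (8 * fx$nu))
  expect_gt(sum(mmid), 0)
  expect_lt(sum(mmid), sum(m0))
})
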