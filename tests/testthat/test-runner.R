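test_that("a uniform rest state converges immediately with zero residual", {
  g <- channel_geometry(ny = 8, nx = 3, nz = 3)
  st <- run_lbm(g, collision_params(0.8), max_steps = 1000, tol = 1e-12,
                check_every = 100)
  expect_identical(st$status, "converged")
  expect_lte(st$steps, 200)
  expect_lt(st$residuals[length(st$residuals)], 1e-12)
})

test_that("the compiled kernel reproduces the R reference step exactly", {
  pg <- hemolbm:::.pack_geometry
  pb <- hemolbm:::.pack_boundaries
  rs <- hemolbm:::.reference_step
  lat <- lattice_d3q19()
  g <- pipe_flow_geometry(R = 3.2, nz = 8)
  sp <- inlet_spec(axis = 3, center = g$meta$center, R = 3.2, u_avg = 0.05)
  pack <- pg(g)
  bnd <- pb(pack, g, sp)
  set.seed(77)
  rho <- runif(pack$na, 0.95, 1.05)
  f0 <- equilibrium_bgk(rho, matrix(runif(3 * pack$na, -0.02, 0.02),
                                    pack$na, 3))
  unpack_f <- function(st) {
    fm <- st$f
    dim(fm) <- c(prod(dim(g$flags)), 19)
    fm[pack$active, ]
  }
  f4 <- array(NA_real_, dim = c(dim(g$flags), 19))
  fm4 <- matrix(0, prod(dim(g$flags)), 19)
  fm4[pack$active, ] <- f0
  dim(fm4) <- c(dim(g$flags), 19)
  for (model in c("bgk", "incompressible", "regularized", "mrt")) {
    p <- collision_params(0.8)
    fr <- f0
    for (s in 1:3) fr <- rs(fr, pack, bnd, p, model, rho_ref = 1)
    st <- run_lbm(g, p, model = model, inlet = sp, f_init = fm4,
                  max_steps = 3, tol = 0, check_every = 0)
    expect_lt(max(abs(fr - unpack_f(st))), 1e-13, label = model)
  }
  # forced path (periodic box, BGK)
  gb <- box_geometry(5)
  packb <- pg(gb)
  bndb <- pb(packb, gb, NULL)
  p <- collision_params(0.7)
  fb <- equilibrium_bgk(rep(1, packb$na), matrix(0, packb$na, 3))
  frb <- fb
  for (s in 1:4) frb <- rs(frb, packb, bndb, p, "bgk",
                           body_force = c(1e-4, 0, -2e-4))
  stb <- run_lbm(gb, p, body_force = c(1e-4, 0, -2e-4), max_steps = 4,
                 tol = 0, check_every = 0)
  fmb <- stb$f
  dim(fmb) <- c(prod(dim(gb$flags)), 19)
  expect_lt(max(abs(frb - fmb[packb$active, ])), 1e-13)
})

test_that("divergence is reported with the offending step and node", {
  lat <- lattice_d3q19()
  g <- box_geometry(5)
  f0 <- array(rep(lat$w, each = 125), dim = c(5, 5, 5, 19))
  f0[3, 3, 3, ] <- -0.1 * lat$w          # density driven negative
  st <- run_lbm(g, collision_params(0.8), f_init = f0, max_steps = 10,
                tol = 0, check_every = 0, on_divergence = "return")
  expect_identical(st$status, "diverged")
  err <- tryCatch(
    run_lbm(g, collision_params(0.8), f_init = f0, max_steps = 10,
            tol = 0, check_every = 0),
    lbm_divergence = function(e) e)
  expect_s3_class(err, "lbm_divergence")
  expect_match(conditionMessage(err), "step")
  expect_false(is.na(err$node))
})

test_that("identical configurations reproduce bit-identical results", {
  run_once <- function() {
    cfg <- run_config(bifurcation_spec(trunk_len = 0.006,
                                       branch_len = 0.006,
                                       sac_radius = 0.002,
                                       sac_offset = c(0.001, 0.003, 0)),
                      model = "bgk", dx = 0.0004, dt = 0.0004 * 0.05 / 0.1,
                      nu_phys = 0.01 * 0.0004^2 / (0.0004 * 0.05 / 0.1),
                      u_avg = 0.1, max_steps = 400, tol = 0,
                      check_every = 100, ramp_steps = 200)
    run_simulation(cfg)
  }
  s1 <- run_once()
  s2 <- run_once()
  expect_identical(s1$f, s2$f)
  expect_identical(s1$u, s2$u)
  # and so do the files they write
  f1 <- withr::local_tempfile(fileext = ".vtk")
  f2 <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(list(rho = s1$rho, velocity = s1$u), f1, dx = s1$sys$dx)
  write_vtk(list(rho = s2$rho, velocity = s2$u), f2, dx = s2$sys$dx)
  expect_identical(readLines(f1), readLines(f2))
  # multiphase initial noise is seeded: same seed, same state
  g <- box_geometry(8)
  sc <- shan_chen_params(-5)
  noisy <- function() {
    set.seed(123)
    rho <- array(1 + 0.01 * (2 * stats::runif(8^3) - 1), dim = c(8, 8, 8))
    run_lbm(g, collision_params(1), multiphase = sc, f_init = rho,
            max_steps = 50, tol = 0, check_every = 0)
  }
  expect_identical(noisy()$f, noisy()$f)
})

test_that("VTK output roundtrips and matches plane extraction", {
  fx <- pipe_fixture("bgk")
  st <- fx$state
  path <- withr::local_tempfile(fileext = ".vtk")
  p <- compute_pressure(st, rho_ref = 1)
  write_vtk(list(density_lu = st$rho, pressure_lu = p,
                 velocity_lu = st$u), path, dx = 1, origin = c(0, 0, 0))
  back <- read_vtk(path)
  expect_equal(back$dx, 1)
  expect_equal(back$dims, dim(st$rho))
  solid <- is.na(st$rho)
  expect_equal(back$fields$density_lu[!solid], st$rho[!solid],
               tolerance = 1e-12)
  expect_equal(back$fields$velocity_lu[, , , 3][!solid],
               st$u[, , , 3][!solid], tolerance = 1e-12)
  # a slice from the file equals extract_plane on the same plane
  c0 <- fx$geom$meta$center
  sl <- extract_plane(st, "zx", coord = c0[2] - 1)
  k <- sl$index
  expect_equal(back$fields$pressure_lu[, k, ][!is.na(sl$pressure)],
               sl$pressure[!is.na(sl$pressure)], tolerance = 1e-12)
})

test_that("probe CSV has one row per probe and survives rereading", {
  g <- pipe_geometry(5.2, nz = 6)
  tau <- 0.8
  st <- run_lbm(g, collision_params(tau),
                body_force = c(0, 0, 8 * (tau - 0.5) / 3 * 0.02 / 5.2^2),
                max_steps = 2000, tol = 1e-8, check_every = 100)
  c0 <- g$meta$center
  probes <- cbind(c0[1] - 1 + (-2:2), c0[2] - 1, 2)
  s <- extract_probes(st, probes)
  expect_equal(nrow(s), 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_probe_csv(s, path, reference = s$speed_m_s * 1.05)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 5L)
  expect_equal(back$speed_m_s, s$speed_m_s, tolerance = 1e-12)
  # comparison columns recompute from the raw columns
  cmp <- compare_fields(back$speed_m_s, back$speed_m_s * 1.05)
  expect_equal(back$percent_diff, cmp$percent, tolerance = 1e-6)
  expect_equal(back$abs_change, cmp$abs_change, tolerance = 1e-9)
})

test_that("YAML configurations build runnable configs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry: bifurcation",
    "bifurcation:",
    "  trunk_len: 0.006",
    "  branch_len: 0.006",
    "  sac_radius: 0.002",
    "  sac_offset: [0.001, 0.003, 0.0]",
    "model: mrt",
    "dx: 0.0004",
    "dt: 0.0002",
    "nu_phys: 3.7037e-6",
    "u_avg: 0.05",
    "max_steps: 50",
    "ramp_steps: 10"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_identical(cfg$model, "mrt")
  expect_s3_class(cfg$geometry, "bifurcation_spec")
  expect_equal(cfg$geometry$sac_radius, 0.002)
  st <- run_simulation(cfg)
  expect_s3_class(st, "lbm_state")
  expect_identical(st$steps, 50L)
})
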