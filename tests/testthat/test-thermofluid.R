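test_that("constant-viscosity solver reproduces the planar Poiseuille parabola", {
  D <- 0.4; mu <- 3.5e-3; u_peak <- 40
  G <- -8 * mu * u_peak / D^2
  n <- 20
  sol <- solve_velocity_profile(rep(mu, n + 1), D, G)
  exact <- u_peak * (1 - (2 * (sol$x - D / 2) / D)^2)
  expect_equal(sol$u, exact, tolerance = 1e-10)
  expect_equal(max(sol$u), u_peak, tolerance = 1e-3)   # 0.1% contract
  # no-slip at both walls
  expect_identical(sol$u[1], 0)
  expect_identical(sol$u[n + 1], 0)
  # planar-gap mean is 2/3 of the peak (trapezoid quadrature of the exact
  # nodal parabola carries its own O(n^-2) bias, hence the looser tolerance)
  w <- (D / n) * c(0.5, rep(1, n - 1), 0.5)
  expect_equal(sum(w * sol$u) / D, (2 / 3) * u_peak, tolerance = 3e-3)
  # wall shear of the parabola: tau = 4 mu u_peak / D on both walls
  expect_equal(sol$tau_prox, 4 * mu * u_peak / D, tolerance = 1e-10)
  expect_equal(sol$tau_dist, sol$tau_prox, tolerance = 1e-10)
})

test_that("velocities scale as 1/mu at fixed pressure gradient", {
  D <- 0.3; G <- -5
  u1 <- solve_velocity_profile(rep(2e-3, 21), D, G)$u
  u2 <- solve_velocity_profile(rep(4e-3, 21), D, G)$u
  expect_equal(u2, u1 / 2, tolerance = 1e-12)
})

test_that("two-layer viscosity profile matches the closed-form oracle", {
  D <- 0.4; mu1 <- 2e-3; mu2 <- 8e-3; G <- -10
  n <- 400
  x <- seq(0, D, length.out = n + 1)
  a <- D / 2                        # interface at a face
  mu <- ifelse(x <= a, mu1, mu2)
  sol <- solve_velocity_profile(mu, D, G)
  exact <- two_layer_profile(x, a, D, mu1, mu2, G)
  expect_equal(sol$u, exact, tolerance = 5e-3)
  expect_gt(max(sol$u), 0)
})

test_that("fixed-flow-rate drive rescales the profile to the target flow", {
  D <- 0.2; n <- 20
  mu <- seq(2e-3, 6e-3, length.out = n + 1)    # asymmetric viscosity
  w <- (D / n) * c(0.5, rep(1, n - 1), 0.5)
  sol <- solve_velocity_profile(mu, D, -4, target_flow = 1.5)
  expect_equal(sum(w * sol$u), 1.5, tolerance = 1e-10)
  expect_equal(sol$flow_rate, 1.5, tolerance = 1e-10)
})

test_that("wall shear from the field state is exact for the parabola and linear in mu", {
  sc <- quick_scene(0.4, u_peak = 40)
  g <- sim_grid(sc, 3, nx_lumen = 20, dz = 0.4)
  st <- field_state(sc, g)
  sh <- wall_shear(st, g)
  mu0 <- viscosity_at(sc$viscosity, 37)
  expect_equal(sh$tau_prox_max, 4 * mu0 * 40 / 0.4, tolerance = 1e-9)
  expect_equal(sh$tau_dist_max, sh$tau_prox_max, tolerance = 1e-9)
  # doubling viscosity (uniform curve) doubles the shear at the same gradient;
  # under the fixed-G calibration from u_peak the shear is the same, so drive
  # the comparison through the raw solver instead
  sol1 <- solve_velocity_profile(rep(mu0, 21), 0.4, -3)
  sol2 <- solve_velocity_profile(rep(2 * mu0, 21), 0.4, -3)
  expect_equal(sol1$u / 2, sol2$u, tolerance = 1e-12)       # same G: u halves
  expect_equal(sol1$tau_prox, sol2$tau_prox, tolerance = 1e-12)
  # identical velocity field with doubled viscosity: rescale G too
  sol3 <- solve_velocity_profile(rep(2 * mu0, 21), 0.4, -6)
  expect_equal(sol3$u, sol1$u, tolerance = 1e-12)
  expect_equal(sol3$tau_prox, 2 * sol1$tau_prox, tolerance = 1e-12)
  # no flow, no shear
  sc0 <- quick_scene(0.4, u_peak = 0)
  st0 <- field_state(sc0, sim_grid(sc0, 3, 20, dz = 0.4))
  expect_equal(wall_shear(st0, g)$tau_max, 0)
})

test_that("equilibrium is preserved exactly without a source", {
  sc <- quick_scene(0.2, u_peak = 20)
  g <- quick_grid(sc)
  st <- field_state(sc, g)
  S0 <- matrix(0, g$nx, g$nz)
  sys <- photocoag:::.diffusion_system(sc, g, 1e-3)
  for (k in 1:5) st <- step_heat(st, sc, g, S0, 1e-3, sys = sys)
  expect_equal(st$T_C, matrix(37, g$nx, g$nz), tolerance = 1e-12)
  expect_equal(st$t, 5e-3)
})

test_that("diffusion of a point release grows variance at 2 alpha t per axis", {
  # no flow, insulated boundaries, uniform properties (lumen = tissue)
  sc <- quick_scene(0.5, u_peak = 0, tissue_margin = 0.75,
                    segment_length = 2)
  g <- sim_grid(sc, spot_diameter = 1.9, nx_lumen = 20, dz = 0.025)
  sys <- photocoag:::.diffusion_system(sc, g, 2e-4, bc = "insulated")
  st <- field_state(sc, g)
  i0 <- round(g$nx / 2); j0 <- round(g$nz / 2)
  st$T_C[i0, j0] <- st$T_C[i0, j0] + 1000
  dt <- 2e-4; nstep <- 50; t_end <- dt * nstep
  S0 <- matrix(0, g$nx, g$nz)
  for (k in seq_len(nstep)) st <- step_heat(st, sc, g, S0, dt, sys = sys)
  theta <- st$T_C - 37
  var_x <- field_variance(theta, g$x, "x")
  var_z <- field_variance(theta, g$z, "z")
  alpha <- 0.15
  # variance grows by 2 alpha t per axis on top of the initial cell variance
  expect_equal(var_x, 2 * alpha * t_end, tolerance = 0.02)
  expect_equal(var_z, 2 * alpha * t_end, tolerance = 0.02)
  # mass is conserved under insulated boundaries
  expect_equal(sum(theta), 1000, tolerance = 1e-9)
})

test_that("pure advection translates a profile at the flow speed", {
  nz <- 60; dz <- 0.1
  theta <- matrix(0, 3, nz)
  theta[2, 10:14] <- c(1, 3, 5, 3, 1)
  u <- matrix(1, 3, nz)
  # unit-CFL upwind is an exact shift: one cell per step
  out <- photocoag:::.advect_upwind(theta, u, dz, dt = 0.1, cfl = 1)
  expect_equal(out[2, 11:15], c(1, 3, 5, 3, 1), tolerance = 1e-14)
  expect_equal(sum(out), sum(theta), tolerance = 1e-12)
  # at fractional CFL the centroid still moves at exactly u
  z <- (seq_len(nz) - 0.5) * dz
  out2 <- photocoag:::.advect_upwind(theta, u, dz, dt = 0.1, cfl = 0.5)
  c0 <- sum(theta[2, ] * z) / sum(theta[2, ])
  c2 <- sum(out2[2, ] * z) / sum(out2[2, ])
  expect_equal(c2 - c0, 1 * 0.1, tolerance = 1e-10)
})

test_that("insulated no-flow runs conserve deposited energy", {
  sc <- quick_scene(0.2, u_peak = 0)
  g <- quick_grid(sc)
  sim <- run_simulation(sc, pulse_train(), grid = g, duration = 0.1,
                        dt = 1e-3, bc = "insulated")
  theta <- sim$state$T_C - 37
  rhoC <- ifelse(g$lumen_x, 0.004, 0.004)
  stored <- sum(rhoC * theta) * g$dx * g$dz
  expect_equal(stored, sim$energy$deposited_J_per_mm, tolerance = 0.01)
  expect_gt(stored, 0)
})

test_that("halving the grid spacing changes the peak wall temperature by < 5%", {
  sc <- quick_scene(0.2)
  tr <- pulse_train()
  g1 <- sim_grid(sc, 3, nx_lumen = 20, dz = 0.2)
  g2 <- sim_grid(sc, 3, nx_lumen = 40, dz = 0.1)
  s1 <- run_simulation(sc, tr, grid = g1, duration = 0.15, dt = 1e-3)
  s2 <- run_simulation(sc, tr, grid = g2, duration = 0.15, dt = 5e-4)
  p1 <- max(s1$traces$T_wall_prox_C) - 37
  p2 <- max(s2$traces$T_wall_prox_C) - 37
  expect_lt(abs(p1 - p2) / p2, 0.05)
})

test_that("a divergent field aborts with a diagnostic rather than propagating NaN", {
  sc <- quick_scene()
  g <- quick_grid(sc)
  st <- field_state(sc, g)
  S_bad <- matrix(NaN, g$nx, g$nz)
  expect_error(step_heat(st, sc, g, S_bad, 1e-3), "diverged")
})
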