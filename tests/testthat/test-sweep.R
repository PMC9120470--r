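test_that("velocity rule reproduces the measured anchors and clamps below 0.05 mm", {
  expect_equal(velocity_for_diameter(0.2), 20)
  expect_equal(velocity_for_diameter(0.4), 40)
  expect_equal(velocity_for_diameter(1.0), 100)
  expect_equal(velocity_for_diameter(0.01), velocity_for_diameter(0.05))
})

test_that("simulation outputs are deterministic for a fixed configuration", {
  sc <- quick_scene()
  g <- quick_grid(sc)
  tr <- pulse_train()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_run(sc, tr, out_dir = d1, grid = g, duration = 0.1)
  simulate_run(sc, tr, out_dir = d2, grid = g, duration = 0.1)
  t1 <- readLines(file.path(d1, "traces.csv"))
  t2 <- readLines(file.path(d2, "traces.csv"))
  expect_identical(t1, t2)
})

test_that("run directories carry traces, summary, config echo and log", {
  sc <- quick_scene()
  out <- withr::local_tempdir()
  sim <- simulate_run(sc, pulse_train(), out_dir = out,
                      grid = quick_grid(sc), duration = 0.1)
  expect_true(file.exists(file.path(out, "traces.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_true(file.exists(file.path(out, "run.log")))
  tr <- utils::read.csv(file.path(out, "traces.csv"))
  expect_named(tr, c("time_s", "T_wall_prox_C", "T_wall_dist_C",
                     "T_center_C", "tau_prox_Pa", "tau_dist_Pa",
                     "tau_max_Pa", "u_center_mm_s", "Omega_max"))
  js <- jsonlite::fromJSON(file.path(out, "summary.json"))
  expect_equal(js$diameter_mm, 0.2)
  expect_true(all(c("peclet", "omega_max_lumen", "coagulated") %in%
                    names(js$diagnostics)))
  # the config echo reloads to the same scene (full provenance)
  sc2 <- load_scene(file.path(out, "config.yaml"))
  expect_equal(sc2$diameter, sc$diameter)
  expect_equal(sc2$u_peak, sc$u_peak)
})

test_that("a zero-power run stays at baseline with no damage verdict", {
  sc <- quick_scene()
  tr <- pulse_train(peak_power = 0)
  sim <- run_simulation(sc, tr, grid = quick_grid(sc), duration = 0.1)
  expect_true(all(abs(sim$traces$T_wall_prox_C - 37) < 1e-9))
  expect_true(all(abs(sim$traces$T_center_C - 37) < 1e-9))
  expect_lt(sim$diagnostics$omega_max_lumen, 1e-6)
  expect_false(sim$diagnostics$coagulated)
  # shear stays at its baseline Poiseuille value throughout
  expect_equal(max(sim$traces$tau_max_Pa), min(sim$traces$tau_max_Pa),
               tolerance = 1e-9)
})

test_that("a single-diameter sweep agrees with a direct simulation", {
  tr <- pulse_train()
  sw <- run_sweep(diameters = 0.2, train = tr, duration = 0.12,
                  nx_lumen = 10, dz = 0.4)
  sc <- vessel_scene(0.2)
  sim <- run_simulation(sc, tr, grid = sim_grid(sc, 3, 10, dz = 0.4),
                        duration = 0.12)
  expect_equal(sw$table$Omega_max, sim$diagnostics$omega_max_lumen)
  expect_equal(sw$table$tau_max_Pa, max(sim$traces$tau_max_Pa))
  expect_false(sw$table$failed)
})

test_that("the sweep table has one row per diameter and survives a failing run", {
  # an invalid velocity for one diameter must not abort the others
  sw <- run_sweep(diameters = c(0.1, 0.2), velocities = c(10, -5),
                  duration = 0.06, nx_lumen = 10, dz = 0.4)
  expect_equal(nrow(sw$table), 2)
  expect_false(sw$table$failed[1])
  expect_true(sw$table$failed[2])
  expect_true(is.na(sw$table$Omega_max[2]))
})

test_that("sweep input validation enforces sorted unique positive diameters", {
  expect_error(run_sweep(diameters = c(0.2, 0.1)), "sorted")
  expect_error(run_sweep(diameters = c(0.1, 0.1)), "unique")
  expect_error(run_sweep(diameters = c(-0.1, 0.2)), "positive")
  expect_error(run_sweep(diameters = c(0.1, 0.2), velocities = 10),
               "one velocity per diameter")
})

test_that("sweep writes per-diameter run directories and the combined table", {
  out <- withr::local_tempdir()
  sw <- run_sweep(diameters = c(0.1, 0.2), duration = 0.08,
                  nx_lumen = 10, dz = 0.4, out_dir = out)
  expect_true(file.exists(file.path(out, "sweep_table.csv")))
  expect_true(file.exists(file.path(out, "D_0.1", "traces.csv")))
  expect_true(file.exists(file.path(out, "D_0.2", "summary.json")))
  tab <- utils::read.csv(file.path(out, "sweep_table.csv"))
  expect_equal(tab$diameter_mm, c(0.1, 0.2))
  # the velocity rule fed the anchored values
  expect_equal(tab$u_peak_mm_s, c(10, 20))
})
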