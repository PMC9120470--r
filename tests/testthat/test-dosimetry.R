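test_that("thermal relaxation time follows D^2 / (16 alpha)", {
  expect_equal(thermal_relaxation_time(1.0, 0.15), 1 / 2.4, tolerance = 1e-12)
  expect_equal(thermal_relaxation_time(1.0, 0.15), 0.41667, tolerance = 1e-4)
  expect_equal(thermal_relaxation_time(0.4, 0.15), 0.066667, tolerance = 1e-4)
  # quadratic in D, inverse in alpha
  D <- c(0.05, 0.1, 0.7)
  expect_equal(thermal_relaxation_time(2 * D), 4 * thermal_relaxation_time(D))
  expect_equal(thermal_relaxation_time(D, alpha = 0.3),
               thermal_relaxation_time(D, alpha = 0.15) / 2)
  expect_error(thermal_relaxation_time(0), "positive")
  expect_error(thermal_relaxation_time(1, alpha = -1), "positive")
})

test_that("adiabatic temperature rise follows mua Phi / rhoC", {
  expect_equal(temperature_rise(0), 0)
  expect_equal(temperature_rise(1, mua = 0.3, rhoC = 0.004), 75)
  # the 7.7 J / 25 ms / 3 mm spot dose: Phi = 7.7 / (pi 1.5^2) = 1.0894 J/mm^2
  phi <- 7.7 / spot_area(3)
  expect_equal(phi, 1.0894, tolerance = 1e-4)
  expect_equal(temperature_rise(phi), 81.70, tolerance = 1e-3)
  expect_error(temperature_rise(1, mua = 0), "positive")
  expect_error(temperature_rise(-1), "non-negative")
})

test_that("pulse-train arithmetic reproduces the duty-cycle bookkeeping", {
  tr <- pulse_train(peak_power = 3000, micro_pulse_duration = 50e-6,
                    duty_cycle = 0.10)
  expect_equal(tr$repetition_rate, 2000)
  expect_equal(tr$average_power, 300)
  # continuous train limit
  cw <- pulse_train(peak_power = 100, micro_pulse_duration = 50e-6,
                    duty_cycle = 1)
  expect_equal(cw$repetition_rate, 1 / 50e-6)
  expect_equal(cw$average_power, 100)
  expect_error(pulse_train(duty_cycle = 1.2), "duty cycle")
  expect_error(pulse_train(duty_cycle = 0), "duty cycle")
})

test_that("macro-pulse schedules must be ordered and non-overlapping", {
  bad <- data.frame(start = c(0.1, 0.05), duration = 0.02, scale = 1)
  expect_error(pulse_train(macro_pulses = bad), "ordered")
  bad2 <- data.frame(start = c(0, 0.01), duration = c(0.05, 0.01), scale = 1)
  expect_error(pulse_train(macro_pulses = bad2), "overlap")
})

test_that("delivered energy equals average power times scaled on-time", {
  m <- data.frame(start = c(0, 0.1, 0.3), duration = c(0.05, 0.02, 0.01),
                  scale = c(1, 0.5, 0.25))
  tr <- pulse_train(macro_pulses = m)
  expect_equal(train_energy(tr), 300 * sum(m$duration * m$scale))
  expect_equal(train_on_time(tr), sum(m$duration))
  # partial-interval integral is exact
  expect_equal(train_energy(tr, 0.025, 0.11), 300 * (0.025 + 0.01 * 0.5))
  # envelope power at sample times
  expect_equal(train_power(tr, c(0.01, 0.07, 0.105, 0.5)),
               c(300, 0, 150, 0))
})

test_that("transit time divides length by velocity with graceful edge cases", {
  expect_identical(transit_time(1, 40), 0.025)
  expect_identical(transit_time(1, 20), 0.05)
  expect_identical(transit_time(0, 40), 0)
  tt <- transit_time(1, 0)
  expect_identical(as.numeric(tt), Inf)
  expect_true(attr(tt, "no_flow"))
  expect_error(transit_time(-1, 10), "non-negative")
})

test_that("stacked protocol clamps the initial pulse to 100-200 ms for large vessels", {
  for (D in c(0.5, 0.7, 1.0)) {
    tr <- stacked_protocol(D)
    expect_gte(tr$macro_pulses$duration[1], 0.1)
    expect_lte(tr$macro_pulses$duration[1], 0.2)
  }
  # below the clamp the initial pulse is 5 x the relaxation time
  tr_small <- stacked_protocol(0.05)
  expect_equal(tr_small$macro_pulses$duration[1],
               5 * thermal_relaxation_time(0.05), tolerance = 1e-12)
  expect_equal(tr_small$macro_pulses$duration[1], 5 * 1.0417e-3,
               tolerance = 1e-4)
})

test_that("venule protocol halves peak scale, doubles durations, keeps energy fixed", {
  for (D in c(0.1, 0.5, 1.0)) {
    art <- stacked_protocol(D, vessel_class = "arteriole")
    ven <- stacked_protocol(D, vessel_class = "venule")
    expect_equal(ven$macro_pulses$scale, art$macro_pulses$scale / 2)
    expect_equal(ven$macro_pulses$duration, art$macro_pulses$duration * 2)
    expect_equal(train_energy(ven), train_energy(art), tolerance = 1e-12)
  }
})

test_that("stacked protocol schedules are valid, chronological trains", {
  tr <- stacked_protocol(0.8, n_followup = 4, gap = 0.03)
  m <- tr$macro_pulses
  expect_equal(nrow(m), 5)
  expect_true(all(diff(m$start) > 0))
  expect_true(all(m$start[-1] >= (m$start + m$duration)[-nrow(m)]))
  expect_true(length(attr(tr, "assumptions")) >= 2)
})

test_that("dosimetry report flags rupture risk and transit-limited pulses", {
  # energy sized to just reach the coagulation onset: no rupture flag
  r <- dosimetry_report(0.4)
  expect_equal(r$predicted_T, 55)
  expect_false(r$rupture_risk)
  expect_true(r$reaches_coag_onset)
  expect_equal(r$thermal_relaxation_time, 0.066667, tolerance = 1e-4)
  # an oversized dose trips the 100 degC flag
  r2 <- dosimetry_report(0.4, energy = 30)
  expect_true(r2$rupture_risk)
  # a 1 mm vessel's relaxation-time pulse (0.42 s) outlasts the 45 ms spot
  # transit at the measured-flow velocity
  r3 <- dosimetry_report(1.0)
  expect_true(r3$pulse_exceeds_transit)
  expect_false(dosimetry_report(0.05)$pulse_exceeds_transit)
})

test_that("reports and trains serialize to parseable JSON", {
  txt <- as_json(dosimetry_report(0.4))
  obj <- jsonlite::fromJSON(txt)
  expect_equal(obj$thermal_relaxation_time, 0.4^2 / (16 * 0.15))
  txt2 <- as_json(stacked_protocol(1.0))
  obj2 <- jsonlite::fromJSON(txt2)
  expect_equal(obj2$average_power, 300)
  expect_true(length(obj2$assumptions) >= 2)
})
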