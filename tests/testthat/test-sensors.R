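test_that("sensor output is gain x clamped signal, area-scaled", {
  spec <- calibrate_gain(water_potential_sensor(), std_params)
  expect_equal(sensor_output(spec, 0.5, 0.5, 99), 0)   # no driving force
  expect_equal(sensor_output(spec, 0.86, 0.43, 99), spec$gain * 0.43)
  expect_equal(sensor_output(spec, 0.86, 0.43, 99, area_factor = 2),
               2 * spec$gain * 0.43)
  # clamp: no output when water would leave the cell
  expect_equal(sensor_output(spec, 0.3, 0.5, 99), 0)
  # no sensor: baseline passes through untouched
  expect_equal(sensor_output(no_sensor(), 0.1, 0.9, 42), 42)
})

test_that("gain auto-calibration reproduces the baseline operating point", {
  p <- std_params
  spec <- calibrate_gain(water_potential_sensor(), p)
  # K = steady extrusion / steady water potential ~ 2.53/0.43 ~ 5.9
  expect_equal(spec$gain, 5.88, tolerance = 0.01)
  expect_equal(sensor_output(spec, p$dPi_target, p$dP_target, NA),
               p$dVwall_baseline, tolerance = 1e-12)
  # alternative couplings hit their own baselines
  for (inp in c("water_potential", "osmotic", "turgor"))
    for (out in c("wall_extrusion", "solute_rate", "hardening")) {
      s <- calibrate_gain(sensor_spec(inp, out), p)
      got <- sensor_output(s, p$dPi_target, p$dP_target, NA)
      want <- switch(out, wall_extrusion = p$dVwall_baseline,
                     solute_rate = p$dm_dt, hardening = p$alpha)
      expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("enumerate_couplings yields 9 couplings plus a control", {
  specs <- enumerate_couplings(std_params)
  expect_length(specs, 10)
  expect_true("water_potential->wall_extrusion" %in% names(specs))
  expect_identical(specs$none$input, "none")
  pairs <- vapply(specs[names(specs) != "none"],
                  function(s) paste(s$input, s$output), character(1))
  expect_length(unique(pairs), 9)
})

test_that("classification flags nothing on an unperturbed run", {
  tc <- baseline_tc()
  base <- steady_state_summary(tc)
  cls <- classify_outcome(tc, base)
  expect_false(cls$growth_changed)
  expect_false(cls$thickness_changed)
  expect_false(cls$turgor_changed)
})

test_that("classification errors without a steady baseline", {
  tc <- baseline_tc()
  base <- steady_state_summary(tc)
  base$steady <- FALSE
  expect_error(classify_outcome(tc, base), "steady")
})
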