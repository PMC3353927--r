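test_that("exponential relaxation has the defining half-time property", {
  expect_equal(exp_relax(0, 1, 0.4, 0.4), 0.5)    # one half-time: midpoint
  expect_equal(exp_relax(0, 1, 0.2, 0.4), 0.75)   # two half-times
  x <- 0
  for (i in 1:200) x <- exp_relax(x, 1, 0.2, 0.4)
  expect_equal(x, 1, tolerance = 1e-12)           # converges to target
})

test_that("the calibrated steady state is a fixed point of step()", {
  p <- std_params
  sensor <- calibrate_gain(water_potential_sensor(), p)
  # place the state exactly on the calibrated operating point
  st <- new_state(p, sensor)
  st$E_smooth <- 2 * p$G_ref * (p$dPi_target - p$dP_target) / p$r
  st$dP_smooth <- p$dP_target
  st$ctrl_smooth <- p$dVwall_baseline
  st2 <- step(st, p, NULL, sensor, t = 0)
  expect_equal(st2$L_wall, st$L_wall, tolerance = 1e-10)
  expect_equal(st2$E_smooth, st$E_smooth, tolerance = 1e-8)
  expect_equal(st2$Pi_i, st$Pi_i, tolerance = 1e-10)
  expect_gt(st2$L, st$L)          # only length and solute content advance
  expect_gt(st2$m, st$m)
})

test_that("removing hardening thins the wall from steady state", {
  p <- std_params
  sensor <- calibrate_gain(water_potential_sensor(), p)
  st <- new_state(p, sensor)
  st$E_smooth <- 2 * p$G_ref * (p$dPi_target - p$dP_target) / p$r
  st$dP_smooth <- p$dP_target
  p0 <- modify_params(p, alpha = 0)
  st2 <- step(st, p0, NULL, sensor, t = 0)
  expect_lt(st2$L_wall, st$L_wall)
})

test_that("baseline trajectory is steady and bit-reproducible", {
  tc <- baseline_tc()
  expect_s3_class(tc, "tip_timecourse")
  expect_identical(attr(tc, "outcome"), "steady")
  # strictly increasing times, constant stride
  expect_true(all(diff(tc$t) > 0))
  expect_equal(max(abs(diff(diff(tc$t)))), 0, tolerance = 1e-9)
  tc2 <- run(std_params, duration = 2000)
  expect_identical(as.data.frame(tc), as.data.frame(tc2))
})

test_that("Eq. 2 and Eq. 8 identities hold along the trajectory", {
  tc <- baseline_tc()
  p <- std_params
  # dP = dPi - dV/(P_os A_mem) with dV = pi r^2 dL/dt, at every sample
  dV <- pi * p$r^2 * tc$dL_dt
  expect_equal(tc$dP[-1], tc$dPi[-1] - dV[-1] / p$G_ref, tolerance = 1e-9)
  # dP <= dPi whenever water flows in
  expect_true(all(tc$dP <= tc$dPi + 1e-12))
})

test_that("solute is conserved along the trajectory", {
  tc <- baseline_tc()
  p <- std_params
  rt <- 8.314e-3 * p$temperature * 1e15
  # m(t) = m(0) + dm_dt * t  (sensor does not control dm here)
  m_t <- tc$Pi_i * (pi * p$r^2 * tc$L) / rt
  m_expect <- m_t[1] + p$dm_dt * tc$t
  expect_equal(m_t, m_expect, tolerance = 1e-6)
})

test_that("burst is absorbing and recorded with zero pressure gradients", {
  tc <- cached_run("alpha_zero", run(std_params, "fig3_alpha_zero",
                                     duration = 1000))
  expect_identical(attr(tc, "outcome"), "burst")
  bt <- attr(tc, "burst_time")
  expect_false(is.na(bt))
  last <- as.data.frame(tc)[nrow(tc), ]
  expect_identical(last$dPi, 0)
  expect_identical(last$dP, 0)
  expect_lte(last$L_wall, std_params$burst_threshold)
  expect_equal(last$t, bt)
  expect_equal(max(tc$t), bt)   # nothing recorded after the burst
  st <- new_state(std_params)
  st$burst <- TRUE
  expect_error(step(st, std_params), "burst")
})

test_that("halving the time step changes steady summaries by < 1%", {
  s1 <- steady_state_summary(cached_run("base1000",
                                        run(std_params, duration = 1000)))
  s2 <- steady_state_summary(run(half_dt_params(), duration = 1000))
  for (v in c("dL_dt", "dPi", "dP", "L_wall", "dVwall_dt"))
    expect_equal(s2[[v]], s1[[v]], tolerance = 0.01)
})

test_that("steady-state summary flags drifting trajectories", {
  tc <- baseline_tc()
  ss <- steady_state_summary(tc)
  expect_true(ss$steady)
  expect_equal(ss$dL_dt * 60, 12.07, tolerance = 0.05)
  # an arrested (pressure-accumulating) run is not steady
  tc2 <- cached_run("alpha_x20", run(std_params, "fig3_alpha_x20",
                                     duration = 2500))
  ss2 <- steady_state_summary(tc2)
  expect_false(ss2$steady)
  # burst trajectories have no steady state
  tc3 <- cached_run("alpha_zero", run(std_params, "fig3_alpha_zero",
                                      duration = 1000))
  expect_error(steady_state_summary(tc3), "burst")
})
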