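test_that("van 't Hoff pressure matches hand arithmetic", {
  expect_equal(vant_hoff_pressure(0, 298.15), 0)
  # RT at 298.15 K: 8.314e-3 * 298.15 = 2.4788 MPa per Osm
  expect_equal(vant_hoff_pressure(1, 298.15), 2.479, tolerance = 1e-3)
  expect_equal(vant_hoff_pressure(0.3, 298.15), 0.7437, tolerance = 1e-3)
  expect_error(vant_hoff_pressure(-0.1), "non-negative")
})

test_that("permeability conversion round-trips and matches the known pair", {
  expect_equal(pos_cm_to_bar(pos_bar_to_cm(0.0936)), 0.0936)
  # concentration form 1.32e-3 cm/s corresponds to the pressure form
  # 9.36e-6 cm/MPa/s (= 0.0936 um/MPa/s) within a few percent at 298 K
  expect_equal(pos_cm_to_bar(1.32e-3), 0.0936, tolerance = 0.03)
})

test_that("water influx follows the driving-force product", {
  expect_equal(water_influx_rate(0.0936, 1005, 0.5, 0.5), 0)
  v <- water_influx_rate(0.0936, 1005, 0.86, 0.43)
  expect_equal(v, 0.0936 * 1005 * 0.43, tolerance = 1e-12)
  expect_equal(v, 40.45, tolerance = 1e-2)
  # sign symmetry: reversed gradient gives efflux
  expect_equal(water_influx_rate(0.0936, 1005, 0.43, 0.86), -v)
})

test_that("cylinder geometry links volume and length rates", {
  expect_equal(length_rate_from_volume(0, 8), 0)
  # 40.4 um^3/s through a r = 8 um cross-section is ~0.2 um/s = 12 um/min
  expect_equal(length_rate_from_volume(40.4, 8), 0.201, tolerance = 1e-3)
  expect_equal(length_rate_from_volume(2 * 40.4, 8),
               2 * length_rate_from_volume(40.4, 8))
  expect_error(length_rate_from_volume(1, 0), "positive")
})

test_that("osmotic pressure rate balances accumulation against dilution", {
  rt <- 8.314e-3 * 298.15 * 1e15   # MPa um^3 / osmol
  # steady state: RT dm/dt == Pi_i dV/dt
  dm <- 1.6 * 40.4 / rt
  expect_equal(osmotic_pressure_rate(dm, 1.6, 40.4, 1e5), 0,
               tolerance = 1e-15)
  # no supply, positive influx: dilution
  expect_lt(osmotic_pressure_rate(0, 1.6, 40.4, 1e5), 0)
  # direct substitution against independent arithmetic
  got <- osmotic_pressure_rate(2.6e-14, 1.6, 40.4, 1e5)
  expect_equal(got, (rt * 2.6e-14 - 1.6 * 40.4) / 1e5, tolerance = 1e-12)
})

test_that("tip tension is the Young-Laplace excess, clamped at zero", {
  expect_equal(tip_tension(0.43, 8, 0), 1.72)
  expect_equal(tip_tension(0.03, 8, 0.12), 0)      # exact balance
  expect_equal(tip_tension(0.01, 8, 0.5), 0)       # clamped
})

test_that("wall viscosity is initial plus hardening x residence time", {
  expect_equal(wall_viscosity(0.3, 0, 2.53, 12.77, 0.25), 0.3)
  # doubling extrusion halves the incremental term
  v1 <- wall_viscosity(0.3, 6.16, 2.53, 12.77, 0.25) - 0.3
  v2 <- wall_viscosity(0.3, 6.16, 5.06, 12.77, 0.25) - 0.3
  expect_equal(v1, 2 * v2)
  # residence-time product by hand: alpha * A_tip * L_wall / dVwall
  expect_equal(wall_viscosity(0.3, 6.162346, 2.53, 12.769, 0.25),
               0.3 + 6.162346 * 12.769 * 0.25 / 2.53, tolerance = 1e-12)
  # zero extrusion: fully hardened cap
  expect_equal(wall_viscosity(0.3, 6.16, 0, 12.77, 0.25, cap = 1e6),
               0.3e6)
})

test_that("tip expansion throughput follows the strain-rate law", {
  expect_equal(tip_expansion_rate(0, 8, 0.25, 12.77), 0)
  # enormous viscosity arrests expansion
  expect_lt(tip_expansion_rate(1.6, 1e9, 0.25, 12.77), 1e-6)
  # steady state: E must equal 2*pi*r*dL/dt ~ 10.1 um^2/s
  p <- std_params
  eta <- wall_viscosity(p$eta_0, p$alpha, p$dVwall_baseline, p$A_tip, 0.25)
  E <- tip_expansion_rate(tip_tension(0.43, 8, p$gamma), eta, 0.25, p$A_tip)
  expect_equal(E, 2 * pi * 8 * 0.2012, tolerance = 1e-3)
  expect_error(tip_expansion_rate(1, 1, 0, 1), "burst")
})

test_that("wall thickness rate conserves film volume", {
  expect_equal(wall_thickness_rate(2.53, 10.12, 12.77, 0.25),
               (2.53 - 0.25 * 10.12) / 12.77)
  expect_equal(wall_thickness_rate(2.53, 2.53 / 0.25, 12.77, 0.25), 0)
  expect_gt(wall_thickness_rate(2.53, 0, 12.77, 0.25), 0)  # thickening
  # calibrated steady triple closes to zero
  p <- std_params
  E <- 2 * p$G_ref * (p$dPi_target - p$dP_target) / p$r
  expect_equal(wall_thickness_rate(p$dVwall_baseline, E, p$A_tip,
                                   p$L_wall_target), 0, tolerance = 1e-12)
})

test_that("solve_turgor agrees with a bisection oracle on random draws", {
  # independent oracle: bisection on the monotone imbalance function
  oracle <- function(dPi, G, r, A_tip, eta, L_wall, gamma) {
    f <- function(dP) G * (dPi - dP) -
      r * A_tip * max(0, dP * r / 2 - gamma) / (2 * eta * L_wall)
    lo <- 0; hi <- dPi
    if (f(hi) >= 0) return(hi)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  set.seed(42)
  for (i in 1:20) {
    dPi <- runif(1, 0.1, 3); G <- runif(1, 10, 300)
    r <- runif(1, 4, 12); A_tip <- runif(1, 5, 30)
    eta <- runif(1, 0.2, 50); L_wall <- runif(1, 0.05, 1)
    gamma <- runif(1, 0, 0.5)
    st <- new_state(std_params)
    st$Pi_i <- vant_hoff_pressure(std_params$C_o) + dPi
    st$L_wall <- L_wall
    p <- modify_params(std_params, r = r, A_tip = A_tip, gamma = gamma,
                       eta_0 = eta, alpha = 0,
                       P_os_bar = G / std_params$A_mem)
    got <- solve_turgor(st, p)
    want <- oracle(dPi, p$P_os_bar * p$A_mem, r, A_tip, eta, L_wall, gamma)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("turgor equals the osmotic gradient in the rigid-wall limit", {
  st <- new_state(std_params)
  p <- modify_params(std_params, eta_0 = 1e12)
  st$dVwall_smooth <- 0   # viscosity cap: fully hardened
  expect_equal(solve_turgor(st, p), std_params$dPi_init, tolerance = 1e-6)
})

test_that("standard operating point shows the 0.43 MPa discrepancy", {
  p <- std_params
  st <- new_state(p)
  dP <- solve_turgor(st, p)
  expect_equal(p$dPi_init - dP, 0.43, tolerance = 0.01)
})
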