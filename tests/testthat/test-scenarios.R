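test_that("effective parameters follow steps and sinusoids", {
  p <- std_params
  sc <- scenario(perturbation("C_o", "step", onset = 100, value = 0.4))
  expect_equal(effective_params(p, sc, 50)$C_o, 0.3)
  # step smoothed with the parameter half-time
  expect_equal(effective_params(p, sc, 100 + p$ht_param)$C_o,
               0.3 + 0.1 * 0.5)
  expect_equal(effective_params(p, sc, 200)$C_o, 0.4, tolerance = 1e-9)

  sc2 <- scenario(perturbation("L_perm", "sinusoid", onset = 0,
                               amplitude = 1 / 3, frequency = 1.2))
  # quarter period of a 1.2/min drive is 12.5 s: sine peak
  e <- effective_params(p, sc2, 12.5)
  expect_equal(e$L_perm, 20 * (1 + 1 / 3), tolerance = 1e-9)
  expect_equal(e$A_mem, 2 * pi * 8 * e$L_perm)   # area tracks the zone
  expect_equal(effective_params(p, sc2, 25)$L_perm, 20, tolerance = 1e-9)
})

test_that("unknown perturbation targets are rejected", {
  expect_error(perturbation("banana", "step", value = 1), "unknown")
  expect_error(perturbation("C_o", "step"), "value")
  expect_error(perturbation("L_perm", "sinusoid", amplitude = 1.5),
               "amplitude")
})

test_that("whole-tube mode grows the osmotic area with the tube", {
  sc <- scenario(A_mem_mode = "whole_tube")
  p <- std_params
  e0 <- effective_params(p, sc, 0, L = p$L_init)
  expect_equal(e0$A_mem, 2 * pi * p$r * p$L_perm)   # starts at the zone
  e1 <- effective_params(p, sc, 0, L = p$L_init + 30)
  expect_equal(e1$A_mem, 2 * pi * p$r * (p$L_perm + 30))
})

test_that("all documented presets resolve", {
  expect_setequal(preset_names(),
                  c("fig3_alpha_zero", "fig3_alpha_x20", "fig3_alpha_half",
                    "fig5_dilute", "fig5_shock", "fig5_hyper",
                    "fig6_whole_tube_permeable", "fig6_whole_tube_no_sensor",
                    "fig10_pectin_sine", "fig10_alpha_sine",
                    "fig11_Lperm_sine", "fig11_Lperm_sine_no_sensor"))
  ps <- preset_scenario("fig3_alpha_zero", std_params)
  expect_s3_class(ps$scenario, "scenario")
  expect_identical(ps$scenario$perturbations[[1]]$parameter, "alpha")
  expect_identical(ps$scenario$perturbations[[1]]$value, 0)
  expect_true(ps$sensor)
  expect_error(preset_scenario("fig99"), "unknown preset")
})
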