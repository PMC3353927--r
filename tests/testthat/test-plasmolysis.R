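test_that("closed-form retraction matches a numerical mass-balance oracle", {
  skip_if_not_installed("deSolve")
  # oracle: integrate the contact-area mass balance
  #   pi r^2 dx/dt = P_os * dPi * 2 pi r * (l - x)
  P_os <- 0.0936; dPi <- vant_hoff_pressure(0.5); r <- 8; l <- 20
  rhs <- function(t, y, parms) {
    list(2 * P_os * dPi * (l - y[1]) / r)
  }
  times <- seq(0, 300, by = 5)
  num <- deSolve::ode(c(x = 0), times, rhs, NULL, rtol = 1e-10,
                      atol = 1e-12)[, "x"]
  ana <- retraction_forward(P_os, dPi, r, l, times)
  expect_equal(ana[-1] / num[-1], rep(1, length(times) - 1),
               tolerance = 1e-6)
  # rate constant and 100-s value by hand
  expect_equal(2 * P_os * dPi / r, 0.029, tolerance = 1e-3)
  expect_equal(retraction_forward(P_os, dPi, r, l, 100), 18.9,
               tolerance = 1e-2)
})

test_that("retraction starts at zero and saturates at the zone length", {
  expect_equal(retraction_forward(0.0936, 1.24, 8, 20, 0), 0)
  expect_equal(retraction_forward(0.0936, 1.24, 8, 20, 1e6), 20)
  # plateau does not depend on the permeability
  expect_equal(retraction_forward(0.01, 1.24, 8, 20, 1e7), 20,
               tolerance = 1e-6)
  # noiseless curves are non-decreasing
  x <- retraction_forward(0.0936, 1.24, 8, 20, seq(0, 400, 10))
  expect_true(all(diff(x) > 0))
})

test_that("synthetic curves are reproducible and carry calibrated noise", {
  c1 <- synth_retraction(seed = 11)
  c2 <- synth_retraction(seed = 11)
  expect_identical(c1$x, c2$x)
  c3 <- synth_retraction(seed = 12)
  expect_false(identical(c1$x, c3$x))
  # zero noise reproduces the forward model exactly
  c0 <- synth_retraction(noise_sd = 0)
  tr <- attr(c0, "truth")
  expect_equal(c0$x, retraction_forward(tr$P_os_bar, attr(c0, "dPi"),
                                        attr(c0, "r"), tr$l, c0$t))
  # residual sd against the forward model within chi-square bounds
  cn <- synth_retraction(noise_sd = 0.5, times = seq(0, 290, 10), seed = 5)
  res <- cn$x - retraction_forward(tr$P_os_bar, attr(cn, "dPi"),
                                   attr(cn, "r"), tr$l, cn$t)
  expect_gt(sd(res), 0.3)
  expect_lt(sd(res), 0.7)
})

test_that("fitting inverts a noiseless curve to the generating truth", {
  cv <- synth_retraction(noise_sd = 0)
  est <- fit_retraction(cv)
  tr <- attr(cv, "truth")
  expect_true(est$converged)
  expect_equal(est$l, tr$l, tolerance = 1e-6)
  expect_equal(est$P_os_cm, tr$P_os_cm, tolerance = 1e-6)
  expect_equal(est$P_os_bar, tr$P_os_bar, tolerance = 1e-6)
})

test_that("bias vanishes as noise shrinks", {
  errs <- vapply(c(0.5, 0.05, 0.005), function(sd) {
    est <- fit_retraction(synth_retraction(noise_sd = sd, seed = 3))
    abs(est$l - 20) / 20
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("early-truncated curves flag a poorly identified plateau", {
  # 1/k ~ 34 s; a 12-s curve barely leaves the linear regime
  short <- synth_retraction(times = seq(0, 12, 2), noise_sd = 0.2,
                            seed = 2)
  long <- synth_retraction(times = seq(0, 300, 10), noise_sd = 0.2,
                           seed = 2)
  est_s <- fit_retraction(short)
  est_l <- fit_retraction(long)
  expect_gt(est_s$l_rse, 5 * est_l$l_rse)
})

test_that("curves round-trip through CSV with their JSON sidecar", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  cv <- synth_retraction(seed = 9)
  write_retraction(cv, tmp)
  back <- read_retraction(tmp)
  expect_equal(back$x, cv$x)
  expect_equal(attr(back, "r"), attr(cv, "r"))
  expect_equal(attr(back, "truth")$l, attr(cv, "truth")$l)
})
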