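test_that("quadratic fit is exact on polynomial traces and matches the normal equations on noisy data", {
  t5 <- c(0, 30, 60, 90, 120)

  # constant trace
  fit <- fit_quadratic(chamber_trace("p", "2014-06-01", t5, rep(400, 5)))
  expect_equal(c(fit$a0, fit$b1, fit$c2), c(400, 0, 0), tolerance = 1e-12)

  # exact quadratic
  y <- 400 + 0.5 * t5 - 0.001 * t5^2
  fit <- fit_quadratic(chamber_trace("p", "2014-06-01", t5, y))
  expect_equal(fit$a0, 400, tolerance = 1e-9)
  expect_equal(fit$b1, 0.5, tolerance = 1e-9)
  expect_equal(fit$c2, -0.001, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-9)

  # noisy trace against an explicit normal-equations solution
  set.seed(1)
  t20 <- seq(0, 120, length.out = 20)
  y20 <- 400 + 0.5 * t20 + rnorm(20, 0, 1)
  fit <- fit_quadratic(chamber_trace("p", "2014-06-01", t20, y20))
  oracle <- normal_eq_quadratic(t20, y20)
  expect_equal(c(fit$a0, fit$b1, fit$c2), oracle, tolerance = 1e-9)
})

test_that("trace construction rejects invalid inputs", {
  expect_error(chamber_trace("p", "2014-06-01", c(0, 30, 60), c(400, 410, 420)),
               "at least 4 samples")
  expect_error(chamber_trace("p", "2014-06-01", c(0, 30, 30, 60), rep(400, 4)),
               "strictly increasing")
  expect_error(chamber_trace("p", "2014-06-01", c(0, 30, 60, 90),
                             c(400, -1, 410, 420)), "positive")
  expect_error(fit_quadratic(data.frame(elapsed_s = c(0, 0, 0, 0),
                                        co2_ppm = rep(400, 4))),
               "singular|distinct")
})

test_that("initial-slope flux matches the ideal-gas hand computation and is linear in its factors", {
  # V/A = 0.15 m, P = 101325 Pa, T = 293.15 K -> rho = 41.57 mol m-3
  geom <- chamber_geometry(collar_diameter_m = 0.10,
                           system_volume_m3 = 0.15 * pi * 0.05^2)
  air <- air_state(temperature_K = 293.15, pressure_Pa = 101325)
  rho <- 101325 / (8.314 * 293.15)
  expect_equal(rho, 41.57, tolerance = 1e-3)
  flux <- initial_slope_flux(list(b1 = 0.5), geom, air)
  expect_equal(flux, 0.5 * rho * 0.15, tolerance = 1e-12)
  expect_equal(flux, 3.118, tolerance = 1e-3)

  expect_equal(initial_slope_flux(list(b1 = 0), geom, air), 0)

  # linear in V (at fixed A), inverse in temperature
  geom2 <- chamber_geometry(0.10, 2 * geom$system_volume_m3)
  expect_equal(initial_slope_flux(list(b1 = 0.5), geom2, air), 2 * flux)
  air2 <- air_state(2 * 293.15, 101325)
  expect_equal(initial_slope_flux(list(b1 = 0.5), geom, air2), flux / 2)
  # negative slope (uptake) passes through unclamped
  expect_lt(initial_slope_flux(list(b1 = -0.1), geom, air), 0)
  expect_error(initial_slope_flux(list(b1 = NaN), geom, air), "non-finite")
})

test_that("trace QC classifies without raising", {
  t5 <- c(0, 30, 60, 90, 120)
  good <- chamber_trace("p", "2014-06-01", t5, 420 + 0.4 * t5)
  res <- qc_trace(good)
  expect_true(res$accept)
  expect_length(res$reasons, 0)

  short <- data.frame(elapsed_s = c(0, 30, 60), co2_ppm = c(420, 430, 440))
  res <- qc_trace(short, min_points = 4)
  expect_false(res$accept)
  expect_true("insufficient_points" %in% res$reasons)

  high <- chamber_trace("p", "2014-06-01", t5, 1200 + 0.4 * t5)
  res <- qc_trace(high, ambient_ppm = 450, max_start_ppm_dev = 150)
  expect_false(res$accept)
  expect_true("implausible_start" %in% res$reasons)

  flat <- chamber_trace("p", "2014-06-01", t5, c(420, 419, 418, 417, 416))
  res <- qc_trace(flat)
  expect_true(res$accept)  # flagged, not rejected
  expect_true("non_increasing_trend" %in% res$flags)
})

test_that("median flux recovery over 1000 noisy synthetic traces is within 1% of truth", {
  true_flux <- 3
  rec <- vapply(seq_len(1000), function(s) {
    tr <- generate_chamber_trace(true_flux, saturation_coeff = 1e-3,
                                 noise_sd_ppm = 1, seed = s)
    initial_slope_flux(fit_quadratic(tr))
  }, numeric(1))
  expect_lt(abs(stats::median(rec) / true_flux - 1), 0.01)
})
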