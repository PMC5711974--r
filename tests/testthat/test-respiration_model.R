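test_that("Q10 fit recovers generating parameters exactly on noiseless data", {
  temps <- c(0, 5, 10, 15, 20)
  obs <- data.frame(soil_temp_c = temps, rs = 2 * 3^((temps - 10) / 10))
  fit <- fit_q10(obs)
  expect_equal(fit$f10, 2, tolerance = 1e-6)
  expect_equal(fit$q10, 3, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("Q10 fit rejects degenerate designs", {
  obs <- data.frame(soil_temp_c = rep(10, 5), rs = c(2, 2.1, 1.9, 2, 2))
  expect_error(fit_q10(obs), "unidentifiable")
  expect_error(fit_q10(data.frame(soil_temp_c = c(5, 10), rs = c(1, 2))),
               "at least 3")
})

test_that("Q10 fit agrees with a brute-force grid search on noisy data", {
  set.seed(7)
  temps <- seq(2, 18, length.out = 12)
  rs <- 2.2 * 2.8^((temps - 10) / 10) + rnorm(12, 0, 0.2)
  fit <- fit_q10(data.frame(soil_temp_c = temps, rs = rs))
  gr <- grid_search_q10(rs, temps,
                        f10_grid = seq(0.1, 10, by = 0.01),
                        q10_grid = seq(1, 6, by = 0.01))
  expect_lt(abs(fit$f10 - gr$f10), 0.01 + 1e-9)
  expect_lt(abs(fit$q10 - gr$q10), 0.01 + 1e-9)
})

test_that("predict_rs follows the exponential temperature response", {
  fit <- list(f10 = 2, q10 = 2)
  expect_equal(predict_rs(fit, 10), 2)
  expect_equal(predict_rs(fit, 20), 4)
  expect_equal(predict_rs(fit, 0), 1)
  # strictly increasing in T when q10 > 1; constant when q10 = 1
  tt <- seq(-5, 25, by = 0.5)
  expect_true(all(diff(predict_rs(list(f10 = 1.5, q10 = 2.5), tt)) > 0))
  expect_equal(stats::var(predict_rs(list(f10 = 1.5, q10 = 1), tt)), 0)
})

test_that("unit bridge from mean molar flux to areal carbon mass is exact", {
  expect_equal(flux_to_annual_units(0, 1000), 0)
  yr <- 365 * 86400
  expect_equal(flux_to_annual_units(1, yr), 3.788, tolerance = 2e-4)
  expect_equal(flux_to_annual_units(2.6, yr), 9.85, tolerance = 1e-3)
  expect_error(flux_to_annual_units(1, -5), "non-negative")
})

test_that("cumulation reduces to the closed form for constant or insensitive models", {
  const_temps <- sinusoid_series(10, 0)
  out <- cumulate(list(f10 = 1, q10 = 2.5), const_temps)
  expect_equal(out$total_tC_ha, flux_to_annual_units(1, 365 * 86400),
               tolerance = 1e-9)
  # q10 = 1 makes the total independent of the temperature series
  varying <- sinusoid_series(8, 8)
  out1 <- cumulate(list(f10 = 1.7, q10 = 1), varying)
  expect_equal(out1$total_tC_ha, flux_to_annual_units(1.7, 365 * 86400),
               tolerance = 1e-9)
  # daily series partitions the total
  expect_equal(sum(out$daily_series$g_c_m2) * 0.01, out$total_tC_ha,
               tolerance = 1e-9)
  # pure scaling in f10
  out2 <- cumulate(list(f10 = 3.4, q10 = 1), varying)
  expect_equal(out2$total_tC_ha, 2 * out1$total_tC_ha, tolerance = 1e-12)
})

test_that("3-hourly cumulation matches 1-minute numerical integration within 0.2%", {
  for (pars in list(c(2, 2.5), c(1, 3.5), c(3, 2))) {
    temps <- sinusoid_series(8, 8)
    got <- cumulate(list(f10 = pars[1], q10 = pars[2]), temps)$total_tC_ha
    want <- integrate_q10_sinusoid(pars[1], pars[2], 8, 8)
    expect_lt(abs(got / want - 1), 0.002)
  }
})

test_that("cumulation demands sufficient temperature coverage", {
  temps <- sinusoid_series(8, 8)
  sparse <- temps[temps$datetime < as.POSIXct("2014-03-01", tz = "UTC"), ]
  expect_error(
    cumulate(list(f10 = 1, q10 = 2), sparse,
             period = c("2014-01-01", "2015-01-01")),
    "insufficient coverage")
})

test_that("logger preparation averages replicates and bridges short gaps only", {
  base <- sinusoid_series(8, 8)[1:100, ]
  two <- rbind(transform(base, logger_id = "a", soil_temp_c = soil_temp_c + 1),
               transform(base, logger_id = "b", soil_temp_c = soil_temp_c - 1))
  prep <- prepare_temperature_series(two)
  expect_equal(prep$soil_temp_c, base$soil_temp_c, tolerance = 1e-12)

  # a 6-hour hole is interpolated; a 3-day hole is not
  hole <- base
  hole$soil_temp_c[10:11] <- NA
  hole$soil_temp_c[40:63] <- NA
  prep <- prepare_temperature_series(hole, max_gap_h = 24)
  expect_true(all(is.finite(prep$soil_temp_c[10:11])))
  expect_true(all(is.na(prep$soil_temp_c[40:63])))
})

test_that("section aggregation returns mean and standard error", {
  agg <- aggregate_section(c(8, 9, 10))
  expect_equal(agg$mean, 9)
  expect_equal(agg$se, 0.577, tolerance = 1e-3)
  expect_equal(aggregate_section(c(5, 5, 5))$se, 0)
  expect_error(aggregate_section(7), "at least 2")
})

test_that("fit quality on study-like noisy campaigns brackets typical field R-squared", {
  # campaign-level scatter around 20% CV reproduces the 0.79-0.86 range
  # typical of seasonal chamber surveys
  temps <- generate_temperature_series(climate_scenario(noise_sd_c = 0), 1)
  sc <- section_scenario("X", n_plots = 100, f10_mean = 2.3, f10_sd = 0.25,
                         q10_mean = 3, q10_sd = 0.4)
  camp <- generate_campaign_observations(sc, temps, n_campaigns = 12,
                                         noise_cv = 0.2, seed = 11)
  r2 <- vapply(split(camp$observations, camp$observations$plot_id),
               function(d) fit_q10(d)$r_squared, numeric(1))
  band <- stats::quantile(r2, c(0.1, 0.9))
  expect_lt(band[1], 0.86)   # band overlaps the typical field range
  expect_gt(band[2], 0.79)
  expect_gt(stats::median(r2), 0.5)
  expect_lt(stats::median(r2), 0.99)
})
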