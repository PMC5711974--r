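make_pairs <- function(control, ratio, start = "2014-03-15") {
  n <- length(control)
  data.frame(campaign_datetime = as.POSIXct(start, tz = "UTC") +
               (seq_len(n) - 1) * 21 * 86400,
             mean_rs_control = control,
             mean_rs_treated = control * ratio,
             treatment = "trenching",
             stringsAsFactors = FALSE)
}

test_that("trenching fraction is the mean per-campaign percent reduction", {
  p <- make_pairs(c(2, 3, 4, 3, 2), ratio = 1)
  expect_equal(trenching_fraction(p)$autotrophic_fraction_pct, 0)

  p <- make_pairs(seq(1.5, 4.5, length.out = 10), ratio = 0.56)
  est <- trenching_fraction(p)
  expect_equal(est$autotrophic_fraction_pct, 44, tolerance = 1e-9)
  expect_equal(est$se_pct, 0, tolerance = 1e-9)

  # a campaign with treated > control contributes a negative reduction
  p <- make_pairs(c(2, 2), ratio = 1)
  p$mean_rs_treated <- c(1, 3)  # +50% and -50%
  expect_equal(trenching_fraction(p)$autotrophic_fraction_pct, 0)

  # non-positive control campaigns are excluded with a warning
  p <- make_pairs(c(2, 0, 2), ratio = 0.5)
  expect_warning(est <- trenching_fraction(p), "excluded")
  expect_equal(est$n_campaigns, 2)
})

test_that("clipping fraction uses only the stabilized window", {
  early <- make_pairs(c(3, 3, 3), ratio = 1, start = "2014-05-01")
  late <- make_pairs(c(2.5, 2.2, 2.0), ratio = 0.65, start = "2014-09-05")
  p <- rbind(early, late)
  p$treatment <- "clipping"
  est <- clipping_fraction(p, "2014-09-01")
  expect_equal(est$autotrophic_fraction_pct, 35, tolerance = 1e-9)
  # window before all campaigns reduces to the trenching statistic
  est_all <- clipping_fraction(p, "2014-01-01")
  ref <- trenching_fraction(p)
  expect_equal(est_all$autotrophic_fraction_pct,
               ref$autotrophic_fraction_pct, tolerance = 1e-12)
  # single late campaign: SE undefined
  one <- make_pairs(2, ratio = 0.5, start = "2014-10-01")
  one$treatment <- "clipping"
  est1 <- clipping_fraction(one, "2014-09-01")
  expect_equal(est1$autotrophic_fraction_pct, 50)
  expect_true(is.na(est1$se_pct))
  expect_error(clipping_fraction(early, "2014-12-01"), "no campaigns")
})

test_that("reduction estimators are invariant to rescaling all fluxes", {
  set.seed(42)
  for (i in 1:20) {
    ctrl <- runif(8, 1, 5)
    ratio <- runif(1, 0.3, 0.9)
    p <- make_pairs(ctrl, ratio)
    p$mean_rs_treated <- p$mean_rs_treated * exp(rnorm(8, 0, 0.05))
    base <- trenching_fraction(p)$autotrophic_fraction_pct
    k <- runif(1, 0.1, 10)
    p2 <- p
    p2$mean_rs_control <- k * p$mean_rs_control
    p2$mean_rs_treated <- k * p$mean_rs_treated
    expect_equal(trenching_fraction(p2)$autotrophic_fraction_pct, base,
                 tolerance = 1e-9)
  }
})

test_that("fine-root scaling is proportional in the target stock and inverse in the reference", {
  expect_equal(scale_autotrophic_eq1(35, 0.79, 0.40), 35 * 0.40 / 0.79,
               tolerance = 1e-12)
  expect_equal(round(scale_autotrophic_eq1(35, 0.79, 0.40)), 18)
  expect_equal(scale_autotrophic_eq1(35, 0.8, 0.8), 35)
  expect_equal(scale_autotrophic_eq1(35, 0.8, 0), 0)
  # homogeneity: degree 1 in f_target, degree -1 in f_ref (within the
  # unclipped regime; the [0, 100] clip intentionally breaks it outside)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 1, 20); fr <- runif(1, 0.5, 2); ft <- runif(1, 0.1, 1)
    k <- runif(1, 0.5, 1.5)
    base <- scale_autotrophic_eq1(a, fr, ft)
    expect_equal(scale_autotrophic_eq1(a, fr, k * ft), k * base,
                 tolerance = 1e-9)
    expect_equal(scale_autotrophic_eq1(a, k * fr, ft), base / k,
                 tolerance = 1e-9)
  }
  expect_error(scale_autotrophic_eq1(35, 0, 0.4), "positive")
  expect_warning(scale_autotrophic_eq1(80, 0.5, 1), "clipped")
})

test_that("annual partition conserves the total exactly", {
  res <- partition_annual(8.9, 44)
  expect_equal(round(res$ra, 1), 3.9)
  expect_equal(round(res$rh, 1), 5.0)
  res <- partition_annual(8.5, 18)
  expect_equal(round(res$ra, 1), 1.5)
  expect_equal(round(res$rh, 1), 7.0)
  expect_equal(partition_annual(7.3, 0)$ra, 0)
  set.seed(9)
  for (i in 1:50) {
    rs <- runif(1, 0, 15); a <- runif(1, 0, 100)
    res <- partition_annual(rs, a)
    expect_identical(res$ra + res$rh, rs)  # exact conservation
  }
})

test_that("partition estimates clip out-of-range fractions with a warning", {
  expect_warning(pe <- partition_estimate(108, "trenching"), "clipped")
  expect_equal(pe$autotrophic_fraction_pct, 100)
  expect_warning(pe <- partition_estimate(-4, "clipping"), "clipped")
  expect_equal(pe$autotrophic_fraction_pct, 0)
})

test_that("trenching and clipping estimators recover imposed fractions in closed loop", {
  sc_tr <- section_scenario("T", autotrophic_fraction_pct = 44,
                            partition_method = "trenching")
  sc_cl <- section_scenario("C", autotrophic_fraction_pct = 35,
                            partition_method = "clipping")
  temps <- generate_temperature_series(climate_scenario(), seed = 2)
  # noiseless: exact recovery
  p <- generate_treatment_pairs(sc_tr, temps, "trenching", noise_cv = 0)
  expect_equal(trenching_fraction(p)$autotrophic_fraction_pct, 44,
               tolerance = 1e-9)
  p <- generate_treatment_pairs(sc_cl, temps, "clipping", noise_cv = 0,
                                stabilization_date = "2014-09-01")
  expect_equal(
    clipping_fraction(p, "2014-09-01")$autotrophic_fraction_pct, 35,
    tolerance = 1e-6)
  # zero imposed fraction: treated equals control
  sc0 <- section_scenario("Z", autotrophic_fraction_pct = 0)
  p0 <- generate_treatment_pairs(sc0, temps, "trenching", noise_cv = 0)
  expect_equal(p0$mean_rs_treated, p0$mean_rs_control, tolerance = 1e-12)
})
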