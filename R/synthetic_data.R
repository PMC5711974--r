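#' Climate scenario for synthetic soil-temperature generation
#'
#' Describes the seasonal course of soil temperature at 5 cm depth as an
#' annual sinusoid (summer peak in mid-July) plus a damped diurnal sinusoid
#' (afternoon peak) and Gaussian reading noise. Defaults emulate a montane
#' site with a mean annual soil temperature of 8.2 degC and a snow-free
#' campaign season from March to the end of November.
#'
#' @param annual_mean_c Mean annual soil temperature (degC, default 8.2).
#' @param seasonal_amplitude_c Amplitude of the annual sinusoid (degC,
#'   default 7.5).
#' @param diurnal_amplitude_c Amplitude of the diurnal cycle at 5 cm depth
#'   (degC, default 1; soil damps the surface cycle strongly).
#' @param noise_sd_c SD of additive reading noise (degC, default 0.8).
#' @param snow_free Character or Date length-2: first and last day of the
#'   snow-free measurement window.
#' @param year_start First day of the simulated logger year.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(annual_mean_c = 8.2, seasonal_amplitude_c = 7.5,
                             diurnal_amplitude_c = 1, noise_sd_c = 0.8,
                             snow_free = c("2014-03-01", "2014-11-30"),
                             year_start = "2014-01-01") {
  if (seasonal_amplitude_c < 0 || diurnal_amplitude_c < 0 || noise_sd_c < 0)
    stop("amplitudes and noise sd must be non-negative", call. = FALSE)
  structure(
    list(annual_mean_c = annual_mean_c,
         seasonal_amplitude_c = seasonal_amplitude_c,
         diurnal_amplitude_c = diurnal_amplitude_c,
         noise_sd_c = noise_sd_c,
         snow_free = as.Date(snow_free),
         year_start = as.Date(year_start)),
    class = "climate_scenario")
}

#' Section scenario: ground truth for one stand section
#'
#' Holds the generating parameters for one chronosequence section: the
#' distribution of per-plot temperature-response parameters, the imposed
#' autotrophic fraction of soil respiration, and the biomass pools sampled
#' by the litter and fine-root protocols. The autotrophic fraction is
#' imposed as a fraction of total efflux (not modelled mechanistically),
#' which is sufficient to test the partition estimators in closed loop.
#'
#' @param section_id Section identifier (e.g. `"MS"`).
#' @param n_plots Number of flux plots (default 12).
#' @param f10_mean,f10_sd Mean and SD of per-plot F10 (umol CO2 m-2 s-1).
#' @param q10_mean,q10_sd Mean and SD of per-plot Q10.
#' @param autotrophic_fraction_pct Ground-truth autotrophic share of Rs.
#' @param partition_method How the section's fraction is estimated in the
#'   emulated design: `"trenching"`, `"clipping"` or `"fine_root_scaling"`.
#' @param herb_biomass_mean,herb_biomass_sd Herb-layer standing C stock
#'   (t C ha-1) across harvest frames.
#' @param fine_root_c_mean,fine_root_c_sd Fine-root C stock 0--10 cm
#'   (t C ha-1) across soil cores.
#' @param tree_litter_tC_ha_yr Annual tree litterfall C (t C ha-1 yr-1;
#'   0 for clearings).
#' @param biomass_increment_tC_ha_yr Annual tree biomass increment
#'   (t C ha-1 yr-1; 0 for clearings).
#' @return An object of class `section_scenario`.
#' @export
section_scenario <- function(section_id, n_plots = 12,
                             f10_mean = 2.5, f10_sd = 0.25,
                             q10_mean = 3.0, q10_sd = 0.4,
                             autotrophic_fraction_pct = 40,
                             partition_method = c("trenching", "clipping",
                                                  "fine_root_scaling"),
                             herb_biomass_mean = 1, herb_biomass_sd = 0.3,
                             fine_root_c_mean = 0.8, fine_root_c_sd = 0.3,
                             tree_litter_tC_ha_yr = 0,
                             biomass_increment_tC_ha_yr = 0) {
  partition_method <- match.arg(partition_method)
  if (n_plots < 2)
    stop("n_plots must be at least 2", call. = FALSE)
  if (any(c(f10_sd, q10_sd, herb_biomass_sd, fine_root_c_sd) < 0))
    stop("scenario SDs must be non-negative", call. = FALSE)
  if (autotrophic_fraction_pct < 0 || autotrophic_fraction_pct > 100)
    stop("autotrophic fraction must lie in [0, 100]", call. = FALSE)
  structure(
    list(section_id = section_id, n_plots = n_plots,
         f10_mean = f10_mean, f10_sd = f10_sd,
         q10_mean = q10_mean, q10_sd = q10_sd,
         autotrophic_fraction_pct = autotrophic_fraction_pct,
         partition_method = partition_method,
         herb_biomass_mean = herb_biomass_mean,
         herb_biomass_sd = herb_biomass_sd,
         fine_root_c_mean = fine_root_c_mean,
         fine_root_c_sd = fine_root_c_sd,
         tree_litter_tC_ha_yr = tree_litter_tC_ha_yr,
         biomass_increment_tC_ha_yr = biomass_increment_tC_ha_yr),
    class = "section_scenario")
}

#' Generate a one-year 3-hourly soil-temperature series
#'
#' Annual sinusoid (peak at day-of-year 196, mid-July) + diurnal sinusoid
#' (peak at 14:00) + seeded Gaussian noise, at 3-hour resolution over 365
#' days. Fully reproducible per seed.
#'
#' @param climate A [climate_scenario()].
#' @param seed Integer RNG seed.
#' @return Data frame with `datetime` (`POSIXct`, UTC) and `soil_temp_c`.
#' @export
generate_temperature_series <- function(climate = climate_scenario(), seed = 1) {
  set.seed(seed)
  t0 <- as.POSIXct(paste(climate$year_start, "00:00:00"), tz = "UTC")
  dt <- t0 + seq(0, by = 3 * 3600, length.out = 365 * 8)
  doy <- as.numeric(difftime(dt, t0, units = "days"))
  hour <- (as.numeric(dt) / 3600) %% 24
  temp <- climate$annual_mean_c +
    climate$seasonal_amplitude_c * cos(2 * pi * (doy - 196) / 365) +
    climate$diurnal_amplitude_c * cos(2 * pi * (hour - 14) / 24) +
    stats::rnorm(length(dt), 0, climate$noise_sd_c)
  data.frame(datetime = dt, soil_temp_c = temp)
}

#' Campaign dates within the snow-free window
#'
#' Campaigns run every 21 days starting at the beginning of the snow-free
#' window, at 12:00 local time.
#'
#' @param climate A [climate_scenario()].
#' @param n_campaigns Number of campaigns to schedule.
#' @return `POSIXct` vector of campaign datetimes.
#' @export
campaign_dates <- function(climate = climate_scenario(), n_campaigns = 12) {
  days <- seq(climate$snow_free[1], climate$snow_free[2], by = 21)
  if (length(days) < n_campaigns)
    stop("snow-free window too short for the requested number of campaigns",
         call. = FALSE)
  as.POSIXct(paste(days[seq_len(n_campaigns)], "12:00:00"), tz = "UTC")
}

# temperature at the series timestamp nearest to each query time
.series_temp_at <- function(temps, when) {
  tn <- as.numeric(as.POSIXct(temps$datetime, tz = "UTC"))
  qn <- as.numeric(when)
  idx <- vapply(qn, function(q) which.min(abs(tn - q)), integer(1))
  temps$soil_temp_c[idx]
}

# multiplicative lognormal noise with mean 1 and coefficient of variation cv
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate campaign flux observations with known per-plot truth
#'
#' Draws per-plot true (F10, Q10) from the section scenario, evaluates the
#' exponential temperature-response model at each campaign's soil
#' temperature, and multiplies by lognormal noise with mean 1 and
#' coefficient of variation `noise_cv`. The generating parameters are
#' returned alongside the data so recovery can be checked in closed loop.
#'
#' @param scenario A [section_scenario()].
#' @param temps Temperature series (see [generate_temperature_series()]);
#'   campaign temperatures are read off this series.
#' @param n_campaigns Number of campaigns (default 12, minimum 3).
#' @param noise_cv Coefficient of variation of multiplicative flux noise
#'   (default 0.2, matching campaign-level scatter typical of chamber
#'   surveys).
#' @param seed Integer RNG seed.
#' @param climate Climate scenario used for campaign scheduling.
#' @return List with `observations` (data frame: `plot_id`, `section_id`,
#'   `datetime`, `rs`, `soil_temp_c`, `soil_moisture_vol`) and `truth`
#'   (data frame: `plot_id`, `f10`, `q10`).
#' @export
generate_campaign_observations <- function(scenario, temps, n_campaigns = 12,
                                           noise_cv = 0.2, seed = 1,
                                           climate = climate_scenario()) {
  if (n_campaigns < 3)
    stop("n_campaigns must be at least 3", call. = FALSE)
  set.seed(seed)
  when <- campaign_dates(climate, n_campaigns)
  camp_temp <- .series_temp_at(temps, when)
  f10 <- pmax(stats::rnorm(scenario$n_plots, scenario$f10_mean,
                           scenario$f10_sd), 0.05)
  q10 <- pmin(pmax(stats::rnorm(scenario$n_plots, scenario$q10_mean,
                                scenario$q10_sd), 0.6), 9.5)
  plot_ids <- sprintf("%s_p%02d", scenario$section_id,
                      seq_len(scenario$n_plots))
  obs <- do.call(rbind, lapply(seq_len(scenario$n_plots), function(i) {
    rs_true <- f10[i] * q10[i]^((camp_temp - 10) / 10)
    data.frame(plot_id = plot_ids[i],
               section_id = scenario$section_id,
               datetime = when,
               rs = rs_true * .ln_noise(n_campaigns, noise_cv),
               soil_temp_c = camp_temp,
               soil_moisture_vol = pmin(pmax(
                 stats::rnorm(n_campaigns, 40, 5), 0), 100),
               stringsAsFactors = FALSE)
  }))
  rownames(obs) <- NULL
  list(observations = obs,
       truth = data.frame(plot_id = plot_ids, f10 = f10, q10 = q10,
                          stringsAsFactors = FALSE))
}

#' Generate treated/control campaign pairs for a partition experiment
#'
#' Control flux follows the section's mean temperature-response model with
#' multiplicative noise. The treated flux has the autotrophic share removed:
#' constant removal for trenching (roots severed from the start); for
#' clipping a linear ramp from zero removal at the first campaign up to the
#' full scenario fraction at `stabilization_date` (clipped vegetation keeps
#' resprouting early on), constant thereafter.
#'
#' @param scenario A [section_scenario()]; its `autotrophic_fraction_pct`
#'   is the imposed ground truth.
#' @param temps Temperature series for campaign temperatures.
#' @param treatment `"trenching"` or `"clipping"`.
#' @param n_campaigns Number of campaigns.
#' @param noise_cv CV of multiplicative noise on each campaign mean
#'   (default 0.05; campaign means over 12 plots are much less noisy than
#'   single chambers).
#' @param stabilization_date When the clipping effect reaches its plateau
#'   (default 1 September of the simulated year).
#' @param seed Integer RNG seed.
#' @param climate Climate scenario used for campaign scheduling.
#' @return Data frame with `campaign_datetime`, `section_id`, `treatment`,
#'   `mean_rs_control`, `mean_rs_treated`; the imposed fraction is attached
#'   as attribute `"true_fraction_pct"`.
#' @export
generate_treatment_pairs <- function(scenario, temps,
                                     treatment = c("trenching", "clipping"),
                                     n_campaigns = 12, noise_cv = 0.05,
                                     stabilization_date = NULL, seed = 1,
                                     climate = climate_scenario()) {
  treatment <- match.arg(treatment)
  set.seed(seed)
  when <- campaign_dates(climate, n_campaigns)
  camp_temp <- .series_temp_at(temps, when)
  base <- scenario$f10_mean * scenario$q10_mean^((camp_temp - 10) / 10)
  a_true <- scenario$autotrophic_fraction_pct
  if (treatment == "trenching") {
    a_t <- rep(a_true, n_campaigns)
  } else {
    if (is.null(stabilization_date))
      stabilization_date <- paste0(format(climate$year_start, "%Y"), "-09-01")
    stab <- as.POSIXct(paste(stabilization_date, "00:00:00"), tz = "UTC")
    ramp <- as.numeric(when - when[1], units = "days") /
      max(as.numeric(stab - when[1], units = "days"), 1)
    a_t <- a_true * pmin(pmax(ramp, 0), 1)
  }
  ctrl <- base * .ln_noise(n_campaigns, noise_cv)
  trt <- base * (1 - a_t / 100) * .ln_noise(n_campaigns, noise_cv)
  out <- data.frame(campaign_datetime = when,
                    section_id = scenario$section_id,
                    treatment = treatment,
                    mean_rs_control = ctrl,
                    mean_rs_treated = trt,
                    stringsAsFactors = FALSE)
  attr(out, "true_fraction_pct") <- a_true
  out
}

#' Forward-simulate a closed-chamber CO2 trace
#'
#' Concentration rises linearly at the rate implied by the true flux and
#' chamber geometry (the exact inverse of [initial_slope_flux()]), minus a
#' quadratic saturation term emulating the flattening of the diffusion
#' gradient, plus seeded Gaussian reading noise. With zero noise,
#' `initial_slope_flux(fit_quadratic(trace))` returns `true_flux` exactly
#' for any saturation coefficient.
#'
#' @param true_flux Soil CO2 efflux to emulate (umol m-2 s-1).
#' @param geom A [chamber_geometry()].
#' @param air An [air_state()].
#' @param saturation_coeff Quadratic headspace saturation (ppm s-2,
#'   default 0).
#' @param noise_sd_ppm SD of reading noise (ppm, default 0).
#' @param seed Integer RNG seed (ignored when `noise_sd_ppm = 0`).
#' @param c0 Starting concentration (ppm, default 420).
#' @param n_samples Number of samples over the closure (default 20).
#' @param duration_s Chamber closure time (seconds, default 120).
#' @param plot_id Identifier stored on the trace.
#' @param start_time Closure timestamp stored on the trace.
#' @return A [chamber_trace()].
#' @export
generate_chamber_trace <- function(true_flux, geom = chamber_geometry(),
                                   air = air_state(), saturation_coeff = 0,
                                   noise_sd_ppm = 0, seed = 1, c0 = 420,
                                   n_samples = 20, duration_s = 120,
                                   plot_id = "sim",
                                   start_time = "2014-06-01 10:00:00") {
  t <- seq(0, duration_s, length.out = n_samples)
  slope <- true_flux * geom$footprint_area_m2 /
    (geom$system_volume_m3 * .molar_density(air))  # ppm s-1
  co2 <- c0 + slope * t - saturation_coeff * t^2
  if (noise_sd_ppm > 0) {
    set.seed(seed)
    co2 <- co2 + stats::rnorm(n_samples, 0, noise_sd_ppm)
  }
  chamber_trace(plot_id, start_time, t, pmax(co2, 1), duration_s)
}

#' Generate biomass harvest samples and fine-root cores
#'
#' Herb frames (0.5 x 0.5 m clip harvests) and fine-root soil cores are
#' drawn so that per-sample C stocks are normal around the scenario means
#' (truncated at zero). Dry masses are back-converted from C stocks with
#' the standard C fractions, so downstream [herb_litter_input()] recovers
#' the stocks. Tree-litter collector catches (for forested sections) are
#' drawn around the scenario's annual litterfall.
#'
#' @param scenario A [section_scenario()].
#' @param n_herb_frames Number of herb harvest frames (default 6).
#' @param n_root_cores Number of fine-root cores (default 12).
#' @param n_collectors Number of tree-litter collectors (default 5; only
#'   generated when the scenario has non-zero tree litterfall).
#' @param herb_c_fraction,litter_c_fraction C fractions used for the dry
#'   mass back-conversion (defaults 0.475 and 0.50).
#' @param frame_area_m2 Harvest frame area (default 0.25).
#' @param collector_area_m2 Litter collector area (default 0.68 m diameter).
#' @param rel_sd Relative SD of collector catches (default 0.15).
#' @param seed Integer RNG seed.
#' @return List with `herb_samples`, `tree_litter_samples` (possibly
#'   `NULL`), `fine_root` (list `section_id`, `fine_root_c_tC_ha`,
#'   `n_cores`, `sd`), and `truth` (the scenario means).
#' @export
generate_biomass_samples <- function(scenario, n_herb_frames = 6,
                                     n_root_cores = 12, n_collectors = 5,
                                     herb_c_fraction = 0.475,
                                     litter_c_fraction = 0.50,
                                     frame_area_m2 = 0.25,
                                     collector_area_m2 = pi * 0.34^2,
                                     rel_sd = 0.15, seed = 1) {
  if (n_herb_frames < 2 || n_root_cores < 2)
    stop("need at least 2 herb frames and 2 root cores", call. = FALSE)
  set.seed(seed)
  herb_stock <- pmax(stats::rnorm(n_herb_frames, scenario$herb_biomass_mean,
                                  scenario$herb_biomass_sd), 0)
  # t C ha-1 -> g C m-2 (x100) -> g dry per frame
  herb_dry <- herb_stock * 100 / herb_c_fraction * frame_area_m2
  herb_samples <- data.frame(section_id = scenario$section_id,
                             dry_mass_g = herb_dry,
                             frame_area_m2 = frame_area_m2,
                             compartment = "herb",
                             stringsAsFactors = FALSE)
  root_stock <- pmax(stats::rnorm(n_root_cores, scenario$fine_root_c_mean,
                                  scenario$fine_root_c_sd), 0)
  fine_root <- list(section_id = scenario$section_id,
                    fine_root_c_tC_ha = mean(root_stock),
                    n_cores = n_root_cores,
                    sd = stats::sd(root_stock))
  tree_samples <- NULL
  if (scenario$tree_litter_tC_ha_yr > 0) {
    catch_c <- pmax(stats::rnorm(
      n_collectors, scenario$tree_litter_tC_ha_yr,
      rel_sd * scenario$tree_litter_tC_ha_yr), 0)
    tree_dry <- catch_c * 100 / litter_c_fraction * collector_area_m2
    tree_samples <- data.frame(section_id = scenario$section_id,
                               dry_mass_g = tree_dry,
                               compartment = "tree_litter",
                               stringsAsFactors = FALSE)
  }
  list(herb_samples = herb_samples,
       tree_litter_samples = tree_samples,
       fine_root = fine_root,
       truth = list(herb_biomass_tC_ha = scenario$herb_biomass_mean,
                    fine_root_c_tC_ha = scenario$fine_root_c_mean,
                    tree_litter_tC_ha_yr = scenario$tree_litter_tC_ha_yr))
}

#' F10 that yields a target annual efflux under a climate scenario
#'
#' Inverts the annual cumulation: because the cumulated total is exactly
#' proportional to F10 at fixed Q10 and temperature series, the F10 whose
#' annual total equals `target_tC_ha` is `target / total(F10 = 1)`. The
#' noise-free climate (deterministic sinusoids) is used.
#'
#' @param target_tC_ha Target annual soil respiration (t C ha-1).
#' @param q10 Q10 of the evaluating model.
#' @param climate A [climate_scenario()].
#' @return F10 in umol CO2 m-2 s-1.
#' @export
f10_for_annual <- function(target_tC_ha, q10, climate = climate_scenario()) {
  quiet <- climate
  quiet$noise_sd_c <- 0
  temps <- generate_temperature_series(quiet, seed = 0)
  unit <- cumulate(list(f10 = 1, q10 = q10), temps)$total_tC_ha
  target_tC_ha / unit
}

#' Bundled three-section study scenarios
#'
#' A ready-made chronosequence triple -- an undisturbed mature spruce stand
#' (`MS`), a sparsely vegetated 3-year-old clearing (`PD03`) and a densely
#' grass-covered 6-year-old clearing (`PD06`) -- with flux magnitudes,
#' autotrophic fractions, biomass pools, litterfall and biomass increment
#' set to the magnitudes observed in montane Norway spruce chronosequence
#' studies. Per-section `f10_mean` is calibrated with [f10_for_annual()] so
#' the expected annual soil respiration matches the target magnitudes
#' (about 8.9, 8.5 and 8.9 t C ha-1 yr-1).
#'
#' @param climate The [climate_scenario()] the scenarios will be run under.
#' @return Named list of three [section_scenario()] objects
#'   (`MS`, `PD03`, `PD06`).
#' @export
default_study_scenarios <- function(climate = climate_scenario()) {
  q10 <- 3.0
  mk_f10 <- function(target) f10_for_annual(target, q10, climate)
  list(
    MS = section_scenario(
      "MS", n_plots = 12,
      f10_mean = mk_f10(8.88), f10_sd = 0.11 * mk_f10(8.88),
      q10_mean = q10, q10_sd = 0.4,
      autotrophic_fraction_pct = 44, partition_method = "trenching",
      herb_biomass_mean = 0.32, herb_biomass_sd = 0.08,
      fine_root_c_mean = 1.56, fine_root_c_sd = 0.68,
      tree_litter_tC_ha_yr = 1.8, biomass_increment_tC_ha_yr = 3.8),
    PD03 = section_scenario(
      "PD03", n_plots = 12,
      f10_mean = mk_f10(8.53), f10_sd = 0.11 * mk_f10(8.53),
      q10_mean = q10, q10_sd = 0.4,
      autotrophic_fraction_pct = 18, partition_method = "fine_root_scaling",
      herb_biomass_mean = 1.16, herb_biomass_sd = 0.45,
      fine_root_c_mean = 0.40, fine_root_c_sd = 0.50,
      tree_litter_tC_ha_yr = 0, biomass_increment_tC_ha_yr = 0),
    PD06 = section_scenario(
      "PD06", n_plots = 12,
      f10_mean = mk_f10(8.85), f10_sd = 0.11 * mk_f10(8.85),
      q10_mean = q10, q10_sd = 0.4,
      autotrophic_fraction_pct = 35, partition_method = "clipping",
      herb_biomass_mean = 2.26, herb_biomass_sd = 0.65,
      fine_root_c_mean = 0.79, fine_root_c_sd = 0.34,
      tree_litter_tC_ha_yr = 0, biomass_increment_tC_ha_yr = 0))
}

#' Simulate a complete multi-section field study
#'
#' Generates, per section: a replicated logger temperature series (the
#' section series plus independent logger noise), campaign flux
#' observations with per-plot truth, treatment pairs for the section's
#' partition experiment (trenching or clipping), and biomass samples. All
#' randomness derives from `seed`; the same seed reproduces the study
#' exactly.
#'
#' @param scenarios Named list of [section_scenario()] objects.
#' @param climate A [climate_scenario()].
#' @param seed Integer master seed.
#' @param n_campaigns Campaigns per section (default 12).
#' @param noise_cv CV of campaign flux noise (default 0.2).
#' @param pair_noise_cv CV of treatment-pair campaign means (default 0.05).
#' @param n_loggers Replicate loggers per section (default 4).
#' @param logger_noise_sd_c SD of per-logger deviation (degC, default 0.3).
#' @return List of class `synthetic_study` with elements `sections` (one
#'   list per section: `loggers`, `temps`, `observations`, `pairs`,
#'   `biomass`, `truth`), plus `climate`, `scenarios` and `seed`.
#' @export
simulate_study <- function(scenarios = default_study_scenarios(),
                           climate = climate_scenario(), seed = 1,
                           n_campaigns = 12, noise_cv = 0.2,
                           pair_noise_cv = 0.05, n_loggers = 4,
                           logger_noise_sd_c = 0.3) {
  sections <- list()
  for (k in seq_along(scenarios)) {
    sc <- scenarios[[k]]
    sseed <- (seed * 131 + k * 7919) %% 2147483647L
    temps <- generate_temperature_series(climate, seed = sseed)
    set.seed(sseed + 1)
    loggers <- do.call(rbind, lapply(seq_len(n_loggers), function(l) {
      data.frame(section_id = sc$section_id,
                 logger_id = sprintf("%s_L%d", sc$section_id, l),
                 datetime = temps$datetime,
                 soil_temp_c = temps$soil_temp_c +
                   stats::rnorm(nrow(temps), 0, logger_noise_sd_c),
                 stringsAsFactors = FALSE)
    }))
    camp <- generate_campaign_observations(sc, temps, n_campaigns, noise_cv,
                                           seed = sseed + 2, climate = climate)
    pairs <- NULL
    if (sc$partition_method %in% c("trenching", "clipping")) {
      pairs <- generate_treatment_pairs(sc, temps,
                                        treatment = sc$partition_method,
                                        n_campaigns = n_campaigns,
                                        noise_cv = pair_noise_cv,
                                        seed = sseed + 3, climate = climate)
    }
    biomass <- generate_biomass_samples(sc, seed = sseed + 4)
    sections[[sc$section_id]] <- list(
      scenario = sc, temps = temps, loggers = loggers,
      observations = camp$observations, pairs = pairs, biomass = biomass,
      truth = list(plots = camp$truth,
                   autotrophic_fraction_pct = sc$autotrophic_fraction_pct))
  }
  structure(list(sections = sections, climate = climate,
                 scenarios = scenarios, seed = seed),
            class = "synthetic_study")
}
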