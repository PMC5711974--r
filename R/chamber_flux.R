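#' Closed-chamber CO2 trace
#'
#' Bundles one closed-chamber headspace CO2 time series measured on a soil
#' collar. Concentrations are mole fractions (ppm, i.e. umol CO2 per mol air)
#' sampled at known times after chamber closure.
#'
#' @param plot_id Identifier of the measurement plot.
#' @param start_time Closure time (`POSIXct` or ISO 8601 string).
#' @param elapsed_s Seconds since closure; non-negative, strictly increasing.
#' @param co2_ppm CO2 mole fraction at each sample; all positive.
#' @param duration_s Total closure duration in seconds. Defaults to the last
#'   sample time.
#'
#' @return An object of class `chamber_trace`.
#' @examples
#' tr <- chamber_trace("p1", "2014-06-01 10:00:00",
#'                     elapsed_s = c(0, 30, 60, 90, 120),
#'                     co2_ppm = 400 + 0.4 * c(0, 30, 60, 90, 120))
#' @export
chamber_trace <- function(plot_id, start_time, elapsed_s, co2_ppm,
                          duration_s = max(elapsed_s)) {
  if (length(elapsed_s) != length(co2_ppm))
    stop("elapsed_s and co2_ppm must have equal length", call. = FALSE)
  if (length(elapsed_s) < 4L)
    stop("invalid trace: at least 4 samples are required for a quadratic fit",
         call. = FALSE)
  if (any(!is.finite(elapsed_s)) || any(!is.finite(co2_ppm)))
    stop("invalid trace: non-finite values", call. = FALSE)
  if (any(diff(elapsed_s) <= 0))
    stop("invalid trace: elapsed_s must be strictly increasing", call. = FALSE)
  if (elapsed_s[1] < 0)
    stop("invalid trace: elapsed_s must be non-negative", call. = FALSE)
  if (any(co2_ppm <= 0))
    stop("invalid trace: co2_ppm must be positive", call. = FALSE)
  if (duration_s < max(elapsed_s))
    stop("invalid trace: duration_s shorter than last sample", call. = FALSE)
  structure(
    list(plot_id = plot_id,
         start_time = as.POSIXct(start_time, tz = "UTC"),
         elapsed_s = as.numeric(elapsed_s),
         co2_ppm = as.numeric(co2_ppm),
         duration_s = as.numeric(duration_s)),
    class = "chamber_trace")
}

#' Chamber and collar geometry
#'
#' Geometry of the chamber/collar system: the collar footprint (the soil area
#' the flux refers to) and the total enclosed headspace volume. Defaults
#' correspond to a 10 cm diameter survey collar with a small-chamber system
#' volume of 1.17 L, typical for portable IRGA soil-respiration chambers; the
#' volume should be overridden with the instrument's actual value when known.
#'
#' @param collar_diameter_m Inner collar diameter in metres (default 0.10).
#' @param system_volume_m3 Chamber + collar headspace volume in cubic metres
#'   (default 1.17e-3).
#' @return An object of class `chamber_geometry` with the derived
#'   `footprint_area_m2`.
#' @export
chamber_geometry <- function(collar_diameter_m = 0.10,
                             system_volume_m3 = 1.17e-3) {
  if (collar_diameter_m <= 0 || system_volume_m3 <= 0)
    stop("geometry values must be positive", call. = FALSE)
  structure(
    list(collar_diameter_m = collar_diameter_m,
         system_volume_m3 = system_volume_m3,
         footprint_area_m2 = pi * (collar_diameter_m / 2)^2),
    class = "chamber_geometry")
}

#' Air state inside the chamber
#'
#' Temperature and pressure used to convert a ppm-per-second concentration
#' rise into a molar flux via the ideal gas law. When pressure is not
#' measured, [barometric_pressure()] gives a standard-atmosphere estimate
#' from site elevation.
#'
#' @param temperature_K Air temperature in kelvin.
#' @param pressure_Pa Air pressure in pascal.
#' @return An object of class `air_state`.
#' @export
air_state <- function(temperature_K = 283.15,
                      pressure_Pa = barometric_pressure(950)) {
  if (temperature_K <= 0 || pressure_Pa <= 0)
    stop("air state values must be positive", call. = FALSE)
  structure(list(temperature_K = temperature_K, pressure_Pa = pressure_Pa),
            class = "air_state")
}

#' Standard-atmosphere pressure at a given elevation
#'
#' International standard atmosphere barometric formula. At 950 m a.s.l. this
#' gives about 90.4 kPa.
#'
#' @param elevation_m Elevation above sea level in metres.
#' @return Pressure in pascal.
#' @export
barometric_pressure <- function(elevation_m) {
  101325 * (1 - 2.25577e-5 * elevation_m)^5.25588
}

#' Fit a quadratic to a chamber CO2 trace
#'
#' Ordinary least squares fit of `co2_ppm ~ a0 + b1 t + c2 t^2` against
#' elapsed time. The linear coefficient `b1` is the concentration rise rate
#' at the moment of closure; the curvature `c2` absorbs the progressive
#' saturation of the headspace (the diffusion gradient flattens as CO2
#' accumulates), so evaluating the derivative at t = 0 minimises
#' chamber-feedback bias relative to a straight-line fit.
#'
#' @param trace A [chamber_trace()], or a data frame with columns `elapsed_s`
#'   and `co2_ppm`.
#' @return An object of class `quadratic_fit`: list with `a0` (ppm), `b1`
#'   (ppm s-1), `c2` (ppm s-2) and `rss` (residual sum of squares, ppm^2).
#' @examples
#' t <- c(0, 30, 60, 90, 120)
#' tr <- chamber_trace("p1", "2014-06-01", t, 400 + 0.5 * t - 0.001 * t^2)
#' fit_quadratic(tr)
#' @export
fit_quadratic <- function(trace) {
  if (inherits(trace, "chamber_trace")) {
    t <- trace$elapsed_s
    y <- trace$co2_ppm
  } else {
    t <- trace$elapsed_s
    y <- trace$co2_ppm
  }
  if (length(t) < 4L)
    stop("invalid trace: at least 4 samples are required", call. = FALSE)
  if (length(unique(t)) < 3L)
    stop("singular fit: need at least 3 distinct sample times", call. = FALSE)
  fit <- stats::lm(y ~ t + I(t^2))
  cf <- unname(stats::coef(fit))
  structure(
    list(a0 = cf[1], b1 = cf[2], c2 = cf[3],
         rss = sum(stats::residuals(fit)^2), n = length(t)),
    class = "quadratic_fit")
}

# molar density of air (mol m-3) from the ideal gas law
.molar_density <- function(air) {
  R_GAS <- 8.314  # J mol-1 K-1
  air$pressure_Pa / (R_GAS * air$temperature_K)
}

#' Soil CO2 efflux from a fitted chamber trace
#'
#' Converts the initial concentration rise rate `b1` (ppm s-1) of a quadratic
#' chamber fit into a molar areal flux:
#' \deqn{F = b_1 \, \rho \, V / A}
#' where \eqn{\rho = P / (R T)} is the molar density of air (mol m-3), `V`
#' the system volume and `A` the collar footprint. Since ppm is umol per mol
#' of air, the result is in umol CO2 m-2 s-1. Negative rates (uptake) are
#' passed through unclamped.
#'
#' @param fit A `quadratic_fit` from [fit_quadratic()], or any list with a
#'   numeric `b1`.
#' @param geom A [chamber_geometry()].
#' @param air An [air_state()].
#' @return Flux in umol CO2 m-2 s-1.
#' @export
initial_slope_flux <- function(fit, geom = chamber_geometry(),
                               air = air_state()) {
  b1 <- fit$b1
  if (!is.finite(b1))
    stop("cannot propagate non-finite fitted slope", call. = FALSE)
  b1 * .molar_density(air) * geom$system_volume_m3 / geom$footprint_area_m2
}

#' Quality control of a chamber trace
#'
#' Deterministic screening that never raises: it classifies a trace as
#' accepted or rejected with machine-readable reason codes. A non-increasing
#' overall trend is flagged (`"non_increasing_trend"`) but not auto-rejected,
#' since genuine CO2 uptake is possible.
#'
#' Reason codes: `"insufficient_points"` (fewer than `min_points` samples)
#' and `"implausible_start"` (first concentration outside
#' `ambient_ppm +/- max_start_ppm_dev`).
#'
#' @param trace A [chamber_trace()] or a data frame with `elapsed_s` and
#'   `co2_ppm` columns (invariants are not assumed; QC inspects raw data).
#' @param min_points Minimum number of samples to accept (default 4).
#' @param ambient_ppm Expected ambient CO2 concentration (default 450 ppm).
#' @param max_start_ppm_dev Maximum allowed deviation of the first sample
#'   from `ambient_ppm` (default 150 ppm, i.e. a 300--600 ppm window).
#' @return A list with `accept` (logical), `reasons` (character vector of
#'   rejection codes, empty when accepted) and `flags` (non-fatal notices).
#' @export
qc_trace <- function(trace, min_points = 4L, ambient_ppm = 450,
                     max_start_ppm_dev = 150) {
  y <- trace$co2_ppm
  reasons <- character(0)
  flags <- character(0)
  if (length(y) < min_points)
    reasons <- c(reasons, "insufficient_points")
  if (length(y) >= 1L && abs(y[1] - ambient_ppm) > max_start_ppm_dev)
    reasons <- c(reasons, "implausible_start")
  if (length(y) >= 2L && y[length(y)] <= y[1])
    flags <- c(flags, "non_increasing_trend")
  list(accept = length(reasons) == 0L, reasons = reasons, flags = flags)
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("Chamber quadratic fit (n = %d)\n", x$n))
  cat(sprintf("  a0 = %.2f ppm, b1 = %.4f ppm/s, c2 = %.3e ppm/s^2\n",
              x$a0, x$b1, x$c2))
  cat(sprintf("  rss = %.4g ppm^2\n", x$rss))
  invisible(x)
}
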