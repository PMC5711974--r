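#' Fit the exponential (Q10) temperature-response model to plot fluxes
#'
#' Fits
#' \deqn{R_s = F_{10} \, Q_{10}^{(T - 10)/10}}
#' to campaign flux observations of one plot by nonlinear least squares
#' (Levenberg-Marquardt, via \pkg{minpack.lm}). `F10` is the soil CO2 efflux
#' at a soil temperature of 10 degC and `Q10` the multiplicative increase in
#' efflux per 10 degC of warming. Fits use the soil temperature measured
#' manually alongside each chamber measurement (5 cm depth), not logger
#' values.
#'
#' Start values are `f10 = mean(rs)`, `q10 = 2`; bounds keep `f10 > 0` and
#' `q10` within (0.5, 10) to prevent pathological exponents on noisy plots.
#' `r_squared = 1 - SSres/SStot` may be negative for very poor fits and is
#' stored as-is.
#'
#' @param observations Data frame with numeric columns `rs` (umol CO2 m-2
#'   s-1) and `soil_temp_c` (degC at 5 cm); typically one plot's campaigns.
#' @param plot_id Optional identifier recorded in the result (taken from a
#'   `plot_id` column when present).
#' @param start Named list of start values, `f10` and `q10`.
#' @param lower,upper Parameter bounds, in the order (f10, q10).
#' @return An object of class `q10_fit`: `plot_id`, `f10`, `q10`,
#'   `r_squared`, `n_obs`, `converged`.
#' @examples
#' temps <- c(2, 6, 10, 14, 18)
#' obs <- data.frame(soil_temp_c = temps, rs = 2 * 3^((temps - 10) / 10))
#' fit_q10(obs)
#' @export
fit_q10 <- function(observations, plot_id = NULL,
                    start = list(f10 = NULL, q10 = 2),
                    lower = c(1e-8, 0.5), upper = c(Inf, 10)) {
  rs <- observations$rs
  tc <- observations$soil_temp_c
  keep <- is.finite(rs) & is.finite(tc)
  rs <- rs[keep]; tc <- tc[keep]
  if (length(rs) < 3L)
    stop("fit_q10 needs at least 3 observations", call. = FALSE)
  if (length(unique(tc)) < 2L)
    stop("unidentifiable fit: all observations at the same temperature",
         call. = FALSE)
  if (is.null(plot_id) && !is.null(observations$plot_id))
    plot_id <- as.character(observations$plot_id[1])
  f10_start <- if (is.null(start$f10)) max(mean(rs), 1e-6) else start$f10
  q10_start <- if (is.null(start$q10)) 2 else start$q10

  dat <- data.frame(rs = rs, tc = tc)
  fit <- try(minpack.lm::nlsLM(
    rs ~ f10 * q10^((tc - 10) / 10),
    data = dat,
    start = list(f10 = f10_start, q10 = q10_start),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)

  if (inherits(fit, "try-error")) {
    # LM failed outright; report the start values as a non-converged fit
    cf <- c(f10 = f10_start, q10 = q10_start)
    converged <- FALSE
    resid <- rs - cf[["f10"]] * cf[["q10"]]^((tc - 10) / 10)
  } else {
    cf <- stats::coef(fit)
    converged <- fit$convInfo$isConv
    resid <- stats::residuals(fit)
  }
  ss_res <- sum(resid^2)
  ss_tot <- sum((rs - mean(rs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(plot_id = plot_id,
         f10 = unname(cf[["f10"]]),
         q10 = unname(cf[["q10"]]),
         r_squared = r2,
         n_obs = length(rs),
         converged = converged),
    class = "q10_fit")
}

#' Predict soil CO2 efflux from a Q10 fit
#'
#' Evaluates \eqn{R_s = F_{10} Q_{10}^{(T-10)/10}} at the given soil
#' temperatures.
#'
#' @param fit A `q10_fit`, or any list with numeric `f10` and `q10`.
#' @param soil_temp_c Soil temperature(s) in degC.
#' @return Efflux in umol CO2 m-2 s-1 (vectorised over `soil_temp_c`).
#' @export
predict_rs <- function(fit, soil_temp_c) {
  fit$f10 * fit$q10^((soil_temp_c - 10) / 10)
}

#' Convert a mean molar flux held over a duration to areal carbon mass
#'
#' Bridges instantaneous chamber units to annual budget units:
#' umol CO2 m-2 s-1 sustained for `seconds` becomes tonnes of carbon per
#' hectare via the molar mass of carbon (12.011 g mol-1):
#' `flux * seconds * 12.011e-6 g C m-2`, then `g C m-2 * 0.01 = t C ha-1`.
#'
#' @param mean_flux Mean flux in umol CO2 m-2 s-1.
#' @param seconds Duration in seconds (non-negative).
#' @return Cumulative flux in t C ha-1.
#' @examples
#' flux_to_annual_units(1, 365 * 86400)  # 3.788 t C ha-1
#' @export
flux_to_annual_units <- function(mean_flux, seconds) {
  if (any(seconds < 0))
    stop("seconds must be non-negative", call. = FALSE)
  M_C <- 12.011  # g mol-1
  g_c_m2 <- mean_flux * seconds * M_C * 1e-6
  g_c_m2 * 1e-6 * 1e4  # g m-2 -> t ha-1
}

#' Average replicate temperature loggers and fill short gaps
#'
#' Collapses a long logger table (several loggers per section, nominal 3-h
#' interval) to a single section series by averaging available loggers per
#' timestamp, then linearly interpolates missing readings up to `max_gap_h`.
#' Gaps longer than that are left as `NA` and will trigger an
#' insufficient-coverage error downstream.
#'
#' @param loggers Data frame with columns `datetime` (`POSIXct` or ISO 8601
#'   string), `soil_temp_c`, and optionally `logger_id` and `section_id`.
#' @param max_gap_h Maximum gap length (hours) to bridge by linear
#'   interpolation (default 24).
#' @return Data frame with `datetime` and `soil_temp_c`, one row per
#'   timestamp, sorted.
#' @export
prepare_temperature_series <- function(loggers, max_gap_h = 24) {
  dt <- as.POSIXct(loggers$datetime, tz = "UTC")
  agg <- stats::aggregate(list(soil_temp_c = loggers$soil_temp_c),
                          by = list(datetime = dt),
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg <- agg[order(agg$datetime), , drop = FALSE]
  agg$soil_temp_c[is.nan(agg$soil_temp_c)] <- NA_real_
  miss <- is.na(agg$soil_temp_c)
  if (any(miss) && any(!miss)) {
    tnum <- as.numeric(agg$datetime)
    filled <- stats::approx(tnum[!miss], agg$soil_temp_c[!miss], xout = tnum,
                            rule = 1)$y
    # only accept interpolated values whose bracketing gap is short enough
    runs <- rle(miss)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      i0 <- idx_start[k]; i1 <- idx_end[k]
      lo <- if (i0 > 1L) tnum[i0 - 1L] else NA_real_
      hi <- if (i1 < length(tnum)) tnum[i1 + 1L] else NA_real_
      gap_h <- (hi - lo) / 3600
      if (is.finite(gap_h) && gap_h <= max_gap_h)
        agg$soil_temp_c[i0:i1] <- filled[i0:i1]
    }
  }
  rownames(agg) <- NULL
  agg
}

#' Cumulate a Q10 model over a continuous temperature series
#'
#' Evaluates the fitted temperature-response model at every logger timestamp
#' within `period`, holds each predicted rate constant over the interval to
#' the next reading (left-constant weighting), and sums to cumulative carbon.
#' The trailing interval is closed with the period end. Also returns the
#' per-calendar-day cumulative series in g C m-2.
#'
#' @param fit A `q10_fit` (or list with `f10`, `q10`).
#' @param temps Data frame with `datetime` and `soil_temp_c` (one reading
#'   per timestamp; see [prepare_temperature_series()]).
#' @param period Length-2 vector (`POSIXct` or string) giving the
#'   half-open cumulation window `[start, end)`. Defaults to the full span
#'   of `temps` plus one trailing nominal interval.
#' @param min_coverage Minimum fraction of the period that must be covered
#'   by finite temperature readings (default 0.95).
#' @param max_interval_h Longest interval (hours) a single reading may
#'   represent (default 24); longer stretches count as uncovered.
#' @return An object of class `annual_flux`: `plot_id`, `period`,
#'   `total_tC_ha` and `daily_series` (data frame `date`, `g_c_m2`).
#' @export
cumulate <- function(fit, temps, period = NULL, min_coverage = 0.95,
                     max_interval_h = 24) {
  dt <- as.POSIXct(temps$datetime, tz = "UTC")
  o <- order(dt)
  dt <- dt[o]
  tc <- temps$soil_temp_c[o]
  if (length(dt) < 2L)
    stop("temperature series too short to cumulate", call. = FALSE)
  spacing <- stats::median(diff(as.numeric(dt)))
  if (is.null(period)) {
    period <- c(dt[1], dt[length(dt)] + spacing)
  } else {
    period <- as.POSIXct(period, tz = "UTC")
  }
  in_win <- dt >= period[1] & dt < period[2]
  dt <- dt[in_win]; tc <- tc[in_win]
  ok <- is.finite(tc)
  period_s <- as.numeric(period[2]) - as.numeric(period[1])
  cap_s <- max_interval_h * 3600
  tn <- as.numeric(dt)
  bounds <- c(tn, as.numeric(period[2]))
  widths <- pmin(diff(bounds), cap_s)
  covered <- sum(widths[ok])
  if (length(dt) == 0L || covered / period_s < min_coverage)
    stop(sprintf(
      "insufficient coverage: %.1f%% of period covered by temperature data",
      if (period_s > 0) 100 * covered / period_s else 0), call. = FALSE)
  dt <- dt[ok]; tc <- tc[ok]
  tn <- tn[ok]
  bounds <- c(tn, as.numeric(period[2]))
  widths <- pmin(diff(bounds), cap_s)

  rs <- predict_rs(fit, tc)                  # umol m-2 s-1 per interval
  g_per_interval <- rs * widths * 12.011e-6  # g C m-2

  day <- as.Date(dt, tz = "UTC")
  daily <- stats::aggregate(list(g_c_m2 = g_per_interval),
                            by = list(date = day), FUN = sum)
  total_g <- sum(g_per_interval)
  structure(
    list(plot_id = fit$plot_id,
         period = period,
         total_tC_ha = total_g * 0.01,
         daily_series = daily),
    class = "annual_flux")
}

#' Section mean and standard error of annual plot fluxes
#'
#' @param annuals List of `annual_flux` objects, or a numeric vector of
#'   plot totals (t C ha-1).
#' @return List with `mean`, `se` (sd/sqrt(n)) and `n`.
#' @export
aggregate_section <- function(annuals) {
  totals <- if (is.numeric(annuals)) annuals
            else vapply(annuals, function(a) a$total_tC_ha, numeric(1))
  if (length(totals) < 2L)
    stop("aggregate_section needs at least 2 plots", call. = FALSE)
  list(mean = mean(totals),
       se = stats::sd(totals) / sqrt(length(totals)),
       n = length(totals))
}

#' @export
print.q10_fit <- function(x, ...) {
  cat(sprintf("Q10 temperature-response fit%s\n",
              if (!is.null(x$plot_id)) paste0(" [", x$plot_id, "]") else ""))
  cat(sprintf("  F10 = %.3f umol m-2 s-1, Q10 = %.3f, R2 = %.3f (n = %d%s)\n",
              x$f10, x$q10, x$r_squared, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
print.annual_flux <- function(x, ...) {
  cat(sprintf("Cumulative soil CO2 efflux%s: %.3f t C ha-1 (%s to %s)\n",
              if (!is.null(x$plot_id)) paste0(" [", x$plot_id, "]") else "",
              x$total_tC_ha, format(x$period[1]), format(x$period[2])))
  invisible(x)
}
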