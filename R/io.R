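#' Read chamber traces from a long-format CSV
#'
#' Expects columns `plot_id`, `start_time` (ISO 8601), `elapsed_s`,
#' `co2_ppm`; one trace per (plot_id, start_time) group.
#'
#' @param path CSV file path.
#' @return List of [chamber_trace()] objects.
#' @export
read_chamber_traces <- function(path) {
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$plot_id, df$start_time, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$elapsed_s), , drop = FALSE]
    chamber_trace(g$plot_id[1], g$start_time[1], g$elapsed_s, g$co2_ppm)
  })
}

#' Compute fluxes for a set of chamber traces
#'
#' Applies QC, quadratic fitting and the initial-slope flux conversion to
#' each trace. Rejected traces get `NA` flux and carry their QC reasons.
#'
#' @param traces List of [chamber_trace()] objects.
#' @param geom A [chamber_geometry()].
#' @param air An [air_state()] (applied to every trace).
#' @param ... Passed to [qc_trace()].
#' @return Data frame with `plot_id`, `start_time`, `flux_umol_m2_s`,
#'   `accepted`, `qc_reasons`.
#' @export
traces_to_fluxes <- function(traces, geom = chamber_geometry(),
                             air = air_state(), ...) {
  rows <- lapply(traces, function(tr) {
    qc <- qc_trace(tr, ...)
    flux <- if (qc$accept)
      initial_slope_flux(fit_quadratic(tr), geom, air) else NA_real_
    data.frame(plot_id = tr$plot_id,
               start_time = tr$start_time,
               flux_umol_m2_s = flux,
               accepted = qc$accept,
               qc_reasons = paste(qc$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic study to the pipeline's CSV dialects
#'
#' Emits the campaign, logger, treatment-pair and biomass tables consumed
#' by the files-mode pipeline, plus a JSON truth sidecar holding every
#' generating parameter, so a run can be replayed from disk.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  secs <- study$sections
  # write full timestamps: a bare midnight date would make readers parse
  # the whole column date-only
  stamp <- function(df) {
    for (nm in intersect(c("datetime", "campaign_datetime"), names(df)))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    df
  }
  grab <- function(f) stamp(do.call(rbind, c(lapply(secs, f),
                                             list(make.row.names = FALSE))))
  paths <- list(
    campaign = file.path(dir, "campaign_observations.csv"),
    loggers = file.path(dir, "logger_temperatures.csv"),
    pairs = file.path(dir, "treatment_pairs.csv"),
    herb = file.path(dir, "herb_biomass.csv"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(grab(function(s) s$observations), paths$campaign,
                   row.names = FALSE)
  utils::write.csv(grab(function(s) s$loggers), paths$loggers,
                   row.names = FALSE)
  pairs <- stamp(do.call(rbind, c(Filter(Negate(is.null),
                                         lapply(secs, `[[`, "pairs")),
                                  list(make.row.names = FALSE))))
  utils::write.csv(pairs, paths$pairs, row.names = FALSE)
  utils::write.csv(grab(function(s) s$biomass$herb_samples), paths$herb,
                   row.names = FALSE)
  truth <- lapply(secs, function(s) list(
    autotrophic_fraction_pct = s$truth$autotrophic_fraction_pct,
    plots = s$truth$plots,
    fine_root_c_tC_ha = s$biomass$fine_root$fine_root_c_tC_ha))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
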