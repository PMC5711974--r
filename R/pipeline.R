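#' Default pipeline configuration
#'
#' Returns the full configuration list with documented defaults. Override
#' entries (or supply a YAML file to [run_pipeline()]) as needed.
#'
#' Sections of the config:
#' \describe{
#'   \item{mode}{`"synthetic"` (simulate a study and analyse it),
#'     `"files"` (read campaign/logger/pair/biomass CSVs) or `"bypass"`
#'     (pre-computed annual fluxes, fractions and litters; budget stage
#'     only).}
#'   \item{chamber/air}{Chamber geometry and air-state policy for raw-trace
#'     flux computation.}
#'   \item{fit}{Q10 optimizer start value and bounds.}
#'   \item{cumulation}{`period` (NULL = full logger span), `max_gap_h`
#'     logger-gap interpolation limit, `min_coverage`.}
#'   \item{partition}{`stabilization_start` for clipping windows;
#'     `weights` for campaign averaging.}
#'   \item{litter}{C fractions and fine-root turnover (yr-1).}
#' }
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    mode = "synthetic",
    seed = 1,
    output_dir = NULL,
    n_campaigns = 12,
    noise_cv = 0.2,
    chamber = list(diameter_m = 0.10, volume_m3 = 1.17e-3),
    air = list(pressure_pa = barometric_pressure(950),
               temperature_offset_c = 0),
    fit = list(q10_start = 2, q10_lower = 0.5, q10_upper = 10),
    cumulation = list(period = NULL, max_gap_h = 24, min_coverage = 0.95),
    partition = list(stabilization_start = "2014-09-01",
                     weights = "campaign"),
    litter = list(c_fraction_herb = 0.475, c_fraction_tree = 0.50,
                  fine_root_turnover = 0.8),
    paths = list(campaign = NULL, loggers = NULL, pairs = NULL,
                 herb = NULL, tree_litter = NULL, fine_roots = NULL),
    sections = NULL,
    bypass = NULL
  ), class = "run_config")
}

# deep-merge user entries over defaults
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else
      base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and complete a pipeline configuration
#'
#' @param config A named list of overrides, a path to a YAML file, or
#'   `NULL` for pure defaults.
#' @return A complete `run_config` list.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  out <- .merge_config(base, config)
  class(out) <- "run_config"
  out
}

#' Validate a pipeline configuration
#'
#' Never raises: returns a data frame of findings with `level`
#' (`"error"`/`"warning"`) and `message`. Warnings cover defaulted or
#' suspicious-but-legal settings (e.g. a clearing with a positive biomass
#' increment); errors cover contradictions and out-of-range parameters.
#'
#' @param config A config list or YAML path (see [load_config()]).
#' @return Data frame with columns `level` and `message` (zero rows when
#'   clean).
#' @export
validate_config <- function(config = NULL) {
  cfg <- load_config(config)
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)

  if (!cfg$mode %in% c("synthetic", "files", "bypass"))
    add("error", sprintf("unknown mode '%s'", cfg$mode))
  if (cfg$litter$fine_root_turnover < 0)
    add("error", "litter$fine_root_turnover must be non-negative")
  for (nm in c("c_fraction_herb", "c_fraction_tree")) {
    v <- cfg$litter[[nm]]
    if (v < 0 || v > 1) add("error", sprintf("litter$%s must lie in [0, 1]", nm))
  }
  if (cfg$chamber$diameter_m <= 0 || cfg$chamber$volume_m3 <= 0)
    add("error", "chamber geometry must be positive")
  if (cfg$air$pressure_pa <= 0)
    add("error", "air$pressure_pa must be positive")
  if (cfg$fit$q10_lower <= 0 || cfg$fit$q10_upper <= cfg$fit$q10_lower)
    add("error", "fit bounds must satisfy 0 < q10_lower < q10_upper")
  if (cfg$cumulation$min_coverage <= 0 || cfg$cumulation$min_coverage > 1)
    add("error", "cumulation$min_coverage must lie in (0, 1]")
  if (cfg$mode == "files") {
    for (nm in c("campaign", "loggers")) {
      p <- cfg$paths[[nm]]
      if (is.null(p))
        add("error", sprintf("files mode requires paths$%s", nm))
      else if (!file.exists(p))
        add("error", sprintf("input file not found: %s", p))
    }
  }
  if (cfg$mode == "bypass" && is.null(cfg$bypass))
    add("error", "bypass mode requires a 'bypass' block")
  if (!is.null(cfg$sections)) {
    for (s in names(cfg$sections)) {
      sec <- cfg$sections[[s]]
      inc <- sec$biomass_increment %||% 0
      if (identical(sec$kind, "clearing") && inc > 0)
        add("warning", sprintf(
          "section '%s' is a clearing but has biomass_increment > 0", s))
    }
  }
  if (is.null(config))
    add("warning", "running with all-default configuration")
  if (length(findings) == 0L)
    return(data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse a simulated study end-to-end
#'
#' Runs the full analysis chain on a [simulate_study()] result: per-plot
#' Q10 fits from campaign observations, annual cumulation over the
#' logger-average temperature series, partition estimation (trenching /
#' clipping / fine-root scaling, with the clipping section as the scaling
#' reference), litter inputs from the biomass samples, and budget assembly.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param config Configuration overrides (see [default_config()]).
#' @return List with `budget` (a `carbon_budget`), `table` (one-decimal
#'   report layout), `fits` (per-plot data frame), `annuals`,
#'   `partitions`, and `litters`.
#' @export
analyze_study <- function(study, config = NULL) {
  cfg <- load_config(config)
  sections <- names(study$sections)
  fits_all <- list(); annual_tab <- list()
  rs_annual <- list(); partitions <- list(); litters <- list()
  increments <- list()
  clip_ref <- NULL

  for (s in sections) {
    sec <- study$sections[[s]]
    temps <- prepare_temperature_series(sec$loggers,
                                        max_gap_h = cfg$cumulation$max_gap_h)
    obs <- sec$observations
    plot_fits <- lapply(split(obs, obs$plot_id), fit_q10)
    annuals <- lapply(plot_fits, cumulate, temps = temps,
                      period = cfg$cumulation$period,
                      min_coverage = cfg$cumulation$min_coverage)
    agg <- aggregate_section(annuals)
    rs_annual[[s]] <- agg$mean
    fits_all[[s]] <- data.frame(
      section_id = s,
      plot_id = vapply(plot_fits, `[[`, character(1), "plot_id"),
      f10 = vapply(plot_fits, `[[`, numeric(1), "f10"),
      q10 = vapply(plot_fits, `[[`, numeric(1), "q10"),
      r_squared = vapply(plot_fits, `[[`, numeric(1), "r_squared"),
      n_obs = vapply(plot_fits, `[[`, integer(1), "n_obs"),
      converged = vapply(plot_fits, `[[`, logical(1), "converged"),
      annual_tC_ha = vapply(annuals, `[[`, numeric(1), "total_tC_ha"),
      stringsAsFactors = FALSE)
    annual_tab[[s]] <- data.frame(section_id = s, mean_tC_ha = agg$mean,
                                  se_tC_ha = agg$se, n_plots = agg$n,
                                  stringsAsFactors = FALSE)

    method <- sec$scenario$partition_method
    if (method == "trenching") {
      partitions[[s]] <- trenching_fraction(sec$pairs, section_id = s,
                                            weights = cfg$partition$weights)
    } else if (method == "clipping") {
      partitions[[s]] <- clipping_fraction(
        sec$pairs, cfg$partition$stabilization_start, section_id = s,
        weights = cfg$partition$weights)
      clip_ref <- s
    }

    herb <- herb_litter_input(sec$biomass$herb_samples,
                              c_fraction = cfg$litter$c_fraction_herb)
    tree <- if (!is.null(sec$biomass$tree_litter_samples))
      tree_litter_input(sec$biomass$tree_litter_samples,
                        c_fraction = cfg$litter$c_fraction_tree)
    else list(mean = 0, sd = NA_real_, n = 0L)
    root <- root_litter_input(sec$biomass$fine_root$fine_root_c_tC_ha,
                              cfg$litter$fine_root_turnover)
    litters[[s]] <- list(tree = tree$mean, herb = herb$mean, root = root)
    increments[[s]] <- sec$scenario$biomass_increment_tC_ha_yr
  }

  # fine-root scaling sections borrow the clipping section's fraction
  for (s in sections) {
    if (study$sections[[s]]$scenario$partition_method != "fine_root_scaling")
      next
    if (is.null(clip_ref))
      stop(sprintf(
        "section '%s' uses fine-root scaling but no clipping reference section exists",
        s), call. = FALSE)
    a_ref <- partitions[[clip_ref]]$autotrophic_fraction_pct
    f_ref <- study$sections[[clip_ref]]$biomass$fine_root$fine_root_c_tC_ha
    f_tgt <- study$sections[[s]]$biomass$fine_root$fine_root_c_tC_ha
    partitions[[s]] <- partition_estimate(
      scale_autotrophic_eq1(a_ref, f_ref, f_tgt),
      method = "fine_root_scaling", section_id = s)
  }

  budget <- assemble_budget(sections, rs_annual, partitions, litters,
                            increments)
  list(budget = budget,
       table = format_budget_table(budget),
       fits = do.call(rbind, c(fits_all, list(make.row.names = FALSE))),
       annuals = do.call(rbind, c(annual_tab, list(make.row.names = FALSE))),
       partitions = partitions,
       litters = litters)
}

# analysis over CSV inputs (files mode)
.analyze_files <- function(cfg) {
  read_req <- function(p, what) {
    if (is.null(p) || !file.exists(p))
      stop(sprintf("%s file not found: %s", what, p %||% "<unset>"),
           call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  obs <- read_req(cfg$paths$campaign, "campaign")
  loggers <- read_req(cfg$paths$loggers, "logger")
  if (is.null(obs$rs)) {
    stop("campaign table has no 'rs' column; compute fluxes from raw traces first",
         call. = FALSE)
  }
  sections <- unique(obs$section_id)
  pairs <- if (!is.null(cfg$paths$pairs))
    read_req(cfg$paths$pairs, "treatment-pair") else NULL

  rs_annual <- list(); partitions <- list(); litters <- list()
  increments <- list(); fits_all <- list(); annual_tab <- list()
  for (s in sections) {
    so <- obs[obs$section_id == s, , drop = FALSE]
    lg <- loggers[loggers$section_id == s, , drop = FALSE]
    temps <- prepare_temperature_series(lg,
                                        max_gap_h = cfg$cumulation$max_gap_h)
    plot_fits <- lapply(split(so, so$plot_id), fit_q10)
    annuals <- lapply(plot_fits, cumulate, temps = temps,
                      period = cfg$cumulation$period,
                      min_coverage = cfg$cumulation$min_coverage)
    agg <- aggregate_section(annuals)
    rs_annual[[s]] <- agg$mean
    fits_all[[s]] <- data.frame(
      section_id = s,
      plot_id = vapply(plot_fits, `[[`, character(1), "plot_id"),
      f10 = vapply(plot_fits, `[[`, numeric(1), "f10"),
      q10 = vapply(plot_fits, `[[`, numeric(1), "q10"),
      r_squared = vapply(plot_fits, `[[`, numeric(1), "r_squared"),
      annual_tC_ha = vapply(annuals, `[[`, numeric(1), "total_tC_ha"),
      stringsAsFactors = FALSE)
    annual_tab[[s]] <- data.frame(section_id = s, mean_tC_ha = agg$mean,
                                  se_tC_ha = agg$se, n_plots = agg$n,
                                  stringsAsFactors = FALSE)
    seccfg <- cfg$sections[[s]] %||% list()
    method <- seccfg$partition_method %||% "trenching"
    if (!is.null(pairs) && method %in% c("trenching", "clipping")) {
      sp <- pairs[pairs$section_id == s, , drop = FALSE]
      partitions[[s]] <- if (method == "trenching")
        trenching_fraction(sp, section_id = s) else
        clipping_fraction(sp, cfg$partition$stabilization_start,
                          section_id = s)
    } else if (!is.null(seccfg$autotrophic_fraction_pct)) {
      partitions[[s]] <- partition_estimate(
        seccfg$autotrophic_fraction_pct,
        method = "fine_root_scaling", section_id = s)
    } else {
      stop(sprintf("no partition source for section '%s'", s), call. = FALSE)
    }
    litters[[s]] <- list(tree = seccfg$tree_litter %||% 0,
                         herb = seccfg$herb_litter %||% 0,
                         root = root_litter_input(
                           seccfg$fine_root_c %||% 0,
                           cfg$litter$fine_root_turnover))
    increments[[s]] <- seccfg$biomass_increment %||% 0
  }
  budget <- assemble_budget(sections, rs_annual, partitions, litters,
                            increments)
  list(budget = budget, table = format_budget_table(budget),
       fits = do.call(rbind, c(fits_all, list(make.row.names = FALSE))),
       annuals = do.call(rbind, c(annual_tab, list(make.row.names = FALSE))),
       partitions = partitions, litters = litters)
}

# budget stage only, from pre-computed components (bypass mode)
.analyze_bypass <- function(cfg) {
  bp <- cfg$bypass
  if (is.null(bp))
    stop("bypass mode requires a 'bypass' config block", call. = FALSE)
  sections <- names(bp$rs_annual)
  rh_given <- bp$rh %||% NULL
  partitions <- lapply(sections, function(s) bp$fractions[[s]])
  names(partitions) <- sections
  budget <- assemble_budget(sections, bp$rs_annual, partitions,
                            bp$litters, bp$increments)
  # when rh is supplied directly (printed one-decimal values), honour it
  if (!is.null(rh_given)) {
    for (s in sections) {
      i <- which(budget$section_id == s)
      budget$rh[i] <- rh_given[[s]]
      budget$ra[i] <- budget$rs_annual[i] - budget$rh[i]
      budget$nep[i] <- compute_nep(
        rh = budget$rh[i], biomass_increment = budget$biomass_increment[i],
        tree_litter = budget$tree_litter[i],
        herb_litter = budget$herb_litter[i],
        root_litter = budget$root_litter[i])
    }
  }
  list(budget = budget, table = format_budget_table(budget),
       fits = NULL, annuals = NULL, partitions = partitions,
       litters = bp$litters)
}

#' Run the carbon-budget pipeline end-to-end
#'
#' Orchestrates all stages according to the config `mode`: synthetic
#' (simulate then analyse), files (CSV inputs), or bypass (budget assembly
#' from pre-computed annual fluxes, fractions and litters). When
#' `output_dir` is set, writes the per-plot fit table, annual totals,
#' partition table, long and wide budget CSVs, and a plain-text run report
#' listing every effective parameter.
#'
#' @param config Config list or YAML path (see [default_config()]).
#' @return Invisibly, a list with `budget`, `table`, `fits`, `annuals`,
#'   `partitions`, `litters` and (when written) `paths`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(mode = "synthetic", seed = 42))
#' res$table
#' }
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_config(config)
  findings <- validate_config(cfg)
  errs <- findings$message[findings$level == "error"]
  if (length(errs) > 0)
    stop(paste(c("invalid configuration:", errs), collapse = "\n  "),
         call. = FALSE)

  res <- switch(cfg$mode,
    synthetic = {
      study <- simulate_study(seed = cfg$seed,
                              n_campaigns = cfg$n_campaigns,
                              noise_cv = cfg$noise_cv)
      analyze_study(study, cfg)
    },
    files = .analyze_files(cfg),
    bypass = .analyze_bypass(cfg))

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    wr <- function(df, name) {
      if (is.null(df)) return(NULL)
      p <- file.path(cfg$output_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    paths$fits <- wr(res$fits, "plot_fits.csv")
    paths$annuals <- wr(res$annuals, "annual_rs.csv")
    part_df <- do.call(rbind, lapply(names(res$partitions), function(s) {
      p <- res$partitions[[s]]
      if (inherits(p, "partition_estimate"))
        data.frame(section_id = s, method = p$method,
                   autotrophic_fraction_pct = p$autotrophic_fraction_pct,
                   se_pct = p$se_pct, stringsAsFactors = FALSE)
      else
        data.frame(section_id = s, method = "given",
                   autotrophic_fraction_pct = p, se_pct = NA_real_,
                   stringsAsFactors = FALSE)
    }))
    paths$partitions <- wr(part_df, "partitions.csv")
    paths$budget_long <- wr(as.data.frame(res$budget), "budget_long.csv")
    paths$budget_table <- wr(res$table, "budget_table.csv")
    rpt <- file.path(cfg$output_dir, "run_report.txt")
    writeLines(c(
      "fluxbudget run report",
      sprintf("mode: %s  seed: %s", cfg$mode, cfg$seed),
      sprintf("fine-root turnover: %g yr-1", cfg$litter$fine_root_turnover),
      sprintf("C fractions: herb %.3f, tree litter %.2f",
              cfg$litter$c_fraction_herb, cfg$litter$c_fraction_tree),
      sprintf("stabilization start (clipping): %s",
              cfg$partition$stabilization_start),
      "",
      "Per-section NEP (t C ha-1 yr-1):",
      sprintf("  %s: %.1f", res$budget$section_id, res$budget$nep)
    ), rpt)
    paths$report <- rpt
    res$paths <- paths
  }
  invisible(res)
}

#' Reported budget components of a montane spruce chronosequence
#'
#' Published per-section carbon-budget components for an undisturbed mature
#' Norway spruce stand (`MS`) and two post-disturbance clearings cleared
#' three (`PD03`) and six (`PD06`) years before the study year: modelled
#' annual soil respiration, autotrophic percentages from trenching,
#' fine-root scaling and clipping, litter inputs, fine-root stocks, tree
#' biomass increment and the heterotrophic respiration component, all at
#' the reported one-decimal precision. Used to replay the budget arithmetic
#' and validate [compute_nep()] against the reported NEP values.
#'
#' @return Data frame with one row per section.
#' @export
reference_budget_inputs <- function() {
  data.frame(
    section_id = c("MS", "PD03", "PD06"),
    rs_annual = c(8.9, 8.5, 8.9),
    autotrophic_fraction_pct = c(44, 18, 35),
    rh = c(5.0, 7.0, 5.8),
    biomass_increment = c(3.8, 0, 0),
    tree_litter = c(1.8, 0, 0),
    herb_litter = c(0.3, 1.2, 2.3),
    root_litter = c(1.2, 0.3, 0.6),
    fine_root_stock_tC_ha = c(1.56, 0.40, 0.79),
    herb_biomass_tC_ha = c(0.32, 1.16, 2.26),
    stringsAsFactors = FALSE)
}
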