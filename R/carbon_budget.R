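#' Herb-layer litter carbon input from clip-harvest samples
#'
#' Converts frame-harvested, oven-dry ground-vegetation biomass to an areal
#' carbon input. Standing herb biomass at the end of the growing season is
#' taken 1:1 as the annual aboveground ground-vegetation litter input -- a
#' deliberately conservative assumption for short-lived herbs and grasses.
#'
#' @param samples Data frame of harvest samples with columns `dry_mass_g`
#'   (oven-dry mass per frame), `frame_area_m2` and `compartment`
#'   (must be `"herb"`).
#' @param c_fraction Carbon fraction of dry biomass (default 0.475).
#' @return List with `mean`, `sd` and `n`; units t C ha-1 yr-1.
#' @examples
#' s <- data.frame(dry_mass_g = 100, frame_area_m2 = 0.25, compartment = "herb")
#' herb_litter_input(s)$mean  # 1.9 t C ha-1 yr-1
#' @export
herb_litter_input <- function(samples, c_fraction = 0.475) {
  .litter_from_samples(samples, "herb", c_fraction)
}

.litter_from_samples <- function(samples, compartment, c_fraction) {
  if (nrow(samples) == 0L)
    stop("no samples provided", call. = FALSE)
  if (!all(samples$compartment == compartment))
    stop(sprintf("all samples must have compartment = '%s'", compartment),
         call. = FALSE)
  if (any(samples$frame_area_m2 <= 0))
    stop("frame_area_m2 must be positive", call. = FALSE)
  g_c_m2 <- samples$dry_mass_g * c_fraction / samples$frame_area_m2
  t_ha <- g_c_m2 * 0.01
  list(mean = mean(t_ha),
       sd = if (length(t_ha) >= 2L) stats::sd(t_ha) else NA_real_,
       n = length(t_ha))
}

#' Tree litterfall carbon input from litter collectors
#'
#' Scales the annual oven-dry litter mass caught per collector to an areal
#' carbon flux. Each sample row is one collector's pooled annual catch.
#'
#' @param samples Data frame with columns `dry_mass_g` (annual dry mass per
#'   collector) and `compartment` (must be `"tree_litter"`).
#' @param c_fraction Carbon fraction of dry litter (default 0.50).
#' @param collector_area_m2 Collector opening area; default is a 0.68 m
#'   diameter round collector (0.3632 m2).
#' @return List with `mean`, `sd` and `n`; units t C ha-1 yr-1.
#' @export
tree_litter_input <- function(samples, c_fraction = 0.50,
                              collector_area_m2 = pi * 0.34^2) {
  if (collector_area_m2 <= 0)
    stop("collector_area_m2 must be positive", call. = FALSE)
  if (nrow(samples) == 0L)
    stop("no samples provided", call. = FALSE)
  if (!all(samples$compartment == "tree_litter"))
    stop("all samples must have compartment = 'tree_litter'", call. = FALSE)
  g_c_m2 <- samples$dry_mass_g * c_fraction / collector_area_m2
  t_ha <- g_c_m2 * 0.01
  list(mean = mean(t_ha),
       sd = if (length(t_ha) >= 2L) stats::sd(t_ha) else NA_real_,
       n = length(t_ha))
}

#' Belowground litter input from fine-root stock and turnover
#'
#' Annual fine-root litter input is the standing fine-root carbon stock
#' (0--10 cm) multiplied by an annual turnover rate.
#'
#' @param fine_root_c Fine-root C stock in t C ha-1 (non-negative).
#' @param turnover Turnover rate in yr-1 (default 0.8).
#' @return Root litter input in t C ha-1 yr-1.
#' @examples
#' root_litter_input(0.79)  # 0.632 t C ha-1 yr-1
#' @export
root_litter_input <- function(fine_root_c, turnover = 0.8) {
  if (any(fine_root_c < 0) || any(turnover < 0))
    stop("fine_root_c and turnover must be non-negative", call. = FALSE)
  fine_root_c * turnover
}

#' Net ecosystem productivity from budget components
#'
#' \deqn{NEP = \Delta B + L_{tree} + L_{herb} + L_{root} - R_h}
#' where \eqn{\Delta B} is the annual tree biomass increment and the L terms
#' the annual litter carbon inputs. Positive NEP means the section is an
#' atmospheric carbon sink. For clearings (no trees) the increment and tree
#' litter are structurally zero, reducing NEP to litter input minus
#' heterotrophic respiration.
#'
#' @param rh Annual heterotrophic respiration (t C ha-1 yr-1); required.
#' @param biomass_increment Annual tree biomass increment (t C ha-1 yr-1).
#' @param tree_litter,herb_litter,root_litter Annual litter C inputs
#'   (t C ha-1 yr-1).
#' @return NEP in t C ha-1 yr-1 (unrounded).
#' @examples
#' compute_nep(rh = 5.0, biomass_increment = 3.8, tree_litter = 1.8,
#'             herb_litter = 0.3, root_litter = 1.2)  # 2.1
#' @export
compute_nep <- function(rh, biomass_increment = 0, tree_litter = 0,
                        herb_litter = 0, root_litter = 0) {
  if (missing(rh) || is.null(rh) || !is.finite(rh))
    stop("heterotrophic respiration (rh) is required", call. = FALSE)
  biomass_increment + tree_litter + herb_litter + root_litter - rh
}

#' Assemble per-section carbon budgets
#'
#' Combines annual soil respiration, an autotrophic-fraction estimate,
#' litter inputs and the tree biomass increment into one budget row per
#' section, enforcing internal consistency (`rh = rs - ra` exactly; NEP from
#' [compute_nep()]). All values stay unrounded; use [format_budget_table()]
#' for one-decimal reporting.
#'
#' @param sections Character vector of section identifiers.
#' @param rs_annual Named numeric vector (or list) of annual soil
#'   respiration per section (t C ha-1 yr-1).
#' @param partitions Named list of `partition_estimate` objects (or bare
#'   percentages) per section.
#' @param litters Named list per section; each element a list with elements
#'   `tree`, `herb`, `root` (t C ha-1 yr-1; missing elements default to 0).
#' @param increments Named numeric vector of annual biomass increments;
#'   sections absent from it get 0 (clearings).
#' @return A data frame of class `carbon_budget` with one row per section:
#'   `section_id`, `biomass_increment`, `rs_annual`,
#'   `autotrophic_fraction_pct`, `ra`, `rh`, `tree_litter`, `herb_litter`,
#'   `root_litter`, `nep`.
#' @export
assemble_budget <- function(sections, rs_annual, partitions, litters,
                            increments = NULL) {
  rows <- lapply(sections, function(s) {
    rs <- rs_annual[[s]]
    if (is.null(rs) || !is.finite(rs))
      stop(sprintf("missing annual soil respiration for section '%s'", s),
           call. = FALSE)
    part <- partitions[[s]]
    if (is.null(part))
      stop(sprintf("missing partition estimate for section '%s'", s),
           call. = FALSE)
    lit <- litters[[s]]
    if (is.null(lit))
      stop(sprintf("missing litter inputs for section '%s'", s),
           call. = FALSE)
    pick <- function(x) if (is.null(x)) 0 else if (is.list(x)) x$mean else x
    frac <- if (inherits(part, "partition_estimate"))
      part$autotrophic_fraction_pct else part
    split <- partition_annual(rs, frac)
    inc <- if (!is.null(increments) && !is.null(increments[[s]]))
      increments[[s]] else 0
    tl <- pick(lit$tree); hl <- pick(lit$herb); rl <- pick(lit$root)
    data.frame(section_id = s,
               biomass_increment = inc,
               rs_annual = rs,
               autotrophic_fraction_pct = frac,
               ra = split$ra,
               rh = split$rh,
               tree_litter = tl,
               herb_litter = hl,
               root_litter = rl,
               nep = compute_nep(rh = split$rh, biomass_increment = inc,
                                 tree_litter = tl, herb_litter = hl,
                                 root_litter = rl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("carbon_budget", "data.frame")
  out
}

#' Budget report table at one-decimal precision
#'
#' Reshapes a [assemble_budget()] result into the conventional report layout
#' (components as rows, sections as columns), rounding to one decimal with
#' round-half-even. Rounding happens only here, at reporting time.
#'
#' @param budget A `carbon_budget` data frame.
#' @return A data frame with a `component` column and one column per
#'   section.
#' @export
format_budget_table <- function(budget) {
  comp <- c(biomass_increment = "Annual biomass increment [t C/ha/yr]",
            rs_annual = "Soil respiration Rs [t C/ha/yr]",
            autotrophic_fraction_pct = "Autotrophic [%]",
            ra = "Autotrophic [t C/ha/yr]",
            rh = "Heterotrophic [t C/ha/yr]",
            tree_litter = "Tree litter [t C/ha/yr]",
            herb_litter = "Herb litter [t C/ha/yr]",
            root_litter = "Root litter [t C/ha/yr]",
            nep = "NEP [t C/ha/yr]")
  out <- data.frame(component = unname(comp), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(budget))) {
    vals <- unlist(budget[i, names(comp)])
    vals <- ifelse(names(comp) == "autotrophic_fraction_pct",
                   round(vals), round(vals, 1))
    out[[budget$section_id[i]]] <- unname(vals)
  }
  out
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat("Per-section carbon budget (t C ha-1 yr-1):\n")
  print.data.frame(format_budget_table(x), row.names = FALSE)
  invisible(x)
}
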