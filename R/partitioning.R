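#' Autotrophic fraction from a trenching experiment
#'
#' In trenched plots all live roots are severed, so the measured efflux
#' approximates heterotrophic respiration only. The autotrophic fraction of
#' total soil respiration is estimated per campaign as the percent reduction
#' `100 * (1 - treated/control)` and averaged with equal campaign weights;
#' the standard error is computed across campaigns. Campaigns with a
#' non-positive control mean are excluded with a warning. Per-campaign
#' reductions are not clamped (a treated flux above its control contributes
#' a negative reduction); only the final estimate is clipped to [0, 100]
#' with a warning.
#'
#' @param pairs Data frame with columns `campaign_datetime`,
#'   `mean_rs_control`, `mean_rs_treated` (both umol CO2 m-2 s-1) and
#'   optionally `treatment`.
#' @param section_id Optional identifier recorded in the result.
#' @param weights `"campaign"` (default; equal weight per campaign) or
#'   `"flux"` (campaigns weighted by their control flux).
#' @return An object of class `partition_estimate`: `section_id`, `method`,
#'   `autotrophic_fraction_pct`, `se_pct` (`NA` for a single campaign),
#'   `n_campaigns`.
#' @examples
#' pairs <- data.frame(campaign_datetime = as.POSIXct("2014-06-01") + 1:5,
#'                     mean_rs_control = c(2, 3, 4, 3, 2))
#' pairs$mean_rs_treated <- 0.56 * pairs$mean_rs_control
#' trenching_fraction(pairs)
#' @export
trenching_fraction <- function(pairs, section_id = NULL,
                               weights = c("campaign", "flux")) {
  weights <- match.arg(weights)
  .reduction_estimate(pairs, method = "trenching", section_id = section_id,
                      weights = weights)
}

#' Autotrophic fraction from a clipping experiment
#'
#' Repeated clipping removes aboveground ground vegetation, cutting the
#' supply of fresh assimilates to roots. Root activity declines only
#' gradually (clipped vegetation resprouts between campaigns), so only
#' campaigns at or after a stabilization date -- when the treated/control
#' difference has plateaued -- are used; the resulting fraction is a
#' conservative (lower-bound) estimate of the autotrophic contribution.
#'
#' @inheritParams trenching_fraction
#' @param stabilization_start Timestamp; only campaigns with
#'   `campaign_datetime >= stabilization_start` enter the estimate.
#' @return A `partition_estimate` with `method = "clipping"`.
#' @export
clipping_fraction <- function(pairs, stabilization_start, section_id = NULL,
                              weights = c("campaign", "flux")) {
  weights <- match.arg(weights)
  stab <- as.POSIXct(stabilization_start, tz = "UTC")
  keep <- as.POSIXct(pairs$campaign_datetime, tz = "UTC") >= stab
  if (!any(keep))
    stop("no campaigns at or after stabilization_start", call. = FALSE)
  .reduction_estimate(pairs[keep, , drop = FALSE], method = "clipping",
                      section_id = section_id, weights = weights)
}

.reduction_estimate <- function(pairs, method, section_id, weights) {
  if (nrow(pairs) < 1L)
    stop("at least one treatment pair is required", call. = FALSE)
  ctrl <- pairs$mean_rs_control
  trt <- pairs$mean_rs_treated
  bad <- !is.finite(ctrl) | !is.finite(trt) | ctrl <= 0
  if (any(bad)) {
    warning(sprintf("%d campaign(s) excluded (non-positive or missing control flux)",
                    sum(bad)), call. = FALSE)
    ctrl <- ctrl[!bad]; trt <- trt[!bad]
  }
  if (length(ctrl) == 0L)
    stop("all campaigns excluded: no positive control fluxes", call. = FALSE)
  red <- 100 * (1 - trt / ctrl)
  if (weights == "flux") {
    frac <- sum(red * ctrl) / sum(ctrl)
  } else {
    frac <- mean(red)
  }
  se <- if (length(red) >= 2L && weights == "campaign")
    stats::sd(red) / sqrt(length(red)) else NA_real_
  partition_estimate(frac, method = method, section_id = section_id,
                     se_pct = se, n_campaigns = length(red))
}

#' Construct a partition estimate, clipping to the [0, 100] percent range
#'
#' @param autotrophic_fraction_pct Autotrophic percentage of soil
#'   respiration; raw values outside [0, 100] are clipped with a warning.
#' @param method One of `"trenching"`, `"clipping"`, `"fine_root_scaling"`.
#' @param section_id Optional section identifier.
#' @param se_pct Optional standard error in percentage points.
#' @param n_campaigns Optional number of campaigns behind the estimate.
#' @return An object of class `partition_estimate`.
#' @export
partition_estimate <- function(autotrophic_fraction_pct,
                               method = c("trenching", "clipping",
                                          "fine_root_scaling"),
                               section_id = NULL, se_pct = NA_real_,
                               n_campaigns = NA_integer_) {
  method <- match.arg(method)
  raw <- autotrophic_fraction_pct
  if (!is.finite(raw))
    stop("autotrophic fraction must be finite", call. = FALSE)
  if (raw < 0 || raw > 100) {
    warning(sprintf("autotrophic fraction %.1f%% outside [0, 100]; clipped",
                    raw), call. = FALSE)
    raw <- min(max(raw, 0), 100)
  }
  structure(
    list(section_id = section_id,
         method = method,
         autotrophic_fraction_pct = raw,
         se_pct = se_pct,
         n_campaigns = n_campaigns),
    class = "partition_estimate")
}

#' Scale an autotrophic fraction by fine-root carbon stocks
#'
#' Transfers an autotrophic percentage measured at a reference section to a
#' target section in proportion to their fine-root carbon stocks
#' (0--10 cm):
#' \deqn{a_{target} = a_{ref} \cdot f_{target} / f_{ref}}
#' The rationale is that root-derived respiration scales with the standing
#' fine-root biomass when vegetation type and conditions are comparable.
#' The ratio is unit-free as long as both stocks share the same units.
#'
#' @param a_ref_pct Autotrophic percentage at the reference section.
#' @param f_ref Fine-root C stock at the reference section (t C ha-1); must
#'   be positive.
#' @param f_target Fine-root C stock at the target section (t C ha-1).
#' @return Autotrophic percentage for the target section, clipped to
#'   [0, 100] with a warning if the raw value falls outside.
#' @examples
#' scale_autotrophic_eq1(35, 0.79, 0.40)  # about 17.7 %
#' @export
scale_autotrophic_eq1 <- function(a_ref_pct, f_ref, f_target) {
  if (f_ref <= 0)
    stop("reference fine-root stock must be positive", call. = FALSE)
  if (a_ref_pct < 0)
    stop("reference autotrophic fraction must be non-negative", call. = FALSE)
  raw <- a_ref_pct * f_target / f_ref
  if (raw < 0 || raw > 100) {
    warning(sprintf("scaled autotrophic fraction %.1f%% outside [0, 100]; clipped",
                    raw), call. = FALSE)
    raw <- min(max(raw, 0), 100)
  }
  raw
}

#' Split an annual soil-respiration total into Ra and Rh
#'
#' Applies a campaign-derived autotrophic percentage to a modelled annual
#' soil-respiration total. The heterotrophic component is the exact
#' complement, so `ra + rh == rs_annual` before any rounding.
#'
#' @param rs_annual Annual soil respiration (t C ha-1 yr-1, non-negative).
#' @param estimate A `partition_estimate`, or a bare autotrophic percentage
#'   in [0, 100].
#' @return List with `ra` and `rh` (t C ha-1 yr-1).
#' @examples
#' partition_annual(8.9, 44)  # ra 3.9, rh 5.0 at one decimal
#' @export
partition_annual <- function(rs_annual, estimate) {
  frac <- if (inherits(estimate, "partition_estimate"))
    estimate$autotrophic_fraction_pct else estimate
  if (rs_annual < 0)
    stop("rs_annual must be non-negative", call. = FALSE)
  if (frac < 0 || frac > 100)
    stop("autotrophic fraction must be within [0, 100]", call. = FALSE)
  ra <- rs_annual * frac / 100
  list(ra = ra, rh = rs_annual - ra)
}

#' @export
print.partition_estimate <- function(x, ...) {
  cat(sprintf("Partition estimate%s (%s): autotrophic %.1f%%%s\n",
              if (!is.null(x$section_id)) paste0(" [", x$section_id, "]") else "",
              x$method, x$autotrophic_fraction_pct,
              if (is.finite(x$se_pct)) sprintf(" (SE %.1f)", x$se_pct) else ""))
  invisible(x)
}
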