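#' Gating configuration for dual-reporter readthrough cytometry
#'
#' Scatter and fluorescence inclusion rules used before computing the
#' readthrough statistic: intact cells are selected by forward and side
#' scatter windows, and events are included in the ratio calculation when
#' their RFP signal exceeds `rfp_min` or their GFP signal exceeds `gfp_min`.
#' Scatter bounds are inclusive ("between"); fluorescence thresholds are
#' strict ("above"). Defaults are the raw linear instrument values used for
#' HT1080 cells on a bench cytometer.
#'
#' @param fsc_min,fsc_max Forward scatter window (AU), inclusive.
#' @param ssc_min,ssc_max Side scatter window (AU), inclusive.
#' @param rfp_min,gfp_min Fluorescence inclusion thresholds (AU), strict.
#' @param bounds_inclusive If `FALSE`, scatter bounds become strict too.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(fsc_min = 23000, fsc_max = 75000,
                          ssc_min = 12500, ssc_max = 67500,
                          rfp_min = 900, gfp_min = 100,
                          bounds_inclusive = TRUE) {
  check_scalar(fsc_min, "fsc_min")
  check_scalar(fsc_max, "fsc_max", lower = fsc_min, strict_lower = TRUE)
  check_scalar(ssc_min, "ssc_min")
  check_scalar(ssc_max, "ssc_max", lower = ssc_min, strict_lower = TRUE)
  check_scalar(rfp_min, "rfp_min", lower = 0)
  check_scalar(gfp_min, "gfp_min", lower = 0)
  structure(
    list(fsc_min = fsc_min, fsc_max = fsc_max,
         ssc_min = ssc_min, ssc_max = ssc_max,
         rfp_min = rfp_min, gfp_min = gfp_min,
         bounds_inclusive = isTRUE(bounds_inclusive)),
    class = "gating_config"
  )
}

check_events <- function(events, channels = c("FSC", "SSC", "GFP", "RFP")) {
  missing_ch <- setdiff(channels, names(events))
  if (length(missing_ch) > 0) {
    abort(sprintf("Event table is missing channel(s): %s.",
                  paste(missing_ch, collapse = ", ")))
  }
  invisible(events)
}

#' Select intact cells by forward and side scatter
#'
#' Retains events inside the scatter window of a [gating_config()] (inclusive
#' bounds by default); event order is preserved.
#'
#' @param events Event table with `FSC` and `SSC` columns.
#' @param config A [gating_config()].
#' @return The subset of `events` inside the scatter gate.
#' @export
gate_scatter <- function(events, config = gating_config()) {
  check_events(events, c("FSC", "SSC"))
  stopifnot(inherits(config, "gating_config"))
  if (config$bounds_inclusive) {
    keep <- events$FSC >= config$fsc_min & events$FSC <= config$fsc_max &
      events$SSC >= config$ssc_min & events$SSC <= config$ssc_max
  } else {
    keep <- events$FSC > config$fsc_min & events$FSC < config$fsc_max &
      events$SSC > config$ssc_min & events$SSC < config$ssc_max
  }
  events[keep, , drop = FALSE]
}

#' Select reporter-positive events by fluorescence
#'
#' Retains events with `RFP > rfp_min` OR `GFP > gfp_min` (strict
#' inequalities). This inclusion rule removes untransfected cells, whose
#' signals sit at autofluorescence baseline, from the readthrough
#' calculation.
#'
#' @inheritParams gate_scatter
#' @return The subset of `events` passing the fluorescence inclusion rule.
#' @export
gate_fluorescence <- function(events, config = gating_config()) {
  check_events(events, c("GFP", "RFP"))
  stopifnot(inherits(config, "gating_config"))
  keep <- events$RFP > config$rfp_min | events$GFP > config$gfp_min
  events[keep, , drop = FALSE]
}

#' Apply the full gating chain
#'
#' Scatter gate followed by the fluorescence inclusion rule.
#'
#' @inheritParams gate_scatter
#' @return Gated event table with attributes `n_total`, `n_scatter_gated`
#'   and `n_included` recording the event counts at each stage.
#' @export
gate_events <- function(events, config = gating_config()) {
  scatter <- gate_scatter(events, config)
  included <- gate_fluorescence(scatter, config)
  attr(included, "n_total") <- nrow(events)
  attr(included, "n_scatter_gated") <- nrow(scatter)
  attr(included, "n_included") <- nrow(included)
  included
}
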