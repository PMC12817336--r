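#' Generative model for a dual-reporter flow-cytometry sample
#'
#' Describes the measurement model behind a transiently transfected
#' dual-fluorescence readthrough reporter sample: a mixture of transfected
#' cells (lognormal reporter expression, RFP proportional to expression, GFP
#' proportional to expression times the true readthrough fraction `theta`),
#' untransfected cells carrying only autofluorescence, and low-scatter debris.
#' `theta = 1` encodes the RFP-GFP fusion control without a separating stop
#' codon, which defines 100% readthrough.
#'
#' @param theta True per-transcript readthrough fraction in `[0, 1]`; the GFP
#'   produced per RFP. `theta = 1` is the fusion control.
#' @param transfected_fraction Proportion of intact cells carrying the
#'   reporter.
#' @param expression_log_mean,expression_log_sd Lognormal parameters (natural
#'   log scale) of per-cell reporter expression in arbitrary fluorescence
#'   units.
#' @param rfp_gain,gfp_gain Channel gains, AU per expression unit.
#' @param autofluor_rfp_mean,autofluor_gfp_mean,autofluor_sd Additive baseline
#'   signal (AU) present in every cell, transfected or not.
#' @param fsc_mean,fsc_sd,ssc_mean,ssc_sd Scatter distribution of intact
#'   cells (AU).
#' @param debris_fraction Proportion of events drawn from a low-scatter debris
#'   cloud that falls outside the standard scatter gate with high probability.
#' @param noise_cv Multiplicative measurement-noise coefficient of variation
#'   applied per channel.
#'
#' @return An object of class `reporter_cell_model` (a validated list).
#' @seealso [simulate_flow_sample()], [flow_preset()]
#' @export
#' @examples
#' m <- reporter_cell_model(theta = 0.002)
#' ev <- simulate_flow_sample(m, n_events = 1000, seed = 1)
reporter_cell_model <- function(theta = 1,
                                transfected_fraction = 0.6,
                                expression_log_mean = log(10000),
                                expression_log_sd = 0.8,
                                rfp_gain = 1,
                                gfp_gain = 1,
                                autofluor_rfp_mean = 30,
                                autofluor_gfp_mean = 0.1,
                                autofluor_sd = 0.3,
                                fsc_mean = 49000,
                                fsc_sd = 8000,
                                ssc_mean = 40000,
                                ssc_sd = 9000,
                                debris_fraction = 0.05,
                                noise_cv = 0.1) {
  check_proportion(theta, "theta")
  check_proportion(transfected_fraction, "transfected_fraction")
  check_proportion(debris_fraction, "debris_fraction")
  check_scalar(expression_log_mean, "expression_log_mean")
  check_scalar(expression_log_sd, "expression_log_sd", lower = 0,
               strict_lower = TRUE)
  check_scalar(rfp_gain, "rfp_gain", lower = 0, strict_lower = TRUE)
  check_scalar(gfp_gain, "gfp_gain", lower = 0, strict_lower = TRUE)
  check_scalar(autofluor_rfp_mean, "autofluor_rfp_mean", lower = 0)
  check_scalar(autofluor_gfp_mean, "autofluor_gfp_mean", lower = 0)
  check_scalar(autofluor_sd, "autofluor_sd", lower = 0)
  check_scalar(fsc_mean, "fsc_mean", lower = 0, strict_lower = TRUE)
  check_scalar(fsc_sd, "fsc_sd", lower = 0, strict_lower = TRUE)
  check_scalar(ssc_mean, "ssc_mean", lower = 0, strict_lower = TRUE)
  check_scalar(ssc_sd, "ssc_sd", lower = 0, strict_lower = TRUE)
  check_scalar(noise_cv, "noise_cv", lower = 0)

  structure(
    list(
      theta = theta,
      transfected_fraction = transfected_fraction,
      expression_log_mean = expression_log_mean,
      expression_log_sd = expression_log_sd,
      rfp_gain = rfp_gain,
      gfp_gain = gfp_gain,
      autofluor_rfp_mean = autofluor_rfp_mean,
      autofluor_gfp_mean = autofluor_gfp_mean,
      autofluor_sd = autofluor_sd,
      fsc_mean = fsc_mean,
      fsc_sd = fsc_sd,
      ssc_mean = ssc_mean,
      ssc_sd = ssc_sd,
      debris_fraction = debris_fraction,
      noise_cv = noise_cv
    ),
    class = "reporter_cell_model"
  )
}

#' @export
print.reporter_cell_model <- function(x, ...) {
  cat("<reporter_cell_model>\n")
  cat(sprintf("  theta (true readthrough fraction): %g\n", x$theta))
  cat(sprintf("  transfected fraction: %g, debris fraction: %g\n",
              x$transfected_fraction, x$debris_fraction))
  cat(sprintf("  expression ~ lognormal(meanlog = %.3f, sdlog = %.3f)\n",
              x$expression_log_mean, x$expression_log_sd))
  cat(sprintf("  gains RFP %g / GFP %g; noise CV %g\n",
              x$rfp_gain, x$gfp_gain, x$noise_cv))
  invisible(x)
}

#' Simulate a dual-reporter flow-cytometry sample
#'
#' Draws per-event scatter and fluorescence values from a
#' [reporter_cell_model()]. Transfected cells have expected
#' `GFP = theta * gfp_gain / rfp_gain * (RFP - autofluorescence)` before
#' measurement noise; untransfected cells carry only autofluorescence; debris
#' events come from a low-scatter cloud. The returned table carries the
#' ground-truth event classes in the `transfected` and `debris` columns (these
#' are dropped when exporting to FCS).
#'
#' @param model A [reporter_cell_model()].
#' @param n_events Number of events to draw (>= 1).
#' @param seed Integer seed; identical model + seed gives identical events.
#' @return A tibble with columns `FSC`, `SSC`, `GFP`, `RFP`, `transfected`,
#'   `debris`, one row per event.
#' @export
simulate_flow_sample <- function(model, n_events, seed = NULL) {
  if (!inherits(model, "reporter_cell_model")) {
    abort("`model` must be a `reporter_cell_model`.")
  }
  check_scalar(n_events, "n_events", lower = 1)
  n_events <- as.integer(n_events)

  with_seed(seed, {
    debris <- runif(n_events) < model$debris_fraction
    transfected <- !debris & runif(n_events) < model$transfected_fraction

    # Scatter: intact cells around the model means; debris as a dim cloud at
    # one fifth of the cell scatter, which lies below the usual gate.
    fsc <- ifelse(
      debris,
      rnorm(n_events, 0.2 * model$fsc_mean, 0.3 * 0.2 * model$fsc_mean),
      rnorm(n_events, model$fsc_mean, model$fsc_sd)
    )
    ssc <- ifelse(
      debris,
      rnorm(n_events, 0.15 * model$ssc_mean, 0.3 * 0.15 * model$ssc_mean),
      rnorm(n_events, model$ssc_mean, model$ssc_sd)
    )

    expr <- ifelse(
      transfected,
      rlnorm(n_events, model$expression_log_mean, model$expression_log_sd),
      0
    )
    af_rfp <- rnorm(n_events, model$autofluor_rfp_mean, model$autofluor_sd)
    af_gfp <- rnorm(n_events, model$autofluor_gfp_mean, model$autofluor_sd)
    rfp <- model$rfp_gain * expr + af_rfp
    gfp <- model$theta * model$gfp_gain * expr + af_gfp

    if (model$noise_cv > 0) {
      rfp <- rfp * (1 + model$noise_cv * rnorm(n_events))
      gfp <- gfp * (1 + model$noise_cv * rnorm(n_events))
    }

    tibble(
      FSC = pmax(fsc, 0),
      SSC = pmax(ssc, 0),
      GFP = pmax(gfp, 0),
      RFP = pmax(rfp, 0),
      transfected = transfected,
      debris = debris
    )
  })
}
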