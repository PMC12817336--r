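#' Specification of a simulated fluorogenic activity assay
#'
#' Linear 4-methylumbelliferone (4-MU) calibration plus lysate readings.
#' Standards read `slope * nmol + intercept + noise`; samples read
#' `slope * (activity * protein * time / dilution) + intercept + noise`,
#' where activity is in mU/mg (1 mU = 1 nmol/min).
#'
#' @param curve_slope Fluorescence per nmol 4-MU (AU/nmol), positive.
#' @param curve_intercept Blank fluorescence (AU).
#' @param standard_points nmol values of the calibration standards; must
#'   include 0 and conventionally span 0-7.5 nmol.
#' @param samples A data frame with columns `sample_id`,
#'   `true_activity_mU_per_mg`, `protein_mg`, `dilution_factor`,
#'   `incubation_min`.
#' @param read_noise_sd Additive reading noise (AU).
#' @return An object of class `assay_sim_spec`.
#' @export
assay_sim_spec <- function(curve_slope = 100,
                           curve_intercept = 50,
                           standard_points = seq(0, 7.5, by = 1.25),
                           samples = tibble(
                             sample_id = "sample1",
                             true_activity_mU_per_mg = 1,
                             protein_mg = 0.05,
                             dilution_factor = 10,
                             incubation_min = 30
                           ),
                           read_noise_sd = 0) {
  check_scalar(curve_slope, "curve_slope", lower = 0, strict_lower = TRUE)
  check_scalar(curve_intercept, "curve_intercept")
  check_scalar(read_noise_sd, "read_noise_sd", lower = 0)
  if (!0 %in% standard_points || length(unique(standard_points)) < 2) {
    abort("`standard_points` must include 0 and at least one other value.")
  }
  req <- c("sample_id", "true_activity_mU_per_mg", "protein_mg",
           "dilution_factor", "incubation_min")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    abort(sprintf("`samples` must have columns: %s.",
                  paste(req, collapse = ", ")))
  }
  if (any(samples$incubation_min <= 0)) {
    abort("`incubation_min` must be positive.")
  }
  if (any(samples$protein_mg <= 0)) abort("`protein_mg` must be positive.")
  if (any(samples$dilution_factor < 1)) {
    abort("`dilution_factor` must be at least 1.")
  }
  if (any(samples$true_activity_mU_per_mg < 0)) {
    abort("`true_activity_mU_per_mg` must be nonnegative.")
  }
  structure(
    list(curve_slope = curve_slope, curve_intercept = curve_intercept,
         standard_points = standard_points, samples = as_tibble(samples),
         read_noise_sd = read_noise_sd),
    class = "assay_sim_spec"
  )
}

#' Simulate an activity-assay plate
#'
#' @param spec An [assay_sim_spec()].
#' @param seed Integer seed.
#' @return A tibble with rows of `type` `"standard"` (known `nmol`) and
#'   `"sample"` (with the reaction metadata), each with a `fluorescence`
#'   reading.
#' @export
simulate_activity_plate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "assay_sim_spec"))
  with_seed(seed, {
    std <- tibble(
      type = "standard",
      sample_id = sprintf("std_%g", spec$standard_points),
      nmol = spec$standard_points,
      fluorescence = spec$curve_slope * spec$standard_points +
        spec$curve_intercept +
        rnorm(length(spec$standard_points), sd = spec$read_noise_sd),
      protein_mg = NA_real_, dilution_factor = NA_real_,
      incubation_min = NA_real_
    )
    s <- spec$samples
    true_nmol <- s$true_activity_mU_per_mg * s$protein_mg *
      s$incubation_min / s$dilution_factor
    if (any(true_nmol < 0)) abort("Negative computed 4-MU amount.")
    smp <- tibble(
      type = "sample",
      sample_id = s$sample_id,
      nmol = NA_real_,
      fluorescence = spec$curve_slope * true_nmol + spec$curve_intercept +
        rnorm(nrow(s), sd = spec$read_noise_sd),
      protein_mg = s$protein_mg,
      dilution_factor = s$dilution_factor,
      incubation_min = s$incubation_min
    )
    bind_rows(std, smp)
  })
}

#' Specification of a simulated western-blot band table
#'
#' Band intensity is proportional to `true_relative_abundance * load_ug`
#' with multiplicative lognormal-style noise; each condition lane carries a
#' loading-control band. A dedicated reference lane loaded at
#' `wt_reference_load_fraction` of the variant load (0.01 encodes the
#' 1:100-load wild-type reference) anchors readthrough-efficacy estimates.
#'
#' @param lanes A data frame with columns `lane`, `condition`, `target`,
#'   `true_relative_abundance`, `load_ug`.
#' @param loading_control_target Name of the loading-control protein (e.g.
#'   the GAPDH role); every lane must carry exactly one such band.
#' @param wt_reference_load_fraction Load of the reference lane as a
#'   fraction of the standard load.
#' @param intensity_noise_cv Multiplicative noise CV.
#' @return An object of class `blot_sim_spec`.
#' @export
blot_sim_spec <- function(lanes,
                          loading_control_target = "GAPDH",
                          wt_reference_load_fraction = 0.01,
                          intensity_noise_cv = 0) {
  req <- c("lane", "condition", "target", "true_relative_abundance",
           "load_ug")
  if (!is.data.frame(lanes) || !all(req %in% names(lanes))) {
    abort(sprintf("`lanes` must have columns: %s.",
                  paste(req, collapse = ", ")))
  }
  if (any(lanes$load_ug <= 0)) abort("`load_ug` must be positive.")
  if (any(lanes$true_relative_abundance < 0)) {
    abort("`true_relative_abundance` must be nonnegative.")
  }
  per_lane <- table(lanes$lane[lanes$target == loading_control_target])
  lanes_all <- unique(lanes$lane)
  if (!all(lanes_all %in% names(per_lane)) || any(per_lane != 1)) {
    abort(sprintf(
      "Every lane needs exactly one loading-control band ('%s').",
      loading_control_target
    ))
  }
  check_proportion(wt_reference_load_fraction, "wt_reference_load_fraction")
  check_scalar(intensity_noise_cv, "intensity_noise_cv", lower = 0)
  structure(
    list(lanes = as_tibble(lanes),
         loading_control_target = loading_control_target,
         wt_reference_load_fraction = wt_reference_load_fraction,
         intensity_noise_cv = intensity_noise_cv),
    class = "blot_sim_spec"
  )
}

#' Simulate a band-intensity table
#'
#' @param spec A [blot_sim_spec()].
#' @param seed Integer seed.
#' @param intensity_per_unit Intensity (AU) per abundance-microgram unit.
#' @return A tibble (`lane`, `condition`, `target`, `intensity`, `load_ug`)
#'   with attributes `loading_control_target` and
#'   `wt_reference_load_fraction`.
#' @export
simulate_blot <- function(spec, seed = NULL, intensity_per_unit = 1000) {
  stopifnot(inherits(spec, "blot_sim_spec"))
  with_seed(seed, {
    l <- spec$lanes
    intensity <- intensity_per_unit * l$true_relative_abundance * l$load_ug
    if (spec$intensity_noise_cv > 0) {
      intensity <- intensity *
        pmax(1 + spec$intensity_noise_cv * rnorm(nrow(l)), 0)
    }
    out <- l %>%
      select("lane", "condition", "target", "load_ug") %>%
      mutate(intensity = intensity, .before = "load_ug")
    structure(out,
              loading_control_target = spec$loading_control_target,
              wt_reference_load_fraction = spec$wt_reference_load_fraction)
  })
}
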