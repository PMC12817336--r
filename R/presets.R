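# Named study-condition presets, loaded from the versioned YAML catalog
# shipped in inst/extdata. Presets record the ground truth each generator
# reproduces (readthrough fraction theta, specific activity, proximity
# geometry), so downstream estimates are recovery tests.

preset_catalog_raw <- function() {
  path <- system.file("extdata", "presets.yaml", package = "ptcrescue")
  if (path == "") {
    # during in-source development (pkgload) inst/ is on the search path
    path <- system.file("inst", "extdata", "presets.yaml",
                        package = "ptcrescue")
  }
  if (path == "") abort("Preset catalog not found.")
  yaml::read_yaml(path)
}

#' List the study-condition presets
#'
#' Each preset names a condition of the underlying rescue study and records
#' the ground-truth parameter its generator reproduces.
#'
#' @return A tibble with `type` (`flow`, `activity`, `proximity`, `blot`),
#'   `name`, `truth` (the defining parameter value), `truth_parameter`, and
#'   `note`.
#' @export
list_presets <- function() {
  cat <- preset_catalog_raw()
  flow <- purrr::imap(cat$flow$presets, function(p, name) {
    tibble(type = "flow", name = name, truth = p$theta,
           truth_parameter = "theta", note = p$note)
  }) %>% bind_rows()
  act <- purrr::imap(cat$activity$presets, function(p, name) {
    tibble(type = "activity", name = name, truth = p$true_activity_mU_per_mg,
           truth_parameter = "true_activity_mU_per_mg", note = p$note)
  }) %>% bind_rows()
  prox <- purrr::imap(cat$proximity$presets, function(p, name) {
    tibble(type = "proximity", name = name, truth = p$fraction_within_02um,
           truth_parameter = "fraction_within_02um", note = p$note)
  }) %>% bind_rows()
  blot <- purrr::imap(cat$blot$presets, function(p, name) {
    tibble(type = "blot", name = name, truth = p$target_abundance,
           truth_parameter = "target_abundance", note = p$note)
  }) %>% bind_rows()
  bind_rows(flow, act, prox, blot)
}

#' Reporter cell model for a named flow preset
#'
#' Combines the shared base measurement model with the preset's true
#' readthrough fraction. `"untransfected"` returns the plate-control model
#' with no transfected cells.
#'
#' @param name Preset name (see [list_presets()]).
#' @return A [reporter_cell_model()].
#' @export
flow_preset <- function(name) {
  cat <- preset_catalog_raw()
  base <- cat$flow$base_model
  if (identical(name, "untransfected")) {
    args <- c(list(theta = 0), base)
    args$transfected_fraction <- 0
    return(do.call(reporter_cell_model, args))
  }
  p <- cat$flow$presets[[name]]
  if (is.null(p)) {
    abort(sprintf("Unknown flow preset '%s'. Available: %s.", name,
                  paste(names(cat$flow$presets), collapse = ", ")))
  }
  do.call(reporter_cell_model, c(list(theta = p$theta), base))
}

#' Assay specification for a named activity preset
#'
#' @param name Preset name (see [list_presets()]).
#' @param curve_slope,curve_intercept Calibration line of the simulated
#'   plate.
#' @param read_noise_sd Reading noise (0 = noise-free).
#' @return An [assay_sim_spec()] with one sample encoding the preset's true
#'   activity.
#' @export
activity_preset <- function(name, curve_slope = 100, curve_intercept = 50,
                            read_noise_sd = 0) {
  cat <- preset_catalog_raw()
  p <- cat$activity$presets[[name]]
  if (is.null(p)) {
    abort(sprintf("Unknown activity preset '%s'. Available: %s.", name,
                  paste(names(cat$activity$presets), collapse = ", ")))
  }
  d <- cat$activity$defaults
  assay_sim_spec(
    curve_slope = curve_slope,
    curve_intercept = curve_intercept,
    samples = tibble(
      sample_id = name,
      true_activity_mU_per_mg = p$true_activity_mU_per_mg,
      protein_mg = p$protein_mg %||% d$protein_mg,
      dilution_factor = p$dilution_factor %||% d$dilution_factor,
      incubation_min = p$incubation_min %||% d$incubation_min
    ),
    read_noise_sd = read_noise_sd
  )
}

#' Image-scene specification for a named proximity preset
#'
#' @param name Preset name (see [list_presets()]).
#' @param ... Overrides passed to [image_scene_spec()].
#' @return An [image_scene_spec()].
#' @export
proximity_preset <- function(name, ...) {
  cat <- preset_catalog_raw()
  p <- cat$proximity$presets[[name]]
  if (is.null(p)) {
    abort(sprintf("Unknown proximity preset '%s'. Available: %s.", name,
                  paste(names(cat$proximity$presets), collapse = ", ")))
  }
  args <- modifyList(
    list(fraction_within_02um = p$fraction_within_02um,
         n_lamp1 = p$n_lamp1, n_fuca1 = p$n_fuca1),
    list(...)
  )
  do.call(image_scene_spec, args)
}

#' Blot specification for a named blot preset
#'
#' `"erf3a-cc885-5nM"` builds a four-band target/loading-control design
#' (treated vs untreated); `"efficacy-dual"` builds a variant lane plus a
#' diluted wild-type reference lane.
#'
#' @param name Preset name (see [list_presets()]).
#' @param intensity_noise_cv Multiplicative band-intensity noise CV.
#' @return A [blot_sim_spec()].
#' @export
blot_preset <- function(name, intensity_noise_cv = 0) {
  cat <- preset_catalog_raw()
  p <- cat$blot$presets[[name]]
  if (is.null(p)) {
    abort(sprintf("Unknown blot preset '%s'. Available: %s.", name,
                  paste(names(cat$blot$presets), collapse = ", ")))
  }
  if (name == "erf3a-cc885-5nM") {
    lanes <- tibble(
      lane = c("untreated", "untreated", "treated", "treated"),
      condition = c("untreated", "untreated", "cc885-5nM", "cc885-5nM"),
      target = c("eRF3a", "GAPDH", "eRF3a", "GAPDH"),
      true_relative_abundance = c(1, 1, p$target_abundance, 1),
      load_ug = 25
    )
    blot_sim_spec(lanes, loading_control_target = "GAPDH",
                  intensity_noise_cv = intensity_noise_cv)
  } else {
    frac <- p$wt_reference_load_fraction %||% 0.01
    lanes <- tibble(
      lane = c("variant", "variant", "wt-ref", "wt-ref"),
      condition = c("dual-treatment", "dual-treatment",
                    "wt-reference", "wt-reference"),
      target = c("FUCA1", "GAPDH", "FUCA1", "GAPDH"),
      true_relative_abundance = c(p$target_abundance, 1, 1, 1),
      load_ug = c(25, 25, 25 * frac, 25)
    )
    blot_sim_spec(lanes, loading_control_target = "GAPDH",
                  wt_reference_load_fraction = frac,
                  intensity_noise_cv = intensity_noise_cv)
  }
}
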