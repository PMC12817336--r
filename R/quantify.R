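# Calibrated enzymatic activity (4-MU standard curve -> mU/mg, % of a
# reference), densitometric ratios, and viability normalization.

#' Fit a 4-MU standard curve
#'
#' Ordinary least squares of fluorescence on nmol 4-MU with a free
#' intercept (the blank is the 0-nmol standard). The slope must come out
#' positive for a usable calibration.
#'
#' @param points Data frame with columns `nmol` and `fluorescence`, or a
#'   plate table from [simulate_activity_plate()] (standard rows are used).
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `points` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(points) {
  if ("type" %in% names(points)) {
    points <- points %>% filter(.data$type == "standard")
  }
  if (!all(c("nmol", "fluorescence") %in% names(points))) {
    abort("`points` must have columns nmol and fluorescence.")
  }
  if (length(unique(points$nmol)) < 2) {
    abort("Need at least 2 distinct nmol values to fit a standard curve.")
  }
  fit <- lm(fluorescence ~ nmol, data = points)
  slope <- unname(coef(fit)["nmol"])
  if (!is.finite(slope) || slope <= 0) {
    abort("Calibration error: fitted slope is not positive.")
  }
  structure(
    list(slope = slope,
         intercept = unname(coef(fit)["(Intercept)"]),
         points = as_tibble(points[, c("nmol", "fluorescence")]),
         fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> fluorescence = %.4g * nmol + %.4g (n = %d)\n",
    x$slope, x$intercept, nrow(x$points)
  ))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         sigma = summary(x$fit)$sigma, n = nrow(x$points))
}

#' @rdname fit_standard_curve
#' @param object A `standard_curve`.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$nmol, y = .data$fluorescence)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "4-MU (nmol)", y = "Fluorescence (AU)") +
    ggplot2::theme_minimal()
}

#' Back-calculate liberated 4-MU from a fluorescence reading
#'
#' `(fluorescence - intercept) / slope`, floored at 0; readings below the
#' blank yield 0 with attribute `floored = TRUE`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param fluorescence Reading(s) in AU.
#' @return nmol value(s); attribute `floored` marks floored entries.
#' @export
fluorescence_to_nmol <- function(curve, fluorescence) {
  stopifnot(inherits(curve, "standard_curve"))
  raw <- (fluorescence - curve$intercept) / curve$slope
  out <- pmax(raw, 0)
  attr(out, "floored") <- raw < 0
  out
}

#' Specific enzymatic activity from a calibrated reading
#'
#' `activity = nmol * dilution_factor / (incubation_min * protein_mg)` in
#' mU/mg (1 mU = 1 nmol/min). `protein_mg` is the protein mass in the
#' reaction before dilution; reaction-volume terms cancel in this
#' bookkeeping.
#'
#' @param measurement Data frame (one or more rows) with `fluorescence`,
#'   `incubation_min`, `protein_mg`, `dilution_factor` (and optionally
#'   `sample_id`); sample rows of [simulate_activity_plate()] work
#'   directly.
#' @param curve A [fit_standard_curve()] result.
#' @return A tibble with `sample_id` (when present), `nmol_4mu`,
#'   `activity_mU_per_mg`, `floored`.
#' @export
specific_activity <- function(measurement, curve) {
  if ("type" %in% names(measurement)) {
    measurement <- measurement %>% filter(.data$type == "sample")
  }
  req <- c("fluorescence", "incubation_min", "protein_mg", "dilution_factor")
  if (!all(req %in% names(measurement))) {
    abort(sprintf("`measurement` must have columns: %s.",
                  paste(req, collapse = ", ")))
  }
  if (any(measurement$incubation_min <= 0)) {
    abort("`incubation_min` must be positive.")
  }
  if (any(measurement$protein_mg <= 0)) {
    abort("`protein_mg` must be positive.")
  }
  nmol <- fluorescence_to_nmol(curve, measurement$fluorescence)
  out <- tibble(
    nmol_4mu = as.numeric(nmol),
    activity_mU_per_mg = as.numeric(nmol) * measurement$dilution_factor /
      (measurement$incubation_min * measurement$protein_mg),
    floored = attr(nmol, "floored")
  )
  if ("sample_id" %in% names(measurement)) {
    out <- out %>% mutate(sample_id = measurement$sample_id, .before = 1)
  }
  out
}

#' Activity as a percentage of a reference sample
#'
#' @param sample,reference Activity values in mU/mg (scalars, or tibbles
#'   from [specific_activity()] whose first row is used).
#' @return `100 * sample / reference`.
#' @export
percent_of_reference <- function(sample, reference) {
  val <- function(x) {
    if (is.data.frame(x)) x$activity_mU_per_mg[1] else x
  }
  s <- val(sample)
  r <- val(reference)
  if (!is.finite(r) || r <= 0) {
    abort("Reference activity must be positive.")
  }
  100 * s / r
}

#' Loading-control-normalized band ratio relative to a baseline condition
#'
#' `(target / control)_condition / (target / control)_baseline * 100`; for
#' example, release-factor band intensity over the loading control,
#' relative to the untreated lane. Invariant to any global intensity gain.
#'
#' @param table Band table (`lane`/`condition`/`target`/`intensity`), e.g.
#'   from [simulate_blot()] or a densitometry CSV.
#' @param target Target protein name.
#' @param control_target Loading-control protein name.
#' @param condition,baseline_condition Condition labels to compare.
#' @return Percentage of the baseline level.
#' @export
normalized_band_ratio <- function(table, target, control_target,
                                  condition, baseline_condition) {
  band <- function(cond, tgt) {
    v <- table$intensity[table$condition == cond & table$target == tgt]
    if (length(v) != 1) {
      abort(sprintf("Expected exactly one '%s' band for condition '%s'.",
                    tgt, cond))
    }
    v
  }
  ctl_c <- band(condition, control_target)
  ctl_b <- band(baseline_condition, control_target)
  if (ctl_c <= 0 || ctl_b <= 0) {
    abort("Loading-control band intensity must be positive.")
  }
  100 * (band(condition, target) / ctl_c) /
    (band(baseline_condition, target) / ctl_b)
}

#' Readthrough efficacy from a diluted-reference blot design
#'
#' Full-length variant band intensity relative to a wild-type reference
#' lane loaded at a known fraction of the variant load:
#' `efficacy% = intensity_variant / intensity_reference * load_fraction *
#' 100`, so a variant band matching the 1%-load reference band means 1%
#' efficacy. The load fraction is taken from the table attribute set by
#' [simulate_blot()] unless supplied.
#'
#' @param table Band table with `lane` and `intensity` columns.
#' @param variant_lane,wt_reference_lane Lane identifiers.
#' @param target Target protein name; defaults to the only non-control
#'   target when the table carries a `loading_control_target` attribute.
#' @param load_fraction Reference load as a fraction of the variant load
#'   (e.g. 0.01 for a 0.25 ug vs 25 ug design).
#' @return Efficacy percentage.
#' @export
readthrough_efficacy_from_blot <- function(table, variant_lane,
                                           wt_reference_lane,
                                           target = NULL,
                                           load_fraction = NULL) {
  load_fraction <- load_fraction %||%
    attr(table, "wt_reference_load_fraction")
  if (is.null(load_fraction)) {
    abort("Missing load metadata: supply `load_fraction`.")
  }
  check_proportion(load_fraction, "load_fraction")
  if (is.null(target)) {
    ctl <- attr(table, "loading_control_target")
    targets <- setdiff(unique(table$target), ctl)
    if (length(targets) != 1) {
      abort("Cannot infer `target`; supply it explicitly.")
    }
    target <- targets
  }
  band <- function(lane) {
    v <- table$intensity[table$lane == lane & table$target == target]
    if (length(v) != 1) {
      abort(sprintf("Expected exactly one '%s' band in lane '%s'.",
                    target, lane))
    }
    v
  }
  ref <- band(wt_reference_lane)
  if (ref <= 0) abort("Reference band intensity must be positive.")
  100 * band(variant_lane) / ref * load_fraction
}

#' Viability as a percentage of untreated controls
#'
#' @param absorbance_sample Absorbance value(s).
#' @param absorbance_untreated_mean Mean untreated-control absorbance
#'   (positive).
#' @return `100 * sample / untreated mean`.
#' @export
viability_percent <- function(absorbance_sample, absorbance_untreated_mean) {
  if (!is.numeric(absorbance_untreated_mean) ||
      length(absorbance_untreated_mean) != 1L ||
      !is.finite(absorbance_untreated_mean) ||
      absorbance_untreated_mean <= 0) {
    abort("The untreated-control mean absorbance must be positive.")
  }
  100 * absorbance_sample / absorbance_untreated_mean
}
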