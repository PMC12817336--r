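test_that("standard curves recover exact lines and interpolate two points", {
  pts <- tibble::tibble(nmol = seq(0, 7.5, 1.25),
                        fluorescence = 100 * seq(0, 7.5, 1.25) + 50)
  curve <- fit_standard_curve(pts)
  expect_equal(curve$slope, 100)
  expect_equal(curve$intercept, 50)
  two <- fit_standard_curve(tibble::tibble(nmol = c(0, 7.5),
                                           fluorescence = c(50, 800)))
  expect_equal(two$slope, 100)
  expect_equal(two$intercept, 50)
  expect_error(fit_standard_curve(tibble::tibble(nmol = c(1, 1),
                                                 fluorescence = c(1, 2))),
               "distinct")
  expect_error(fit_standard_curve(tibble::tibble(nmol = c(0, 5),
                                                 fluorescence = c(100, 10))),
               "slope")
})

test_that("noisy calibration has small slope bias", {
  biases <- vapply(1:20, function(seed) {
    spec <- assay_sim_spec(curve_slope = 100, curve_intercept = 50,
                           standard_points = seq(0, 7.5, length.out = 8),
                           read_noise_sd = 5)
    plate <- simulate_activity_plate(spec, seed = seed)
    fit_standard_curve(plate)$slope
  }, numeric(1))
  expect_lt(abs(mean(biases) / 100 - 1), 0.02)
})

test_that("fluorescence back-calculation floors below-blank readings", {
  curve <- fit_standard_curve(tibble::tibble(nmol = c(0, 7.5),
                                             fluorescence = c(50, 800)))
  expect_equal(as.numeric(fluorescence_to_nmol(curve, 50)), 0)
  expect_equal(as.numeric(fluorescence_to_nmol(curve, 800)), 7.5)
  below <- fluorescence_to_nmol(curve, 20)
  expect_equal(as.numeric(below), 0)
  expect_true(attr(below, "floored"))
})

test_that("specific activity follows the mU/mg bookkeeping", {
  curve <- fit_standard_curve(tibble::tibble(nmol = c(0, 7.5),
                                             fluorescence = c(0, 7.5)))
  m <- tibble::tibble(fluorescence = 1.5, incubation_min = 30,
                      protein_mg = 0.05, dilution_factor = 1)
  expect_equal(specific_activity(m, curve)$activity_mU_per_mg, 1)
  m10 <- m; m10$dilution_factor <- 10
  expect_equal(specific_activity(m10, curve)$activity_mU_per_mg, 10)
  # invariant under doubling both the liberated 4-MU and the time
  m2 <- m; m2$fluorescence <- 3; m2$incubation_min <- 60
  expect_equal(specific_activity(m2, curve)$activity_mU_per_mg, 1)
  expect_error(specific_activity(dplyr::mutate(m, incubation_min = 0), curve),
               "incubation")
})

test_that("activity round trip through the simulator is exact", {
  for (preset in c("q82x-g418-max", "w188x-g418-max", "wt-untreated")) {
    spec <- activity_preset(preset)
    plate <- simulate_activity_plate(spec, seed = 1)
    curve <- fit_standard_curve(plate)
    act <- specific_activity(plate, curve)
    expect_equal(act$activity_mU_per_mg,
                 spec$samples$true_activity_mU_per_mg, tolerance = 1e-10)
  }
})

test_that("percent of reference is a plain ratio with guards", {
  expect_equal(percent_of_reference(3.65, 100), 3.65)
  expect_equal(percent_of_reference(5, 5), 100)
  expect_error(percent_of_reference(1, 0), "positive")
})

test_that("loading-control-normalized ratios behave like densitometry", {
  blot <- simulate_blot(blot_preset("erf3a-cc885-5nM"), seed = 1)
  level <- normalized_band_ratio(blot, "eRF3a", "GAPDH",
                                 "cc885-5nM", "untreated")
  expect_equal(level, 50)
  expect_equal(normalized_band_ratio(blot, "eRF3a", "GAPDH",
                                     "untreated", "untreated"), 100)
  # doubling every intensity changes nothing
  blot2 <- blot
  blot2$intensity <- blot2$intensity * 2
  expect_equal(normalized_band_ratio(blot2, "eRF3a", "GAPDH",
                                     "cc885-5nM", "untreated"), 50)
})

test_that("readthrough efficacy anchors on the diluted reference lane", {
  blot <- simulate_blot(blot_preset("efficacy-dual"), seed = 1)
  eff <- readthrough_efficacy_from_blot(blot, "variant", "wt-ref")
  expect_equal(eff, 3)
  # a variant band equal to the 1%-load reference band means 1% efficacy
  equal_band <- blot
  ref_int <- equal_band$intensity[equal_band$lane == "wt-ref" &
                                    equal_band$target == "FUCA1"]
  equal_band$intensity[equal_band$lane == "variant" &
                         equal_band$target == "FUCA1"] <- ref_int
  expect_equal(readthrough_efficacy_from_blot(equal_band, "variant", "wt-ref"),
               1)
  # linear in the variant band
  double_band <- blot
  double_band$intensity[double_band$lane == "variant" &
                          double_band$target == "FUCA1"] <-
    2 * double_band$intensity[double_band$lane == "variant" &
                                double_band$target == "FUCA1"]
  expect_equal(readthrough_efficacy_from_blot(double_band, "variant",
                                              "wt-ref"), 6)
  stripped <- blot
  attr(stripped, "wt_reference_load_fraction") <- NULL
  attr(stripped, "loading_control_target") <- NULL
  expect_error(readthrough_efficacy_from_blot(stripped, "variant", "wt-ref",
                                              target = "FUCA1"),
               "load")
})

test_that("blot efficacy forward-inverse identity holds", {
  # noise-free: recovered efficacy equals the generator abundance exactly
  blot <- simulate_blot(blot_preset("efficacy-dual"), seed = 1)
  expect_equal(readthrough_efficacy_from_blot(blot, "variant", "wt-ref"),
               100 * 0.03, tolerance = 1e-12)
  # with noise: mean over 20 seeds within 3 s.d. of the truth
  effs <- vapply(1:20, function(seed) {
    b <- simulate_blot(blot_preset("efficacy-dual",
                                   intensity_noise_cv = 0.05), seed = seed)
    readthrough_efficacy_from_blot(b, "variant", "wt-ref")
  }, numeric(1))
  expect_lt(abs(mean(effs) - 3), 3 * sd(effs) / sqrt(20) + 0.15)
})

test_that("simulated blots validate their design", {
  lanes <- tibble::tibble(
    lane = c("a", "a"), condition = c("x", "x"),
    target = c("FUCA1", "GAPDH"),
    true_relative_abundance = c(0, 1), load_ug = c(25, 25)
  )
  spec <- blot_sim_spec(lanes)
  b <- simulate_blot(spec, seed = 1)
  expect_equal(b$intensity[b$target == "FUCA1"], 0)
  # loads scale intensity: 25 ug vs 0.25 ug at equal abundance is 100x
  lanes2 <- tibble::tibble(
    lane = c("a", "a", "b", "b"), condition = c("x", "x", "y", "y"),
    target = c("T", "GAPDH", "T", "GAPDH"),
    true_relative_abundance = 1, load_ug = c(25, 25, 0.25, 25)
  )
  b2 <- simulate_blot(blot_sim_spec(lanes2), seed = 1)
  ratio <- b2$intensity[b2$lane == "a" & b2$target == "T"] /
    b2$intensity[b2$lane == "b" & b2$target == "T"]
  expect_equal(ratio, 100)
  expect_error(blot_sim_spec(lanes[1, ]), "loading-control")
})

test_that("viability normalization is linear with guards", {
  expect_equal(viability_percent(0.8, 0.8), 100)
  expect_equal(viability_percent(0, 0.8), 0)
  expect_equal(viability_percent(c(0.4, 0.8), 0.8), c(50, 100))
  expect_error(viability_percent(0.5, 0), "positive")
})

test_that("activity simulator honours its arithmetic", {
  spec <- assay_sim_spec(curve_slope = 100, curve_intercept = 50,
                         standard_points = c(0, 7.5))
  plate <- simulate_activity_plate(spec, seed = 1)
  std <- plate[plate$type == "standard", ]
  expect_equal(std$fluorescence[std$nmol == 7.5], 800)
  zero <- assay_sim_spec(
    curve_slope = 100, curve_intercept = 50,
    samples = tibble::tibble(sample_id = "s", true_activity_mU_per_mg = 0,
                             protein_mg = 0.05, dilution_factor = 1,
                             incubation_min = 30)
  )
  p0 <- simulate_activity_plate(zero, seed = 1)
  expect_equal(p0$fluorescence[p0$type == "sample"], 50)  # blank only
})
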