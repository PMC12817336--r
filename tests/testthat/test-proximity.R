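make_objects <- function(labels, img = NULL, pixel_size_um = 0.1) {
  label_objects(labels, img = img, min_area_px = 1,
                pixel_size_um = pixel_size_um)
}

test_that("simple geometries give the expected distances", {
  # two 1-px objects 2 px apart at 0.1 um/px: center and edge both 0.2 um
  src <- matrix(0L, 10, 10); src[5, 3] <- 1L
  tgt <- matrix(0L, 10, 10); tgt[5, 5] <- 1L
  s <- nearest_distances(make_objects(src), make_objects(tgt))
  expect_equal(s$per_object$center_to_center_um, 0.2)
  expect_equal(s$per_object$edge_to_edge_um, 0.2)
  # concentric objects: both distances 0
  big <- matrix(0L, 20, 20)
  d2 <- outer((1:20 - 10)^2, (1:20 - 10)^2, "+")
  big[d2 <= 16] <- 1L
  small <- matrix(0L, 20, 20); small[10, 10] <- 1L
  s2 <- nearest_distances(make_objects(small), make_objects(big))
  expect_equal(s2$per_object$center_to_center_um, 0)
  expect_equal(s2$per_object$edge_to_edge_um, 0)
})

test_that("nearest distances equal the O(n^2) brute-force oracle", {
  set.seed(6)
  for (rep in 1:3) {
    lab_s <- matrix(0L, 60, 60)
    lab_t <- matrix(0L, 60, 60)
    # plant up to 50 small rectangles per channel
    plant <- function(lab, n) {
      k <- 0L
      for (i in seq_len(n)) {
        r0 <- sample(2:56, 1); c0 <- sample(2:56, 1)
        h <- sample(1:3, 1); w <- sample(1:3, 1)
        patch <- lab[r0:(r0 + h), c0:(c0 + w)]
        if (all(patch == 0)) {
          k <- k + 1L
          lab[r0:(r0 + h), c0:(c0 + w)] <- k
        }
      }
      lab
    }
    lab_s <- plant(lab_s, 25)
    lab_t <- plant(lab_t, 25)
    src <- make_objects(lab_s)
    tgt <- make_objects(lab_t)
    s <- nearest_distances(src, tgt)
    oracle <- brute_force_distances(src, tgt)
    expect_equal(s$per_object$center_to_center_um,
                 oracle$center_to_center_um)
    expect_equal(s$per_object$edge_to_edge_um, oracle$edge_to_edge_um)
  }
})

test_that("edge distance never exceeds center distance", {
  set.seed(7)
  spec <- small_scene_spec()
  scene <- simulate_image_scene(spec, seed = 8)
  cfg <- fixture_config()
  src <- segment_channel(scene$fuca1, cfg)
  tgt <- segment_channel(scene$lamp1, cfg)
  s <- nearest_distances(src, tgt)
  expect_true(all(s$per_object$edge_to_edge_um <=
                    s$per_object$center_to_center_um + 1e-9))
})

test_that("fraction within radius is non-decreasing in the radius", {
  set.seed(9)
  spec <- small_scene_spec()
  scene <- simulate_image_scene(spec, seed = 10)
  cfg <- fixture_config()
  src <- segment_channel(scene$fuca1, cfg)
  tgt <- segment_channel(scene$lamp1, cfg)
  radii <- c(0.05, 0.1, 0.2, 0.4, 1, 100)
  fracs <- vapply(radii, function(r) {
    nearest_distances(src, tgt, radius_um = r)$fraction_within
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_equal(fracs[length(fracs)], 1)
})

test_that("empty channels yield a warned empty summary", {
  src <- make_objects(matrix(0L, 10, 10))
  tgt <- make_objects({m <- matrix(0L, 10, 10); m[5, 5] <- 1L; m})
  expect_warning(s <- nearest_distances(src, tgt), "Empty")
  expect_true(is.na(s$fraction_within))
  expect_equal(s$n_source, 0)
})

test_that("mismatched pixel sizes are rejected", {
  m <- matrix(0L, 10, 10); m[5, 5] <- 1L
  a <- label_objects(m, pixel_size_um = 0.1)
  b <- label_objects(m, pixel_size_um = 0.2)
  expect_error(nearest_distances(a, b), "pixel sizes")
})

test_that("per-cell intensity is relative to the reference and linear", {
  img <- matrix(2, 20, 20)
  masks <- matrix(0L, 20, 20)
  masks[2:5, 2:5] <- 1L
  masks[10:13, 10:13] <- 2L
  ref <- 2  # reference condition mean intensity per area
  out <- intensity_per_cell(img, masks, reference_mean = ref)
  expect_equal(out$relative_percent, c(100, 100))
  out2 <- intensity_per_cell(2 * img, masks, reference_mean = ref)
  expect_equal(out2$relative_percent, c(200, 200))
  out0 <- intensity_per_cell(img * 0, masks, reference_mean = ref)
  expect_equal(out0$relative_percent, c(0, 0))
  expect_error(intensity_per_cell(img, masks * 0L), "No cell masks")
})

test_that("segmentation chain recovers planted scene geometry", {
  spec <- proximity_preset("wild-type")
  recalls <- c(); errs <- c()
  for (seed in 1:3) {
    scene <- simulate_image_scene(spec, seed = seed)
    truth <- scene$truth[scene$truth$channel == "fuca1", ]
    rep <- run_proximity(scene)
    pooled <- attr(rep, "pooled")
    recalls <- c(recalls, rep$n_fuca1 / nrow(truth))
    errs <- c(errs, abs(pooled$mean_center_um - mean(truth$nearest_center_um)))
  }
  expect_gt(mean(recalls), 0.9)
  expect_lt(mean(errs), 0.1)  # within one pixel-equivalent
})

test_that("degenerate preset: all puncta within radius gives fraction 1", {
  spec <- small_scene_spec(fraction_within_02um = 1, n_fuca1 = 12,
                           n_lamp1 = 8)
  scene <- simulate_image_scene(spec, seed = 12)
  truth <- scene$truth[scene$truth$channel == "fuca1", ]
  expect_true(all(truth$nearest_edge_um <= 0.2))
  rep <- run_proximity(scene, fixture_config())
  expect_gt(attr(rep, "pooled")$fraction_within, 0.95)
})
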