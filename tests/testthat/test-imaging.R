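test_that("contrast normalization is invariant to affine intensity maps", {
  set.seed(1)
  img <- matrix(runif(32 * 32, 0, 200), 32)
  a <- normalize_contrast(img)
  b <- normalize_contrast(3.7 * img + 55)
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("constant images pass through contrast normalization unchanged", {
  img <- matrix(5, 16, 16)
  expect_warning(out <- normalize_contrast(img), "Constant")
  expect_identical(out, img)
})

test_that("rolling-ball background subtraction removes flat offsets", {
  img <- matrix(7, 64, 64)
  expect_equal(rolling_ball_background(img, 10), matrix(0, 64, 64))
  set.seed(2)
  base <- matrix(runif(64 * 64), 64)
  a <- rolling_ball_background(base, 10)
  b <- rolling_ball_background(base + 123, 10)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("rolling ball preserves features narrower than the element", {
  img <- matrix(0, 64, 64)
  img[30:32, 30:32] <- 10  # 3-px punctum on zero background
  out <- rolling_ball_background(img, 10)
  # oracle: grayscale opening of an isolated small square on zero
  # background is zero, so the punctum survives fully
  expect_equal(out[30:32, 30:32], img[30:32, 30:32])
  # oversized element degenerates to flat-background subtraction
  expect_warning(rolling_ball_background(matrix(1, 8, 8), 50), "larger")
})

test_that("Phansalkar threshold matches the pixelwise formula oracle", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32)
  img[10:20, 10:20] <- img[10:20, 10:20] + 2
  img <- img / max(img)
  radius <- 5; k <- 0.25; r <- 0.5; p <- 2; q <- 10
  mask <- phansalkar_threshold(img, radius_px = radius, k = k, r = r,
                               p = p, q = q)
  # oracle: direct per-pixel evaluation with replicate padding
  pad <- radius
  padded <- matrix(0, 32 + 2 * pad, 32 + 2 * pad)
  padded[pad + 1:32, pad + 1:32] <- img
  for (i in seq_len(pad)) {
    padded[i, ] <- padded[pad + 1, ]; padded[32 + pad + i, ] <- padded[32 + pad, ]
  }
  for (j in seq_len(pad)) {
    padded[, j] <- padded[, pad + 1]; padded[, 32 + pad + j] <- padded[, 32 + pad]
  }
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  oracle <- matrix(0, 32, 32)
  clear <- matrix(TRUE, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    vals <- padded[cbind(pad + i + offs$di, pad + j + offs$dj)]
    m <- mean(vals)
    s <- sqrt(mean(vals^2) - m^2)
    thr <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
    oracle[i, j] <- as.numeric(img[i, j] > thr)
    # pixels numerically on the threshold are excluded: the convolution
    # computes the same statistics up to floating-point rounding
    clear[i, j] <- abs(img[i, j] - thr) > 1e-8
  }
  expect_true(all(mask[clear] == oracle[clear]))
  expect_gt(mean(clear), 0.98)
})

test_that("Phansalkar marks dim constant images as background", {
  # value m with s = 0: threshold m (1 + p e^{-qm} - k) >= m for small m
  img <- matrix(0.15, 32, 32)
  mask <- phansalkar_threshold(img)
  expect_equal(sum(mask), 0)
})

test_that("bright discs on dark background are segmented as foreground", {
  img <- matrix(0, 32, 32)
  d2 <- outer((1:32 - 16)^2, (1:32 - 16)^2, "+")
  img[d2 <= 25] <- 1
  mask <- phansalkar_threshold(img, radius_px = 10)
  expect_true(all(mask[d2 <= 9] == 1))  # disc interior is foreground
})

test_that("adaptive filter removes speckle and preserves solid regions", {
  m <- matrix(0, 16, 16)
  m[8, 8] <- 1  # isolated pixel
  expect_equal(sum(adaptive_filter(m)), 0)
  sq <- matrix(0, 16, 16)
  sq[5:9, 5:9] <- 1
  expect_equal(adaptive_filter(sq), sq)
})

test_that("adaptive filter equals a brute-force median on random masks", {
  brute_median <- function(x, radius) {
    out <- x
    nr <- nrow(x); nc <- ncol(x)
    offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
    offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ri <- pmin(pmax(i + offs$di, 1), nr)
      cj <- pmin(pmax(j + offs$dj, 1), nc)
      out[i, j] <- median(x[cbind(ri, cj)])
    }
    out
  }
  set.seed(4)
  for (rep in 1:5) {
    m <- matrix(rbinom(16 * 16, 1, 0.4), 16)
    expect_equal(adaptive_filter(m, 1), brute_median(m, 1))
  }
  g <- matrix(runif(16 * 16), 16)
  expect_equal(adaptive_filter(g, 1), brute_median(g, 1))
})

test_that("watershed assigns every foreground pixel and splits fused discs", {
  mk_disc <- function(m, ci, cj, r) {
    d2 <- outer((seq_len(nrow(m)) - ci)^2, (seq_len(ncol(m)) - cj)^2, "+")
    m[d2 <= r^2] <- 1
    m
  }
  # two well-separated discs
  m <- mk_disc(mk_disc(matrix(0, 48, 48), 12, 12, 8), 36, 36, 8)
  lab <- watershed_split(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab > 0), sum(m > 0))
  # two discs fused by a thin neck still split into 2
  fused <- mk_disc(mk_disc(matrix(0, 40, 60), 20, 18, 8), 20, 42, 8)
  fused[19:21, 18:42] <- 1
  lab2 <- watershed_split(fused)
  expect_equal(max(lab2), 2)
  expect_equal(sum(lab2 > 0), sum(fused > 0))
  # labels are contiguous 1..K
  expect_setequal(setdiff(unique(as.vector(lab2)), 0), 1:2)
})

test_that("objects that erode away entirely keep one marker", {
  m <- matrix(0, 20, 20)
  m[9:11, 9:11] <- 1  # 3x3: gone after 2 erosion cycles
  lab <- watershed_split(m, erosion_cycles = 5)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab > 0), 9)
  # empty mask gives an empty label map
  expect_equal(max(watershed_split(matrix(0, 10, 10))), 0)
})

test_that("watershed output is deterministic", {
  set.seed(5)
  m <- matrix(rbinom(40 * 40, 1, 0.3), 40)
  expect_identical(watershed_split(m), watershed_split(m))
})

test_that("label_objects measures centroids, areas and boundaries", {
  m <- matrix(0L, 40, 40)
  d2 <- outer((1:40 - 20)^2, (1:40 - 20)^2, "+")
  m[d2 <= 25] <- 1L
  obj <- label_objects(m, pixel_size_um = 0.1)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$x_um, (20 - 0.5) * 0.1, tolerance = 0.01)
  expect_equal(obj$y_um, (20 - 0.5) * 0.1, tolerance = 0.01)
  expect_equal(obj$area_px, sum(m))
  # single pixel object and min-area filtering
  m2 <- matrix(0L, 10, 10)
  m2[3, 3] <- 1L
  m2[7:8, 7:8] <- 2L
  all_obj <- label_objects(m2, min_area_px = 1)
  expect_equal(nrow(all_obj), 2)
  filtered <- label_objects(m2, min_area_px = 2)
  expect_equal(nrow(filtered), 1)
  expect_equal(attr(filtered, "n_dropped"), 1L)
})
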