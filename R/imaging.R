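# Segmentation chain: contrast normalization, rolling-ball background
# subtraction, Phansalkar local thresholding, adaptive (median) filtering,
# and erosion-marker watershed splitting. All functions take and return
# plain numeric matrices; binary masks are 0/1 matrices and label maps are
# integer matrices with 0 background.

# Disc neighborhood: offsets with di^2 + dj^2 <= r^2 (a plus shape at r = 1).
disc_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  d <- -r:r
  k <- outer(d^2, d^2, "+") <= radius_px^2
  storage.mode(k) <- "double"
  k
}

# --- grayscale morphology with a disc structuring element -----------------
# Row/column shifts use replicate boundary handling. The disc is decomposed
# into horizontal line segments per row offset; each line min/max uses
# logarithmic doubling, so an erosion costs O(r log r) matrix operations.

shift_rows <- function(x, k) {
  idx <- pmin(pmax(seq_len(nrow(x)) + k, 1L), nrow(x))
  x[idx, , drop = FALSE]
}

shift_cols <- function(x, k) {
  idx <- pmin(pmax(seq_len(ncol(x)) + k, 1L), ncol(x))
  x[, idx, drop = FALSE]
}

# centered sliding window min/max of half-width w along columns
win_cols <- function(x, w, op) {
  if (w == 0) return(x)
  width <- 2L * w + 1L
  m <- shift_cols(x, -w)  # left-anchor the window
  span <- 1L
  while (span < width) {
    step <- min(span, width - span)
    m <- op(m, shift_cols(m, step))
    span <- span + step
  }
  m
}

gray_morph <- function(img, radius_px, op) {
  r <- as.integer(radius_px)
  out <- NULL
  for (di in -r:r) {
    w <- floor(sqrt(radius_px^2 - di^2))
    h <- win_cols(shift_rows(img, di), w, op)
    out <- if (is.null(out)) h else op(out, h)
  }
  out
}

gray_erode <- function(img, radius_px) gray_morph(img, radius_px, pmin)

gray_dilate <- function(img, radius_px) gray_morph(img, radius_px, pmax)

# grayscale opening: erosion followed by dilation with the same disc
gray_opening <- function(img, radius_px) {
  gray_dilate(gray_erode(img, radius_px), radius_px)
}

#' Percentile contrast normalization
#'
#' Linearly rescales intensities so that the `saturated_percent`/100-th and
#' complementary percentiles map to 0 and 1 (values beyond them are
#' clipped), mirroring an automatic display-contrast adjustment. The
#' transform is monotone, so images equal up to an affine intensity change
#' normalize identically.
#'
#' @param img Numeric intensity matrix.
#' @param saturated_percent Percentage of pixels saturated at each end
#'   (default 0.35).
#' @return Matrix rescaled to `[0, 1]`; a constant image is returned
#'   unchanged with a warning.
#' @export
normalize_contrast <- function(img, saturated_percent = 0.35) {
  if (length(img) == 0) abort("Empty image.")
  p <- saturated_percent / 100
  lo <- quantile(img, p, names = FALSE)
  hi <- quantile(img, 1 - p, names = FALSE)
  if (hi <= lo) {
    warn("Constant image: contrast normalization left it unchanged.")
    return(img)
  }
  pmin(pmax((img - lo) / (hi - lo), 0), 1)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image
#' with a disc structuring element of the given radius (the classical
#' morphological implementation of the rolling-ball estimate) and subtracts
#' it. Features narrower than the disc survive; adding a constant offset to
#' the input does not change the output.
#'
#' @param img Numeric intensity matrix.
#' @param radius_px Structuring-element radius in pixels (default 50).
#' @return Nonnegative background-subtracted matrix.
#' @export
rolling_ball_background <- function(img, radius_px = 50) {
  check_scalar(radius_px, "radius_px", lower = 1)
  if (2 * radius_px + 1 > min(dim(img))) {
    warn("Structuring element larger than the image: flat background assumed.")
    return(img - min(img))
  }
  bg <- gray_opening(img, radius_px)
  # opening never exceeds the image pointwise, so this is nonnegative
  img - bg
}

local_stats <- function(img, radius_px) {
  w <- disc_kernel(radius_px)
  w <- w / sum(w)
  m <- as.matrix(EBImage::filter2(img, w, boundary = "replicate"))
  ex2 <- as.matrix(EBImage::filter2(img^2, w, boundary = "replicate"))
  s <- sqrt(pmax(ex2 - m^2, 0))
  list(mean = m, sd = s)
}

#' Phansalkar local adaptive threshold
#'
#' A pixel is foreground iff its value exceeds
#' `m * (1 + p * exp(-q * m) + k * (s / r - 1))`, where `m` and `s` are the
#' local mean and standard deviation within a disc of the given radius.
#' Designed for low-contrast stained images: the exponential term raises
#' the threshold where the local mean is small, suppressing background
#' noise. Intensities are expected in `[0, 1]`; inputs with a larger range
#' are divided by their maximum first. Local statistics use replicate
#' boundary handling.
#'
#' @param img Numeric intensity matrix.
#' @param radius_px Neighborhood radius in pixels (default 15).
#' @param k,r,p,q Phansalkar parameters; defaults follow the published
#'   formulation (k = 0.25, r = 0.5, p = 2, q = 10).
#' @return Binary 0/1 mask matrix.
#' @export
phansalkar_threshold <- function(img, radius_px = 15, k = 0.25, r = 0.5,
                                 p = 2.0, q = 10.0) {
  check_scalar(radius_px, "radius_px", lower = 1)
  mx <- max(img)
  if (mx > 1) img <- img / mx
  st <- local_stats(img, radius_px)
  thr <- st$mean * (1 + p * exp(-q * st$mean) + k * (st$sd / r - 1))
  mask <- (img > thr) * 1
  dim(mask) <- dim(img)
  mask
}

#' Adaptive (median) filter
#'
#' Median filter within a disc neighborhood (center included); with the
#' default 1-pixel radius this removes isolated single-pixel speckle while
#' leaving solid regions unchanged. Binary masks use an exact majority-vote
#' implementation; grayscale images use a direct per-pixel median (intended
#' for small images). Boundaries are handled by replication.
#'
#' @param x Binary 0/1 mask or numeric intensity matrix.
#' @param radius_px Neighborhood radius in pixels (default 1).
#' @return Filtered matrix of the same kind.
#' @export
adaptive_filter <- function(x, radius_px = 1) {
  check_scalar(radius_px, "radius_px", lower = 1)
  kern <- disc_kernel(radius_px)
  n_in_disc <- sum(kern)
  if (all(x %in% c(0, 1))) {
    s <- as.matrix(EBImage::filter2(x, kern, boundary = "replicate"))
    out <- (s > n_in_disc / 2) * 1
    dim(out) <- dim(x)
    return(out)
  }
  # grayscale: gather the disc offsets as shifted copies and take medians
  rad <- as.integer(radius_px)
  offsets <- which(kern == 1, arr.ind = TRUE) - rad - 1L
  nr <- nrow(x)
  nc <- ncol(x)
  stack <- vapply(seq_len(nrow(offsets)), function(i) {
    di <- offsets[i, 1]
    dj <- offsets[i, 2]
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    x[ri, cj, drop = FALSE]
  }, matrix(0, nr, nc))
  out <- apply(stack, c(1, 2), median)
  out
}

#' Erosion-marker watershed splitting
#'
#' Splits touching objects in a binary mask: markers are the connected
#' components that survive `erosion_cycles` iterations of single-pixel
#' (3x3) erosion; a component that erodes away entirely keeps its
#' pre-erosion extent as a single marker, so no object is lost. Labels are
#' then assigned by geodesic propagation of the markers across the mask
#' (the marker-constrained watershed of the distance transform), leaving
#' every foreground pixel labeled.
#'
#' @param mask Binary 0/1 matrix.
#' @param erosion_cycles Number of erosion iterations (default 5).
#' @return Integer label matrix (contiguous labels 1..K, 0 background) with
#'   attribute `parameters`.
#' @export
watershed_split <- function(mask, erosion_cycles = 5) {
  if (!all(mask %in% c(0, 1))) abort("`mask` must be binary (0/1).")
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask > 0)) {
    attr(out, "parameters") <- list(erosion_cycles = erosion_cycles)
    return(out)
  }
  comp <- EBImage::bwlabel(mask)
  eroded <- mask
  brush <- EBImage::makeBrush(3, shape = "box")
  for (i in seq_len(erosion_cycles)) {
    eroded <- as.matrix(EBImage::erode(eroded, brush))
  }
  markers <- as.matrix(EBImage::bwlabel(eroded))

  # rescue components whose markers eroded away: whole component as marker
  comp_ids <- setdiff(unique(as.vector(comp)), 0)
  surviving <- setdiff(unique(as.vector(comp[markers > 0])), 0)
  lost <- setdiff(comp_ids, surviving)
  if (length(lost) > 0) {
    next_label <- max(markers)
    add <- matrix(0, nrow(mask), ncol(mask))
    for (i in seq_along(lost)) {
      add[comp == lost[i]] <- next_label + i
    }
    markers <- markers + add
  }

  lab <- EBImage::propagate(EBImage::Image(matrix(0, nrow(mask), ncol(mask))),
                            seeds = markers, mask = mask > 0)
  lab <- as.matrix(EBImage::imageData(lab))

  # contiguous labels 1..K
  ids <- sort(setdiff(unique(as.vector(lab)), 0))
  relabel <- integer(max(ids) + 1)
  relabel[ids + 1] <- seq_along(ids)
  out <- matrix(0L, nrow(mask), ncol(mask))
  pos <- lab > 0
  out[pos] <- relabel[lab[pos] + 1]
  attr(out, "parameters") <- list(erosion_cycles = erosion_cycles)
  out
}

#' Measure labeled objects
#'
#' Computes per-object centroids (optionally intensity-weighted), areas,
#' boundary-pixel sets and intensities from a label map, dropping objects
#' below a minimum area.
#'
#' @param labels Integer label matrix (0 = background).
#' @param img Optional intensity matrix for intensity statistics and
#'   weighted centroids.
#' @param min_area_px Objects smaller than this are dropped (counted in
#'   `attr(, "n_dropped")`).
#' @param pixel_size_um Micrometers per pixel; coordinates are reported in
#'   µm (pixel centers at `(index - 0.5) * pixel_size_um`).
#' @param weighted Use intensity-weighted centroids (needs `img`).
#' @return A tibble of class `object_table`: `label`, `x_um`, `y_um`,
#'   `area_px`, `mean_intensity`, `total_intensity`, `r_max_um` (max
#'   centroid-to-boundary distance), plus list-columns `boundary_um` and
#'   `pixels` (n x 2 matrices of µm coordinates / pixel indices).
#' @export
label_objects <- function(labels, img = NULL, min_area_px = 1,
                          pixel_size_um = 1, weighted = FALSE) {
  ps <- pixel_size_um
  idx <- which(labels > 0)
  empty <- tibble(
    label = integer(), x_um = numeric(), y_um = numeric(),
    area_px = integer(), mean_intensity = numeric(),
    total_intensity = numeric(), r_max_um = numeric(),
    boundary_um = list(), pixels = list()
  )
  if (length(idx) == 0) {
    return(structure(empty, n_dropped = 0L, pixel_size_um = ps,
                     class = c("object_table", class(empty))))
  }
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))

  # boundary: pixel with any 4-neighbor of a different label (or image edge)
  nr <- nrow(labels)
  nc <- ncol(labels)
  padded <- matrix(-1L, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- labels
  ctr <- padded[2:(nr + 1), 2:(nc + 1)]
  is_boundary <- (padded[1:nr, 2:(nc + 1)] != ctr) |
    (padded[3:(nr + 2), 2:(nc + 1)] != ctr) |
    (padded[2:(nr + 1), 1:nc] != ctr) |
    (padded[2:(nr + 1), 3:(nc + 2)] != ctr)
  boundary_flag <- is_boundary[idx]

  intens <- if (!is.null(img)) img[idx] else rep(NA_real_, length(idx))
  split_idx <- split(seq_along(idx), lab)

  rows <- purrr::imap(split_idx, function(ii, label_chr) {
    r <- rc[ii, 1]
    c <- rc[ii, 2]
    x <- (c - 0.5) * ps
    y <- (r - 0.5) * ps
    w <- if (weighted && !is.null(img)) {
      wt <- intens[ii]
      if (sum(wt) <= 0) rep(1, length(ii)) else wt
    } else {
      rep(1, length(ii))
    }
    cx <- sum(x * w) / sum(w)
    cy <- sum(y * w) / sum(w)
    bidx <- ii[boundary_flag[ii]]
    b_um <- cbind(x_um = (rc[bidx, 2] - 0.5) * ps,
                  y_um = (rc[bidx, 1] - 0.5) * ps)
    tibble(
      label = as.integer(label_chr),
      x_um = cx, y_um = cy,
      area_px = length(ii),
      mean_intensity = if (!is.null(img)) mean(intens[ii]) else NA_real_,
      total_intensity = if (!is.null(img)) sum(intens[ii]) else NA_real_,
      r_max_um = max(sqrt((b_um[, 1] - cx)^2 + (b_um[, 2] - cy)^2)),
      boundary_um = list(b_um),
      pixels = list(rc[ii, , drop = FALSE])
    )
  })
  out <- bind_rows(rows)
  n_dropped <- sum(out$area_px < min_area_px)
  out <- out %>% filter(.data$area_px >= min_area_px)
  structure(out, n_dropped = n_dropped, pixel_size_um = ps,
            class = c("object_table", class(empty)))
}
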