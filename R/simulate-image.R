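#' Specification of a synthetic two-channel lysosome/puncta scene
#'
#' Describes a single confocal-plane scene: a target channel of
#' lysosome-like discs (LAMP1 role, sub-micrometer diameters) and a source
#' channel of enzyme puncta (FUCA1 role) whose edge-to-edge distance to the
#' nearest lysosome follows a two-component mixture: a fraction
#' `fraction_within_02um` of puncta are membrane-apposed - they sit
#' directly at the lysosome boundary at sub-resolution edge distances
#' (`within_ring_edge_range_um`, well below 0.2 µm), spread over the
#' lysosome population and across opposite sides of each organelle,
#' emulating a luminal enzyme read out against a membrane marker - while
#' the remainder sit at an edge distance drawn uniformly from
#' `beyond_edge_range_um`. Rendering applies a Gaussian point-spread blur,
#' a constant background with a linear gradient, and intensity-dependent
#' photon noise.
#'
#' @param image_shape Image size in pixels (rows, cols).
#' @param pixel_size_um Micrometers per pixel.
#' @param n_lamp1,n_fuca1 Object counts per channel.
#' @param lamp1_diameter_um Sampling range of lysosome diameters (µm); upper
#'   bound must stay below 0.7 µm.
#' @param fuca1_diameter_um Sampling range of puncta diameters (µm).
#' @param fraction_within_02um Mixture weight of the lysosome-associated
#'   component.
#' @param within_radius_um Edge-distance bound defining "within" (µm).
#' @param within_ring_edge_range_um Uniform edge-distance range (µm) of
#'   membrane-apposed puncta; must stay below `within_radius_um`.
#' @param beyond_edge_range_um Uniform range of edge distances for the
#'   remainder (µm); must start above `within_radius_um`.
#' @param lamp1_peak,fuca1_peak Object peak intensities (AU).
#' @param psf_sigma_px Gaussian blur width in pixels.
#' @param background_level Constant background (AU).
#' @param background_gradient Left-to-right linear background ramp (AU).
#' @param photon_noise_scale Noise s.d. is `scale * sqrt(intensity)`.
#' @param seed Default seed used by [simulate_image_scene()].
#' @return An object of class `image_scene_spec`.
#' @export
image_scene_spec <- function(image_shape = c(160, 160),
                             pixel_size_um = 0.1,
                             n_lamp1 = 33,
                             n_fuca1 = 90,
                             lamp1_diameter_um = c(0.22, 0.26),
                             fuca1_diameter_um = c(0.2, 0.22),
                             fraction_within_02um = 0.6,
                             within_radius_um = 0.2,
                             within_ring_edge_range_um = c(0.04, 0.10),
                             beyond_edge_range_um = c(0.27, 0.34),
                             lamp1_peak = 150,
                             fuca1_peak = 150,
                             psf_sigma_px = 0.5,
                             background_level = 10,
                             background_gradient = 2,
                             photon_noise_scale = 0.5,
                             seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 64))
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  check_scalar(n_lamp1, "n_lamp1", lower = 0)
  check_scalar(n_fuca1, "n_fuca1", lower = 0)
  check_proportion(fraction_within_02um, "fraction_within_02um")
  check_scalar(within_radius_um, "within_radius_um", lower = 0,
               strict_lower = TRUE)
  stopifnot(length(lamp1_diameter_um) == 2, length(fuca1_diameter_um) == 2,
            length(beyond_edge_range_um) == 2)
  if (lamp1_diameter_um[2] >= 0.7) {
    abort("`lamp1_diameter_um` upper bound must be below 0.7 um.")
  }
  if (lamp1_diameter_um[1] / pixel_size_um < 2 ||
      fuca1_diameter_um[1] / pixel_size_um < 2) {
    abort("Object diameters must span at least 2 pixels.")
  }
  if (beyond_edge_range_um[1] <= within_radius_um) {
    abort("`beyond_edge_range_um` must start above `within_radius_um`.")
  }
  if (within_ring_edge_range_um[2] >= within_radius_um) {
    abort("`within_ring_edge_range_um` must stay below `within_radius_um`.")
  }
  structure(
    list(
      image_shape = as.integer(image_shape),
      pixel_size_um = pixel_size_um,
      n_lamp1 = as.integer(n_lamp1),
      n_fuca1 = as.integer(n_fuca1),
      lamp1_diameter_um = lamp1_diameter_um,
      fuca1_diameter_um = fuca1_diameter_um,
      fraction_within_02um = fraction_within_02um,
      within_radius_um = within_radius_um,
      within_ring_edge_range_um = within_ring_edge_range_um,
      beyond_edge_range_um = beyond_edge_range_um,
      lamp1_peak = lamp1_peak,
      fuca1_peak = fuca1_peak,
      psf_sigma_px = psf_sigma_px,
      background_level = background_level,
      background_gradient = background_gradient,
      photon_noise_scale = photon_noise_scale,
      seed = seed
    ),
    class = "image_scene_spec"
  )
}

# Draw a flat disc of the given peak intensity onto `img` (µm coordinates:
# pixel (i, j) has center ((j - 0.5) ps, (i - 0.5) ps)).
draw_disc <- function(img, x_um, y_um, r_um, peak, pixel_size_um) {
  ps <- pixel_size_um
  i_range <- max(1, floor(y_um / ps - r_um / ps)):
    min(nrow(img), ceiling(y_um / ps + r_um / ps) + 1)
  j_range <- max(1, floor(x_um / ps - r_um / ps)):
    min(ncol(img), ceiling(x_um / ps + r_um / ps) + 1)
  yc <- (i_range - 0.5) * ps
  xc <- (j_range - 0.5) * ps
  d2 <- outer((yc - y_um)^2, (xc - x_um)^2, "+")
  patch <- img[i_range, j_range]
  patch[d2 <= r_um^2] <- patch[d2 <= r_um^2] + peak
  img[i_range, j_range] <- patch
  img
}

#' Simulate a two-channel scene with ground-truth geometry
#'
#' Places lysosome-like discs and enzyme puncta according to an
#' [image_scene_spec()], renders both channels with blur, background and
#' noise, and returns the ground-truth object table alongside. Edge and
#' center distances in the truth table are computed analytically from the
#' placed centers and radii (edge distance floored at 0 for overlapping
#' objects).
#'
#' @param spec An [image_scene_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param max_attempts Placement attempts per object before failing.
#' @return A list of class `image_scene` with `lamp1` and `fuca1` intensity
#'   matrices, `truth` (tibble: `channel`, `label`, `x_um`, `y_um`,
#'   `radius_um`, `group`, `nearest_center_um`, `nearest_edge_um`), and
#'   `spec`.
#' @export
simulate_image_scene <- function(spec, seed = spec$seed, max_attempts = 500) {
  stopifnot(inherits(spec, "image_scene_spec"))
  ps <- spec$pixel_size_um
  h_um <- spec$image_shape[1] * ps
  w_um <- spec$image_shape[2] * ps

  with_seed(seed, {
    # puncta separability: centers at least radii + 3.1 px apart, beyond
    # the mask-merging range of the blur + threshold chain
    sep_gap <- 3.1 * ps
    # Lysosome spacing guarantees that membrane-apposed punctum clusters
    # of neighboring organelles can never violate the puncta separation:
    # two clusters extend at most `ring_dmax` from their centers each.
    ring_dmax <- spec$lamp1_diameter_um[2] / 2 +
      spec$fuca1_diameter_um[2] / 2 + spec$within_ring_edge_range_um[2]
    lamp_spacing <- spec$fuca1_diameter_um[2] + sep_gap + 2 * ring_dmax

    # --- LAMP1 discs ---
    lamp <- matrix(numeric(0), nrow = 0, ncol = 3)  # x, y, r (µm)
    for (i in seq_len(spec$n_lamp1)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        r <- runif(1, spec$lamp1_diameter_um[1], spec$lamp1_diameter_um[2]) / 2
        margin <- r + 2 * ps
        x <- runif(1, margin, w_um - margin)
        y <- runif(1, margin, h_um - margin)
        ok <- nrow(lamp) == 0 ||
          all(sqrt((lamp[, 1] - x)^2 + (lamp[, 2] - y)^2) > lamp_spacing)
        if (ok) {
          lamp <- rbind(lamp, c(x, y, r))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("Could not place a lysosome disc within the attempt budget.")
      }
    }

    # --- FUCA1 puncta relative to a partner lysosome ---
    if (spec$n_fuca1 > 0 && nrow(lamp) == 0) {
      abort("Cannot place puncta without target discs.")
    }
    fuca <- matrix(numeric(0), nrow = 0, ncol = 3)
    groups <- character(0)
    # exact mixture composition: the realized within-fraction equals the
    # specified one up to rounding
    n_within <- round(spec$fraction_within_02um * spec$n_fuca1)
    if (n_within > 2 * spec$n_lamp1) {
      abort(paste0(
        "Placement error: at most two lysosome-associated puncta fit per ",
        "lysosome; reduce `fraction_within_02um`, `n_fuca1` or raise ",
        "`n_lamp1`."
      ))
    }
    # Assign lysosome roles for the associated pool: `n_pair` lysosomes
    # host two membrane-apposed puncta on roughly opposite sides; the rest
    # of the pool sits concentric with its own lysosome (one per organelle,
    # center-to-center near 0). Two associated puncta on one lysosome can
    # only stay resolvable on opposite sides, while a concentric punctum
    # admits no resolvable companion.
    n_pair <- max(0L, n_within - spec$n_lamp1)
    n_conc <- n_within - 2L * n_pair
    try_place <- function(partner, kind) {
      for (att in seq_len(max_attempts)) {
        p <- partner %||% sample.int(nrow(lamp), 1)
        rl <- lamp[p, 3]
        r <- runif(1, spec$fuca1_diameter_um[1], spec$fuca1_diameter_um[2]) / 2
        d <- switch(kind,
          conc = rl * runif(1, 0, 0.4),
          ring = rl + r + runif(1, spec$within_ring_edge_range_um[1],
                                spec$within_ring_edge_range_um[2]),
          beyond = rl + r + runif(1, spec$beyond_edge_range_um[1],
                                  spec$beyond_edge_range_um[2])
        )
        ang <- runif(1, 0, 2 * pi)
        x <- lamp[p, 1] + d * cos(ang)
        y <- lamp[p, 2] + d * sin(ang)
        margin <- r + 2 * ps
        if (x < margin || x > w_um - margin ||
            y < margin || y > h_um - margin) {
          next
        }
        # realized nearest edge over all lysosomes must respect the group
        edges <- pmax(sqrt((lamp[, 1] - x)^2 + (lamp[, 2] - y)^2) -
                        lamp[, 3] - r, 0)
        min_edge <- min(edges)
        if (kind != "beyond" && min_edge > spec$within_radius_um) next
        if (kind == "beyond" && min_edge <= spec$within_radius_um) next
        if (nrow(fuca) > 0) {
          sep <- sqrt((fuca[, 1] - x)^2 + (fuca[, 2] - y)^2)
          if (any(sep < fuca[, 3] + r + sep_gap)) next
        }
        return(c(x, y, r))
      }
      abort("Could not place a punctum within the attempt budget.")
    }
    # Pairs are the most constrained, so they claim lysosomes first from a
    # shuffled pool; a pair that cannot fit on one lysosome falls back to
    # another unused one. Both puncta of a pair are sampled jointly so a
    # poorly placed first punctum cannot lock out its companion.
    pool <- sample(seq_len(max(nrow(lamp), 1)))
    place_pair <- function(partner) {
      for (att in 1:40) {
        a <- tryCatch(try_place(partner, "ring"), error = function(e) NULL)
        if (is.null(a)) return(FALSE)
        fuca <<- rbind(fuca, a)
        b <- tryCatch(try_place(partner, "ring"), error = function(e) NULL)
        if (!is.null(b)) {
          fuca <<- rbind(fuca, b)
          groups <<- c(groups, "within", "within")
          return(TRUE)
        }
        fuca <<- fuca[-nrow(fuca), , drop = FALSE]
      }
      FALSE
    }
    # concentric puncta go first (the field is empty, so they always fit),
    # then the pairs, which can fall back across the remaining pool
    for (i in seq_len(n_conc)) {
      done <- FALSE
      for (k in seq_along(pool)) {
        p <- tryCatch(try_place(pool[k], "conc"), error = function(e) NULL)
        if (!is.null(p)) {
          fuca <- rbind(fuca, p)
          groups <- c(groups, "within")
          pool <- pool[-k]
          done <- TRUE
          break
        }
      }
      if (!done) {
        abort("Could not place a concentric punctum within the attempt budget.")
      }
    }
    for (i in seq_len(n_pair)) {
      done <- FALSE
      for (k in seq_along(pool)) {
        if (place_pair(pool[k])) {
          pool <- pool[-k]
          done <- TRUE
          break
        }
      }
      if (!done) {
        abort("Could not place a punctum pair within the attempt budget.")
      }
    }
    for (i in seq_len(spec$n_fuca1 - n_within)) {
      fuca <- rbind(fuca, try_place(NULL, "beyond"))
      groups <- c(groups, "beyond")
    }

    # --- ground truth (analytic, from placed centers and radii) ---
    truth_lamp <- if (nrow(lamp) > 0) {
      tibble(channel = "lamp1", label = seq_len(nrow(lamp)),
             x_um = lamp[, 1], y_um = lamp[, 2], radius_um = lamp[, 3],
             group = NA_character_, nearest_center_um = NA_real_,
             nearest_edge_um = NA_real_)
    } else {
      tibble()
    }
    truth_fuca <- if (nrow(fuca) > 0) {
      centers <- sqrt(outer(fuca[, 1], lamp[, 1], "-")^2 +
                        outer(fuca[, 2], lamp[, 2], "-")^2)
      edges <- pmax(sweep(centers, 2, lamp[, 3], "-") - fuca[, 3], 0)
      tibble(channel = "fuca1", label = seq_len(nrow(fuca)),
             x_um = fuca[, 1], y_um = fuca[, 2], radius_um = fuca[, 3],
             group = groups,
             nearest_center_um = apply(centers, 1, min),
             nearest_edge_um = apply(edges, 1, min))
    } else {
      tibble()
    }

    # --- rendering ---
    render <- function(objs, peak) {
      img <- matrix(0, spec$image_shape[1], spec$image_shape[2])
      for (i in seq_len(nrow(objs))) {
        img <- draw_disc(img, objs[i, 1], objs[i, 2], objs[i, 3], peak, ps)
      }
      if (spec$psf_sigma_px > 0) {
        img <- as.matrix(EBImage::gblur(img, sigma = spec$psf_sigma_px))
      }
      ramp <- matrix(rep(seq(0, 1, length.out = ncol(img)), each = nrow(img)),
                     nrow(img))
      img <- img + spec$background_level + spec$background_gradient * ramp
      if (spec$photon_noise_scale > 0) {
        img <- img + rnorm(length(img),
                           sd = spec$photon_noise_scale * sqrt(pmax(img, 0)))
      }
      pmax(img, 0)
    }
    lamp_img <- render(lamp, spec$lamp1_peak)
    fuca_img <- render(fuca, spec$fuca1_peak)

    structure(
      list(lamp1 = lamp_img, fuca1 = fuca_img,
           truth = bind_rows(truth_lamp, truth_fuca), spec = spec),
      class = "image_scene"
    )
  })
}

#' Write and read a two-channel scene as TIFF plus sidecar metadata
#'
#' The two channels are written as a two-page 16-bit TIFF; the pixel size
#' and channel roles go to a YAML sidecar next to the image.
#'
#' @param scene An `image_scene` (or a list with `lamp1` and `fuca1`
#'   matrices plus `spec`).
#' @param path Output TIFF path; the sidecar is `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  scale <- 65535
  pages <- list(scene$lamp1 / scale, scene$fuca1 / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  yaml::write_yaml(
    list(pixel_size_um = scene$spec$pixel_size_um,
         channels = list("1" = "lamp1", "2" = "fuca1")),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_scene_tiff
#' @return `read_scene_tiff()` returns a list with `lamp1`, `fuca1` and
#'   `pixel_size_um`.
#' @export
read_scene_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  list(lamp1 = pages[[1]] * 65535, fuca1 = pages[[2]] * 65535,
       pixel_size_um = meta$pixel_size_um)
}
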