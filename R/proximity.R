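# Object-based proximity: nearest-neighbor center-to-center and
# edge-to-edge distances between two segmented channels.

pair_edge_distance <- function(src_boundary, tgt_boundary,
                               src_pixels, tgt_pixels) {
  # overlapping objects have edge distance 0
  key <- function(px) px[, 1] * 10000000 + px[, 2]
  if (length(intersect(key(src_pixels), key(tgt_pixels))) > 0) {
    return(0)
  }
  d2 <- outer(src_boundary[, 1], tgt_boundary[, 1], "-")^2 +
    outer(src_boundary[, 2], tgt_boundary[, 2], "-")^2
  sqrt(min(d2))
}

#' Nearest-neighbor distances between two object channels
#'
#' For every source object, the Euclidean centroid distance to the nearest
#' target object (center-to-center) and the minimum boundary-pixel distance
#' to the nearest target object (edge-to-edge), both in micrometers.
#' Overlapping objects have edge distance 0; equidistant targets resolve to
#' the lowest label. Aggregates include the fraction of source objects with
#' edge distance at most `radius_um` and the mean center-to-center
#' distance.
#'
#' Edge distances are exact: candidate targets are pruned with the
#' centroid-distance lower bound `center - r_max(source) - r_max(target)`
#' and boundary pairs are evaluated until no candidate can improve the
#' minimum.
#'
#' @param source,target [label_objects()] tables (source = enzyme puncta,
#'   target = lysosome channel).
#' @param radius_um Radius for the within-fraction aggregate (default
#'   0.2 µm).
#' @return An object of class `proximity_summary`: list with `per_object`
#'   (tibble: `label`, `nearest_center_label`, `center_to_center_um`,
#'   `nearest_edge_label`, `edge_to_edge_um`), `fraction_within`,
#'   `mean_center_um`, `radius_um`, `n_source`, `n_target`.
#' @export
nearest_distances <- function(source, target, radius_um = 0.2) {
  ps_s <- attr(source, "pixel_size_um")
  ps_t <- attr(target, "pixel_size_um")
  if (!is.null(ps_s) && !is.null(ps_t) && !isTRUE(all.equal(ps_s, ps_t))) {
    abort("Source and target channels have different pixel sizes.")
  }
  empty <- tibble(label = integer(), nearest_center_label = integer(),
                  center_to_center_um = numeric(),
                  nearest_edge_label = integer(),
                  edge_to_edge_um = numeric())
  if (nrow(source) == 0 || nrow(target) == 0) {
    warn("Empty source or target channel: empty proximity summary.")
    return(structure(
      list(per_object = empty, fraction_within = NA_real_,
           mean_center_um = NA_real_, radius_um = radius_um,
           n_source = nrow(source), n_target = nrow(target)),
      class = "proximity_summary"
    ))
  }

  centers <- sqrt(outer(source$x_um, target$x_um, "-")^2 +
                    outer(source$y_um, target$y_um, "-")^2)

  per <- purrr::map(seq_len(nrow(source)), function(i) {
    d_c <- centers[i, ]
    i_center <- which.min(d_c)  # ties: lowest label (targets label-ordered)

    lb <- d_c - source$r_max_um[i] - target$r_max_um
    ord <- order(lb, target$label)
    best <- Inf
    best_j <- NA_integer_
    for (j in ord) {
      if (lb[j] >= best) break
      d_e <- pair_edge_distance(source$boundary_um[[i]],
                                target$boundary_um[[j]],
                                source$pixels[[i]], target$pixels[[j]])
      if (d_e < best) {
        best <- d_e
        best_j <- j
      }
      if (best == 0) break
    }
    tibble(
      label = source$label[i],
      nearest_center_label = target$label[i_center],
      center_to_center_um = d_c[i_center],
      nearest_edge_label = target$label[best_j],
      edge_to_edge_um = best
    )
  }) %>% bind_rows()

  structure(
    list(
      per_object = per,
      fraction_within = mean(per$edge_to_edge_um <= radius_um),
      mean_center_um = mean(per$center_to_center_um),
      radius_um = radius_um,
      n_source = nrow(source),
      n_target = nrow(target)
    ),
    class = "proximity_summary"
  )
}

#' @export
print.proximity_summary <- function(x, ...) {
  cat(sprintf(
    "<proximity_summary> %d source vs %d target objects\n",
    x$n_source, x$n_target
  ))
  cat(sprintf("  fraction within %.2g um: %.3f; mean center-to-center %.3f um\n",
              x$radius_um, x$fraction_within, x$mean_center_um))
  invisible(x)
}

#' @rdname nearest_distances
#' @param x A `proximity_summary`.
#' @param ... Unused.
#' @export
tidy.proximity_summary <- function(x, ...) {
  x$per_object
}

#' @rdname nearest_distances
#' @export
glance.proximity_summary <- function(x, ...) {
  tibble(fraction_within = x$fraction_within,
         mean_center_um = x$mean_center_um,
         radius_um = x$radius_um,
         n_source = x$n_source, n_target = x$n_target)
}

#' Per-cell relative marker intensity
#'
#' Integrated marker intensity per cell divided by the cell mask area (2D
#' area standing in for cell volume in a single plane), expressed relative
#' to a reference condition mean, times 100.
#'
#' @param img Marker intensity matrix.
#' @param cell_masks Integer label matrix of disjoint cell masks.
#' @param reference_mean Mean area-normalized intensity of the reference
#'   (e.g. wild-type) condition; must be positive. `NULL` reports raw
#'   area-normalized intensities.
#' @return A tibble: `cell`, `area_px`, `intensity_per_area`,
#'   `relative_percent` (when a reference is given).
#' @export
intensity_per_cell <- function(img, cell_masks, reference_mean = NULL) {
  if (!any(cell_masks > 0)) abort("No cell masks provided.")
  idx <- which(cell_masks > 0)
  lab <- cell_masks[idx]
  vals <- img[idx]
  out <- tibble(cell = lab, value = vals) %>%
    group_by(.data$cell) %>%
    summarise(area_px = n(),
              intensity_per_area = sum(.data$value) / n(),
              .groups = "drop")
  if (!is.null(reference_mean)) {
    check_scalar(reference_mean, "reference_mean", lower = 0,
                 strict_lower = TRUE)
    out <- out %>%
      mutate(relative_percent = 100 * .data$intensity_per_area / reference_mean)
  }
  out
}

#' Default parameters of the segmentation and proximity chain
#'
#' @param pixel_size_um Micrometers per pixel.
#' @param saturated_percent Contrast-normalization saturation.
#' @param rolling_ball_radius_px Background structuring-element radius.
#' @param phansalkar_radius_px,phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q
#'   Local-threshold parameters.
#' @param adaptive_radius_px Median-filter radius.
#' @param erosion_cycles Watershed marker erosion cycles.
#' @param min_area_px Minimum object area kept.
#' @param radius_um Within-radius for the proximity fraction.
#' @return A named list.
#' @export
proximity_config <- function(pixel_size_um = 0.1,
                             saturated_percent = 0.35,
                             rolling_ball_radius_px = 50,
                             phansalkar_radius_px = 15,
                             phansalkar_k = 0.25,
                             phansalkar_r = 0.5,
                             phansalkar_p = 2.0,
                             phansalkar_q = 10.0,
                             adaptive_radius_px = 1,
                             erosion_cycles = 5,
                             min_area_px = 2,
                             radius_um = 0.2) {
  as.list(environment())
}

#' Segment one channel with the full chain
#'
#' Contrast normalization, rolling-ball background subtraction, Phansalkar
#' thresholding, adaptive median filtering, erosion-marker watershed and
#' object measurement, in that order.
#'
#' @param img Intensity matrix.
#' @param config A [proximity_config()].
#' @return An [label_objects()] table.
#' @export
segment_channel <- function(img, config = proximity_config()) {
  norm <- normalize_contrast(img, config$saturated_percent)
  bgsub <- rolling_ball_background(norm, config$rolling_ball_radius_px)
  mask <- phansalkar_threshold(bgsub,
                               radius_px = config$phansalkar_radius_px,
                               k = config$phansalkar_k,
                               r = config$phansalkar_r,
                               p = config$phansalkar_p,
                               q = config$phansalkar_q)
  mask <- adaptive_filter(mask, config$adaptive_radius_px)
  labels <- watershed_split(mask, config$erosion_cycles)
  label_objects(labels, img = bgsub, min_area_px = config$min_area_px,
                pixel_size_um = config$pixel_size_um)
}

#' Run the proximity pipeline over one or more two-channel scenes
#'
#' Segments the target (lysosome) and source (puncta) channel of each scene
#' with [segment_channel()] and computes nearest-neighbor distances. Scenes
#' with no detected source objects are flagged and excluded from pooled
#' aggregates.
#'
#' @param scenes A single scene (list with `lamp1` and `fuca1` matrices,
#'   e.g. from [simulate_image_scene()]) or a list of such scenes.
#' @param config A [proximity_config()].
#' @return A tibble of class `proximity_report`, one row per scene
#'   (`scene`, `n_lamp1`, `n_fuca1`, `fraction_within`, `mean_center_um`,
#'   `zero_source`); pooled aggregates (per-object pooling across scenes)
#'   in `attr(, "pooled")`, per-scene `proximity_summary` objects in
#'   `attr(, "summaries")`, and the configuration in `attr(, "config")`.
#' @export
run_proximity <- function(scenes, config = proximity_config()) {
  if (!is.null(scenes$lamp1)) scenes <- list(scenes)
  summaries <- purrr::imap(scenes, function(scene, i) {
    lamp_obj <- segment_channel(scene$lamp1, config)
    fuca_obj <- segment_channel(scene$fuca1, config)
    if (nrow(fuca_obj) == 0 || nrow(lamp_obj) == 0) {
      return(structure(
        list(per_object = tibble(), fraction_within = NA_real_,
             mean_center_um = NA_real_, radius_um = config$radius_um,
             n_source = nrow(fuca_obj), n_target = nrow(lamp_obj)),
        class = "proximity_summary"
      ))
    }
    nearest_distances(fuca_obj, lamp_obj, radius_um = config$radius_um)
  })

  per_scene <- purrr::imap(summaries, function(s, i) {
    tibble(
      scene = if (is.character(i)) i else as.integer(i),
      n_lamp1 = s$n_target,
      n_fuca1 = s$n_source,
      fraction_within = s$fraction_within,
      mean_center_um = s$mean_center_um,
      zero_source = s$n_source == 0
    )
  }) %>% bind_rows()

  all_objects <- purrr::map(summaries, "per_object") %>% bind_rows()
  pooled <- if (nrow(all_objects) > 0) {
    tibble(
      fraction_within = mean(all_objects$edge_to_edge_um <= config$radius_um),
      mean_center_um = mean(all_objects$center_to_center_um),
      n_objects = nrow(all_objects),
      n_scenes = length(summaries)
    )
  } else {
    tibble(fraction_within = NA_real_, mean_center_um = NA_real_,
           n_objects = 0L, n_scenes = length(summaries))
  }

  structure(per_scene, pooled = pooled, summaries = summaries,
            config = config,
            class = c("proximity_report", class(per_scene)))
}

#' Plot the edge-to-edge distance distribution of a proximity analysis
#'
#' @param object A `proximity_report` (from [run_proximity()]) or
#'   `proximity_summary`.
#' @param binwidth_um Histogram bin width (µm).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proximity_report <- function(object, binwidth_um = 0.05, ...) {
  per <- purrr::map(attr(object, "summaries"), "per_object") %>% bind_rows()
  radius <- attr(object, "config")$radius_um
  ggplot2::ggplot(per, ggplot2::aes(x = .data$edge_to_edge_um)) +
    ggplot2::geom_histogram(binwidth = binwidth_um, boundary = 0,
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = radius, linetype = 2) +
    ggplot2::labs(x = "Edge-to-edge distance to nearest lysosome (µm)",
                  y = "Puncta") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.proximity_report
#' @export
autoplot.proximity_summary <- function(object, binwidth_um = 0.05, ...) {
  ggplot2::ggplot(object$per_object,
                  ggplot2::aes(x = .data$edge_to_edge_um)) +
    ggplot2::geom_histogram(binwidth = binwidth_um, boundary = 0,
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$radius_um, linetype = 2) +
    ggplot2::labs(x = "Edge-to-edge distance to nearest lysosome (µm)",
                  y = "Puncta") +
    ggplot2::theme_minimal()
}
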