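# Shared fixtures, built in code.

# Minimal event table with explicit values.
events_tbl <- function(fsc, ssc, gfp, rfp) {
  tibble::tibble(FSC = fsc, SSC = ssc, GFP = gfp, RFP = rfp)
}

# A noise-free reporter model for exact identities.
noise_free_model <- function(theta, ...) {
  reporter_cell_model(
    theta = theta,
    autofluor_rfp_mean = 0, autofluor_gfp_mean = 0, autofluor_sd = 0,
    debris_fraction = 0, noise_cv = 0, transfected_fraction = 1,
    ...
  )
}

# A small scene spec that renders and segments quickly.
small_scene_spec <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(128, 128), n_lamp1 = 8, n_fuca1 = 20),
    list(...)
  )
  do.call(image_scene_spec, args)
}

# Segmentation config with a saturation suited to tiny sparse fixtures.
fixture_config <- function(...) {
  proximity_config(saturated_percent = 0.05, ...)
}

# Brute-force nearest distances: full O(n^2) scan over all object pairs and
# all boundary-pixel pairs, no pruning. Independent oracle for
# nearest_distances().
brute_force_distances <- function(source, target) {
  purrr::map_dfr(seq_len(nrow(source)), function(i) {
    d_center <- sqrt((source$x_um[i] - target$x_um)^2 +
                       (source$y_um[i] - target$y_um)^2)
    edge <- vapply(seq_len(nrow(target)), function(j) {
      key <- function(px) px[, 1] * 1e7 + px[, 2]
      if (length(intersect(key(source$pixels[[i]]),
                           key(target$pixels[[j]]))) > 0) {
        return(0)
      }
      a <- source$boundary_um[[i]]
      b <- target$boundary_um[[j]]
      min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
    }, numeric(1))
    tibble::tibble(
      label = source$label[i],
      center_to_center_um = min(d_center),
      edge_to_edge_um = min(edge)
    )
  })
}
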