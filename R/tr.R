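# Translational-readthrough statistic on gated dual-reporter event tables.

ratio_estimate <- function(events, estimator, background = NULL) {
  gfp <- events$GFP
  rfp <- events$RFP
  corrected <- FALSE
  if (!is.null(background)) {
    check_events(background, c("GFP", "RFP"))
    if (nrow(background) == 0) {
      abort("Background event table is empty.")
    }
    gfp <- pmax(gfp - median(background$GFP), 0)
    rfp <- pmax(rfp - median(background$RFP), 0)
    corrected <- TRUE
  }
  value <- switch(estimator,
    "ratio-of-means" = mean(gfp) / mean(rfp),
    "median-of-ratios" = {
      ok <- rfp > 0
      if (!any(ok)) abort("No events with positive RFP for per-cell ratios.")
      median(gfp[ok] / rfp[ok])
    }
  )
  list(value = value, corrected = corrected)
}

#' Translational-readthrough statistic normalized to a 100% control
#'
#' Computes the GFP/RFP signal ratio of a gated sample, normalized to the
#' GFP/RFP ratio of a gated 100% readthrough control (an RFP-GFP fusion
#' without a separating stop codon), expressed as a percentage. The default
#' estimator is the ratio of channel means over included events, which stays
#' well defined when per-cell GFP is near zero; `"median-of-ratios"` uses the
#' median of per-cell GFP/RFP instead. Optional background correction
#' subtracts the per-channel medians of an untransfected sample before
#' forming ratios, flooring at zero.
#'
#' @param sample,control Gated event tables (see [gate_events()]); the
#'   control must be nonempty.
#' @param estimator `"ratio-of-means"` (default) or `"median-of-ratios"`.
#' @param background Optional untransfected event table used for median
#'   background subtraction (off by default).
#' @return An object of class `tr_result` with fields `tr_percent`,
#'   `sample_ratio`, `control_ratio`, `estimator`, `background_corrected`,
#'   and the sample's gate counts `n_total`, `n_scatter_gated`,
#'   `n_included` (NA when the input was not produced by [gate_events()]).
#' @export
#' @examples
#' ctl <- gate_events(simulate_flow_sample(reporter_cell_model(theta = 1),
#'                                         5000, seed = 1))
#' tr_statistic(ctl, ctl)$tr_percent  # exactly 100
tr_statistic <- function(sample, control,
                         estimator = c("ratio-of-means", "median-of-ratios"),
                         background = NULL) {
  estimator <- match.arg(estimator)
  check_events(sample, c("GFP", "RFP"))
  check_events(control, c("GFP", "RFP"))
  if (nrow(sample) == 0) {
    abort("Gated sample is empty; the GFP/RFP ratio is undefined.")
  }
  if (nrow(control) == 0) {
    abort("Gated control is empty; normalization is undefined.")
  }
  rs <- ratio_estimate(sample, estimator, background)
  rc <- ratio_estimate(control, estimator, background)
  if (!is.finite(rc$value) || rc$value <= 0) {
    abort("Control GFP/RFP ratio is zero or undefined; cannot normalize.")
  }

  counts <- function(tbl, field) attr(tbl, field) %||% NA_integer_
  structure(
    list(
      tr_percent = 100 * rs$value / rc$value,
      sample_ratio = rs$value,
      control_ratio = rc$value,
      estimator = estimator,
      background_corrected = rs$corrected,
      n_total = counts(sample, "n_total"),
      n_scatter_gated = counts(sample, "n_scatter_gated"),
      n_included = nrow(sample)
    ),
    class = "tr_result"
  )
}

#' @export
print.tr_result <- function(x, ...) {
  cat(sprintf("<tr_result> TR = %.4g%% (%s%s)\n", x$tr_percent, x$estimator,
              if (x$background_corrected) ", background-corrected" else ""))
  cat(sprintf("  sample ratio %.4g / control ratio %.4g; %s events included\n",
              x$sample_ratio, x$control_ratio, format(x$n_included)))
  invisible(x)
}

#' @rdname tr_statistic
#' @param x A `tr_result`.
#' @param ... Unused.
#' @export
tidy.tr_result <- function(x, ...) {
  tibble(
    tr_percent = x$tr_percent,
    sample_ratio = x$sample_ratio,
    control_ratio = x$control_ratio,
    estimator = x$estimator,
    background_corrected = x$background_corrected,
    n_total = x$n_total,
    n_scatter_gated = x$n_scatter_gated,
    n_included = x$n_included
  )
}

#' @rdname tr_statistic
#' @export
glance.tr_result <- function(x, ...) {
  tibble(tr_percent = x$tr_percent, estimator = x$estimator,
         n_included = x$n_included)
}

#' Summarize readthrough replicates per condition
#'
#' Reports mean, sample standard deviation (n - 1 denominator) and replicate
#' count per condition. A single replicate yields `NA` for the standard
#' deviation.
#'
#' @param results A data frame with a `tr_percent` column (e.g. row-bound
#'   [tidy()] outputs), or a list of `tr_result` objects.
#' @param grouping Column name(s) in `results` defining conditions, or (for
#'   a list input) a vector of condition labels, one per result.
#' @return A tibble with one row per condition: grouping columns,
#'   `mean_tr_percent`, `sd_tr_percent`, `n`.
#' @export
summarize_replicates <- function(results, grouping = "condition") {
  if (is.data.frame(results)) {
    if (!all(grouping %in% names(results))) {
      abort(sprintf("Grouping column(s) not found: %s.",
                    paste(setdiff(grouping, names(results)), collapse = ", ")))
    }
    df <- results
  } else if (is.list(results)) {
    if (length(results) == 0) abort("No results to summarize.")
    if (length(grouping) != length(results)) {
      abort("For list input, `grouping` must give one label per result.")
    }
    df <- purrr::map2(results, grouping, function(r, g) {
      tibble(condition = g, tr_percent = r$tr_percent)
    }) %>% bind_rows()
    grouping <- "condition"
  } else {
    abort("`results` must be a data frame or a list of tr_result objects.")
  }
  if (nrow(df) == 0) abort("No results to summarize.")
  df %>%
    group_by(across(all_of(grouping))) %>%
    summarise(
      mean_tr_percent = mean(.data$tr_percent),
      sd_tr_percent = if (n() > 1) sd(.data$tr_percent) else NA_real_,
      n = n(),
      .groups = "drop"
    )
}

#' Quantify readthrough across a plate of FCS files
#'
#' Applies the scatter and fluorescence gates to every well of a plate and
#' computes the readthrough statistic of each data well against the plate's
#' own 100% fusion control.
#'
#' @param layout Data frame with columns `well`, `file`, `condition`, `role`;
#'   `role` is `"sample"`, `"control"` (exactly one; the theta = 1 fusion
#'   control) or `"untransfected"` (optional; used for background correction
#'   when `background_correct = TRUE`).
#' @param fcs_dir Directory containing the FCS files named in `layout$file`.
#' @param config A [gating_config()].
#' @param estimator Passed to [tr_statistic()].
#' @param background_correct Subtract untransfected-well channel medians
#'   before forming ratios (requires an `"untransfected"` role).
#' @param channel_names Channel-name map passed to [read_fcs()].
#' @param min_events Wells with fewer included events are flagged
#'   `low_quality` (not dropped).
#' @param out_dir Optional directory; when given, a per-well CSV
#'   (`tr_report.csv`), a condition summary CSV (`tr_summary.csv`) and a JSON
#'   provenance report (`tr_report.json`, gates, estimator, file hashes) are
#'   written there.
#' @return A tibble with one row per well (gate counts, ratios,
#'   `tr_percent`, `low_quality`), of class `tr_plate`; the condition summary
#'   is in `attr(, "summary")` and the provenance list in
#'   `attr(, "provenance")`.
#' @export
run_plate <- function(layout, fcs_dir,
                      config = gating_config(),
                      estimator = "ratio-of-means",
                      background_correct = FALSE,
                      channel_names = default_channel_names(),
                      min_events = 100,
                      out_dir = NULL) {
  required <- c("well", "file", "condition", "role")
  if (!is.data.frame(layout) || !all(required %in% names(layout))) {
    abort("`layout` must have columns well, file, condition, role.")
  }
  if (sum(layout$role == "control") != 1) {
    abort("Plate layout must name exactly one well with role 'control'.")
  }
  paths <- file.path(fcs_dir, layout$file)
  missing_files <- layout$file[!file.exists(paths)]
  if (length(missing_files) > 0) {
    abort(sprintf("Missing FCS file(s) for mapped wells: %s.",
                  paste(missing_files, collapse = ", ")))
  }

  gated <- purrr::map(paths, function(p) {
    gate_events(read_fcs(p, channel_names = channel_names), config)
  })
  names(gated) <- layout$well

  control <- gated[[which(layout$role == "control")]]
  if (nrow(control) == 0) {
    abort("Control well has no events after gating.")
  }
  background <- NULL
  if (background_correct) {
    i_bg <- which(layout$role == "untransfected")
    if (length(i_bg) != 1) {
      abort("Background correction needs exactly one 'untransfected' well.")
    }
    background <- gated[[i_bg]]
  }

  rows <- purrr::imap(gated, function(ev, well) {
    i <- match(well, layout$well)
    role <- layout$role[i]
    if (role == "untransfected") {
      # the autofluorescence control carries no reporter; no TR is defined
      row <- tibble(
        tr_percent = NA_real_, sample_ratio = NA_real_,
        control_ratio = NA_real_, estimator = estimator,
        background_corrected = !is.null(background),
        n_total = attr(ev, "n_total") %||% NA_integer_,
        n_scatter_gated = attr(ev, "n_scatter_gated") %||% NA_integer_,
        n_included = nrow(ev)
      )
    } else {
      res <- tr_statistic(ev, control, estimator = estimator,
                          background = background)
      row <- tidy(res)
    }
    row %>%
      mutate(well = well, condition = layout$condition[i],
             role = role, file = layout$file[i],
             low_quality = .data$n_included < min_events,
             .before = 1)
  })
  report <- bind_rows(rows)

  summary_tbl <- report %>%
    filter(.data$role != "untransfected") %>%
    summarize_replicates(grouping = "condition")

  provenance <- list(
    gates = unclass(config),
    estimator = estimator,
    background_correct = background_correct,
    channel_names = as.list(channel_names),
    min_events = min_events,
    file_md5 = as.list(tools::md5sum(paths)),
    package_version = as.character(utils::packageVersion("ptcrescue"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "tr_report.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tbl, file.path(out_dir, "tr_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(report = report, summary = summary_tbl, provenance = provenance),
      file.path(out_dir, "tr_report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  structure(report, summary = summary_tbl, provenance = provenance,
            class = c("tr_plate", class(report)))
}

#' Plot a readthrough condition summary
#'
#' Replicate points with the condition mean and one standard deviation,
#' mirroring the usual presentation of dual-reporter readthrough data.
#'
#' @param object A tibble with `condition` and `tr_percent` columns (e.g. a
#'   [run_plate()] result or row-bound [tidy()] outputs).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tr_plate <- function(object, ...) {
  plot_tr_summary(object)
}

#' @rdname autoplot.tr_plate
#' @export
plot_tr_summary <- function(object, ...) {
  df <- as_tibble(object)
  summ <- summarize_replicates(df, grouping = "condition")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$tr_percent)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(
        y = .data$mean_tr_percent,
        ymin = .data$mean_tr_percent -
          ifelse(is.na(.data$sd_tr_percent), 0, .data$sd_tr_percent),
        ymax = .data$mean_tr_percent +
          ifelse(is.na(.data$sd_tr_percent), 0, .data$sd_tr_percent)
      ),
      shape = 95, size = 1
    ) +
    ggplot2::labs(x = NULL, y = "Translational readthrough (%)") +
    ggplot2::theme_minimal()
}
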