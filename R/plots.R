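#' Plot time-resolved flow curves
#'
#' @param ... Flow-curve tibbles (as returned by [flow_curve()],
#'   [average_rois()] or [analytic_flow_curve()]); they are overlaid and
#'   colored by `roi_label`.
#' @return A ggplot object.
#' @export
plot_flow_curves <- function(...) {
  curves <- dplyr::bind_rows(list(...))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time_ms, y = .data$flow_ml_s,
                               colour = .data$roi_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "flow (mL/s)", colour = NULL)
}

#' @describeIn velocity_magnitude Histogram of the velocity-magnitude
#'   distribution in the ROI.
#' @param object A `velocity_histogram`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.velocity_histogram <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$bin_hi[1] - h$bin_lo[1]) +
    ggplot2::geom_vline(xintercept = object$median_cm_s,
                        linetype = "dashed") +
    ggplot2::labs(x = "velocity magnitude (cm/s)", y = "voxel count")
}

#' Plot flow error against voxels per diameter
#'
#' Visualizes the resolution error law: median percentage flow difference
#' (or RMS) against nROI, one point per tube/resolution combination.
#'
#' @param battery A [partial_volume_battery()] or [run_battery()] tibble.
#' @param metric `"median_diff_pct"` (default) or `"rms"`.
#' @return A ggplot object.
#' @export
plot_nroi_error <- function(battery, metric = c("median_diff_pct", "rms")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(battery,
                  ggplot2::aes(x = .data$n_roi, y = .data[[metric]],
                               colour = factor(.data$tube_id_mm))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "voxels per diameter (nROI)",
                  y = if (metric == "rms") "normalized RMS"
                      else "median flow difference (%)",
                  colour = "tube ID (mm)")
}
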