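#' Time-resolved percentage flow difference
#'
#' \eqn{\mathrm{difference}(t) = (f_{test}(t) - f_{ref}(t)) /
#' \overline{f_{ref}} \times 100\%}, the test-vs-reference flow discrepancy
#' normalized by the time-mean reference flow. The median over time is the
#' study's summary statistic.
#'
#' @param test,ref Flow-curve tibbles on a common time grid.
#' @return A tibble `time_ms`, `diff_pct` with the median over time attached
#'   as `attr(, "median_pct")`.
#' @export
flow_difference <- function(test, ref) {
  check_common_grid(test, ref)
  mref <- mean(ref$flow_ml_s)
  if (mref == 0) stop("Reference curve has zero time-mean flow.")
  out <- tibble::tibble(
    time_ms = test$time_ms,
    diff_pct = (test$flow_ml_s - ref$flow_ml_s) / mref * 100)
  attr(out, "median_pct") <- median(out$diff_pct)
  out
}

#' Median-over-time percentage flow difference
#' @inheritParams flow_difference
#' @return Scalar, %.
#' @export
median_flow_difference <- function(test, ref) {
  attr(flow_difference(test, ref), "median_pct")
}

check_common_grid <- function(test, ref) {
  stopifnot(is.data.frame(test), is.data.frame(ref))
  if (nrow(test) != nrow(ref) ||
      max(abs(test$time_ms - ref$time_ms)) > 1e-9) {
    stop("Curves are not on a common time grid.")
  }
  invisible(TRUE)
}

#' Normalized root-mean-square flow error
#'
#' \eqn{\mathrm{RMS} = \sqrt{\sum_t (f_{test} - f_{ref})^2 / N} \,/\,
#' \overline{f_{ref}}}: the RMS of the time-resolved flow difference
#' normalized by the time-mean reference flow (dimensionless).
#'
#' @inheritParams flow_difference
#' @return Non-negative scalar.
#' @export
normalized_rms <- function(test, ref) {
  check_common_grid(test, ref)
  mref <- mean(ref$flow_ml_s)
  if (mref == 0) stop("Reference curve has zero time-mean flow.")
  sqrt(mean((test$flow_ml_s - ref$flow_ml_s)^2)) / mref
}

#' Voxels per vessel (ROI) diameter
#'
#' \eqn{n_{ROI} = D / \Delta x}: the resolution-normalized predictor of flow
#' error. The study reports integer values for the aneurysm dimensions.
#'
#' @param diameter_mm ROI or vessel diameter, mm.
#' @param voxel_size_mm 1D (isotropic) voxel size, mm.
#' @param rounded Round to the nearest integer for reporting (default
#'   FALSE).
#' @return Scalar (or integer if `rounded`).
#' @export
n_roi <- function(diameter_mm, voxel_size_mm, rounded = FALSE) {
  if (any(diameter_mm <= 0) || any(voxel_size_mm <= 0)) {
    stop("Diameter and voxel size must be positive.")
  }
  r <- diameter_mm / voxel_size_mm
  if (rounded) round(r) else r
}

#' Approximate boundary-voxel count of a circular lumen
#'
#' \eqn{N_{boundary} \approx \pi D / \Delta x}: the number of voxels cut by
#' the lumen perimeter, the voxels that dominate partial-volume flow error.
#'
#' @inheritParams n_roi
#' @return Scalar.
#' @export
boundary_voxel_count <- function(diameter_mm, voxel_size_mm) {
  if (any(diameter_mm <= 0) || any(voxel_size_mm <= 0)) {
    stop("Diameter and voxel size must be positive.")
  }
  pi * diameter_mm / voxel_size_mm
}

#' Reynolds number
#'
#' \eqn{Re = u \, ID \, \rho / \mu} with unit handling: velocity in cm/s,
#' diameter in cm, density in kg/m^3, dynamic viscosity in cP.
#'
#' @param u_cm_s Mean velocity, cm/s.
#' @param id_cm Inner diameter, cm.
#' @param rho_kg_m3 Fluid density (default 997, water).
#' @param mu_cp Dynamic viscosity in centipoise (default 0.890, water).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(u_cm_s, id_cm, rho_kg_m3 = 997, mu_cp = 0.890) {
  if (any(c(u_cm_s, id_cm, rho_kg_m3, mu_cp) <= 0)) {
    stop("All Reynolds-number inputs must be positive.")
  }
  (u_cm_s / 100) * (id_cm / 100) * rho_kg_m3 / (mu_cp * 1e-3)
}

#' One-row flow comparison summary
#'
#' Bundles the study's per-dataset comparison: median percentage flow
#' difference, normalized RMS and (optionally) nROI.
#'
#' @inheritParams flow_difference
#' @param diameter_mm,voxel_size_mm Optional; when both given, `n_roi` is
#'   included.
#' @return One-row tibble: `test_label`, `ref_label`, `median_diff_pct`,
#'   `rms`, `n_roi`.
#' @export
flow_comparison <- function(test, ref, diameter_mm = NULL,
                            voxel_size_mm = NULL) {
  nroi <- if (!is.null(diameter_mm) && !is.null(voxel_size_mm)) {
    n_roi(diameter_mm, voxel_size_mm)
  } else {
    NA_real_
  }
  tibble::tibble(
    test_label = test$roi_label[1], ref_label = ref$roi_label[1],
    median_diff_pct = median_flow_difference(test, ref),
    rms = normalized_rms(test, ref),
    n_roi = nroi)
}

#' Time-averaged velocity-magnitude map and histogram
#'
#' Per voxel, the time mean of \eqn{\sqrt{v_x^2 + v_y^2 + v_z^2}}; over a 3D
#' ROI, the histogram and median of that map (the study's aneurysm-sac
#' summary).
#'
#' @param ds A [velocity_dataset()] with all three components.
#' @param roi Optional logical array `[x, y, z]` restricting the histogram;
#'   default: all voxels.
#' @param bins Histogram bin count (default 40).
#' @param v_max_cm_s Upper histogram edge; default 1.2 x venc.
#' @return A `velocity_histogram`: list with `map` (`[x,y,z]`, cm/s),
#'   `histogram` (tibble `bin_lo`, `bin_hi`, `count`), `median_cm_s`, `roi`.
#' @export
velocity_magnitude <- function(ds, roi = NULL, bins = 40,
                               v_max_cm_s = NULL) {
  stopifnot(inherits(ds, "velocity_dataset"))
  if (!all(c("x", "y", "z") %in% names(ds$velocity))) {
    stop("Velocity magnitude needs all three encoded components.")
  }
  d <- dim(ds$magnitude)
  sp2 <- ds$velocity$x^2 + ds$velocity$y^2 + ds$velocity$z^2
  sp <- sqrt(sp2)
  map <- array(rowMeans(matrix(sp, prod(d[1:3]), d[4])), dim = d[1:3])
  if (is.null(roi)) roi <- array(TRUE, dim = d[1:3])
  stopifnot(identical(dim(roi), d[1:3]))
  vals <- map[roi]
  if (is.null(v_max_cm_s)) v_max_cm_s <- 1.2 * ds$venc_cm_s
  edges <- seq(0, v_max_cm_s, length.out = bins + 1)
  cuts <- cut(pmin(vals, v_max_cm_s), breaks = edges, include.lowest = TRUE)
  hist_tbl <- tibble::tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    count = as.integer(table(cuts)))
  structure(list(map = map, histogram = hist_tbl,
                 median_cm_s = median(vals), roi = roi),
            class = "velocity_histogram")
}

#' @export
print.velocity_histogram <- function(x, ...) {
  cat(sprintf("<velocity_histogram> median %.3g cm/s over %d voxels\n",
              x$median_cm_s, sum(x$roi)))
  invisible(x)
}

#' Repeatability coefficient of repeated flow measurements
#'
#' Per time point, \eqn{RC(t) = 1.96 \sqrt{2 \, SD(t)^2} / f_{mean}(t)
#' \times 100\%} with SD the (n-1) sample standard deviation across repeats;
#' the time-averaged RC summarizes test-retest variation.
#'
#' @param repeats List of >= 2 flow-curve tibbles on a common time grid.
#' @return Scalar time-averaged RC in %.
#' @seealso [repeatability_curve()] for the per-time-point series.
#' @export
repeatability_coefficient <- function(repeats) {
  mean(repeatability_curve(repeats)$rc_pct)
}

#' Per-time-point repeatability coefficient
#' @inheritParams repeatability_coefficient
#' @return Tibble `time_ms`, `rc_pct`.
#' @export
repeatability_curve <- function(repeats) {
  stopifnot(is.list(repeats), length(repeats) >= 2)
  t0 <- repeats[[1]]$time_ms
  F <- vapply(repeats, function(cv) {
    check_common_grid(cv, repeats[[1]])
    cv$flow_ml_s
  }, numeric(length(t0)))
  m <- rowMeans(F)
  if (any(m == 0)) stop("Mean flow is zero at some time point.")
  s <- apply(F, 1, sd)
  tibble::tibble(time_ms = t0, rc_pct = 1.96 * sqrt(2 * s^2) / m * 100)
}
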