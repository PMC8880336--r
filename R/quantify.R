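#' Static-tissue background mask from magnitude
#'
#' Pixels whose time-averaged magnitude stays below a fraction of the robust
#' (99th percentile) magnitude across every slice are classified as static
#' background, suitable for fitting the eddy-current offset plane.
#'
#' @param ds A [velocity_dataset()].
#' @param fraction Magnitude fraction separating background from lumen
#'   (default 0.5).
#' @return Logical in-plane matrix `[x, y]`.
#' @export
static_background_mask <- function(ds, fraction = 0.5) {
  stopifnot(inherits(ds, "velocity_dataset"))
  d <- dim(ds$magnitude)
  tavg <- array(rowMeans(matrix(ds$magnitude, prod(d[1:3]), d[4])),
                dim = d[1:3])
  ref <- quantile(tavg, 0.99, names = FALSE)
  static <- tavg < fraction * ref
  apply(static, c(1, 2), all)
}

#' Correct eddy-current background phase
#'
#' Fits, per slice and velocity component, a least-squares plane
#' \eqn{a + b x + c y} to the velocity of static-background pixels at the
#' reference cardiac phase (the peak-flow phase by default) and subtracts it
#' from all phases of that slice. This removes the spatially linear velocity
#' offset that residual eddy currents superimpose on phase-contrast data.
#'
#' @param ds A [velocity_dataset()].
#' @param static_mask Logical in-plane matrix of static pixels (>= 10
#'   pixels); default [static_background_mask()].
#' @param reference_phase Index of the phase the fit is computed at; default
#'   the phase maximizing the preliminary lumen speed (peak flow).
#' @return The corrected dataset; the fitted coefficients are attached as
#'   `attr(, "background_fit")` (tibble: slice, component, a, b, c).
#' @export
correct_background_phase <- function(ds, static_mask = NULL,
                                     reference_phase = NULL) {
  stopifnot(inherits(ds, "velocity_dataset"))
  if (is.null(static_mask)) static_mask <- static_background_mask(ds)
  d <- dim(ds$magnitude)
  stopifnot(identical(dim(static_mask), d[1:2]))
  if (sum(static_mask) < 10) {
    stop("Static mask must contain at least 10 pixels.")
  }
  if (is.null(reference_phase)) {
    speed <- Reduce(`+`, lapply(ds$velocity, abs))
    per_phase <- colSums(matrix(speed, prod(d[1:3]), d[4]))
    reference_phase <- which.max(per_phase)
  }
  gc <- grid_coords(ds)
  idx <- which(static_mask, arr.ind = TRUE)
  X <- cbind(1, gc$x[idx[, 1]], gc$y[idx[, 2]])
  if (qr(X)$rank < 3) {
    stop("Static pixels are collinear; the offset plane is not identifiable.")
  }
  plane_x <- outer(gc$x, rep(1, d[2]))
  plane_y <- outer(rep(1, d[1]), gc$y)

  fits <- list()
  for (nm in names(ds$velocity)) {
    for (k in seq_len(d[3])) {
      vref <- ds$velocity[[nm]][, , k, reference_phase][static_mask]
      beta <- qr.solve(X, vref)
      plane <- beta[1] + beta[2] * plane_x + beta[3] * plane_y
      ds$velocity[[nm]][, , k, ] <-
        ds$velocity[[nm]][, , k, ] - as.vector(plane)
      fits[[length(fits) + 1]] <- tibble::tibble(
        slice = k, component = nm,
        a = beta[1], b = beta[2], c = beta[3])
    }
  }
  attr(ds, "background_fit") <- dplyr::bind_rows(fits)
  ds$provenance$background_corrected <- list(reference_phase = reference_phase)
  ds
}

#' Null velocities outside the flow lumen
#'
#' Thresholds the time-averaged magnitude at `threshold_fraction` of the
#' robust lumen magnitude (its 99th percentile) and zeroes the velocity of
#' sub-threshold voxels at all phases. Magnitude is untouched. Boundary
#' voxels whose mixed signal stays above the threshold are retained -- these
#' are the voxels that drive the partial-volume flow bias.
#'
#' @param ds A [velocity_dataset()].
#' @param threshold_fraction In (0, 1); default 0.5.
#' @return Dataset with `$lumen_mask` (logical `[x, y, z]`) set.
#' @export
mask_lumen <- function(ds, threshold_fraction = 0.5) {
  stopifnot(inherits(ds, "velocity_dataset"))
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("`threshold_fraction` must be in (0, 1).")
  }
  d <- dim(ds$magnitude)
  tavg <- array(rowMeans(matrix(ds$magnitude, prod(d[1:3]), d[4])),
                dim = d[1:3])
  ref <- quantile(tavg, 0.99, names = FALSE)
  lum <- tavg >= threshold_fraction * ref
  if (!any(lum)) stop("Lumen is empty after magnitude thresholding.")
  keep <- as.vector(lum)
  for (nm in names(ds$velocity)) {
    v <- matrix(ds$velocity[[nm]], prod(d[1:3]), d[4])
    v[!keep, ] <- 0
    ds$velocity[[nm]] <- array(v, dim = d)
  }
  ds$lumen_mask <- lum
  ds$provenance$lumen_threshold <- threshold_fraction
  ds
}

# 3x3 in-plane median with replicated edges
median_filter_3x3 <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  Mp <- M[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  stackd <- array(0, dim = c(nr, nc, 9))
  k <- 0
  for (dj in 0:2) {
    for (di in 0:2) {
      k <- k + 1
      stackd[, , k] <- Mp[di + seq_len(nr), dj + seq_len(nc)]
    }
  }
  apply(stackd, c(1, 2), median)
}

#' Correct velocity aliasing (phase wraps)
#'
#' Voxels whose velocity differs from the median of their 3 x 3 in-plane
#' neighborhood by more than the venc are shifted by the multiple of
#' \eqn{2 \cdot \mathrm{venc}} that minimizes the difference. Already
#' consistent data pass through unchanged, and the operation is idempotent.
#' Double wraps (true speed beyond 3 venc) are not guaranteed to be
#' recovered; any residual outliers are flagged in
#' `attr(, "unwrap_report")`.
#'
#' @param ds A [velocity_dataset()].
#' @return Corrected dataset with an `unwrap_report` attribute (tibble:
#'   component, corrected voxel count, residual outlier count).
#' @export
unwrap_aliasing <- function(ds) {
  stopifnot(inherits(ds, "velocity_dataset"))
  d <- dim(ds$magnitude)
  venc <- ds$venc_cm_s
  report <- list()
  for (nm in names(ds$velocity)) {
    n_fix <- 0L
    n_res <- 0L
    for (it in seq_len(d[4])) {
      for (k in seq_len(d[3])) {
        M <- ds$velocity[[nm]][, , k, it]
        med <- median_filter_3x3(M)
        cand <- abs(M - med) > venc
        if (any(cand)) {
          shift <- 2 * venc * round((med - M) / (2 * venc))
          M[cand] <- M[cand] + shift[cand]
          n_fix <- n_fix + sum(cand)
          n_res <- n_res + sum(abs(M[cand] - med[cand]) > venc)
          ds$velocity[[nm]][, , k, it] <- M
        }
      }
    }
    report[[nm]] <- tibble::tibble(component = nm, corrected = n_fix,
                                   residual_outliers = n_res)
  }
  attr(ds, "unwrap_report") <- dplyr::bind_rows(report)
  ds
}

#' Circular ROI contour
#'
#' @param center_mm Length-2 in-plane center (mm, world coordinates).
#' @param radius_mm Radius in mm (> 0).
#' @param plane Slice index the ROI lives on.
#' @param label ROI label (the study uses stations A, B, C).
#' @return An `roi_contour` object.
#' @export
roi_circle <- function(center_mm, radius_mm, plane = 1L, label = "custom") {
  if (radius_mm <= 0) stop("`radius_mm` must be positive.")
  structure(list(type = "circle", center_mm = center_mm,
                 radius_mm = radius_mm, plane = plane, label = label),
            class = "roi_contour")
}

#' Closed-spline ROI contour
#'
#' Control points are interpolated by a periodic cubic spline evaluated at
#' >= 64 points per segment, emulating hand-drawn b-spline lumen contours.
#'
#' @param points_mm K x 2 matrix of control points (mm), in drawing order,
#'   not repeated at the end.
#' @inheritParams roi_circle
#' @return An `roi_contour` object.
#' @export
roi_spline <- function(points_mm, plane = 1L, label = "custom") {
  points_mm <- as.matrix(points_mm)
  if (nrow(points_mm) < 3 || ncol(points_mm) != 2) {
    stop("`points_mm` must be a K x 2 matrix with K >= 3.")
  }
  structure(list(type = "spline", points_mm = points_mm,
                 plane = plane, label = label),
            class = "roi_contour")
}

contour_polygon <- function(contour, n_per_segment = 64) {
  if (contour$type == "circle") {
    th <- seq(0, 2 * pi, length.out = 256 + 1)[-1]
    cbind(contour$center_mm[1] + contour$radius_mm * cos(th),
          contour$center_mm[2] + contour$radius_mm * sin(th))
  } else {
    K <- nrow(contour$points_mm)
    tt <- seq(0, K, length.out = n_per_segment * K + 1)
    px <- spline(0:K, c(contour$points_mm[, 1], contour$points_mm[1, 1]),
                 method = "periodic", xout = tt)$y
    py <- spline(0:K, c(contour$points_mm[, 2], contour$points_mm[1, 2]),
                 method = "periodic", xout = tt)$y
    cbind(px, py)[-1, ]
  }
}

#' Rasterize an ROI contour onto a dataset's pixel grid
#'
#' A pixel belongs to the ROI iff its center lies inside the contour; points
#' on the contour count as inside. This deterministic pixel-center rule (no
#' partial-pixel weighting) matches common ROI tools.
#'
#' @param contour An [roi_circle()] or [roi_spline()].
#' @param ds A [velocity_dataset()] supplying the grid, or any list with
#'   elements `spacing_mm`, `origin_mm` and a `magnitude` array.
#' @return An `roi_mask`: logical pixel matrix, pixel area (mm^2), plane and
#'   label.
#' @export
rasterize_roi <- function(contour, ds) {
  stopifnot(inherits(contour, "roi_contour"))
  gc <- grid_coords(ds)
  poly <- contour_polygon(contour)
  if (min(poly[, 1]) < min(gc$x) - ds$spacing_mm / 2 ||
      max(poly[, 1]) > max(gc$x) + ds$spacing_mm / 2 ||
      min(poly[, 2]) < min(gc$y) - ds$spacing_mm / 2 ||
      max(poly[, 2]) > max(gc$y) + ds$spacing_mm / 2) {
    stop("Contour lies (partly) outside the pixel grid.")
  }
  nx <- length(gc$x); ny <- length(gc$y)
  if (contour$type == "circle") {
    dx <- outer(gc$x - contour$center_mm[1], rep(1, ny))
    dy <- outer(rep(1, nx), gc$y - contour$center_mm[2])
    pix <- sqrt(dx^2 + dy^2) <= contour$radius_mm + 1e-9
  } else {
    PX <- rep(gc$x, times = ny)
    PY <- rep(gc$y, each = nx)
    inside <- pracma::inpolygon(PX, PY, poly[, 1], poly[, 2],
                                boundary = TRUE)
    pix <- matrix(inside, nx, ny)
  }
  if (!any(pix)) stop("Rasterized ROI is empty.")
  structure(list(pixels = pix, pixel_area_mm2 = ds$spacing_mm^2,
                 plane = contour$plane, label = contour$label),
            class = "roi_mask")
}

#' Time-resolved flow through an ROI
#'
#' Sums, at each cardiac phase, the through-plane velocity of every ROI
#' pixel times the pixel area: \eqn{f(t) = \sum_i v_i(t) A_{pix}}, converted
#' to mL/s. The ROI plane must be perpendicular to the through-plane axis.
#'
#' @param ds A [velocity_dataset()].
#' @param mask An [rasterize_roi()] result.
#' @param component Through-plane velocity component; defaults to the only
#'   component present, else `"z"`.
#' @return A tibble with columns `time_ms`, `flow_ml_s`, `roi_label`.
#' @export
flow_curve <- function(ds, mask, component = NULL) {
  stopifnot(inherits(ds, "velocity_dataset"), inherits(mask, "roi_mask"))
  if (is.null(component)) {
    component <- if (length(ds$velocity) == 1) names(ds$velocity) else "z"
  }
  if (!component %in% names(ds$velocity)) {
    stop("Component `", component, "` is not present in the dataset.")
  }
  d <- dim(ds$magnitude)
  if (!any(mask$pixels)) stop("Empty ROI mask.")
  v <- ds$velocity[[component]][, , mask$plane, ]
  v <- matrix(v, d[1] * d[2], d[4])
  # cm/s * mm^2: x10 to mm/s, /1000 mm^3 -> mL
  f <- colSums(v[as.vector(mask$pixels), , drop = FALSE]) *
    mask$pixel_area_mm2 / 100
  tibble::tibble(time_ms = ds$times_ms, flow_ml_s = f,
                 roi_label = mask$label)
}

#' Average flow curves over ROIs
#'
#' Pointwise arithmetic mean of the flow of several ROI stations measured on
#' a common time grid (the study averages stations A, B and C).
#'
#' @param curves List of [flow_curve()] tibbles.
#' @param label Label of the averaged curve.
#' @return A flow-curve tibble.
#' @export
average_rois <- function(curves, label = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1)
  t0 <- curves[[1]]$time_ms
  for (cv in curves) {
    if (length(cv$time_ms) != length(t0) ||
        max(abs(cv$time_ms - t0)) > 1e-9) {
      stop("Flow curves are not on a common time grid.")
    }
  }
  if (is.null(label)) {
    label <- paste0("mean(",
                    paste(vapply(curves, function(cv) cv$roi_label[1],
                                 character(1)), collapse = ","), ")")
  }
  f <- rowMeans(vapply(curves, function(cv) cv$flow_ml_s,
                       numeric(length(t0))))
  tibble::tibble(time_ms = t0, flow_ml_s = f, roi_label = label)
}

#' Analytic reference flow curve of a phantom field
#'
#' @param field A `velocity_field`.
#' @param times_ms Sampling times; default the waveform's phase times.
#' @param label Curve label (default "analytic").
#' @return A flow-curve tibble.
#' @export
analytic_flow_curve <- function(field, times_ms = NULL, label = "analytic") {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(times_ms)) times_ms <- phase_times(field$waveform)
  tibble::tibble(time_ms = times_ms, flow_ml_s = field$flow(times_ms),
                 roi_label = label)
}
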