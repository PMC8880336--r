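#' Velocity dataset container
#'
#' Reconstructed phase-contrast data on a voxel grid: a magnitude volume and
#' one velocity volume per encoded direction, each indexed `[x, y, z, t]`,
#' with the acquisition metadata needed for quantification.
#'
#' @param magnitude Numeric array `[x, y, z, t]`, arbitrary units.
#' @param velocity Named list of arrays (subset of `x`, `y`, `z`), each the
#'   same shape as `magnitude`, in cm/s.
#' @param venc_cm_s Velocity-encoding value, cm/s.
#' @param spacing_mm Isotropic voxel size, mm.
#' @param period_ms Cardiac period, ms.
#' @param times_ms Phase times, ms (default uniform over the period).
#' @param origin_mm World coordinate (mm) of the center of voxel `[1,1,1]`.
#' @param provenance Free-form list echoing the generating configuration.
#' @return A `velocity_dataset` object.
#' @export
velocity_dataset <- function(magnitude, velocity, venc_cm_s, spacing_mm,
                             period_ms, times_ms = NULL,
                             origin_mm = NULL, provenance = list()) {
  stopifnot(is.array(magnitude), length(dim(magnitude)) == 4,
            is.list(velocity), length(velocity) >= 1,
            venc_cm_s > 0, spacing_mm > 0, period_ms > 0)
  if (is.null(names(velocity)) || !all(names(velocity) %in% c("x", "y", "z"))) {
    stop("`velocity` must be a named list with names among x, y, z.")
  }
  for (nm in names(velocity)) {
    if (!identical(dim(velocity[[nm]]), dim(magnitude))) {
      stop("Velocity component `", nm, "` shape differs from magnitude.")
    }
  }
  d <- dim(magnitude)
  if (is.null(times_ms)) times_ms <- period_ms * (seq_len(d[4]) - 1) / d[4]
  if (is.null(origin_mm)) {
    origin_mm <- -(d[1:3] - 1) / 2 * spacing_mm
  }
  structure(
    list(magnitude = magnitude, velocity = velocity,
         venc_cm_s = venc_cm_s, spacing_mm = spacing_mm,
         period_ms = period_ms, times_ms = times_ms,
         origin_mm = origin_mm, provenance = provenance),
    class = "velocity_dataset")
}

#' @export
print.velocity_dataset <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "<velocity_dataset> %d x %d x %d voxels (%g mm), %d phases, venc %g cm/s, components %s\n",
    d[1], d[2], d[3], x$spacing_mm, d[4], x$venc_cm_s,
    paste(names(x$velocity), collapse = "")))
  invisible(x)
}

#' Number of cardiac phases in a dataset
#' @param ds A `velocity_dataset`.
#' @return Integer count.
#' @export
n_phases <- function(ds) dim(ds$magnitude)[4]

# in-plane voxel-center coordinates (mm)
grid_coords <- function(ds) {
  d <- dim(ds$magnitude)
  list(x = ds$origin_mm[1] + (seq_len(d[1]) - 1) * ds$spacing_mm,
       y = ds$origin_mm[2] + (seq_len(d[2]) - 1) * ds$spacing_mm,
       z = ds$origin_mm[3] + (seq_len(d[3]) - 1) * ds$spacing_mm)
}

#' Write a velocity dataset as NIfTI volumes with a JSON sidecar
#'
#' Writes `<prefix>_mag.nii.gz`, one `<prefix>_v<d>.nii.gz` per velocity
#' component, and `<prefix>.json` holding `venc_cm_s`, `period_ms`,
#' `spacing_mm`, `times_ms`, `origin_mm`, the component list and the
#' provenance echo.
#'
#' @param ds A [velocity_dataset()].
#' @param prefix Output path prefix (directories must exist).
#' @return `prefix`, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "velocity_dataset"))
  pix <- rep(ds$spacing_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(ds$magnitude, pixdim = pix),
                     paste0(prefix, "_mag.nii.gz"))
  for (nm in names(ds$velocity)) {
    RNifti::writeNifti(RNifti::asNifti(ds$velocity[[nm]], pixdim = pix),
                       paste0(prefix, "_v", nm, ".nii.gz"))
  }
  sidecar <- list(venc_cm_s = ds$venc_cm_s, period_ms = ds$period_ms,
                  spacing_mm = ds$spacing_mm, times_ms = ds$times_ms,
                  origin_mm = ds$origin_mm,
                  components = names(ds$velocity),
                  provenance = ds$provenance)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a velocity dataset written by [write_dataset()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [velocity_dataset()].
#' @export
read_dataset <- function(prefix) {
  sidecar_path <- paste0(prefix, ".json")
  if (!file.exists(sidecar_path)) stop("Sidecar not found: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (fld in c("venc_cm_s", "period_ms", "spacing_mm")) {
    if (is.null(sc[[fld]])) {
      stop("Sidecar is missing required field `", fld, "`.")
    }
  }
  mag <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_mag.nii.gz"))),
               dim = dim(RNifti::readNifti(paste0(prefix, "_mag.nii.gz"))))
  comps <- sc$components
  vel <- lapply(setNames(comps, comps), function(nm) {
    v <- RNifti::readNifti(paste0(prefix, "_v", nm, ".nii.gz"))
    array(as.numeric(v), dim = dim(v))
  })
  velocity_dataset(mag, vel,
                   venc_cm_s = sc$venc_cm_s, spacing_mm = sc$spacing_mm,
                   period_ms = sc$period_ms, times_ms = sc$times_ms,
                   origin_mm = sc$origin_mm,
                   provenance = as.list(sc$provenance))
}
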