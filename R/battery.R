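#' Experiment configuration for the simulation battery
#'
#' Collects the study conditions: four silicone-tube diameters driven at
#' matched mean flows with a common ~60 cm/s peak velocity, isotropic voxel
#' sizes, compressed-sensing acceleration factors, venc 60 cm/s, 24 cardiac
#' phases over an 800 ms cycle.
#'
#' @param tube_ids_mm Tube inner diameters, mm.
#' @param mean_flows_ml_s Mean flows matched to the tubes, mL/s.
#' @param voxel_sizes_mm Isotropic voxel sizes, mm.
#' @param cs_factors Acceleration factors (1 = fully sampled).
#' @param venc_cm_s Velocity encoding, cm/s.
#' @param period_ms,n_phases Cardiac period and phase count.
#' @param peak_velocity_cm_s Peak centerline velocity, cm/s.
#' @param snr Lumen SNR (`Inf` = noiseless).
#' @param roi_dilation_voxels ROI radius margin beyond the lumen edge, in
#'   voxels (default 0.5; reproduces boundary-voxel inclusion).
#' @param magnitude_threshold Lumen magnitude threshold fraction.
#' @param supersampling Fine samples per voxel edge.
#' @param background_signal Static-tissue signal, a.u.
#' @param seed Base seed for all random draws.
#' @return A `battery_config` list.
#' @export
battery_config <- function(tube_ids_mm = c(2, 3, 4, 5),
                           mean_flows_ml_s = c(0.6, 1.2, 2.3, 3.1),
                           voxel_sizes_mm = c(0.5, 1.0, 1.5),
                           cs_factors = 1,
                           venc_cm_s = 60, period_ms = 800, n_phases = 24,
                           peak_velocity_cm_s = 60, snr = Inf,
                           roi_dilation_voxels = 0.5,
                           magnitude_threshold = 0.5,
                           supersampling = 8, background_signal = 0.3,
                           seed = 1L) {
  stopifnot(length(tube_ids_mm) == length(mean_flows_ml_s),
            all(tube_ids_mm > 0), all(voxel_sizes_mm > 0),
            all(cs_factors >= 1))
  structure(
    list(tube_ids_mm = tube_ids_mm, mean_flows_ml_s = mean_flows_ml_s,
         voxel_sizes_mm = voxel_sizes_mm, cs_factors = cs_factors,
         venc_cm_s = venc_cm_s, period_ms = period_ms, n_phases = n_phases,
         peak_velocity_cm_s = peak_velocity_cm_s, snr = snr,
         roi_dilation_voxels = roi_dilation_voxels,
         magnitude_threshold = magnitude_threshold,
         supersampling = supersampling,
         background_signal = background_signal,
         seed = as.integer(seed)),
    class = "battery_config")
}

#' Write / read a battery configuration as JSON
#'
#' The round trip is lossless: `read_battery_config(write_battery_config())`
#' reproduces the configuration exactly.
#'
#' @param config A [battery_config()].
#' @param path JSON file path.
#' @return `path` (write) / a `battery_config` (read).
#' @export
write_battery_config <- function(config, path) {
  stopifnot(inherits(config, "battery_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_battery_config
#' @export
read_battery_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$snr <- as.numeric(x$snr)   # JSON renders Inf as the string "Inf"
  do.call(battery_config, x)
}

#' Simulate one phase-contrast tube dataset
#'
#' Full forward model for one study condition: pulsatile parabolic (or
#' Womersley) field, Hadamard velocity encoding with partial-volume complex
#' averaging, optional complex Gaussian noise, optional variable-density
#' undersampling with iterative reconstruction, then decoding.
#'
#' @param id_mm Tube inner diameter, mm.
#' @param mean_flow_ml_s Cycle-mean flow, mL/s.
#' @param voxel_mm Isotropic voxel size, mm.
#' @param cs Acceleration factor (1 = fully sampled).
#' @param venc_cm_s,period_ms,n_phases,peak_velocity_cm_s Acquisition and
#'   flow conditions (study defaults).
#' @param snr Lumen SNR; `Inf` for noiseless.
#' @param profile `"parabolic"` (default) or `"womersley"`.
#' @param directions Encoding directions (3 for 4D flow, 1 for 2D-flow
#'   emulation).
#' @param supersampling,background_signal Voxelization settings.
#' @param recon_iterations IST iterations when `cs > 1`.
#' @param seed Seed for noise and sampling masks.
#' @return A [velocity_dataset()]; the generating `velocity_field` is
#'   attached as `attr(, "field")`.
#' @export
simulate_tube_dataset <- function(id_mm, mean_flow_ml_s, voxel_mm,
                                  cs = 1, venc_cm_s = 60, period_ms = 800,
                                  n_phases = 24, peak_velocity_cm_s = 60,
                                  snr = Inf,
                                  profile = c("parabolic", "womersley"),
                                  directions = c("x", "y", "z"),
                                  supersampling = 8, background_signal = 0.3,
                                  recon_iterations = 30, seed = 1L) {
  profile <- match.arg(profile)
  geom <- tube_geometry(id_mm)
  wf <- tube_waveform(geom, mean_flow_ml_s,
                      peak_velocity_cm_s = peak_velocity_cm_s,
                      period_ms = period_ms, n_phases = n_phases)
  field <- if (profile == "parabolic") {
    parabolic_field(geom, wf)
  } else {
    womersley_field(geom, wf)
  }
  scheme <- encoding_scheme(venc_cm_s, directions)
  imgs <- encode_velocity(field, voxel_mm, scheme,
                          supersampling = supersampling,
                          background_signal = background_signal)
  if (is.finite(snr)) imgs <- add_noise(imgs, snr, seed = seed)
  if (cs > 1) {
    d <- dim(imgs$data)
    mask <- make_mask(d[1:2], cs, n_phases = d[5],
                      seed = as.integer(seed) + 7919L)
    imgs <- undersample_reconstruct(imgs, mask, method = "ist",
                                    iterations = recon_iterations)
  }
  ds <- decode_velocity(imgs)
  ds$provenance <- c(ds$provenance,
                     list(id_mm = id_mm, mean_flow_ml_s = mean_flow_ml_s,
                          voxel_mm = voxel_mm, cs = cs, snr = snr,
                          profile = profile, seed = as.integer(seed)))
  attr(ds, "field") <- field
  ds
}

#' Quantify tube flow from a decoded dataset
#'
#' The study's processing chain: background-phase correction, magnitude
#' lumen masking, aliasing correction, circular ROIs at the lumen edge
#' (dilated by a configurable margin) on each axial station, flow
#' integration, and averaging over stations.
#'
#' @param ds A [velocity_dataset()] of a tube aligned with z.
#' @param diameter_mm Known lumen diameter (defaults to the provenance
#'   entry).
#' @param roi_dilation_voxels ROI radius margin in voxels (default 0.5).
#' @param magnitude_threshold Lumen threshold fraction (default 0.5).
#' @param stations Slice indices to place ROIs on (default: all slices,
#'   labelled A, B, C, ...).
#' @param correct_background,unwrap Toggle those pre-processing stages.
#' @return The station-averaged flow-curve tibble; per-station curves in
#'   `attr(, "stations")`.
#' @export
quantify_tube_flow <- function(ds, diameter_mm = NULL,
                               roi_dilation_voxels = 0.5,
                               magnitude_threshold = 0.5,
                               stations = NULL,
                               correct_background = TRUE, unwrap = TRUE) {
  stopifnot(inherits(ds, "velocity_dataset"))
  if (is.null(diameter_mm)) diameter_mm <- ds$provenance$id_mm
  if (is.null(diameter_mm)) stop("`diameter_mm` is required.")
  if (correct_background) ds <- correct_background_phase(ds)
  ds <- mask_lumen(ds, magnitude_threshold)
  if (unwrap) ds <- unwrap_aliasing(ds)
  d <- dim(ds$magnitude)
  if (is.null(stations)) stations <- seq_len(d[3])
  labels <- LETTERS[seq_along(stations)]
  radius <- diameter_mm / 2 + roi_dilation_voxels * ds$spacing_mm
  curves <- purrr::map2(stations, labels, function(k, lb) {
    roi <- roi_circle(c(0, 0), radius, plane = k, label = lb)
    flow_curve(ds, rasterize_roi(roi, ds))
  })
  out <- average_rois(curves)
  attr(out, "stations") <- curves
  out
}

#' Run the full simulation battery
#'
#' Enumerates tube x voxel-size x acceleration combinations, simulates and
#' quantifies each, and compares the recovered flow against the analytic
#' reference (and optionally a 2D-flow emulation reference: single-direction
#' encoding at 0.5 mm in-plane). Any combination that fails is logged and
#' skipped; the remaining combinations still run.
#'
#' @param config A [battery_config()].
#' @param reference `"analytic"` (default) and/or `"2d"`.
#' @param verbose Log progress to stderr (default TRUE).
#' @return Tibble, one row per combination x reference: condition columns,
#'   `n_roi`, `median_diff_pct`, `rms`, plus list-columns `test_curve` and
#'   `ref_curve`. The configuration echo is in `attr(, "config")`.
#' @export
run_battery <- function(config, reference = "analytic", verbose = TRUE) {
  stopifnot(inherits(config, "battery_config"))
  reference <- match.arg(reference, c("analytic", "2d"), several.ok = TRUE)
  grid <- tidyr::expand_grid(
    tube = seq_along(config$tube_ids_mm),
    voxel_mm = config$voxel_sizes_mm,
    cs = config$cs_factors)

  ref2d <- list()
  if ("2d" %in% reference) {
    for (i in seq_along(config$tube_ids_mm)) {
      ds2 <- simulate_tube_dataset(
        config$tube_ids_mm[i], config$mean_flows_ml_s[i], voxel_mm = 0.5,
        cs = 1, venc_cm_s = config$venc_cm_s, period_ms = config$period_ms,
        n_phases = config$n_phases,
        peak_velocity_cm_s = config$peak_velocity_cm_s,
        snr = config$snr, directions = "z",
        supersampling = config$supersampling,
        background_signal = config$background_signal,
        seed = config$seed + i)
      ref2d[[i]] <- quantify_tube_flow(
        ds2, diameter_mm = config$tube_ids_mm[i],
        roi_dilation_voxels = config$roi_dilation_voxels,
        magnitude_threshold = config$magnitude_threshold)
    }
  }

  rows <- list()
  for (j in seq_len(nrow(grid))) {
    i <- grid$tube[j]
    id <- config$tube_ids_mm[i]
    vox <- grid$voxel_mm[j]
    cs <- grid$cs[j]
    if (verbose) {
      message(sprintf("battery: ID %g mm, voxel %g mm, CS %g", id, vox, cs))
    }
    res <- tryCatch({
      ds <- simulate_tube_dataset(
        id, config$mean_flows_ml_s[i], vox, cs = cs,
        venc_cm_s = config$venc_cm_s, period_ms = config$period_ms,
        n_phases = config$n_phases,
        peak_velocity_cm_s = config$peak_velocity_cm_s,
        snr = config$snr, supersampling = config$supersampling,
        background_signal = config$background_signal,
        seed = config$seed + 100L * j)
      test <- quantify_tube_flow(
        ds, diameter_mm = id,
        roi_dilation_voxels = config$roi_dilation_voxels,
        magnitude_threshold = config$magnitude_threshold)
      refs <- list()
      if ("analytic" %in% reference) {
        refs$analytic <- analytic_flow_curve(attr(ds, "field"),
                                             times_ms = ds$times_ms)
      }
      if ("2d" %in% reference) refs$`2d` <- ref2d[[i]]
      purrr::imap(refs, function(rc, nm) {
        cmp <- flow_comparison(test, rc, diameter_mm = id,
                               voxel_size_mm = vox)
        tibble::tibble(
          tube_id_mm = id, mean_flow_ml_s = config$mean_flows_ml_s[i],
          voxel_mm = vox, cs = cs, reference = nm,
          n_roi = cmp$n_roi, median_diff_pct = cmp$median_diff_pct,
          rms = cmp$rms, test_curve = list(test), ref_curve = list(rc))
      }) |> dplyr::bind_rows()
    }, error = function(e) {
      message(sprintf("battery: combination failed (%s); skipping",
                      conditionMessage(e)))
      NULL
    })
    rows[[j]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  out
}

#' Partial-volume error sweep over voxels-per-diameter
#'
#' The resolution battery behind the nROI error law: for each tube and each
#' requested nROI the voxel size is set to `diameter / n_roi`, the noiseless
#' fully-sampled pipeline is run, and the recovered station-averaged flow is
#' compared against the analytic reference.
#'
#' @param n_roi_values Integer vector of voxels-per-diameter values.
#' @param config A [battery_config()]; its voxel and CS lists are ignored,
#'   conditions (tubes, venc, phases, ROI and threshold defaults) are used.
#' @param verbose Log progress (default TRUE).
#' @return Tibble: `tube_id_mm`, `n_roi`, `voxel_mm`, `median_diff_pct`,
#'   `rms`.
#' @export
partial_volume_battery <- function(n_roi_values = 2:10,
                                   config = battery_config(),
                                   verbose = TRUE) {
  stopifnot(all(n_roi_values > 0))
  grid <- tidyr::expand_grid(tube = seq_along(config$tube_ids_mm),
                             n_roi = n_roi_values)
  purrr::pmap(grid, function(tube, n_roi) {
    id <- config$tube_ids_mm[tube]
    vox <- id / n_roi
    if (verbose) {
      message(sprintf("partial-volume sweep: ID %g mm, nROI %g", id, n_roi))
    }
    ds <- simulate_tube_dataset(
      id, config$mean_flows_ml_s[tube], vox, cs = 1,
      venc_cm_s = config$venc_cm_s, period_ms = config$period_ms,
      n_phases = config$n_phases,
      peak_velocity_cm_s = config$peak_velocity_cm_s,
      snr = Inf, supersampling = config$supersampling,
      background_signal = config$background_signal,
      seed = config$seed)
    test <- quantify_tube_flow(
      ds, diameter_mm = id,
      roi_dilation_voxels = config$roi_dilation_voxels,
      magnitude_threshold = config$magnitude_threshold)
    ref <- analytic_flow_curve(attr(ds, "field"), times_ms = ds$times_ms)
    tibble::tibble(tube_id_mm = id, n_roi = n_roi, voxel_mm = vox,
                   median_diff_pct = median_flow_difference(test, ref),
                   rms = normalized_rms(test, ref))
  }) |> dplyr::bind_rows()
}
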