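#' Velocity-encoding scheme
#'
#' Describes how velocity maps to signal phase. Velocity `v` along an encoded
#' direction contributes phase \eqn{\pi v / \mathrm{venc}} to the decoded
#' phase difference, so speeds beyond the venc wrap (alias). Three-direction
#' encoding uses the balanced symmetric four-point (Hadamard) scheme: four
#' segments whose first-moment signs are the rows of a 4 x 3 Hadamard-type
#' matrix scaled by 1/2. Single-direction encoding (2D-flow emulation) uses a
#' two-point scheme.
#'
#' @param venc_cm_s Velocity-encoding value in cm/s (> 0); the study uses 60
#'   (tubes) and 80 (aneurysm).
#' @param directions Character subset of `c("x","y","z")`; one entry for
#'   2D-flow emulation, three for 4D flow.
#' @return An `encoding_scheme` with the segment matrix `H` (segments x
#'   directions; phase per segment is `pi/venc * H %*% v`) and the decoding
#'   combination matrix `C` with `C %*% H = I`.
#' @export
encoding_scheme <- function(venc_cm_s, directions = c("x", "y", "z")) {
  if (!is.numeric(venc_cm_s) || venc_cm_s <= 0) stop("`venc_cm_s` must be > 0.")
  directions <- match.arg(directions, c("x", "y", "z"), several.ok = TRUE)
  if (length(directions) == 3) {
    Hd <- rbind(c(-1, -1, -1),
                c( 1,  1, -1),
                c( 1, -1,  1),
                c(-1,  1,  1))
    H <- Hd / 2
    C <- t(Hd) / 2           # C %*% H = I3
    label <- "balanced four-point (Hadamard)"
  } else if (length(directions) == 1) {
    H <- matrix(c(-0.5, 0.5), ncol = 1)
    C <- matrix(c(-1, 1), nrow = 1)
    label <- "two-point"
  } else {
    stop("Encoding supports one direction (2D flow) or three (4D flow).")
  }
  colnames(H) <- directions
  structure(list(venc_cm_s = venc_cm_s, directions = directions,
                 H = H, C = C, scheme = label),
            class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(sprintf("<encoding_scheme> %s, venc %g cm/s, directions %s\n",
              x$scheme, x$venc_cm_s, paste(x$directions, collapse = "")))
  invisible(x)
}

# wrap phase into (-pi, pi]
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# complex block mean: A is a complex vector over a fine grid with x fastest
# (nx*ss), then y (ny*ss), then z (ss sub-slices of one voxel slab);
# returns the nx x ny complex matrix of voxel means.
block_mean_slab <- function(A, nx, ny, ss) {
  dim(A) <- c(ss, nx, ss, ny, ss)
  A <- aperm(A, c(1, 3, 5, 2, 4))
  dim(A) <- c(ss^3, nx * ny)
  matrix(colMeans(A), nx, ny)
}

#' Voxelize an analytic field into phase-contrast complex images
#'
#' Renders the continuous velocity field onto a voxel grid the way a
#' phase-contrast acquisition does: every fine-grid sample carries a complex
#' signal with magnitude `lumen_signal` inside the lumen (or
#' `background_signal` in static surroundings) and phase
#' \eqn{\pi/\mathrm{venc} \, (H_s \cdot v)} for encoding segment `s`; the
#' fine grid is complex box-averaged into voxels. This complex (not
#' velocity) averaging is the mechanism of the partial-volume flow bias at
#' vessel boundaries, and phase wraps naturally into \eqn{(-\pi, \pi]}.
#'
#' @param field A `velocity_field`.
#' @param spacing_mm Isotropic voxel size in mm.
#' @param scheme An [encoding_scheme()].
#' @param shape Optional integer 3-vector of grid dimensions (voxels). By
#'   default the in-plane extent covers the lumen diameter plus a 3-voxel
#'   static margin on each side; tubes get `nz = 3` slices, cavities a cube.
#' @param grid_center Grid center in mm (defaults to the lumen center).
#' @param lumen_signal,background_signal Signal magnitudes (a.u.);
#'   `lumen_signal > background_signal >= 0`. The default background 0.3
#'   mimics the agarose embedding of the flow models.
#' @param wall_signal Signal magnitude of the tube-wall annulus when the
#'   field's geometry defines one (default 0: silicone is a signal void).
#' @param supersampling Fine samples per voxel edge (>= 4; default 8).
#' @param times Cardiac phase times in ms; default [phase_times()] of the
#'   field's waveform.
#' @return A `complex_images` object: complex array
#'   `[x, y, z, segment, phase]` plus spacing/period/scheme metadata.
#' @export
encode_velocity <- function(field, spacing_mm, scheme,
                            shape = NULL, grid_center = NULL,
                            lumen_signal = 1, background_signal = 0.3,
                            wall_signal = 0, supersampling = 8,
                            times = NULL) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(scheme, "encoding_scheme"))
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive.")
  if (supersampling < 4) stop("`supersampling` must be at least 4.")
  if (!(lumen_signal > background_signal && background_signal >= 0)) {
    stop("Require lumen_signal > background_signal >= 0.")
  }
  h <- spacing_mm / supersampling
  if (!is.null(field$geometry)) {
    D <- field$geometry$inner_diameter_mm
  } else {
    D <- 2 * field$radius_mm
  }
  if (D / h < 2) {
    stop("Supersampling too coarse: lumen diameter spans fewer than two ",
         "fine-grid cells.")
  }
  if (is.null(shape)) {
    n_in <- ceiling((D + 6 * spacing_mm) / spacing_mm)
    if (!is.null(field$geometry)) {
      shape <- c(n_in, n_in, 3L)
    } else {
      shape <- rep(n_in, 3L)
    }
  }
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  if (is.null(grid_center)) {
    grid_center <- if (!is.null(field$geometry)) field$geometry$center
                   else field$center
  }
  if (is.null(times)) times <- phase_times(field$waveform)
  nt <- length(times)
  ss <- as.integer(supersampling)
  nseg <- nrow(scheme$H)

  # voxel centers; fine coordinates are a uniform h-grid through each voxel
  vox_center <- function(n, c0) (seq_len(n) - (n + 1) / 2) * spacing_mm + c0
  fine_axis <- function(centers) {
    off <- (seq_len(ss) - (ss + 1) / 2) * h
    as.vector(outer(off, centers, "+"))
  }
  cx <- vox_center(nx, grid_center[1])
  cy <- vox_center(ny, grid_center[2])
  cz <- vox_center(nz, grid_center[3])
  fx <- fine_axis(cx)
  fy <- fine_axis(cy)

  data <- array(complex(real = 0), dim = c(nx, ny, nz, nseg, nt))
  n_inplane <- length(fx) * length(fy)
  px <- rep(fx, times = length(fy))
  py <- rep(fy, each = length(fx))
  scale <- pi / scheme$venc_cm_s
  Ht <- t(scheme$H)
  dir_idx <- match(scheme$directions, c("x", "y", "z"))

  for (k in seq_len(nz)) {
    fz <- cz[k] + (seq_len(ss) - (ss + 1) / 2) * h
    pts <- cbind(rep(px, times = ss),
                 rep(py, times = ss),
                 rep(fz, each = n_inplane))
    mag <- ifelse(field$in_lumen(pts), lumen_signal, background_signal)
    if (!is.null(field$in_wall)) mag[field$in_wall(pts)] <- wall_signal
    for (it in seq_len(nt)) {
      v <- field$velocity(pts, times[it])
      phi <- (v[, dir_idx, drop = FALSE] %*% Ht) * scale   # N x nseg
      for (s in seq_len(nseg)) {
        S <- mag * exp(1i * phi[, s])
        data[, , k, s, it] <- block_mean_slab(S, nx, ny, ss)
      }
    }
  }

  structure(
    list(data = data, spacing_mm = spacing_mm,
         period_ms = field$waveform$period_ms, times_ms = times,
         scheme = scheme, lumen_signal = lumen_signal,
         background_signal = background_signal,
         grid_center = grid_center,
         provenance = list(kind = field$kind, supersampling = ss)),
    class = "complex_images")
}

#' @export
print.complex_images <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<complex_images> %d x %d x %d voxels, %d segments, %d phases, %g mm\n",
    d[1], d[2], d[3], d[4], d[5], x$spacing_mm))
  invisible(x)
}

#' Decode phase-contrast images into a velocity dataset
#'
#' Inverts the four-point (or two-point) encoding: per direction `d` the
#' decoded velocity is \eqn{v_d = \mathrm{venc} \, \Delta\phi_d / \pi} with
#' \eqn{\Delta\phi_d} the segment-phase combination wrapped into
#' \eqn{(-\pi, \pi]}; the magnitude image is the mean complex modulus over
#' segments. Speeds beyond the venc alias into the opposite sign.
#'
#' @param images A `complex_images` object.
#' @param scheme Encoding scheme; defaults to the one stored in `images`.
#' @return A [velocity_dataset()].
#' @export
decode_velocity <- function(images, scheme = NULL) {
  stopifnot(inherits(images, "complex_images"))
  if (is.null(scheme)) scheme <- images$scheme
  d <- dim(images$data)
  if (d[4] != nrow(scheme$H)) {
    stop("Segment count does not match the encoding scheme.")
  }
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nseg <- d[4]; nt <- d[5]
  phi <- Arg(images$data)

  vel <- list()
  for (di in seq_along(scheme$directions)) {
    delta <- array(0, dim = c(nx, ny, nz, nt))
    for (s in seq_len(nseg)) {
      delta <- delta + scheme$C[di, s] *
        array(phi[, , , s, ], dim = c(nx, ny, nz, nt))
    }
    vel[[scheme$directions[di]]] <-
      scheme$venc_cm_s * wrap_phase(delta) / pi
  }

  M <- Mod(images$data)
  M <- aperm(M, c(1, 2, 3, 5, 4))
  dim(M) <- c(nx * ny * nz * nt, nseg)
  mag <- array(rowMeans(M), dim = c(nx, ny, nz, nt))

  velocity_dataset(
    magnitude = mag, velocity = vel,
    venc_cm_s = scheme$venc_cm_s, spacing_mm = images$spacing_mm,
    period_ms = images$period_ms, times_ms = images$times_ms,
    provenance = c(images$provenance,
                   list(scheme = scheme$scheme,
                        lumen_signal = images$lumen_signal)))
}

#' Add complex Gaussian noise to encoded images
#'
#' I.i.d. Gaussian noise of standard deviation `lumen_signal / snr` is added
#' to the real and imaginary channels of every segment and phase.
#'
#' @param images A `complex_images` object.
#' @param snr Signal-to-noise ratio of the lumen signal (> 0); `Inf` returns
#'   the input unchanged.
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return A `complex_images` object.
#' @export
add_noise <- function(images, snr, seed = 1L) {
  stopifnot(inherits(images, "complex_images"))
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be positive.")
  if (is.infinite(snr)) return(images)
  sigma <- images$lumen_signal / snr
  n <- length(images$data)
  noise <- withr::with_seed(seed, {
    complex(real = rnorm(n, sd = sigma), imaginary = rnorm(n, sd = sigma))
  })
  images$data <- images$data + array(noise, dim = dim(images$data))
  images$provenance$snr <- snr
  images$provenance$noise_seed <- seed
  images
}
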