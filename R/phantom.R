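#' Cylindrical tube geometry
#'
#' @param inner_diameter_mm Inner (lumen) diameter in mm, > 0. The study
#'   conditions use 2--5 mm, the calibre of intracranial arteries.
#' @param wall_thickness_mm Optional signal-void wall annulus thickness in
#'   mm (default 0: the lumen borders static tissue directly, the two-level
#'   signal model). A positive thickness models silicone tubing as a signal
#'   void between lumen and embedding medium.
#' @param length_mm Tube length in mm (default 60).
#' @param axis Tube axis direction (3-vector, normalized internally).
#' @param center Axis midpoint in mm.
#' @return A `tube_geometry` object.
#' @export
tube_geometry <- function(inner_diameter_mm, wall_thickness_mm = 0,
                          length_mm = 60,
                          axis = c(0, 0, 1), center = c(0, 0, 0)) {
  if (!is.numeric(inner_diameter_mm) || inner_diameter_mm <= 0) {
    stop("`inner_diameter_mm` must be positive.")
  }
  stopifnot(wall_thickness_mm >= 0, length_mm > 0,
            length(axis) == 3, length(center) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("`axis` must be a non-zero vector.")
  structure(
    list(inner_diameter_mm = inner_diameter_mm,
         radius_mm = inner_diameter_mm / 2,
         wall_thickness_mm = wall_thickness_mm,
         length_mm = length_mm,
         axis = axis / nrm,
         center = center),
    class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("<tube_geometry> ID %.3g mm, length %g mm\n",
              x$inner_diameter_mm, x$length_mm))
  invisible(x)
}

# membership test for the (signal-void) tube wall annulus
tube_wall_test <- function(geometry) {
  function(points) {
    tc <- tube_coords(geometry, points)
    tc$r >= geometry$radius_mm &
      tc$r < geometry$radius_mm + geometry$wall_thickness_mm &
      abs(tc$xi) <= geometry$length_mm / 2
  }
}

# axial coordinate and radial distance of points (N x 3, mm) w.r.t. a tube
tube_coords <- function(geometry, points) {
  p <- sweep(points, 2, geometry$center)
  xi <- drop(p %*% geometry$axis)
  rad2 <- rowSums(p^2) - xi^2
  list(xi = xi, r = sqrt(pmax(rad2, 0)))
}

#' Waveform matched to a tube's peak velocity
#'
#' Convenience constructor: converts a configured peak centerline velocity to
#' the peak flow of a parabolic (Poiseuille) profile,
#' \eqn{Q_{peak} = v_{max} \pi R^2 / 2}, and builds the raised-cosine
#' waveform with the requested cycle-mean flow.
#'
#' @param geometry A [tube_geometry()].
#' @param mean_flow_ml_s Cycle-averaged flow, mL/s.
#' @param peak_velocity_cm_s Peak centerline velocity, cm/s (default 60, the
#'   study's common peak across tubes).
#' @inheritParams pulsatile_waveform
#' @return A [pulsatile_waveform()] object.
#' @export
tube_waveform <- function(geometry, mean_flow_ml_s, peak_velocity_cm_s = 60,
                          period_ms = 800, n_phases = 24,
                          systolic_fraction = 0.35) {
  stopifnot(inherits(geometry, "tube_geometry"))
  R <- geometry$radius_mm
  # cm/s -> mm/s (x10); mm^3/s -> mL/s (/1000)
  peak_flow <- (peak_velocity_cm_s * 10) * pi * R^2 / 2 / 1000
  pulsatile_waveform(mean_flow_ml_s, peak_flow_ml_s = peak_flow,
                     period_ms = period_ms, n_phases = n_phases,
                     systolic_fraction = systolic_fraction)
}

new_velocity_field <- function(kind, geometry, waveform, velocity, flow,
                               in_lumen, extra = list()) {
  structure(
    c(list(kind = kind, geometry = geometry, waveform = waveform,
           velocity = velocity, flow = flow, in_lumen = in_lumen), extra),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %s\n", x$kind))
  invisible(x)
}

#' Quasi-steady parabolic (Poiseuille) pulsatile field
#'
#' Axial velocity \eqn{v(r, t) = v_{max}(t) (1 - (r/R)^2)} inside the lumen
#' and zero outside, with \eqn{v_{max}(t) = 2 Q(t) / (\pi R^2)} so the
#' cross-sectional integral reproduces the waveform's instantaneous flow at
#' every time. Appropriate for the laminar, low-Womersley regime.
#'
#' @param geometry A [tube_geometry()].
#' @param waveform A [pulsatile_waveform()] with non-negative flow.
#' @return A `velocity_field`: `$velocity(points, t_ms)` maps an N x 3 matrix
#'   of mm coordinates and a time in ms to an N x 3 matrix of cm/s;
#'   `$flow(t_ms)` gives the analytic flow in mL/s; `$in_lumen(points)` tests
#'   lumen membership.
#' @export
parabolic_field <- function(geometry, waveform) {
  stopifnot(inherits(geometry, "tube_geometry"),
            inherits(waveform, "pulse_waveform"))
  if (waveform$mean_flow_ml_s < 0) stop("Mean flow must be non-negative.")
  R <- geometry$radius_mm
  axis <- geometry$axis
  # v_max in mm/s from Q in mL/s: 2 * (1000*Q) / (pi R^2)
  vmax_mm_s <- function(t_ms) 2000 * waveform$flow(t_ms) / (pi * R^2)

  in_lumen <- function(points) {
    tc <- tube_coords(geometry, points)
    tc$r < R & abs(tc$xi) <= geometry$length_mm / 2
  }
  velocity <- function(points, t_ms) {
    tc <- tube_coords(geometry, points)
    inside <- tc$r < R & abs(tc$xi) <= geometry$length_mm / 2
    # mm/s -> cm/s
    sp <- (vmax_mm_s(t_ms) / 10) * (1 - (tc$r / R)^2) * inside
    outer(sp, axis)
  }
  new_velocity_field("parabolic tube", geometry, waveform,
                     velocity, waveform$flow, in_lumen,
                     extra = list(in_wall = tube_wall_test(geometry)))
}

# Bessel J0/J1 for complex argument (power series; adequate for |z| <~ 25,
# i.e. Womersley numbers up to ~20)
besselJ01_complex <- function(z) {
  q <- -(z * z) / 4
  term0 <- rep(1 + 0i, length(z))
  term1 <- rep(1 + 0i, length(z))
  s0 <- term0
  s1 <- term1
  for (k in 1:90) {
    term0 <- term0 * q / (k * k)
    term1 <- term1 * q / (k * (k + 1))
    s0 <- s0 + term0
    s1 <- s1 + term1
  }
  list(J0 = s0, J1 = (z / 2) * s1)
}

#' Womersley pulsatile field
#'
#' Oscillatory laminar flow in a rigid straight tube. The waveform is
#' decomposed into a steady component plus up to `n_harmonics` Fourier
#' harmonics; the steady part gets the parabolic profile and each harmonic
#' the classic annular-lag profile parameterized by the Womersley number
#' \eqn{\alpha_n = R \sqrt{\omega_n / \nu}}. Each harmonic's cross-sectional
#' flow equals the harmonic's flow amplitude, so the field's total flow
#' reproduces the (Fourier-truncated) waveform. As \eqn{\alpha \to 0} the
#' profile degenerates to the parabolic field.
#'
#' @inheritParams parabolic_field
#' @param kinematic_viscosity_mm2_s Kinematic viscosity in mm^2/s. Default
#'   3.39, a 40/60 glycerol-water blood analogue (3.72 cP, ~1099 kg/m^3).
#' @param n_harmonics Number of Fourier harmonics kept (max 8).
#' @return A `velocity_field` (same contract as [parabolic_field()]);
#'   `$flow(t_ms)` is the truncated-waveform flow.
#' @export
womersley_field <- function(geometry, waveform,
                            kinematic_viscosity_mm2_s = 3.39,
                            n_harmonics = 8) {
  stopifnot(inherits(geometry, "tube_geometry"),
            inherits(waveform, "pulse_waveform"))
  if (kinematic_viscosity_mm2_s <= 0) stop("Viscosity must be positive.")
  n_harmonics <- min(n_harmonics, 8L)
  R <- geometry$radius_mm
  axis <- geometry$axis
  h <- waveform_harmonics(waveform, n_harmonics)
  period_s <- waveform$period_ms / 1000
  omega <- 2 * pi * seq_along(h$c) / period_s      # rad/s
  alpha <- R * sqrt(omega / kinematic_viscosity_mm2_s)
  lambda <- (1i)^1.5 * alpha
  bw <- besselJ01_complex(lambda)
  denom <- 1 - 2 * bw$J1 / (lambda * bw$J0)        # flow normalizer
  amp_mm_s <- 1000 * h$c / (pi * R^2)              # mean-velocity amplitude

  keep <- Mod(h$c) > 1e-12 * max(waveform$mean_flow_ml_s,
                                 waveform$peak_flow_ml_s, 1e-9)

  flow_fun <- function(t_ms) {
    out <- rep_len(h$a0, length(t_ms))
    for (n in which(keep)) {
      out <- out + Re(h$c[n] * exp(1i * omega[n] * t_ms / 1000))
    }
    out
  }
  axial_mm_s <- function(r, t_ms) {
    u <- 2000 * h$a0 / (pi * R^2) * (1 - (r / R)^2)
    for (n in which(keep)) {
      phi <- (1 - besselJ01_complex(lambda[n] * r / R)$J0 / bw$J0[n]) /
        denom[n]
      u <- u + Re(amp_mm_s[n] * phi * exp(1i * omega[n] * t_ms / 1000))
    }
    u
  }
  in_lumen <- function(points) {
    tc <- tube_coords(geometry, points)
    tc$r < R & abs(tc$xi) <= geometry$length_mm / 2
  }
  velocity <- function(points, t_ms) {
    tc <- tube_coords(geometry, points)
    inside <- tc$r < R & abs(tc$xi) <= geometry$length_mm / 2
    sp <- numeric(nrow(points))
    if (any(inside)) {
      sp[inside] <- axial_mm_s(tc$r[inside], t_ms) / 10
    }
    outer(sp, axis)
  }
  new_velocity_field("womersley tube", geometry, waveform, velocity,
                     flow_fun, in_lumen,
                     extra = list(alpha = alpha,
                                  viscosity_mm2_s = kinematic_viscosity_mm2_s,
                                  in_wall = tube_wall_test(geometry)))
}

#' Idealized vortex in a spherical cavity
#'
#' A stand-in for the rotating flow in an aneurysm sac: azimuthal
#' (solid-body-like) rotation about the z axis through the cavity center,
#' with speed \eqn{v(\rho, r) = v_{peak} \frac{3\sqrt{3}}{2}
#' \frac{\rho}{a}\left(1 - (r/a)^2\right)} for cylindrical radius \eqn{\rho}
#' and spherical radius \eqn{r}. Speed vanishes at the vortex core and at the
#' wall (no-slip), the maximum over the cavity equals `peak_speed_cm_s`, and
#' the speed distribution is available in closed form for histogram tests.
#' A stagnation region (speed below 5% of peak) surrounds the core and wall.
#'
#' @param radius_mm Cavity radius in mm, > 0.
#' @param peak_speed_cm_s Peak speed in cm/s.
#' @param center Cavity center, mm.
#' @return A steady `velocity_field` with `$flow(t)` identically 0 (closed
#'   recirculation) and a steady waveform placeholder.
#' @export
vortex_cavity_field <- function(radius_mm, peak_speed_cm_s,
                                center = c(0, 0, 0)) {
  if (!is.numeric(radius_mm) || radius_mm <= 0) {
    stop("`radius_mm` must be positive.")
  }
  a <- radius_mm
  scale <- 3 * sqrt(3) / 2  # normalizes the max of (rho/a)(1-(r/a)^2) to 1
  in_lumen <- function(points) {
    p <- sweep(points, 2, center)
    rowSums(p^2) < a^2
  }
  velocity <- function(points, t_ms) {
    p <- sweep(points, 2, center)
    r2 <- rowSums(p^2)
    rho <- sqrt(p[, 1]^2 + p[, 2]^2)
    inside <- r2 < a^2
    sp <- peak_speed_cm_s * scale * (rho / a) * (1 - r2 / a^2) * inside
    # unit azimuthal direction; zero on the axis
    safe <- pmax(rho, 1e-300)
    cbind(-p[, 2] / safe, p[, 1] / safe, 0) * sp
  }
  wf <- pulsatile_waveform(0, period_ms = 800, n_phases = 2, shape = "steady")
  new_velocity_field("vortex cavity", NULL, wf, velocity,
                     function(t_ms) rep_len(0, length(t_ms)), in_lumen,
                     extra = list(radius_mm = a,
                                  peak_speed_cm_s = peak_speed_cm_s,
                                  center = center))
}
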