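# Numeric cross-section flow oracle: integrate the axial velocity of a field
# over a dense Cartesian grid in the plane z = z_mm (flow in mL/s).
integrate_flow_oracle <- function(field, t_ms, z_mm = 0, h_mm = 0.01,
                                  extent_mm = NULL) {
  if (is.null(extent_mm)) extent_mm <- field$geometry$radius_mm * 1.05
  x <- seq(-extent_mm, extent_mm, by = h_mm)
  g <- expand.grid(x = x, y = x)
  v <- field$velocity(cbind(g$x, g$y, z_mm), t_ms)
  sum(v[, 3]) * 10 * h_mm^2 / 1000    # cm/s -> mm/s, mm^3/s -> mL/s
}

# Uniform-velocity cylindrical "field" for encoding contract tests.
uniform_tube_field <- function(v_cm_s, diameter_mm = 4, n_phases = 4,
                               period_ms = 800) {
  geom <- tube_geometry(diameter_mm)
  wf <- pulsatile_waveform(0.1, period_ms = period_ms, n_phases = n_phases,
                           shape = "steady")
  v_cm_s <- rep_len(v_cm_s, 3)
  in_lumen <- function(points) {
    r <- sqrt(points[, 1]^2 + points[, 2]^2)
    r < geom$radius_mm
  }
  velocity <- function(points, t_ms) {
    outer(as.numeric(in_lumen(points)), v_cm_s)
  }
  structure(list(kind = "uniform tube", geometry = geom, waveform = wf,
                 velocity = velocity, in_lumen = in_lumen,
                 flow = function(t) rep_len(NA_real_, length(t))),
            class = "velocity_field")
}

# Half-space "field": lumen occupies x < 0, uniform axial velocity inside.
# Voxels centered on x = 0 are split exactly in half, giving the two-point
# complex-averaging oracle a clean target.
halfspace_field <- function(v_cm_s, n_phases = 2, period_ms = 800) {
  wf <- pulsatile_waveform(0.1, period_ms = period_ms, n_phases = n_phases,
                           shape = "steady")
  in_lumen <- function(points) points[, 1] < 0
  velocity <- function(points, t_ms) {
    cbind(0, 0, v_cm_s * (points[, 1] < 0))
  }
  structure(list(kind = "half space", geometry = tube_geometry(1e6),
                 waveform = wf, velocity = velocity, in_lumen = in_lumen,
                 flow = function(t) rep_len(NA_real_, length(t))),
            class = "velocity_field")
}

# Exact two-sided p of the one-sample (paired) signed-rank test by
# enumerating all 2^n sign assignments of the absolute-difference ranks.
signed_rank_enum_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided p of the rank-sum test by enumerating all assignments of
# the pooled ranks to the first sample.
rank_sum_enum_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n <- length(x); m <- length(y)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(n)])
  combs <- utils::combn(n + m, n)
  w_all <- apply(combs, 2, function(idx) sum(pooled[idx]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Dense-grid closed-form speed sample of the spherical vortex (cm/s).
vortex_speed_oracle <- function(radius_mm, peak_cm_s, h_mm = 0.1) {
  x <- seq(-radius_mm, radius_mm, by = h_mm)
  g <- expand.grid(x = x, y = x, z = x)
  r2 <- g$x^2 + g$y^2 + g$z^2
  keep <- r2 < radius_mm^2
  rho <- sqrt(g$x[keep]^2 + g$y[keep]^2)
  peak_cm_s * (3 * sqrt(3) / 2) * (rho / radius_mm) *
    (1 - r2[keep] / radius_mm^2)
}
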