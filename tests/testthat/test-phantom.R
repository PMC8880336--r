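test_that("raised-cosine waveform reproduces its configured mean flow", {
  for (cfg in list(c(0.6, 2), c(1.2, 3), c(2.3, 4), c(3.1, 5))) {
    geom <- tube_geometry(cfg[2])
    wf <- tube_waveform(geom, cfg[1])
    t <- seq(0, wf$period_ms, length.out = 20001)[-20001]
    expect_equal(mean(wf$flow(t)), cfg[1], tolerance = 1e-9)
    expect_equal(max(wf$flow(t)), wf$peak_flow_ml_s, tolerance = 1e-4)
  }
  expect_error(pulsatile_waveform(-1), "non-negative")
  expect_error(pulsatile_waveform(2, peak_flow_ml_s = 1), "peak")
})

test_that("parabolic field integrates to the analytic flow", {
  # steady case: R = 2.5 mm, v_max = 60 cm/s -> Q = pi R^2 v_max / 2
  geom <- tube_geometry(5)
  wf <- pulsatile_waveform(600 * pi * 2.5^2 / 2 / 1000, period_ms = 800,
                           shape = "steady")
  f <- parabolic_field(geom, wf)
  q_oracle <- integrate_flow_oracle(f, 0)
  expect_equal(q_oracle, 5.89, tolerance = 1e-3)
  expect_equal(f$flow(0), q_oracle, tolerance = 1e-3)

  # zero waveform -> zero field
  f0 <- parabolic_field(geom, pulsatile_waveform(0, shape = "steady"))
  pts <- cbind(runif(50, -2, 2), runif(50, -2, 2), 0)
  expect_true(all(f0$velocity(pts, 123) == 0))

  # study condition: ID 2 mm at mean flow 0.6 mL/s
  g2 <- tube_geometry(2)
  f2 <- parabolic_field(g2, tube_waveform(g2, 0.6))
  t <- seq(0, 800, length.out = 8001)[-8001]
  expect_equal(mean(f2$flow(t)), 0.6, tolerance = 1e-9)

  expect_error(tube_geometry(-1), "positive")
})

test_that("tube fields conserve flow along the axis and obey no-slip", {
  geom <- tube_geometry(3)
  wf <- tube_waveform(geom, 1.2)
  for (f in list(parabolic_field(geom, wf),
                 womersley_field(geom, wf))) {
    q1 <- integrate_flow_oracle(f, 250, z_mm = -10, h_mm = 0.005)
    q2 <- integrate_flow_oracle(f, 250, z_mm = 12, h_mm = 0.005)
    expect_equal(q1, q2, tolerance = 2e-3)
    expect_equal(q1, f$flow(250), tolerance = 2e-3)
    # no-slip: speed 1e-6 mm inside the wall is bounded by the shear-rate
    # scale 2 v_max delta / R
    r_in <- geom$radius_mm - 1e-6
    v_wall <- f$velocity(cbind(r_in, 0, 0), 250)
    expect_lt(max(abs(v_wall)), 1e-4)
    # outside the lumen the field vanishes
    expect_true(all(f$velocity(cbind(2, 2, 0), 250) == 0))
  }
})

test_that("womersley field degenerates to parabolic at low frequency", {
  geom <- tube_geometry(4)
  wf <- tube_waveform(geom, 2.3)
  # steady waveform: the two constructions agree identically
  wfs <- pulsatile_waveform(2.3, period_ms = 800, shape = "steady")
  fp <- parabolic_field(geom, wfs)
  fw <- womersley_field(geom, wfs)
  pts <- cbind(seq(-1.9, 1.9, by = 0.1), 0, 0)
  expect_equal(fw$velocity(pts, 300), fp$velocity(pts, 300),
               tolerance = 1e-9)

  # alpha -> 0 (huge viscosity): quasi-steady limit of the pulsatile case
  fw0 <- womersley_field(geom, wf, kinematic_viscosity_mm2_s = 4e5)
  fp0 <- parabolic_field(geom, wf)
  vmax <- 60  # cm/s reference scale
  for (t in c(0, 100, 280)) {
    dv <- fw0$velocity(pts, t) - fp0$velocity(pts, t)
    expect_lt(max(abs(dv)), 0.005 * vmax)
  }
})

test_that("single-harmonic womersley flow matches its closed form", {
  geom <- tube_geometry(5)
  period <- 1287  # ms; alpha ~ 3 at nu = 3.39 mm^2/s
  wf <- structure(
    list(period_ms = period, n_phases = 24, mean_flow_ml_s = 2,
         peak_flow_ml_s = 3, base_flow_ml_s = 1, systolic_fraction = NA,
         shape = "cosine",
         flow = function(t_ms) 2 + cos(2 * pi * t_ms / period)),
    class = "pulse_waveform")
  f <- womersley_field(geom, wf)
  expect_equal(f$alpha[1], 2.5 * sqrt(2 * pi / 1.287 / 3.39),
               tolerance = 1e-6)
  for (t in c(0, 300, 700, 1000)) {
    q_num <- integrate_flow_oracle(f, t, h_mm = 0.005)
    q_closed <- 2 + cos(2 * pi * t / period)
    expect_equal(q_num, q_closed, tolerance = 5e-3)
  }
  expect_error(womersley_field(geom, wf, kinematic_viscosity_mm2_s = -1),
               "positive")
})

test_that("fourier-truncated waveform keeps mean and peak within 1%", {
  geom <- tube_geometry(3)
  wf <- tube_waveform(geom, 1.2)
  f <- womersley_field(geom, wf)
  t <- seq(0, 800, length.out = 4001)[-4001]
  q <- f$flow(t)
  expect_equal(mean(q), wf$mean_flow_ml_s,
               tolerance = 0.01 * wf$mean_flow_ml_s)
  expect_equal(max(q), wf$peak_flow_ml_s,
               tolerance = 0.01 * wf$peak_flow_ml_s)
})

test_that("vortex cavity field has the advertised closed-form structure", {
  f0 <- vortex_cavity_field(8.75, 0)
  pts <- cbind(runif(20, -8, 8), runif(20, -8, 8), runif(20, -8, 8))
  expect_true(all(f0$velocity(pts, 0) == 0))

  f <- vortex_cavity_field(8.75, 60)
  expect_equal(drop(f$velocity(cbind(0, 0, 0), 0)), c(0, 0, 0))
  # wall no-slip
  expect_lt(max(abs(f$velocity(cbind(8.75 - 1e-6, 0, 0), 0))), 1e-3)
  # maximum speed equals the configured peak (at rho = a/sqrt(3), z = 0)
  rho_star <- 8.75 / sqrt(3)
  v_star <- f$velocity(cbind(rho_star, 0, 0), 0)
  expect_equal(sqrt(sum(v_star^2)), 60, tolerance = 1e-9)

  # evaluated speeds match the closed-form sample; median agrees with the
  # dense-grid quantile oracle
  x <- seq(-8.7, 8.7, by = 0.25)
  g <- expand.grid(x = x, y = x, z = x)
  keep <- g$x^2 + g$y^2 + g$z^2 < 8.75^2
  v <- f$velocity(as.matrix(g[keep, ]), 0)
  speeds <- sqrt(rowSums(v^2))
  oracle <- vortex_speed_oracle(8.75, 60, h_mm = 0.1)
  expect_equal(median(speeds), median(oracle), tolerance = 0.01)
  # stagnation region exists: a non-trivial share of the cavity is below
  # 5% of peak speed
  expect_gt(mean(speeds < 3), 0.02)
  expect_error(vortex_cavity_field(-2, 60), "positive")
})
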