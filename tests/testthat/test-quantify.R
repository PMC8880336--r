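# hand-built dataset: two-level magnitude cylinder with prescribed
# velocities, for tests that need exact control of every voxel
toy_dataset <- function(nx = 16, nz = 2, nt = 4, spacing = 1,
                        lumen_radius = 4.2, v_axial = 30,
                        lumen_mag = 1, bg_mag = 0.1, venc = 60) {
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing
  r <- sqrt(outer(x^2, x^2, "+"))
  lum <- r < lumen_radius
  mag <- array(rep(ifelse(lum, lumen_mag, bg_mag), nz * nt),
               dim = c(nx, nx, nz, nt))
  vz <- array(rep(ifelse(lum, v_axial, 0), nz * nt),
              dim = c(nx, nx, nz, nt))
  zero <- array(0, dim = dim(vz))
  velocity_dataset(mag, list(x = zero, y = zero, z = vz),
                   venc_cm_s = venc, spacing_mm = spacing, period_ms = 800)
}

test_that("background correction is exact on noiseless planar offsets", {
  ds <- toy_dataset()
  # zero offset: identity
  ds0 <- correct_background_phase(ds)
  expect_equal(ds0$velocity$z, ds$velocity$z, tolerance = 1e-12)

  # inject a known plane on every slice and phase of component z
  gc <- pcflow:::grid_coords(ds)
  plane <- outer(2.0 + 0.1 * gc$x, rep(1, 16)) +
    outer(rep(1, 16), -0.05 * gc$y)
  dsb <- ds
  for (k in 1:2) for (it in 1:4) {
    dsb$velocity$z[, , k, it] <- dsb$velocity$z[, , k, it] + plane
  }
  fixed <- correct_background_phase(dsb)
  fit <- attr(fixed, "background_fit")
  fz <- fit[fit$component == "z", ]
  expect_equal(fz$a, rep(2.0, 2), tolerance = 1e-6)
  expect_equal(fz$b, rep(0.1, 2), tolerance = 1e-6)
  expect_equal(fz$c, rep(-0.05, 2), tolerance = 1e-6)
  # corrected static region is clean and the lumen is restored
  static <- static_background_mask(dsb)
  expect_lt(max(abs(fixed$velocity$z[, , 1, 1][static])), 1e-9)
  expect_equal(fixed$velocity$z, ds$velocity$z, tolerance = 1e-9)
})

test_that("background correction never increases static-region velocity", {
  ds <- toy_dataset()
  static <- static_background_mask(ds)
  withr::with_seed(5, {
    for (k in 1:2) for (it in 1:4) {
      ds$velocity$z[, , k, it] <- ds$velocity$z[, , k, it] +
        1.5 + 0.2 * pcflow:::grid_coords(ds)$x + rnorm(16 * 16, sd = 0.3)
    }
  })
  before <- mean(abs(ds$velocity$z[, , 1, 1][static]))
  fixed <- correct_background_phase(ds)
  after <- mean(abs(fixed$velocity$z[, , 1, 1][static]))
  expect_lte(after, before)
})

test_that("noisy plane recovery stays within its standard-error bound", {
  sigma <- 0.5
  devs <- withr::with_seed(99, {
    vapply(1:20, function(i) {
      ds <- toy_dataset()
      plane <- 1.0 + 0.08 * pcflow:::grid_coords(ds)$x
      for (k in 1:2) for (it in 1:4) {
        ds$velocity$z[, , k, it] <- ds$velocity$z[, , k, it] +
          outer(plane, rep(1, 16)) + rnorm(16 * 16, sd = sigma)
      }
      fit <- attr(correct_background_phase(ds, reference_phase = 1),
                  "background_fit")
      fit$a[fit$component == "z"][1] - 1.0
    }, numeric(1))
  })
  n_static <- sum(static_background_mask(toy_dataset()))
  # intercept error is Op(sigma / sqrt(N)); allow 3x for 20 seeded repeats
  expect_lt(max(abs(devs)), 3 * sigma / sqrt(n_static) * 3)
  expect_lt(median(abs(devs)), 3 * sigma / sqrt(n_static))
})

test_that("lumen masking nulls exactly the sub-threshold voxels", {
  ds <- toy_dataset(lumen_mag = 1, bg_mag = 0.1)
  masked <- mask_lumen(ds, 0.5)
  lum <- masked$lumen_mask
  expect_true(all(masked$velocity$z[, , 1, 1][lum[, , 1]] == 30))
  expect_true(all(masked$velocity$z[, , 1, 1][!lum[, , 1]] == 0))
  # magnitude untouched
  expect_identical(masked$magnitude, ds$magnitude)

  # threshold below the background level nulls nothing
  ds2 <- toy_dataset(bg_mag = 0.8)
  ds2$velocity$z[] <- 5
  m2 <- mask_lumen(ds2, 0.5)
  expect_true(all(m2$velocity$z == 5))

  # a half-volume boundary voxel (magnitude 0.55) survives threshold 0.5
  ds3 <- toy_dataset(bg_mag = 0.1)
  ds3$magnitude[2, 2, , ] <- 0.55
  ds3$velocity$z[2, 2, , ] <- 12
  m3 <- mask_lumen(ds3, 0.5)
  expect_true(all(m3$velocity$z[2, 2, , ] == 12))
  expect_error(mask_lumen(ds, 1.5), "threshold_fraction")
})

test_that("aliasing correction fixes single wraps and is idempotent", {
  ds <- toy_dataset(v_axial = 75, venc = 60)
  # wrapped voxel: true 90 decoded as -30 inside a 75 cm/s neighborhood
  ds$velocity$z[8, 8, 1, 1] <- -30
  fixed <- unwrap_aliasing(ds)
  expect_equal(fixed$velocity$z[8, 8, 1, 1], 90)
  rep1 <- attr(fixed, "unwrap_report")
  expect_equal(rep1$corrected[rep1$component == "z"], 1L)

  # idempotent
  fixed2 <- unwrap_aliasing(fixed)
  expect_equal(fixed2$velocity$z, fixed$velocity$z)

  # clean data pass through untouched
  clean <- toy_dataset()
  out <- unwrap_aliasing(clean)
  expect_equal(out$velocity$z, clean$velocity$z)
  expect_equal(sum(attr(out, "unwrap_report")$corrected), 0L)
})

test_that("circle rasterization matches the pixel-center area oracle", {
  ds <- toy_dataset(nx = 48, spacing = 0.5)
  roi <- roi_circle(c(0, 0), 5, plane = 1)
  mask <- rasterize_roi(roi, ds)
  expect_equal(sum(mask$pixels) * mask$pixel_area_mm2, pi * 25,
               tolerance = 0.03)

  # sub-pixel circle centered on a pixel center -> single-pixel mask
  gc <- pcflow:::grid_coords(ds)
  tiny <- roi_circle(c(gc$x[10], gc$y[20]), 0.4 * 0.5, plane = 1)
  expect_equal(sum(rasterize_roi(tiny, ds)$pixels), 1L)

  # identical contour on another grid with the same spacing -> same mask
  ds4 <- toy_dataset(nx = 48, nz = 3, nt = 8, spacing = 0.5)
  expect_identical(rasterize_roi(roi, ds)$pixels,
                   rasterize_roi(roi, ds4)$pixels)

  out <- roi_circle(c(40, 0), 5, plane = 1)
  expect_error(rasterize_roi(out, ds), "outside")
})

test_that("spline contours rasterize like the shape they trace", {
  ds <- toy_dataset(nx = 48, spacing = 0.5)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ctrl <- cbind(4.5 * cos(th), 4.5 * sin(th))
  sp_mask <- rasterize_roi(roi_spline(ctrl, plane = 1), ds)
  ci_mask <- rasterize_roi(roi_circle(c(0, 0), 4.5, plane = 1), ds)
  # control points on a circle: spline and circle masks agree to ~1 pixel row
  expect_lt(sum(xor(sp_mask$pixels, ci_mask$pixels)),
            0.05 * sum(ci_mask$pixels))
  expect_error(roi_spline(ctrl[1:2, ]), "K >= 3")
})

test_that("flow curves integrate velocity times pixel area", {
  # uniform 10 cm/s over 25 pixels of 1 mm^2 -> 2.5 mL/s at every phase
  ds <- toy_dataset(nx = 17, spacing = 1, v_axial = 10, lumen_radius = 2.9)
  expect_equal(sum(ds$velocity$z[, , 1, 1] > 0), 25L)
  roi <- roi_circle(c(0, 0), 2.9, plane = 1)
  fc <- flow_curve(ds, rasterize_roi(roi, ds))
  expect_equal(fc$flow_ml_s, rep(2.5, 4))
  expect_equal(nrow(fc), 4L)

  # analytic parabolic flow recovered by fine-grid ROI integration
  geom <- tube_geometry(5)
  wf <- pulsatile_waveform(600 * pi * 2.5^2 / 2 / 1000, shape = "steady",
                           n_phases = 2)
  f <- parabolic_field(geom, wf)
  imgs <- encode_velocity(f, 0.25, encoding_scheme(80))
  dsf <- decode_velocity(imgs)
  roi2 <- roi_circle(c(0, 0), 2.5 + 0.125, plane = 2)
  fc2 <- flow_curve(dsf, rasterize_roi(roi2, dsf))
  expect_equal(fc2$flow_ml_s[1], 5.89, tolerance = 0.02 * 5.89)

  # all-zero velocity -> zero curve
  ds0 <- toy_dataset(v_axial = 0)
  fc0 <- flow_curve(ds0, rasterize_roi(roi, ds0))
  expect_true(all(fc0$flow_ml_s == 0))
})

test_that("ROI averaging is the pointwise mean and order-invariant", {
  mk <- function(v, lab) tibble::tibble(time_ms = c(0, 400),
                                        flow_ml_s = v, roi_label = lab)
  a <- mk(c(1, 1), "A"); b <- mk(c(2, 2), "B"); c3 <- mk(c(3, 3), "C")
  avg <- average_rois(list(a, b, c3))
  expect_equal(avg$flow_ml_s, c(2, 2))
  expect_equal(average_rois(list(c3, a, b))$flow_ml_s, avg$flow_ml_s)
  expect_equal(average_rois(list(a, a, a))$flow_ml_s, a$flow_ml_s)
  bad <- tibble::tibble(time_ms = c(0, 100, 200), flow_ml_s = 1:3,
                        roi_label = "X")
  expect_error(average_rois(list(a, bad)), "common time grid")
})

test_that("the full chain recovers analytic flow at high resolution", {
  # nROI = 14, noiseless, fully sampled: relative RMS below 2%
  id <- 5
  ds <- simulate_tube_dataset(id, 3.1, id / 14, snr = Inf, seed = 1)
  test <- suppressMessages(quantify_tube_flow(ds))
  ref <- analytic_flow_curve(attr(ds, "field"), times_ms = ds$times_ms)
  expect_lt(normalized_rms(test, ref), 0.02)

  # mass consistency: stations A, B, C agree within 1% on time-averaged flow
  st <- attr(test, "stations")
  means <- vapply(st, function(cv) mean(cv$flow_ml_s), numeric(1))
  expect_lt(max(means) / min(means) - 1, 0.01)
})
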