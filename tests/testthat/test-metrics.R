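mk_curve <- function(v, lab = "x") {
  tibble::tibble(time_ms = seq(0, length.out = length(v), by = 100),
                 flow_ml_s = v, roi_label = lab)
}

test_that("percentage flow difference matches its definition", {
  a <- mk_curve(c(1.1, 2.2)); b <- mk_curve(c(1, 2), "ref")
  d <- flow_difference(a, b)
  expect_equal(d$diff_pct, c(100 * 0.1 / 1.5, 100 * 0.2 / 1.5),
               tolerance = 1e-12)
  expect_equal(attr(d, "median_pct"), 10, tolerance = 1e-9)
  expect_true(all(flow_difference(a, a)$diff_pct == 0))
  expect_error(flow_difference(a, mk_curve(c(0, 0))), "zero time-mean")
})

test_that("normalized RMS matches its definition and scale invariance", {
  a <- mk_curve(c(1.1, 2.2)); b <- mk_curve(c(1, 2))
  expect_equal(normalized_rms(a, b), sqrt((0.01 + 0.04) / 2) / 1.5,
               tolerance = 1e-12)
  expect_equal(round(normalized_rms(a, b), 4), 0.1054)
  expect_equal(normalized_rms(a, a), 0)

  # common rescaling of both curves changes neither metric
  s <- 7.3
  a2 <- mk_curve(s * c(1.1, 2.2)); b2 <- mk_curve(s * c(1, 2))
  expect_equal(normalized_rms(a2, b2), normalized_rms(a, b))
  expect_equal(flow_difference(a2, b2)$diff_pct,
               flow_difference(a, b)$diff_pct)

  # rms is zero iff the curves are identical
  expect_gt(normalized_rms(mk_curve(c(1, 2.0001)), b), 0)
})

test_that("voxels-per-diameter and boundary-voxel counts are the stated ratios", {
  expect_equal(n_roi(17.5, 0.5), 35)
  expect_equal(n_roi(17.5, 1.5), 11.6667, tolerance = 1e-4)
  expect_equal(n_roi(17.5, 1.5, rounded = TRUE), 12)
  expect_equal(n_roi(1.2, 1.2), 1)
  expect_error(n_roi(-1, 1), "positive")

  expect_equal(boundary_voxel_count(5, 0.5), 10 * pi)
  expect_equal(boundary_voxel_count(1, 1), pi)
  expect_equal(boundary_voxel_count(3, 0.25),
               2 * boundary_voxel_count(3, 0.5))
})

test_that("reynolds number handles its mixed units", {
  expect_equal(reynolds_number(20, 0.5), 1120, tolerance = 1e-2 * 1120)
  expect_equal(reynolds_number(40, 0.5), 2 * reynolds_number(20, 0.5))
  expect_equal(reynolds_number(10, 0.25), 280.1, tolerance = 0.05)
  expect_error(reynolds_number(-1, 1), "positive")
})

test_that("velocity magnitude is the time-mean of the voxel speed", {
  dims <- c(4, 4, 2, 3)
  const <- function(v) array(v, dim = dims)
  ds <- velocity_dataset(const(1),
                         list(x = const(3), y = const(4), z = const(0)),
                         venc_cm_s = 60, spacing_mm = 1, period_ms = 800)
  vm <- velocity_magnitude(ds)
  expect_true(all(abs(vm$map - 5) < 1e-12))
  expect_equal(vm$median_cm_s, 5)

  # alternating sign: magnitude is taken before time averaging
  vx <- const(3); vx[, , , 2] <- -3
  ds2 <- velocity_dataset(const(1),
                          list(x = vx, y = const(0), z = const(0)),
                          venc_cm_s = 60, spacing_mm = 1, period_ms = 800)
  expect_true(all(abs(velocity_magnitude(ds2)$map - 3) < 1e-12))

  ds1 <- velocity_dataset(const(1), list(z = const(1)), venc_cm_s = 60,
                          spacing_mm = 1, period_ms = 800)
  expect_error(velocity_magnitude(ds1), "three")
  expect_equal(sum(vm$histogram$count), prod(dims[1:3]))
})

test_that("vortex dataset median speed matches the dense-grid oracle", {
  f <- vortex_cavity_field(5, 30)
  imgs <- encode_velocity(f, 0.5, encoding_scheme(60),
                          times = c(0, 400), supersampling = 4)
  ds <- decode_velocity(imgs)
  roi <- array(FALSE, dim = dim(ds$magnitude)[1:3])
  gc <- pcflow:::grid_coords(ds)
  for (k in seq_along(gc$z)) {
    r2 <- outer(gc$x^2, gc$y^2, "+") + gc$z[k]^2
    roi[, , k] <- r2 < (5 - 0.5)^2   # stay clear of wall partial volume
  }
  vm <- velocity_magnitude(ds, roi = roi)
  # dense-grid closed-form oracle restricted to the same interior region
  x <- seq(-4.5, 4.5, by = 0.1)
  g <- expand.grid(x = x, y = x, z = x)
  r2 <- g$x^2 + g$y^2 + g$z^2
  keep <- r2 < 4.5^2
  rho <- sqrt(g$x[keep]^2 + g$y[keep]^2)
  sp <- 30 * (3 * sqrt(3) / 2) * (rho / 5) * (1 - r2[keep] / 25)
  expect_equal(vm$median_cm_s, median(sp), tolerance = 0.02 * median(sp))
})

test_that("repeatability coefficient follows the 1.96*sqrt(2)*SD/mean rule", {
  base <- mk_curve(rep(1, 5))
  expect_equal(repeatability_coefficient(rep(list(base), 5)), 0)

  # five repeats, one time point with values [1,1,1,1,2]
  reps <- rep(list(mk_curve(c(1, 1))), 5)
  reps[[5]]$flow_ml_s[2] <- 2
  rc <- repeatability_curve(reps)
  expect_equal(rc$rc_pct[1], 0)
  expect_equal(rc$rc_pct[2], 1.96 * sqrt(2) * sd(c(1, 1, 1, 1, 2)) / 1.2 * 100,
               tolerance = 1e-12)
  expect_equal(round(rc$rc_pct[2], 1), 103.3)
  expect_equal(repeatability_coefficient(reps), mean(rc$rc_pct))
  expect_error(repeatability_coefficient(list(base)), "length")
})

test_that("flow comparison bundles the summary row", {
  a <- mk_curve(c(1.1, 2.2), "4D"); b <- mk_curve(c(1, 2), "2D")
  cmp <- flow_comparison(a, b, diameter_mm = 3, voxel_size_mm = 0.5)
  expect_equal(cmp$n_roi, 6)
  expect_equal(cmp$median_diff_pct, 10, tolerance = 1e-9)
  expect_equal(cmp$test_label, "4D")
})
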