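# a mildly asymmetric test shape (rectangle with a notch) so that
# half-turn ambiguity does not mask window-contract failures
notched_template <- function(size = 121L, hw = 40, hh = 22) {
  m <- matrix(0L, size, size)
  c0 <- (size + 1) / 2
  xs <- matrix(rep(1:size, each = size), size)
  ys <- matrix(rep(1:size, times = size), size)
  m[abs(xs - c0) <= hw & abs(ys - c0) <= hh] <- 1L
  m[xs - c0 > hw - 14 & c0 - ys > hh - 10] <- 0L
  m
}

rotated_raster <- function(tmpl_mask, angle) {
  cen <- spinetrack:::mask_centroid(tmpl_mask)
  n <- nrow(tmpl_mask)
  storage.mode(tmpl_mask) <- "double"
  spinetrack:::cpp_rasterize_rotated(tmpl_mask, cen[1], cen[2], n, n,
                                     cen[1], cen[2], angle)
}

test_that("fit_angle recovers the identity pose", {
  tm <- notched_template()
  shape <- as_mean_shape(tm)
  fit <- fit_angle(shape, tm)
  expect_lte(abs(fit$angle_deg), 0.1)
  expect_gte(fit$overlap, 0.99)
  expect_false(fit$low_confidence)
})

test_that("fit_angle recovers known rotations within 0.5 degrees", {
  tm <- notched_template()
  shape <- as_mean_shape(tm)
  for (ang in c(-30, -7, 0, 7, 30)) {
    mask <- rotated_raster(tm, ang)
    fit <- fit_angle(shape, mask, prev_angle_deg = 0)
    expect_lte(abs(fit$angle_deg - ang), 0.5)
    expect_gte(fit$overlap, 0.95)
  }
})

test_that("the +-90 window constrains the fit and flags low confidence", {
  tm <- notched_template()
  shape <- as_mean_shape(tm)
  mask <- rotated_raster(tm, 100)
  fit <- fit_angle(shape, mask, prev_angle_deg = 0)
  expect_lte(fit$angle_deg, 90 + 1e-6)
  expect_gte(fit$angle_deg, -90 - 1e-6)
})

test_that("fit_angle on an empty mask returns a missing marker", {
  shape <- as_mean_shape(notched_template())
  fit <- fit_angle(shape, matrix(0L, 50, 50))
  expect_true(fit$missing)
  expect_true(is.na(fit$angle_deg))
})

test_that("fit overlap is invariant under simultaneous translation", {
  tm <- notched_template(81L, hw = 25, hh = 14)
  shape <- as_mean_shape(tm)
  big <- matrix(0L, 200, 200)
  big[30 + 1:81, 40 + 1:81] <- tm
  big2 <- matrix(0L, 200, 200)
  big2[95 + 1:81, 70 + 1:81] <- tm
  f1 <- fit_angle(shape, big)
  f2 <- fit_angle(shape, big2)
  expect_equal(f1$overlap, f2$overlap, tolerance = 1e-10)
  expect_equal(f1$angle_deg, f2$angle_deg, tolerance = 1e-6)
})

test_that("track_vertebra: static phantom gives zero deltas", {
  tm <- notched_template(81L, hw = 25, hh = 14)
  frames <- replicate(5, {
    f <- matrix(0L, 120, 120); f[20 + 1:81, 20 + 1:81] <- tm; f
  }, simplify = FALSE)
  seq <- label_mask_sequence(frames, label_map = c("1" = "C4"))
  tr <- track_vertebra(seq, as_mean_shape(tm, "C4"))
  expect_true(all(abs(tr$dtheta_deg) <= 0.1))
  expect_equal(tr$dtheta_deg[1], 0)
})

test_that("track_vertebra telescoping: deltas sum to the angle difference", {
  tm <- notched_template()
  angles <- seq(-10, 14, by = 2)
  frames <- lapply(angles, function(a) rotated_raster(tm, a))
  seq <- label_mask_sequence(frames, label_map = c("1" = "C4"))
  tr <- track_vertebra(seq, as_mean_shape(tm, "C4"))
  expect_equal(sum(tr$dtheta_deg[-1]),
               tr$theta_deg[length(angles)] - tr$theta_deg[1],
               tolerance = 1e-9)
  # recovered angles match the programmed grid up to a constant offset
  err <- tr$theta_deg - angles
  expect_lte(max(abs(err - mean(err))), 0.5)
})

test_that("track_vertebra errors when the vertebra is never present", {
  frames <- replicate(3, matrix(0L, 20, 20), simplify = FALSE)
  frames[[1]][3:6, 3:6] <- 2L
  seq <- label_mask_sequence(frames, label_map = c("1" = "C4", "2" = "C5"))
  expect_error(track_vertebra(seq, as_mean_shape(square_mask(), "C4")),
               class = "spinetrack_no_trace")
})

test_that("relative_rotation subtracts deltas and propagates missing", {
  up <- rotation_trace("C4", c(0, 1, 2, 2), c(0, 1, 1, 0), rep(1, 4))
  lo <- rotation_trace("C5", c(0, 0.5, 1, 1), c(0, 0.5, 0.5, 0), rep(1, 4))
  seg <- relative_rotation(up, lo)
  expect_equal(seg$dtheta_rel_deg, c(0, 0.5, 0.5, 0))
  expect_equal(seg$segment, "C4-C5")

  self <- relative_rotation(up, up)
  expect_true(all(self$dtheta_rel_deg == 0))

  lo_na <- rotation_trace("C5", c(0, NA, 1, 1), c(0, NA, NA, 0), rep(1, 4),
                          missing_frames = 2L)
  seg_na <- relative_rotation(up, lo_na)
  expect_equal(seg_na$missing_frames, c(2L, 3L))
  expect_true(all(is.na(seg_na$dtheta_rel_deg[2:3])))

  expect_error(relative_rotation(up, rotation_trace("C5", 0, 0, 1)),
               class = "spinetrack_consistency_error")
})

test_that("smooth_trace has unit DC gain and matches the kernel on an impulse", {
  expect_equal(smooth_trace(rep(3.7, 25), 3), rep(3.7, 25), tolerance = 1e-12)
  n <- 51L; s <- 3
  x <- numeric(n); x[26] <- 1
  out <- smooth_trace(x, s)
  r <- ceiling(4 * s)
  k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
  expect_equal(out[(26 - r):(26 + r)], k, tolerance = 1e-12)
  expect_equal(sum(out), sum(x), tolerance = 1e-9)
})

test_that("smooth_trace interpolates missing values and re-flags them", {
  x <- c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10)
  out <- smooth_trace(x, 1)
  expect_true(is.na(out[3]))
  expect_false(anyNA(out[-3]))
  expect_error(smooth_trace(rep(NA_real_, 5), 3),
               class = "spinetrack_all_missing")
  expect_error(smooth_trace(1:5, 0), class = "spinetrack_config_error")
})

test_that("fit_config validates its fields", {
  expect_error(fit_config(coarse_step_deg = 0),
               class = "spinetrack_config_error")
  expect_error(fit_config(coarse_step_deg = 100),
               class = "spinetrack_config_error")
  expect_error(fit_config(refine_tol_deg = 0),
               class = "spinetrack_config_error")
})
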