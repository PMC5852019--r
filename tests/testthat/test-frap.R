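# closed-form FRAP stack builder: pixel = background + fluorescence * decay^k,
# with separate fluorescence levels inside and outside the measurement region
synthetic_frap_stack <- function(times = c(-5, seq(5, 60, 5), 120, 180),
                                 roi_level, cell_level, bg_level = 4,
                                 decay = 1) {
  ny <- 40; nx <- 80
  mask <- matrix(FALSE, ny, nx); mask[11:30, 11:70] <- TRUE
  box <- roi_spec("measure", 21, 11, 20, 20)
  bg <- roi_spec("background", 1, 1, 6, 6)
  frames <- lapply(seq_along(times), function(k) {
    f <- matrix(bg_level, ny, nx)
    d <- decay^(k - 1)
    f[mask] <- bg_level + cell_level[k] * d
    f[11:30, 21:40] <- bg_level + roi_level[k] * d
    f
  })
  frap_series(frames, times, roi_spec("bleach", 21, 11, 20, 20), box, mask, bg)
}

test_that("a series without bleach or drift normalizes to exactly 1", {
  n <- 15
  s <- synthetic_frap_stack(roi_level = rep(10, n), cell_level = rep(10, n))
  curve <- double_normalize(s)
  expect_equal(curve$normalized_intensity, rep(1, n))
})

test_that("an ROI at background level gives 0 at the first post-bleach point", {
  n <- 15
  s <- synthetic_frap_stack(roi_level = c(10, 0, rep(6, n - 2)),
                            cell_level = rep(10, n))
  curve <- double_normalize(s)
  expect_equal(curve$normalized_intensity[1], 1)
  expect_equal(curve$normalized_intensity[2], 0)
})

test_that("double normalization removes a global per-frame decay", {
  n <- 15
  # recovery-free cell: ROI drops to 40% of the cell level and stays there,
  # while everything (including the ROI) fades by 0.98 per frame
  s <- synthetic_frap_stack(roi_level = c(10, rep(4, n - 1)),
                            cell_level = rep(10, n), decay = 0.98)
  curve <- double_normalize(s)
  # hand-derived closed form: background cancels, the decay cancels in the
  # ROI / whole-cell ratio, leaving the pure post-bleach contrast
  mask_px <- 20 * 60; roi_px <- 20 * 20
  cell_post <- (4 * roi_px + 10 * (mask_px - roi_px)) / mask_px
  expected <- (4 / cell_post) / (10 / 10)
  expect_equal(curve$normalized_intensity[-1], rep(expected, n - 1),
               tolerance = 1e-12)
})

test_that("scaling and matched offsets leave the curve invariant", {
  n <- 15
  s <- synthetic_frap_stack(roi_level = c(10, 2, seq(3, 8, length.out = n - 2)),
                            cell_level = rep(9, n))
  base <- double_normalize(s)$normalized_intensity
  s2 <- s
  s2$frames <- lapply(s$frames, function(f) 3.7 * f + 2.2)
  expect_equal(double_normalize(s2)$normalized_intensity, base,
               tolerance = 1e-12)
})

test_that("curve averaging keeps timepoints and propagates symmetry", {
  n <- 15
  s <- synthetic_frap_stack(roi_level = c(10, 2, seq(3, 8, length.out = n - 2)),
                            cell_level = rep(10, n))
  c1 <- double_normalize(s)
  expect_equal(average_curves(list(c1))$normalized_intensity,
               c1$normalized_intensity)
  c2 <- c1
  c2$normalized_intensity <- 2 - c1$normalized_intensity
  avg <- average_curves(list(c1, c2))
  expect_equal(avg$normalized_intensity, rep(1, n))
  expect_equal(attr(avg, "n_cells"), 2L)
  c3 <- c1; c3$time_s <- c1$time_s + 1
  expect_error(average_curves(list(c1, c3)), "share identical timepoints")
})

test_that("recovery fit reproduces exact single-exponential parameters", {
  t <- frap_default_times()
  v <- 0.2 + 0.6 * (1 - exp(-0.05 * t))
  curve <- structure(data.frame(time_s = c(-5, t),
                                normalized_intensity = c(1, v)),
                     class = c("recovery_curve", "data.frame"))
  fit <- fit_recovery(curve)
  expect_equal(fit$i0, 0.2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.6, tolerance = 1e-6)
  expect_equal(fit$rate_per_s, 0.05, tolerance = 1e-6)
  expect_equal(fit$mobile_fraction, 0.75, tolerance = 1e-6)
  expect_equal(fit$half_time_s, log(2) / fit$rate_per_s, tolerance = 1e-9)
})

test_that("a flat post-bleach curve yields zero mobile fraction", {
  curve <- structure(data.frame(time_s = c(-5, frap_default_times()),
                                normalized_intensity = c(1, rep(0.2, 14))),
                     class = c("recovery_curve", "data.frame"))
  fit <- fit_recovery(curve)
  expect_equal(fit$mobile_fraction, 0)
})

test_that("simulated immobile FRAP shows no recovery", {
  g <- cell_geometry(5, 0.5, 0.05)
  sp <- scene_spec(g, emitter_distribution("uniform", 250), motion_model(0),
                   quiet_camera(seed = 21), image_shape = c(64, 140))
  sim <- simulate_frap_series(sp, roi_spec("bleach", 20, 18, 50, 30))
  curve <- double_normalize(sim$series)
  fit <- fit_recovery(curve)
  expect_lt(fit$mobile_fraction, 0.1)
  expect_lt(mean(curve$normalized_intensity[-1]), 0.15)
})

test_that("fast-diffusing FRAP recovers toward the cell-average plateau", {
  g <- cell_geometry(5, 0.5, 0.05)
  sp <- scene_spec(g, emitter_distribution("uniform", 250),
                   motion_model(0.3), quiet_camera(seed = 22),
                   image_shape = c(64, 140))
  sim <- simulate_frap_series(sp, roi_spec("bleach", 20, 18, 50, 30))
  curve <- double_normalize(sim$series)
  late <- curve$normalized_intensity[curve$time_s >= 120]
  expect_gt(mean(late), 0.85)
})

test_that("zero bleach depth leaves the normalized curve near 1", {
  g <- cell_geometry(5, 0.5, 0.05)
  sp <- scene_spec(g, emitter_distribution("uniform", 250),
                   motion_model(0.05), quiet_camera(seed = 23),
                   image_shape = c(64, 140))
  sim <- simulate_frap_series(sp, roi_spec("bleach", 20, 18, 50, 30),
                              bleach_depth = 0,
                              timepoints_s = c(5, 10, 15, 20, 25))
  curve <- double_normalize(sim$series)
  expect_true(all(abs(curve$normalized_intensity - 1) < 0.1))
})

test_that("acquisition bleaching is compensated by the normalization", {
  g <- cell_geometry(5, 0.5, 0.05)
  sp <- scene_spec(g, emitter_distribution("uniform", 250), motion_model(0),
                   quiet_camera(seed = 24), image_shape = c(64, 140))
  sim <- simulate_frap_series(sp, roi_spec("bleach", 20, 18, 50, 30),
                              bleach_depth = 0, acq_bleach_factor = 0.97)
  curve <- double_normalize(sim$series)
  expect_true(all(abs(curve$normalized_intensity - 1) < 0.1))
})
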