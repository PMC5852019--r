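render_spot <- function(x0, y0, sx = 1.3, sy = 1.3, amp = 500, offset = 10,
                        shape = c(24, 24)) {
  xs <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
  ys <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1], shape[2])
  amp * exp(-(xs - x0)^2 / (2 * sx^2) - (ys - y0)^2 / (2 * sy^2)) + offset
}

test_that("a noiseless spot is localized to better than 0.05 px", {
  f <- render_spot(10.30, 7.60)
  loc <- detect_and_fit(f)
  expect_equal(nrow(loc), 1L)
  expect_lt(abs(loc$x_px - 10.30), 0.05)
  expect_lt(abs(loc$y_px - 7.60), 0.05)
  # isotropic input: fitted widths symmetric
  expect_lt(abs(loc$sigma_x_px - loc$sigma_y_px), 0.02)
})

test_that("an elliptical spot recovers distinct axis widths", {
  f <- render_spot(12.2, 11.7, sx = 1.8, sy = 1.1)
  loc <- detect_and_fit(f, fit_window_px = 11)
  expect_equal(nrow(loc), 1L)
  expect_lt(abs(loc$sigma_x_px - 1.8), 0.1)
  expect_lt(abs(loc$sigma_y_px - 1.1), 0.1)
})

test_that("a blank frame yields no localizations", {
  set.seed(31)
  f <- matrix(rpois(64 * 64, 10), 64, 64)
  expect_equal(nrow(detect_and_fit(f)), 0L)
})

test_that("a drifting spot links into one full-length trajectory", {
  locs <- data.frame(frame = 1:10, x_px = 5 + (1:10), y_px = 12)
  tr <- link_frame_by_frame(locs, max_disp_px = 3)
  expect_equal(length(unique(tr$traj_id)), 1L)
  expect_equal(nrow(tr), 10L)
})

test_that("two distant parallel spots never swap identities", {
  locs <- rbind(data.frame(frame = 1:10, x_px = 5 + (1:10), y_px = 5),
                data.frame(frame = 1:10, x_px = 5 + (1:10), y_px = 25))
  tr <- link_frame_by_frame(locs, max_disp_px = 3)
  expect_equal(length(unique(tr$traj_id)), 2L)
  ys <- tapply(tr$y_px, tr$traj_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))
})

test_that("crossing paths are assigned like the exhaustive matcher", {
  # two antiparallel tracks passing on adjacent rows
  t_seq <- 1:11
  locs <- rbind(data.frame(frame = t_seq, x_px = t_seq, y_px = 10),
                data.frame(frame = t_seq, x_px = 12 - t_seq, y_px = 10.5))
  tr <- link_frame_by_frame(locs, max_disp_px = 3)
  expect_equal(length(unique(tr$traj_id)), 2L)
  for (f in 1:10) {
    a <- locs[locs$frame == f, ]
    b <- locs[locs$frame == f + 1, ]
    got <- merge(tr[tr$frame == f, c("traj_id", "x_px", "y_px")],
                 tr[tr$frame == f + 1, c("traj_id", "x_px", "y_px")],
                 by = "traj_id")
    oracle <- oracle_pairs(a$x_px, a$y_px, b$x_px, b$y_px, 3)
    # same pair set: compare matched coordinates
    got_pairs <- sort(paste(got$x_px.x, got$y_px.x, got$x_px.y, got$y_px.y))
    oracle_pairs_str <- sort(paste(a$x_px[oracle[, 1]], a$y_px[oracle[, 1]],
                                   b$x_px[oracle[, 2]], b$y_px[oracle[, 2]]))
    expect_equal(got_pairs, oracle_pairs_str)
  }
})

test_that("greedy linking matches exhaustive assignment on random triples", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(1:3, 1)
    xa <- runif(n, 0, 30); ya <- runif(n, 0, 30)
    xb <- xa + rnorm(n, 0, 1); yb <- ya + rnorm(n, 0, 1)
    locs <- rbind(data.frame(frame = 1, x_px = xa, y_px = ya),
                  data.frame(frame = 2, x_px = xb, y_px = yb))
    tr <- link_frame_by_frame(locs, max_disp_px = 4)
    linked <- merge(tr[tr$frame == 1, c("traj_id", "x_px")],
                    tr[tr$frame == 2, c("traj_id", "x_px")], by = "traj_id")
    oracle <- oracle_pairs(xa, ya, xb, yb, 4)
    got <- sort(paste(linked$x_px.x, linked$x_px.y))
    want <- sort(paste(xa[oracle[, 1]], xb[oracle[, 2]]))
    expect_equal(got, want)
  }
})

test_that("clean single bleach steps are accepted at the right frame", {
  res <- single_bleach_step_filter(c(100, 100, 100, 5, 5, 5))
  expect_true(res$accept)
  expect_equal(res$step_frame, 4L)
  set.seed(33)
  noisy <- c(rnorm(12, 200, 5), rnorm(10, 3, 5))
  res2 <- single_bleach_step_filter(noisy, background_level = 0)
  expect_true(res2$accept)
  expect_equal(res2$step_frame, 13L)
})

test_that("double steps and ramps are rejected", {
  expect_false(single_bleach_step_filter(c(200, 200, 100, 100, 5, 5))$accept)
  ramp <- seq(100, 5, length.out = 20)
  res <- single_bleach_step_filter(ramp)
  expect_false(res$accept)
  # the ramp is genuinely better described by a line than by one step
  rss_step <- {
    c1 <- res$step_frame
    sum((ramp[1:(c1 - 1)] - mean(ramp[1:(c1 - 1)]))^2) +
      sum((ramp[c1:20] - mean(ramp[c1:20]))^2)
  }
  rss_line <- sum(resid(lm(ramp ~ seq_along(ramp)))^2)
  expect_lt(rss_line, rss_step)
  expect_false(single_bleach_step_filter(rep(50, 10))$accept)
  expect_false(single_bleach_step_filter(c(5, 5, 5, 100, 100, 100))$accept)
})

test_that("MSD matches closed forms and the brute-force oracle", {
  # straight-line motion at constant speed: MSD(k dt) = (v k dt)^2
  v_px <- 2
  tr <- data.frame(frame = 1:20, x_px = v_px * (1:20), y_px = 0)
  msd <- compute_msd(tr, pixel_size_um = 0.1, frame_interval_s = 0.05,
                     max_lag = 4)
  expect_equal(msd$msd_um2, (v_px * 0.1)^2 * (1:4)^2, tolerance = 1e-12)
  expect_equal(msd$n_pairs, 19:16)
  # stationary
  tr0 <- data.frame(frame = 1:10, x_px = 3, y_px = 4)
  expect_true(all(compute_msd(tr0)$msd_um2 == 0))
  # random walk vs explicit double loop
  set.seed(34)
  trr <- data.frame(frame = 1:10, x_px = cumsum(rnorm(10)),
                    y_px = cumsum(rnorm(10)))
  msd_r <- compute_msd(trr, 0.096, 0.033, max_lag = 6)
  for (k in 1:6) {
    acc <- c()
    for (i in 1:(10 - k))
      acc <- c(acc, (trr$x_px[i + k] - trr$x_px[i])^2 +
                    (trr$y_px[i + k] - trr$y_px[i])^2)
    expect_equal(msd_r$msd_um2[k], mean(acc) * 0.096^2, tolerance = 1e-12)
  }
  expect_error(compute_msd(trr[1:4, ], max_lag = 4), "too short")
  gap <- data.frame(frame = c(1, 2, 4, 5, 6), x_px = 1:5, y_px = 0)
  expect_error(compute_msd(gap), "consecutive")
})

test_that("diffusion estimation inverts MSD(t) = 4 D t", {
  msd <- structure(data.frame(lag_s = (1:4) * 0.033,
                              msd_um2 = 4 * 0.1 * (1:4) * 0.033,
                              n_pairs = 9:6),
                   class = c("msd_curve", "data.frame"))
  est <- estimate_D(msd)
  expect_equal(est$d_um2_s, 0.1, tolerance = 1e-12)
  expect_equal(est$intercept_um2, 0, tolerance = 1e-12)
  est0 <- estimate_D(msd, through_origin = TRUE)
  expect_equal(est0$d_um2_s, 0.1, tolerance = 1e-12)
  # plateau (confined): zero slope
  plat <- structure(data.frame(lag_s = (1:4) * 0.033, msd_um2 = rep(0.01, 4),
                               n_pairs = 9:6),
                    class = c("msd_curve", "data.frame"))
  expect_equal(estimate_D(plat)$d_um2_s, 0)
  # an intercept from localization noise does not bias the default fit
  noisy <- structure(data.frame(lag_s = (1:4) * 0.033,
                                msd_um2 = 0.002 + 4 * 0.05 * (1:4) * 0.033,
                                n_pairs = 9:6),
                     class = c("msd_curve", "data.frame"))
  expect_equal(estimate_D(noisy)$d_um2_s, 0.05, tolerance = 1e-12)
  expect_equal(estimate_D(noisy)$intercept_um2, 0.002, tolerance = 1e-12)
})

test_that("localization precision improves with the photon budget", {
  errs <- vapply(c(500, 3000, 20000), function(photons) {
    g <- cell_geometry(6, 1, 0.096)
    cam <- camera_model(photons_per_frame = photons, background_level = 10,
                        read_noise_sd = 1, seed = 35)
    sp <- scene_spec(g, emitter_distribution("uniform", 4), motion_model(0),
                     cam, n_frames = 12)
    mv <- render_movie(sp)
    locs <- detect_movie(mv$frames, threshold = 4)
    err <- c()
    for (f in seq_along(mv$frames)) {
      tt <- mv$truth[mv$truth$frame == f, ]
      lf <- locs[locs$frame == f, ]
      if (!nrow(lf)) next
      for (i in seq_len(nrow(tt))) {
        d <- sqrt((lf$x_px - tt$x_px[i])^2 + (lf$y_px - tt$y_px[i])^2)
        if (min(d) < 2) err <- c(err, min(d))
      }
    }
    mean(err)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
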