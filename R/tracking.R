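#' Detect single molecules and fit elliptical Gaussians
#'
#' Candidate peaks are local maxima of a lightly Gaussian-smoothed frame
#' that exceed `median + threshold * MAD` of the frame (robust units above
#' background). Candidates closer than one fit window are merged to the
#' brighter one, and each survivor is refined by a least-squares
#' two-dimensional elliptical Gaussian fit
#' `A * exp(-(x - x0)^2 / (2 sx^2) - (y - y0)^2 / (2 sy^2)) + offset`
#' in its window, giving the peak center with sub-pixel resolution.
#' Candidates whose fit diverges are dropped (counted in the `n_dropped`
#' attribute), never fatal.
#'
#' @param frame Image matrix.
#' @param threshold Detection level in robust MAD units above the frame
#'   median (default 5).
#' @param fit_window_px Odd window size for the fit (default 9).
#' @param psf_sigma_px Starting value for the Gaussian widths.
#' @param smooth_sigma_px Pre-detection smoothing width (default 1).
#' @return data.frame `(x_px, y_px, amplitude, sigma_x_px, sigma_y_px,
#'   offset, fit_rms)`, one row per accepted localization; attribute
#'   `n_dropped` counts discarded candidates.
#' @export
detect_and_fit <- function(frame, threshold = 5, fit_window_px = 9L,
                           psf_sigma_px = 1.3, smooth_sigma_px = 1) {
  stopifnot(is.matrix(frame), fit_window_px %% 2 == 1, fit_window_px >= 5)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      amplitude = numeric(0), sigma_x_px = numeric(0),
                      sigma_y_px = numeric(0), offset = numeric(0),
                      fit_rms = numeric(0))
  sm <- .gauss_smooth(frame, smooth_sigma_px)
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  level <- bg + threshold * max(noise, 1e-12)
  cand <- .local_maxima(sm)
  cand <- cand[sm[cand] > level]
  if (!length(cand)) { attr(empty, "n_dropped") <- 0L; return(empty) }

  ny <- nrow(frame)
  cy <- (cand - 1L) %% ny + 1L
  cx <- (cand - 1L) %/% ny + 1L
  o <- order(sm[cand], decreasing = TRUE)
  cx <- cx[o]; cy <- cy[o]
  keep <- rep(TRUE, length(cx))
  for (i in seq_along(cx)) {
    if (!keep[i]) next
    if (i < length(cx)) {
      later <- (i + 1L):length(cx)
      close <- keep[later] &
        pmax(abs(cx[later] - cx[i]), abs(cy[later] - cy[i])) < fit_window_px
      keep[later[close]] <- FALSE
    }
  }
  cx <- cx[keep]; cy <- cy[keep]

  half <- fit_window_px %/% 2L
  inb <- cx - half >= 1 & cx + half <= ncol(frame) &
    cy - half >= 1 & cy + half <= ny
  n_dropped <- sum(!inb)
  cx <- cx[inb]; cy <- cy[inb]

  res <- vector("list", length(cx))
  for (i in seq_along(cx)) {
    win <- frame[(cy[i] - half):(cy[i] + half),
                 (cx[i] - half):(cx[i] + half)]
    fit <- .fit_elliptical_gaussian(win, psf_sigma_px)
    if (is.null(fit)) { n_dropped <- n_dropped + 1L; next }
    res[[i]] <- data.frame(
      x_px = cx[i] - half - 1 + fit$x0, y_px = cy[i] - half - 1 + fit$y0,
      amplitude = fit$A, sigma_x_px = fit$sx, sigma_y_px = fit$sy,
      offset = fit$offset, fit_rms = fit$rms)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res)) do.call(rbind, res) else empty
  attr(out, "n_dropped") <- n_dropped
  out
}

# separable Gaussian smoothing via EBImage 2D convolution
.gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  w <- 2L * ceiling(2.5 * sigma) + 1L
  g <- stats::dnorm(seq_len(w) - (w + 1) / 2, sd = sigma)
  k <- (g %o% g); k <- k / sum(k)
  EBImage::filter2(img, k, boundary = "replicate")
}

# linear indices of strict-ish 3x3 local maxima (ties broken toward the
# top-left neighbour so plateau pixels yield a single candidate)
.local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1), 2:(nx + 1)] <- img
  ctr <- pad[2:(ny + 1), 2:(nx + 1)]
  strict <- ctr > pad[1:ny, 2:(nx + 1)] &       # N
    ctr > pad[1:ny, 1:nx] &                     # NW
    ctr > pad[1:ny, 3:(nx + 2)] &               # NE
    ctr > pad[2:(ny + 1), 1:nx] &               # W
    ctr >= pad[2:(ny + 1), 3:(nx + 2)] &        # E
    ctr >= pad[3:(ny + 2), 1:nx] &              # SW
    ctr >= pad[3:(ny + 2), 2:(nx + 1)] &        # S
    ctr >= pad[3:(ny + 2), 3:(nx + 2)]          # SE
  which(strict)
}

# least-squares elliptical Gaussian on a square window; NULL on failure
.fit_elliptical_gaussian <- function(win, sigma_start) {
  w <- nrow(win)
  xs <- rep(seq_len(w), each = w)
  ys <- rep(seq_len(w), w)
  z <- as.vector(win)
  off0 <- min(z)
  zc <- pmax(z - off0, 0)
  if (sum(zc) <= 0) return(NULL)
  x00 <- sum(xs * zc) / sum(zc)
  y00 <- sum(ys * zc) / sum(zc)
  a0 <- max(z) - off0
  df <- data.frame(xs = xs, ys = ys, z = z)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      z ~ A * exp(-(xs - x0)^2 / (2 * sx^2) - (ys - y0)^2 / (2 * sy^2)) + off,
      data = df,
      start = list(A = a0, x0 = x00, y0 = y00,
                   sx = sigma_start, sy = sigma_start, off = off0),
      lower = c(A = 0, x0 = 1, y0 = 1, sx = 0.3, sy = 0.3, off = -Inf),
      upper = c(A = Inf, x0 = w, y0 = w, sx = w, sy = w, off = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (cf[["A"]] <= 0) return(NULL)
  list(x0 = cf[["x0"]], y0 = cf[["y0"]], A = cf[["A"]],
       sx = cf[["sx"]], sy = cf[["sy"]], offset = cf[["off"]],
       rms = sqrt(mean(stats::resid(fit)^2)))
}

#' Localize every frame of a movie
#'
#' Runs [detect_and_fit()] on each frame and stacks the results with a
#' `frame` column.
#'
#' @param frames List of image matrices.
#' @param ... Passed to [detect_and_fit()].
#' @return data.frame of localizations with a `frame` column first.
#' @export
detect_movie <- function(frames, ...) {
  out <- lapply(seq_along(frames), function(f) {
    loc <- detect_and_fit(frames[[f]], ...)
    if (nrow(loc)) cbind(frame = f, loc) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), amplitude = numeric(0),
                      sigma_x_px = numeric(0), sigma_y_px = numeric(0),
                      offset = numeric(0), fit_rms = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Link localizations into trajectories frame by frame
#'
#' Greedy nearest-neighbour assignment between consecutive frames: candidate
#' pairs within `max_disp_px` are assigned closest-first; localizations left
#' unmatched start new trajectories. There is no gap closing: a trajectory
#' ends the first frame its molecule is not re-detected.
#'
#' @param locs data.frame with columns `frame`, `x_px`, `y_px` (extra
#'   columns are carried through).
#' @param max_disp_px Maximum displacement between consecutive frames (px).
#' @return The input data.frame with a `traj_id` column, ordered by
#'   trajectory then frame.
#' @export
link_frame_by_frame <- function(locs, max_disp_px) {
  stopifnot(max_disp_px > 0,
            all(c("frame", "x_px", "y_px") %in% names(locs)))
  n <- nrow(locs)
  traj <- integer(n)
  if (n == 0L) { locs$traj_id <- integer(0); return(locs) }
  frames <- sort(unique(locs$frame))
  next_id <- 0L
  prev_idx <- integer(0)
  prev_frame <- -Inf
  for (f in frames) {
    cur_idx <- which(locs$frame == f)
    assigned <- rep(FALSE, length(cur_idx))
    if (f == prev_frame + 1L && length(prev_idx)) {
      pairs <- .greedy_pairs(locs$x_px[prev_idx], locs$y_px[prev_idx],
                             locs$x_px[cur_idx], locs$y_px[cur_idx],
                             max_disp_px)
      if (nrow(pairs)) {
        traj[cur_idx[pairs[, 2]]] <- traj[prev_idx[pairs[, 1]]]
        assigned[pairs[, 2]] <- TRUE
      }
    }
    for (i in which(!assigned)) {
      next_id <- next_id + 1L
      traj[cur_idx[i]] <- next_id
    }
    prev_idx <- cur_idx
    prev_frame <- f
  }
  locs$traj_id <- traj
  locs <- locs[order(locs$traj_id, locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  locs
}

# greedy closest-first matching between point sets; returns matrix of
# (index_a, index_b) pairs
.greedy_pairs <- function(xa, ya, xb, yb, max_disp) {
  if (!length(xa) || !length(xb))
    return(matrix(integer(0), 0, 2))
  d <- outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2
  ok <- which(d <= max_disp^2)
  if (!length(ok)) return(matrix(integer(0), 0, 2))
  ia <- (ok - 1L) %% length(xa) + 1L
  ib <- (ok - 1L) %/% length(xa) + 1L
  o <- order(d[ok], ia, ib)
  ia <- ia[o]; ib <- ib[o]
  used_a <- logical(length(xa)); used_b <- logical(length(xb))
  out <- matrix(integer(0), 0, 2)
  for (k in seq_along(ia)) {
    if (used_a[ia[k]] || used_b[ib[k]]) next
    used_a[ia[k]] <- TRUE; used_b[ib[k]] <- TRUE
    out <- rbind(out, c(ia[k], ib[k]))
  }
  out
}

#' Single-bleach-step trace filter
#'
#' Tests whether an intensity trace shows exactly one downward bleaching
#' step. The best one-step piecewise-constant fit is found by exhaustive
#' change-point search; the trace is accepted iff (i) the step is downward
#' and significant against a constant fit, (ii) adding a second change
#' point does not significantly improve the fit (F-test at `alpha`), and
#' (iii) when `background_level` is given, the post-step level lies within
#' 3 residual standard deviations of it.
#'
#' @param intensity Numeric trace (length >= 6), e.g. the `amplitude`
#'   column of one trajectory.
#' @param background_level Optional expected dark level.
#' @param alpha Significance level of the F-tests (default 0.01).
#' @return List with `accept`, `step_frame` (first post-step index),
#'   `pre_level`, `post_level`, `p_step`, `p_second_step`.
#' @export
single_bleach_step_filter <- function(intensity, background_level = NULL,
                                      alpha = 0.01) {
  y <- as.numeric(intensity)
  n <- length(y)
  if (n < 6L) stop("trace must have length >= 6")
  rss_const <- sum((y - mean(y))^2)

  css <- cumsum(y); css2 <- cumsum(y^2)
  seg_rss <- function(i, j) {   # rss of segment i..j around its mean
    s <- css[j] - if (i > 1) css[i - 1] else 0
    s2 <- css2[j] - if (i > 1) css2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # one change point: post segment starts at c, c in 2..n
  rss1 <- vapply(2:n, function(c) seg_rss(1, c - 1) + seg_rss(c, n),
                 numeric(1))
  c1 <- (2:n)[which.min(rss1)]
  rss1_min <- min(rss1)
  # two change points c < d
  rss2_min <- Inf
  if (n >= 3L) {
    for (c in 2:(n - 1)) {
      tail_rss <- vapply((c + 1):n, function(d)
        seg_rss(c, d - 1) + seg_rss(d, n), numeric(1))
      tot <- seg_rss(1, c - 1) + tail_rss
      if (min(tot) < rss2_min) rss2_min <- min(tot)
    }
  }

  pre <- mean(y[1:(c1 - 1)]); post <- mean(y[c1:n])
  scale2 <- mean(y^2) + 1e-300
  # significance of the single step vs a constant trace
  p_step <- if (rss1_min / scale2 < 1e-12) 0 else
    stats::pf(((rss_const - rss1_min) / 2) / (rss1_min / max(n - 3, 1)),
              2, max(n - 3, 1), lower.tail = FALSE)
  # does a second step significantly improve on one step?
  p_second <- if (rss1_min / scale2 < 1e-12) 1 else
    stats::pf(((rss1_min - rss2_min) / 2) / (rss2_min / max(n - 5, 1) + 1e-300),
              2, max(n - 5, 1), lower.tail = FALSE)

  sigma_post <- sqrt(seg_rss(c1, n) / max(n - c1, 1))
  bg_ok <- if (is.null(background_level)) TRUE else
    abs(post - background_level) <= 3 * max(sigma_post, 1e-12)

  accept <- (post < pre) && (p_step < alpha) && (p_second >= alpha) && bg_ok
  list(accept = accept, step_frame = c1, pre_level = pre,
       post_level = post, p_step = p_step, p_second_step = p_second)
}

#' Time-averaged mean square displacement
#'
#' For each lag `k = 1..max_lag`, the mean over all ordered pairs
#' `(i, i + k)` of the squared Euclidean displacement, converted to um^2.
#' The trajectory must span consecutive frames.
#'
#' @param trajectory data.frame with `frame`, `x_px`, `y_px` (one
#'   trajectory; frames strictly increasing by 1).
#' @param pixel_size_um Pixel size (um/px).
#' @param frame_interval_s Frame interval (s).
#' @param max_lag Largest lag K (default 4).
#' @return An `msd_curve`: data.frame `(lag_s, msd_um2, n_pairs)`.
#' @export
compute_msd <- function(trajectory, pixel_size_um = 0.096,
                        frame_interval_s = 0.033, max_lag = 4L) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(trajectory)))
  tr <- trajectory[order(trajectory$frame), , drop = FALSE]
  if (nrow(tr) >= 2 && any(diff(tr$frame) != 1L))
    stop("trajectory frames must be consecutive (no gaps)")
  n <- nrow(tr)
  if (n < max_lag + 1L)
    stop("trajectory too short: need length >= max_lag + 1")
  x <- tr$x_px * pixel_size_um
  y <- tr$y_px * pixel_size_um
  msd <- numeric(max_lag)
  npairs <- integer(max_lag)
  for (k in seq_len(max_lag)) {
    dx <- x[(1 + k):n] - x[1:(n - k)]
    dy <- y[(1 + k):n] - y[1:(n - k)]
    msd[k] <- mean(dx^2 + dy^2)
    npairs[k] <- n - k
  }
  out <- data.frame(lag_s = seq_len(max_lag) * frame_interval_s,
                    msd_um2 = msd, n_pairs = npairs)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of `MSD` on lag time over the first
#' `n_points` lags (default the first four), following `MSD(t) = 4 D t`:
#' `D = slope / 4`. By default the fit has a free intercept (localization
#' noise offsets the MSD); `through_origin = TRUE` forces the zero-intercept
#' form. Negative slopes are reported as-is with `negative_slope = TRUE`.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param n_points Number of initial lags used (default 4).
#' @param through_origin Force a zero intercept? Default `FALSE`.
#' @return List with `d_um2_s`, `intercept_um2`, `n_points_used`,
#'   `negative_slope`.
#' @export
estimate_D <- function(msd, n_points = 4L, through_origin = FALSE) {
  stopifnot(inherits(msd, "msd_curve") || is.data.frame(msd))
  if (nrow(msd) < n_points) stop("msd curve has fewer than n_points lags")
  d <- msd[seq_len(n_points), , drop = FALSE]
  if (through_origin) {
    slope <- sum(d$lag_s * d$msd_um2) / sum(d$lag_s^2)
    icpt <- 0
  } else {
    fit <- stats::lm(msd_um2 ~ lag_s, data = d)
    slope <- unname(stats::coef(fit)[2])
    icpt <- unname(stats::coef(fit)[1])
  }
  list(d_um2_s = slope / 4, intercept_um2 = icpt,
       n_points_used = as.integer(n_points),
       negative_slope = slope < 0)
}

#' Per-trajectory diffusion coefficients for a linked data set
#'
#' Splits a linked localization table by `traj_id`, drops trajectories too
#' short to supply `n_points` MSD lags (count in attribute `n_excluded`),
#' and returns one MSD line fit per remaining trajectory.
#'
#' @param tracks data.frame from [link_frame_by_frame()].
#' @inheritParams compute_msd
#' @inheritParams estimate_D
#' @return data.frame `(traj_id, n_frames, d_um2_s, intercept_um2)` with
#'   attribute `n_excluded`.
#' @export
diffusion_coefficients <- function(tracks, pixel_size_um = 0.096,
                                   frame_interval_s = 0.033,
                                   n_points = 4L, through_origin = FALSE) {
  stopifnot("traj_id" %in% names(tracks))
  split_tr <- split(tracks, tracks$traj_id)
  long <- vapply(split_tr, nrow, integer(1)) >= n_points + 1L
  res <- lapply(split_tr[long], function(tr) {
    msd <- compute_msd(tr, pixel_size_um, frame_interval_s, max_lag = n_points)
    est <- estimate_D(msd, n_points, through_origin)
    data.frame(traj_id = tr$traj_id[1], n_frames = nrow(tr),
               d_um2_s = est$d_um2_s, intercept_um2 = est$intercept_um2)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(traj_id = integer(0), n_frames = integer(0),
               d_um2_s = numeric(0), intercept_um2 = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!long)
  out
}
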