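#' Simulate a FRAP time series
#'
#' Renders one pre-bleach frame, switches emitters inside the bleach ROI
#' dark with probability `bleach_depth` at time zero, then renders frames at
#' the requested post-bleach times while diffusion evolves between frames
#' (Brownian substeps with reflecting boundaries). A fraction
#' `mobile_fraction` of emitters diffuses with the scene's motion model; the
#' remainder is immobile. An optional global acquisition-bleaching factor
#' dims every emitter by `acq_bleach_factor^k` at the k-th acquired frame,
#' which the double normalization of [double_normalize()] must remove.
#'
#' @param spec A [scene_spec()]; `n_frames` is ignored (frames follow
#'   `timepoints_s`).
#' @param bleach_roi An [roi_spec()] rectangle; must intersect the cell.
#' @param bleach_depth Probability that an emitter inside the ROI is
#'   bleached, in `[0, 1]`.
#' @param timepoints_s Strictly increasing post-bleach acquisition times (s).
#' @param measure_box Optional [roi_spec()] measurement box; defaults to a
#'   50 x 50 px box centered on the bleach ROI (clipped to the image).
#' @param pre_bleach_time_s Time of the single pre-bleach frame (< 0).
#' @param mobile_fraction Fraction of emitters that diffuse, in `[0, 1]`.
#' @param acq_bleach_factor Per-frame global intensity decay factor
#'   (1 = none).
#' @param seed Optional seed; defaults to the scene's camera seed.
#' @return A list with `series` (a [frap_series()]) and `truth`
#'   (emitter counts, realized bleached/mobile numbers).
#' @export
simulate_frap_series <- function(spec, bleach_roi, bleach_depth = 1,
                                 timepoints_s = frap_default_times(),
                                 measure_box = NULL,
                                 pre_bleach_time_s = -5,
                                 mobile_fraction = 1,
                                 acq_bleach_factor = 1,
                                 seed = spec$optics$seed) {
  stopifnot(inherits(spec, "scene_spec"), inherits(bleach_roi, "roi_spec"))
  if (!length(timepoints_s)) stop("timepoints_s must be non-empty")
  if (any(diff(timepoints_s) <= 0) || any(timepoints_s <= 0))
    stop("timepoints_s must be strictly increasing and positive")
  if (bleach_depth < 0 || bleach_depth > 1)
    stop("bleach_depth must be in [0, 1]")
  if (pre_bleach_time_s >= 0) stop("pre_bleach_time_s must be < 0")
  if (!is.null(seed)) set.seed(seed)

  mask <- spec$mask
  geometry <- spec$geometry
  center_px <- attr(mask, "center_px")
  shape <- spec$image_shape
  roi_idx <- roi_bounds(bleach_roi, shape)
  if (!any(mask[roi_idx$rows, roi_idx$cols]))
    stop("bleach_roi does not intersect the cell mask")

  em <- sample_emitters(spec$distribution, mask, geometry)
  n <- nrow(em)
  mobile <- stats::runif(n) < mobile_fraction
  p <- cbind(em$x_px, em$y_px)

  in_roi <- em$x_px >= roi_idx$cols[1] - 0.5 &
    em$x_px <= roi_idx$cols[length(roi_idx$cols)] + 0.5 &
    em$y_px >= roi_idx$rows[1] - 0.5 &
    em$y_px <= roi_idx$rows[length(roi_idx$rows)] + 0.5

  frames <- vector("list", length(timepoints_s) + 1L)
  frames[[1]] <- .render_frame(data.frame(x_px = p[, 1], y_px = p[, 2]),
                               shape, spec$optics)

  bleached <- in_roi & stats::runif(n) < bleach_depth
  live <- !bleached

  t_prev <- 0
  for (k in seq_along(timepoints_s)) {
    dt <- timepoints_s[k] - t_prev
    t_prev <- timepoints_s[k]
    idx <- which(live & mobile)
    if (length(idx) && spec$motion$d_um2_s > 0) {
      n_sub <- max(1L, ceiling(dt / 0.1))
      for (s in seq_len(n_sub))
        p[idx, ] <- .diffuse_step(p[idx, , drop = FALSE], dt / n_sub,
                                  spec$motion, geometry, center_px)
    }
    li <- which(live)
    frames[[k + 1L]] <- .render_frame(
      data.frame(x_px = p[li, 1], y_px = p[li, 2]), shape, spec$optics,
      photon_scale = acq_bleach_factor^k)
  }

  if (is.null(measure_box)) {
    cx <- mean(range(roi_idx$cols)); cy <- mean(range(roi_idx$rows))
    x0 <- max(1L, round(cx) - 24L); y0 <- max(1L, round(cy) - 24L)
    w <- min(50L, shape[2] - x0 + 1L); h <- min(50L, shape[1] - y0 + 1L)
    measure_box <- roi_spec("measure", x0, y0, w, h)
  }
  bg <- .auto_background_region(mask)
  series <- frap_series(frames = frames,
                        timepoints_s = c(pre_bleach_time_s, timepoints_s),
                        bleach_roi = bleach_roi, measure_box = measure_box,
                        cell_mask = mask, background_region = bg)
  list(series = series,
       truth = list(n_emitters = n, n_bleached = sum(bleached),
                    n_in_roi = sum(in_roi), mobile = mobile,
                    mobile_fraction = mean(mobile)))
}

#' Post-bleach acquisition times used throughout
#'
#' The 14 standard post-bleach sampling times: every 5 s from 5 to 60 s,
#' then 120 and 180 s.
#' @return Numeric vector of times in seconds.
#' @export
frap_default_times <- function() c(seq(5, 60, by = 5), 120, 180)

# find a small corner rectangle guaranteed outside the cell mask
.auto_background_region <- function(mask, size = 6L) {
  ny <- nrow(mask); nx <- ncol(mask)
  corners <- list(c(1L, 1L), c(1L, nx - size + 1L),
                  c(ny - size + 1L, 1L), c(ny - size + 1L, nx - size + 1L))
  for (cc in corners) {
    rows <- cc[1]:(cc[1] + size - 1L); cols <- cc[2]:(cc[2] + size - 1L)
    if (all(rows >= 1 & rows <= ny) && all(cols >= 1 & cols <= nx) &&
        !any(mask[rows, cols]))
      return(roi_spec("background", cols[1], rows[1], size, size))
  }
  stop("no cell-free corner available for a background region")
}
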