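#' Brownian / confined motion model
#'
#' Free two-dimensional Brownian motion with diffusion coefficient
#' `d_um2_s`: per-frame displacements are isotropic Gaussian with variance
#' `2 * D * dt` per axis, so the free-motion MSD obeys `MSD(t) = 4 D t`.
#' The cell outline acts as a specular reflecting boundary. When
#' `confinement_radius_um` is set, each emitter is additionally reflected at
#' a hard disc of that radius centered on its starting position (the
#' simplest mechanism that produces an MSD plateau, mimicking a tethered
#' membrane protein).
#'
#' @param d_um2_s Diffusion coefficient (um^2/s, >= 0).
#' @param frame_interval_s Time step between frames (s, default 0.033).
#' @param confinement_radius_um Optional trap radius (um); `NULL` = free.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(d_um2_s = 0.1, frame_interval_s = 0.033,
                         confinement_radius_um = NULL) {
  if (d_um2_s < 0) stop("d_um2_s must be >= 0")
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (!is.null(confinement_radius_um) && confinement_radius_um <= 0)
    stop("confinement_radius_um must be > 0 when set")
  structure(list(d_um2_s = d_um2_s, frame_interval_s = frame_interval_s,
                 confinement_radius_um = confinement_radius_um),
            class = "motion_model")
}

# Reflect points (n x 2, px) back into the spherocylinder; specular
# reflection about the nearest boundary point, iterated for safety.
# The effective radius sits ~0.71 px inside the outline so that every
# reflected position rounds onto a pixel of the rasterized mask.
.reflect_into_cell <- function(p, geometry, center_px) {
  r <- .radius_px(geometry)
  r <- max(r - 0.71, 0.3 * r)
  u <- .axis_vector(geometry)
  hl <- .axis_half_length_px(geometry)
  for (it in 1:12) {
    dx <- p[, 1] - center_px[1]
    dy <- p[, 2] - center_px[2]
    proj <- pmin(pmax(dx * u[1] + dy * u[2], -hl), hl)
    cx <- center_px[1] + proj * u[1]
    cy <- center_px[2] + proj * u[2]
    d <- sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2)
    out <- which(d > r)
    if (!length(out)) break
    dd <- d[out]
    f <- (2 * r - dd) / dd        # mirror: c + (2r - d) * unit
    # pathological overshoot (d > 2r): clamp just inside the boundary
    f[dd >= 2 * r] <- 0.999 * r / dd[dd >= 2 * r]
    p[out, 1] <- cx[out] + f * (p[out, 1] - cx[out])
    p[out, 2] <- cy[out] + f * (p[out, 2] - cy[out])
  }
  p
}

# Reflect points into per-emitter discs (centers n x 2, radius px)
.reflect_into_disc <- function(p, centers, radius_px) {
  for (it in 1:12) {
    dx <- p[, 1] - centers[, 1]
    dy <- p[, 2] - centers[, 2]
    d <- sqrt(dx^2 + dy^2)
    out <- which(d > radius_px)
    if (!length(out)) break
    dd <- d[out]
    f <- (2 * radius_px - dd) / dd
    f[dd >= 2 * radius_px] <- 0.999 * radius_px / dd[dd >= 2 * radius_px]
    p[out, 1] <- centers[out, 1] + f * dx[out]
    p[out, 2] <- centers[out, 2] + f * dy[out]
  }
  p
}

# One diffusion step of duration dt_s for positions p (n x 2, px units)
.diffuse_step <- function(p, dt_s, motion, geometry, center_px,
                          trap_centers = NULL) {
  n <- nrow(p)
  if (n == 0L || motion$d_um2_s == 0) return(p)
  sd_px <- sqrt(2 * motion$d_um2_s * dt_s) / geometry$pixel_size_um
  p2 <- p + matrix(stats::rnorm(2 * n, 0, sd_px), ncol = 2)
  p2 <- .reflect_into_cell(p2, geometry, center_px)
  if (!is.null(motion$confinement_radius_um) && !is.null(trap_centers)) {
    # the tether wins over the cell boundary: confinement is applied last
    rc_px <- motion$confinement_radius_um / geometry$pixel_size_um
    p2 <- .reflect_into_disc(p2, trap_centers, rc_px)
  }
  p2
}

#' Simulate ground-truth emitter trajectories
#'
#' Draws starting positions from the scene's emitter distribution, then
#' propagates each emitter by Brownian steps with reflecting boundaries
#' (cell outline, plus the optional confinement disc centered on the
#' starting position). Photobleaching is a per-frame Bernoulli event with
#' probability `optics$bleach_prob_per_frame`; a bleached emitter goes
#' permanently dark and emits no further localizations.
#'
#' @param spec A [scene_spec()].
#' @param seed Optional integer seed; defaults to the scene's camera seed.
#' @return A data.frame `(emitter_id, frame, x_px, y_px)` with one row per
#'   live emitter per frame, plus attributes `bleach_frame` (first dark
#'   frame per emitter, `Inf` if never) and `mask`.
#' @export
simulate_trajectories <- function(spec, seed = spec$optics$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  mask <- spec$mask
  geometry <- spec$geometry
  center_px <- attr(mask, "center_px")
  em <- sample_emitters(spec$distribution, mask, geometry)
  n <- nrow(em)
  nf <- spec$n_frames
  b <- spec$optics$bleach_prob_per_frame
  # frames survived: emitter visible in frames 1..vis
  vis <- if (b > 0) pmin(1L + stats::rgeom(n, b), nf) else rep(nf, n)
  # a rgeom draw of 0 means the emitter bleaches right after frame 1
  p <- cbind(em$x_px, em$y_px)
  trap <- p
  rows <- vector("list", nf)
  alive <- rep(TRUE, n)
  for (f in seq_len(nf)) {
    if (f > 1L) {
      alive <- vis >= f
      idx <- which(alive)
      if (length(idx))
        p[idx, ] <- .diffuse_step(p[idx, , drop = FALSE],
                                  spec$motion$frame_interval_s, spec$motion,
                                  geometry, center_px,
                                  trap_centers = trap[idx, , drop = FALSE])
    }
    idx <- which(alive)
    if (length(idx))
      rows[[f]] <- data.frame(emitter_id = idx, frame = f,
                              x_px = p[idx, 1], y_px = p[idx, 2])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(emitter_id = integer(0), frame = integer(0),
               x_px = numeric(0), y_px = numeric(0))
  out <- out[order(out$emitter_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bleach_frame") <- ifelse(vis >= nf, Inf, vis + 1)
  attr(out, "mask") <- mask
  out
}
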