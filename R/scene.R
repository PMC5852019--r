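#' Photophysics and camera model
#'
#' Emission and detection parameters for rendering: each live emitter
#' contributes `photons_per_frame` expected counts spread over an isotropic
#' 2D Gaussian PSF of width `psf_sigma_px`; a constant `background_level`
#' is added; the expected image is Poisson-sampled (shot noise) and Gaussian
#' read noise of s.d. `read_noise_sd` is added. Set `shot_noise = FALSE`
#' for noiseless expected-value renders.
#'
#' @param photons_per_frame Mean signal photons per emitter per frame.
#' @param psf_sigma_px Gaussian PSF standard deviation (pixels).
#' @param bleach_prob_per_frame Per-frame probability of irreversible
#'   photobleaching, in `[0, 1]`.
#' @param background_level Mean background counts per pixel.
#' @param read_noise_sd Gaussian read noise s.d. (counts).
#' @param shot_noise Apply Poisson sampling? Default `TRUE`.
#' @param seed Integer RNG seed carried by the scene; identical seed and
#'   scene specification give bit-identical output.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(photons_per_frame = 2000, psf_sigma_px = 1.3,
                         bleach_prob_per_frame = 0, background_level = 10,
                         read_noise_sd = 1, shot_noise = TRUE, seed = 1L) {
  if (photons_per_frame < 0 || background_level < 0 || read_noise_sd < 0)
    stop("photon, background and read-noise rates must be >= 0")
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (bleach_prob_per_frame < 0 || bleach_prob_per_frame > 1)
    stop("bleach_prob_per_frame must be in [0, 1]")
  structure(list(photons_per_frame = photons_per_frame,
                 psf_sigma_px = psf_sigma_px,
                 bleach_prob_per_frame = bleach_prob_per_frame,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 seed = seed),
            class = "camera_model")
}

#' Full synthetic-scene specification
#'
#' Bundles geometry, emitter distribution, motion, photophysics/camera and
#' frame count into the ground-truth description of one synthetic movie.
#' `channel_coupling` (two-channel scenes) is the fraction of channel-B
#' clusters placed at channel-A cluster sites, emulating toxin-induced
#' co-clustering of outer- and inner-membrane proteins.
#'
#' @param geometry A [cell_geometry()].
#' @param distribution An [emitter_distribution()].
#' @param motion A [motion_model()].
#' @param optics A [camera_model()].
#' @param n_frames Number of frames (>= 1).
#' @param channel_coupling Optional fraction in `[0, 1]`.
#' @param image_shape `c(rows, cols)`; default fits the cell with margin.
#' @return An object of class `scene_spec` (carries the rasterized mask).
#' @export
scene_spec <- function(geometry, distribution, motion = motion_model(),
                       optics = camera_model(), n_frames = 1,
                       channel_coupling = NULL, image_shape = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(distribution, "emitter_distribution"),
            inherits(motion, "motion_model"),
            inherits(optics, "camera_model"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(channel_coupling) &&
      (channel_coupling < 0 || channel_coupling > 1))
    stop("channel_coupling must be in [0, 1]")
  if (is.null(image_shape)) image_shape <- .default_image_shape(geometry)
  mask <- render_cell_mask(geometry, image_shape)
  structure(list(geometry = geometry, distribution = distribution,
                 motion = motion, optics = optics,
                 n_frames = as.integer(n_frames),
                 channel_coupling = channel_coupling,
                 image_shape = as.integer(image_shape), mask = mask),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("<scene_spec> %d frame(s), %dx%d px, %s emitters (n=%d), ",
                     "D=%.3g um2/s\n"),
              x$n_frames, x$image_shape[1], x$image_shape[2],
              x$distribution$mode, x$distribution$n_emitters,
              x$motion$d_um2_s))
  invisible(x)
}

# Render expected photon counts for emitters at (x, y) with per-emitter
# photon budgets, on an ny x nx image (no background, no noise).
.render_psf_sum <- function(x, y, photons, shape, psf_sigma_px) {
  ny <- shape[1]; nx <- shape[2]
  img <- matrix(0, ny, nx)
  if (!length(x)) return(img)
  w <- ceiling(4 * psf_sigma_px)
  amp <- photons / (2 * pi * psf_sigma_px^2)
  for (k in seq_along(x)) {
    j0 <- max(1L, floor(x[k]) - w); j1 <- min(nx, ceiling(x[k]) + w)
    i0 <- max(1L, floor(y[k]) - w); i1 <- min(ny, ceiling(y[k]) + w)
    if (j0 > j1 || i0 > i1) next
    ex <- exp(-((j0:j1) - x[k])^2 / (2 * psf_sigma_px^2))
    ey <- exp(-((i0:i1) - y[k])^2 / (2 * psf_sigma_px^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp[k] * (ey %o% ex)
  }
  img
}

# Apply background + shot noise + read noise to an expected image
.apply_camera_noise <- function(expected, optics) {
  img <- expected + optics$background_level
  if (optics$shot_noise)
    img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                  nrow(img), ncol(img))
  if (optics$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, optics$read_noise_sd),
                        nrow(img), ncol(img))
  img
}

# Render one frame from emitter positions (data.frame x_px, y_px)
.render_frame <- function(positions, shape, optics, photon_scale = 1) {
  expected <- .render_psf_sum(positions$x_px, positions$y_px,
                              rep(optics$photons_per_frame * photon_scale,
                                  nrow(positions)),
                              shape, optics$psf_sigma_px)
  .apply_camera_noise(expected, optics)
}

#' Render a synthetic single-molecule movie
#'
#' Simulates ground-truth trajectories with [simulate_trajectories()] and
#' renders each frame: Gaussian PSFs at the live emitter positions scaled to
#' the photon budget, constant background, Poisson shot noise and Gaussian
#' read noise.
#'
#' @param spec A [scene_spec()].
#' @param seed Optional seed; defaults to the scene's camera seed.
#' @return A list with `frames` (list of matrices), `truth` (the trajectory
#'   table of [simulate_trajectories()]) and `spec`.
#' @export
render_movie <- function(spec, seed = spec$optics$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_trajectories(spec, seed = NULL)
  frames <- lapply(seq_len(spec$n_frames), function(f) {
    .render_frame(truth[truth$frame == f, , drop = FALSE],
                  spec$image_shape, spec$optics)
  })
  list(frames = frames, truth = truth, spec = spec)
}

#' Render a two-channel co-clustering scene
#'
#' Channel A receives `n_clusters` clusters placed uniformly in the cell; a
#' binomial fraction `channel_coupling` of channel-B clusters is centered on
#' the corresponding channel-A sites (pairwise), the rest placed
#' independently. Both channels are rendered as single frames with the
#' scene's camera model.
#'
#' @param spec A [scene_spec()] with `channel_coupling` set and a
#'   `clustered` emitter distribution.
#' @param seed Optional seed; defaults to the scene's camera seed.
#' @return A list with `channel_a`, `channel_b` (matrices), and `truth`
#'   containing cluster centers, the per-cluster `coupled` flags and the
#'   realized `coupled_fraction`.
#' @export
render_two_channel_scene <- function(spec, seed = spec$optics$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(spec$channel_coupling))
    stop("spec$channel_coupling must be set for two-channel scenes")
  if (spec$distribution$mode != "clustered")
    stop("two-channel scenes require a clustered emitter distribution")
  if (!is.null(seed)) set.seed(seed)
  mask <- spec$mask
  geometry <- spec$geometry

  em_a <- sample_emitters(spec$distribution, mask, geometry)
  centers_a <- attr(em_a, "cluster_centers")
  k <- spec$distribution$n_clusters
  coupled <- stats::runif(k) < spec$channel_coupling

  # channel-B centers: coupled ones coincide with the paired A site
  em_b_free <- sample_emitters(spec$distribution, mask, geometry)
  centers_b <- attr(em_b_free, "cluster_centers")
  centers_b[coupled, ] <- centers_a[coupled, ]
  # re-draw B emitters around the final centers
  sig_px <- spec$distribution$cluster_sigma_um / geometry$pixel_size_um
  cl <- em_b_free$cluster
  n_b <- nrow(em_b_free)
  pos <- matrix(NA_real_, n_b, 2)
  todo <- seq_len(n_b)
  center_px <- attr(mask, "center_px")
  iter <- 0
  while (length(todo)) {
    iter <- iter + 1
    if (iter > 2000) stop("two-channel sampling failed")
    p <- as.matrix(centers_b[cl[todo], , drop = FALSE]) +
      matrix(stats::rnorm(2 * length(todo), 0, sig_px), ncol = 2)
    keep <- .inside_cell(geometry, p[, 1], p[, 2], center_px) &
      .on_mask(mask, p[, 1], p[, 2])
    pos[todo[keep], ] <- p[keep, , drop = FALSE]
    todo <- todo[!keep]
  }
  em_b <- data.frame(x_px = pos[, 1], y_px = pos[, 2], cluster = cl)

  channel_a <- .render_frame(em_a, spec$image_shape, spec$optics)
  channel_b <- .render_frame(em_b, spec$image_shape, spec$optics)
  list(channel_a = channel_a, channel_b = channel_b,
       truth = list(centers_a = centers_a, centers_b = centers_b,
                    coupled = coupled,
                    coupled_fraction = mean(coupled),
                    emitters_a = em_a, emitters_b = em_b),
       spec = spec)
}
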