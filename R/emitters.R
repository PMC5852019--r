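#' Emitter spatial distribution
#'
#' Describes how fluorophore-tagged molecules are laid out in the cell:
#' `uniform` over the cell body, `clustered` (uniform cluster centers with
#' isotropic Gaussian spread), `septal` (an axial Gaussian band at mid-cell,
#' emulating divisome recruitment) or `polar` (a 50/50 mixture of axial
#' Gaussians at the two poles).
#'
#' @param mode One of `"uniform"`, `"clustered"`, `"septal"`, `"polar"`.
#' @param n_emitters Number of emitters (>= 0).
#' @param n_clusters Number of clusters (clustered mode, >= 1).
#' @param cluster_sigma_um Isotropic cluster spread (um).
#' @param septal_sigma_frac Axial s.d. of the mid-cell band, as a fraction
#'   of cell length.
#' @param polar_sigma_frac Axial s.d. of each polar cap band, as a fraction
#'   of cell length.
#' @return An object of class `emitter_distribution`.
#' @export
emitter_distribution <- function(mode = c("uniform", "clustered", "septal", "polar"),
                                 n_emitters = 100,
                                 n_clusters = 1,
                                 cluster_sigma_um = 0.1,
                                 septal_sigma_frac = 0.05,
                                 polar_sigma_frac = 0.05) {
  mode <- match.arg(mode)
  if (n_emitters < 0) stop("n_emitters must be >= 0")
  if (mode == "clustered" && n_clusters < 1)
    stop("clustered mode requires n_clusters >= 1")
  structure(list(mode = mode, n_emitters = as.integer(n_emitters),
                 n_clusters = as.integer(n_clusters),
                 cluster_sigma_um = cluster_sigma_um,
                 septal_sigma_frac = septal_sigma_frac,
                 polar_sigma_frac = polar_sigma_frac),
            class = "emitter_distribution")
}

# rejection-sample `n` continuous points from `propose(m)` (returns m x 2)
# that fall inside both the continuous outline and the rasterized mask
.rejection_sample <- function(n, propose, geometry, mask, center_px) {
  out <- matrix(numeric(0), 0, 2)
  iter <- 0
  while (nrow(out) < n) {
    iter <- iter + 1
    if (iter > 2000) stop("emitter sampling failed: acceptance region empty?")
    m <- max(2L * (n - nrow(out)), 16L)
    p <- propose(m)
    keep <- .inside_cell(geometry, p[, 1], p[, 2], center_px) &
      .on_mask(mask, p[, 1], p[, 2])
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample emitter positions
#'
#' Draws i.i.d. continuous emitter positions from the stated distribution
#' mode, constrained to lie inside the rasterized cell mask (positions are
#' resampled until they do).
#'
#' @param distribution An [emitter_distribution()].
#' @param mask Binary cell mask from [render_cell_mask()].
#' @param geometry The [cell_geometry()] (defaults to the mask attribute).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `x_px`, `y_px` and `cluster` (cluster
#'   index in clustered mode, `NA` otherwise), plus attribute
#'   `cluster_centers` in clustered mode.
#' @export
sample_emitters <- function(distribution, mask,
                            geometry = attr(mask, "geometry"),
                            seed = NULL) {
  stopifnot(inherits(distribution, "emitter_distribution"))
  if (is.null(geometry)) stop("mask carries no geometry; pass `geometry`")
  center_px <- attr(mask, "center_px")
  if (is.null(center_px)) center_px <- c((ncol(mask) + 1) / 2, (nrow(mask) + 1) / 2)
  if (!is.null(seed)) set.seed(seed)
  n <- distribution$n_emitters
  if (n == 0L)
    return(data.frame(x_px = numeric(0), y_px = numeric(0), cluster = integer(0)))
  if (!any(mask)) stop("cannot place emitters: cell mask is empty")

  ps <- geometry$pixel_size_um
  r_px <- .radius_px(geometry)
  hl <- .axis_half_length_px(geometry)
  L_px <- geometry$length_um / ps
  u <- .axis_vector(geometry)
  v <- c(-u[2], u[1])

  bbox_propose <- function(m) {
    ext <- hl + r_px
    cbind(stats::runif(m, center_px[1] - ext, center_px[1] + ext),
          stats::runif(m, center_px[2] - ext, center_px[2] + ext))
  }
  axial_propose <- function(centers_ax_px, sigma_ax_px) {
    force(centers_ax_px); force(sigma_ax_px)
    function(m) {
      a <- sample(centers_ax_px, m, replace = TRUE) +
        stats::rnorm(m, 0, sigma_ax_px)
      t <- stats::runif(m, -r_px, r_px)
      cbind(center_px[1] + a * u[1] + t * v[1],
            center_px[2] + a * u[2] + t * v[2])
    }
  }

  cluster <- rep(NA_integer_, n)
  centers <- NULL
  pos <- switch(distribution$mode,
    uniform = .rejection_sample(n, bbox_propose, geometry, mask, center_px),
    clustered = {
      k <- distribution$n_clusters
      centers <- .rejection_sample(k, bbox_propose, geometry, mask, center_px)
      cluster <- sample.int(k, n, replace = TRUE)
      sig_px <- distribution$cluster_sigma_um / ps
      out <- matrix(NA_real_, n, 2)
      todo <- seq_len(n)
      iter <- 0
      while (length(todo)) {
        iter <- iter + 1
        if (iter > 2000) stop("emitter sampling failed: cluster spread outside mask?")
        p <- centers[cluster[todo], , drop = FALSE] +
          matrix(stats::rnorm(2 * length(todo), 0, sig_px), ncol = 2)
        keep <- .inside_cell(geometry, p[, 1], p[, 2], center_px) &
          .on_mask(mask, p[, 1], p[, 2])
        out[todo[keep], ] <- p[keep, , drop = FALSE]
        todo <- todo[!keep]
      }
      out
    },
    septal = .rejection_sample(
      n, axial_propose(0, distribution$septal_sigma_frac * L_px),
      geometry, mask, center_px),
    polar = .rejection_sample(
      n, axial_propose(c(-L_px / 2, L_px / 2),
                       distribution$polar_sigma_frac * L_px),
      geometry, mask, center_px)
  )
  res <- data.frame(x_px = pos[, 1], y_px = pos[, 2], cluster = cluster)
  if (!is.null(centers))
    attr(res, "cluster_centers") <- data.frame(x_px = centers[, 1],
                                               y_px = centers[, 2])
  res
}
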