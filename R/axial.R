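#' Threshold and clean an image into labeled cell regions
#'
#' Pixels at or above a user-chosen intensity become foreground; high
#' frequency noise is then reduced with a 3x3 median (majority) filter on
#' the binary image (zero-padded borders), and the surviving foreground is
#' labeled into 8-connected regions.
#'
#' @param image Image matrix.
#' @param user_threshold Intensity threshold; must lie within the image's
#'   intensity range.
#' @return List with `mask` (logical), `labels` (integer matrix) and
#'   `n_regions`.
#' @export
binarize_and_clean <- function(image, user_threshold) {
  stopifnot(is.matrix(image))
  if (user_threshold > max(image))
    stop("user_threshold outside the image intensity range (above the ",
         "maximum ", signif(max(image), 4), "): nothing would survive")
  binary <- image >= user_threshold
  cleaned <- .binary_median3(binary)
  if (!any(cleaned)) stop("empty mask after thresholding and cleaning")
  labels <- label_components(cleaned)
  list(mask = cleaned, labels = labels, n_regions = max(labels))
}

# 3x3 median filter on a binary image = majority vote of the 9-neighborhood,
# with edge replication so constant images stay constant
.binary_median3 <- function(b) {
  ny <- nrow(b); nx <- ncol(b)
  p <- matrix(0L, ny + 2L, nx + 2L)
  p[2:(ny + 1), 2:(nx + 1)] <- b
  p[1, ] <- p[2, ]; p[ny + 2, ] <- p[ny + 1, ]
  p[, 1] <- p[, 2]; p[, nx + 2] <- p[, nx + 1]
  s <- p[1:ny, 1:nx] + p[1:ny, 2:(nx + 1)] + p[1:ny, 3:(nx + 2)] +
    p[2:(ny + 1), 1:nx] + p[2:(ny + 1), 2:(nx + 1)] + p[2:(ny + 1), 3:(nx + 2)] +
    p[3:(ny + 2), 1:nx] + p[3:(ny + 2), 2:(nx + 1)] + p[3:(ny + 2), 3:(nx + 2)]
  s >= 5L
}

#' Identify the poles of a cell region
#'
#' The poles are the two pixels of a connected region with the largest
#' mutual separation. The search is exact: for large regions it is
#' restricted to the convex hull of the pixel set (which contains the
#' diameter); ties are broken deterministically toward the pair whose first
#' pole has the smallest (row, column).
#'
#' @param mask Logical matrix of one connected region, or a label matrix
#'   with `region_id`.
#' @param region_id Label to extract when `mask` is a label matrix.
#' @return A `pole_pair`: list with `pole1_px`, `pole2_px` (each `(x, y)`),
#'   `separation_px`, `region_id`.
#' @export
find_poles <- function(mask, region_id = NULL) {
  stopifnot(is.matrix(mask))
  if (!is.null(region_id)) mask <- mask == region_id
  idx <- which(mask != 0, arr.ind = TRUE)   # (row, col)
  if (nrow(idx) < 2) stop("region needs >= 2 pixels to define poles")
  pts <- idx
  if (nrow(pts) > 400) {
    hull <- tryCatch(grDevices::chull(pts[, 2], pts[, 1]),
                     error = function(e) seq_len(nrow(pts)))
    if (length(hull) >= 2) pts <- pts[hull, , drop = FALSE]
  }
  n <- nrow(pts)
  d2 <- (outer(pts[, 1], pts[, 1], "-"))^2 + (outer(pts[, 2], pts[, 2], "-"))^2
  best <- max(d2)
  cand <- which(d2 >= best - 1e-9, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  # normalize pair order: pole1 = lexicographically smaller (row, col)
  key <- t(apply(cand, 1, function(p) {
    a <- pts[p[1], ]; b <- pts[p[2], ]
    if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) c(a, b) else c(b, a)
  }))
  o <- order(key[, 1], key[, 2], key[, 3], key[, 4])
  k <- key[o[1], ]
  structure(list(pole1_px = c(x = unname(k[2]), y = unname(k[1])),
                 pole2_px = c(x = unname(k[4]), y = unname(k[3])),
                 separation_px = sqrt(best),
                 region_id = region_id),
            class = "pole_pair")
}

#' Pole-to-pole cell length
#'
#' The straight-line distance from one pole to the other, in micrometres.
#'
#' @param pole_pair A `pole_pair` from [find_poles()].
#' @param pixel_size_um Pixel size (um/px).
#' @return Length in micrometres.
#' @export
cell_length <- function(pole_pair, pixel_size_um = 0.096) {
  stopifnot(inherits(pole_pair, "pole_pair"))
  pole_pair$separation_px * pixel_size_um
}

#' Axial fluorescence profile of a cell
#'
#' Samples the image by bilinear interpolation along 11 lines parallel to
#' the pole-to-pole axis (offsets uniformly spaced and symmetric about it),
#' averages the lines pointwise, and resamples the mean profile onto 101
#' positions covering 0-100% of the pole separation so that profiles of
#' different cells are comparable. Offsets default to spanning the cell
#' width (`width / (n_offsets - 1)` spacing estimated from `mask`).
#' Sampling positions that leave the image are clipped to the border, with
#' a warning.
#'
#' @param image Image matrix.
#' @param pole_pair A `pole_pair` from [find_poles()].
#' @param n_offsets Number of parallel lines (default 11).
#' @param offset_spacing_px Spacing between adjacent lines (px); default
#'   derives it from `mask`, or 1 px when no mask is given.
#' @param mask Optional region mask used to estimate the cell width.
#' @param background Constant subtracted from the sampled intensities.
#' @param n_positions Number of axial sample positions (default 101).
#' @param normalize_intensity Additionally min-max scale the intensity to
#'   0-100? Default `FALSE` (the 0-100 normalization is positional).
#' @return An `axial_profile`: data.frame `(position_pct, intensity)` with
#'   attributes `pole_pair`, `offsets_px`.
#' @export
extract_axial_profile <- function(image, pole_pair, n_offsets = 11L,
                                  offset_spacing_px = NULL, mask = NULL,
                                  background = 0, n_positions = 101L,
                                  normalize_intensity = FALSE) {
  stopifnot(is.matrix(image), inherits(pole_pair, "pole_pair"))
  p1 <- pole_pair$pole1_px; p2 <- pole_pair$pole2_px
  axis_vec <- c(p2[["x"]] - p1[["x"]], p2[["y"]] - p1[["y"]])
  len <- sqrt(sum(axis_vec^2))
  if (len == 0) stop("degenerate pole pair")
  u <- axis_vec / len
  v <- c(-u[2], u[1])
  if (is.null(offset_spacing_px)) {
    offset_spacing_px <- if (!is.null(mask)) {
      idx <- which(mask != 0, arr.ind = TRUE)
      perp <- abs((idx[, 2] - p1[["x"]]) * v[1] + (idx[, 1] - p1[["y"]]) * v[2])
      width <- 2 * max(perp)
      if (width > 0) width / (n_offsets - 1) else 1
    } else 1
  }
  offs <- (seq_len(n_offsets) - (n_offsets + 1) / 2) * offset_spacing_px
  s <- seq(0, 1, length.out = n_positions)
  prof <- matrix(0, n_positions, n_offsets)
  clipped <- FALSE
  for (j in seq_len(n_offsets)) {
    xs <- p1[["x"]] + s * axis_vec[1] + offs[j] * v[1]
    ys <- p1[["y"]] + s * axis_vec[2] + offs[j] * v[2]
    if (any(xs < 1 | xs > ncol(image) | ys < 1 | ys > nrow(image)))
      clipped <- TRUE
    prof[, j] <- .interp_bilinear(image, xs, ys, outside = "clamp")
  }
  if (clipped)
    warning("offset lines leave the image; samples clipped to the border")
  intensity <- rowMeans(prof) - background
  if (normalize_intensity) {
    rg <- range(intensity)
    intensity <- if (diff(rg) > 0) 100 * (intensity - rg[1]) / diff(rg)
                 else rep(0, length(intensity))
  }
  out <- data.frame(position_pct = 100 * s, intensity = intensity)
  class(out) <- c("axial_profile", "data.frame")
  attr(out, "pole_pair") <- pole_pair
  attr(out, "offsets_px") <- offs
  out
}

#' Septal and polar distribution indices of an axial profile
#'
#' Formalizes the mid-cell vs polar readout of an axial profile: the septal
#' index is the mean intensity over the central `central_frac` of positions
#' divided by the overall mean; the polar index is the mean over the two
#' outer `polar_frac` windows divided by the overall mean. Both equal 1 for
#' a flat profile.
#'
#' @param profile An `axial_profile`.
#' @param central_frac Width of the mid-cell window as a fraction of cell
#'   length (default 0.2).
#' @param polar_frac Width of each polar window (default 0.1).
#' @param cell_length_um Optional cell length to carry through.
#' @return List with `septal_index`, `polar_index`, `cell_length_um`.
#' @export
distribution_stats <- function(profile, central_frac = 0.2,
                               polar_frac = 0.1, cell_length_um = NA_real_) {
  stopifnot(inherits(profile, "axial_profile"))
  pos <- profile$position_pct
  v <- profile$intensity
  if (!all(is.finite(v))) stop("profile contains non-finite intensities")
  m <- mean(v)
  if (abs(m) < 1e-12) stop("undefined indices: profile mean is zero")
  half <- 100 * central_frac / 2
  central <- abs(pos - 50) <= half
  polar <- pos <= 100 * polar_frac | pos >= 100 * (1 - polar_frac)
  list(septal_index = mean(v[central]) / m,
       polar_index = mean(v[polar]) / m,
       cell_length_um = cell_length_um)
}
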