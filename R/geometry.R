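#' Spherocylindrical cell geometry
#'
#' Describes a rod-shaped bacterium as a spherocylinder (a rectangle capped
#' by two semicircles): total pole-to-pole length `length_um`, cap radius
#' `radius_um`, sampled at `pixel_size_um` per pixel and rotated in-plane by
#' `orientation_deg`.
#'
#' The package uses 1-based pixel coordinates with pixel centers at integer
#' positions; point coordinates are `(x = column, y = row)`. Physical
#' distances are pixel distances multiplied by `pixel_size_um`.
#'
#' @param length_um Pole-to-pole cell length in micrometres. Must exceed
#'   `2 * radius_um`.
#' @param radius_um Cap (half-width) radius in micrometres.
#' @param pixel_size_um Pixel sampling in micrometres per pixel
#'   (default 0.096, a typical EMCCD pixel in the magnified image).
#' @param orientation_deg In-plane rotation of the long axis, degrees
#'   counter-clockwise from the image x (column) axis.
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry(length_um = 3, radius_um = 0.5)
#' mask <- render_cell_mask(geom, c(64, 64))
#' sum(mask)
#' @export
cell_geometry <- function(length_um = 3, radius_um = 0.5,
                          pixel_size_um = 0.096, orientation_deg = 0) {
  stopifnot(is.numeric(length_um), length(length_um) == 1L, is.finite(length_um),
            is.numeric(radius_um), length(radius_um) == 1L, is.finite(radius_um),
            is.numeric(pixel_size_um), length(pixel_size_um) == 1L)
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (radius_um <= 0) stop("radius_um must be > 0")
  if (length_um <= 2 * radius_um)
    stop("invalid geometry: length_um must exceed 2 * radius_um ",
         "(a spherocylinder needs a positive cylindrical segment)")
  structure(list(length_um = length_um, radius_um = radius_um,
                 pixel_size_um = pixel_size_um,
                 orientation_deg = orientation_deg),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> %.3g x %.3g um (radius), %.3g um/px, %g deg\n",
              x$length_um, x$radius_um, x$pixel_size_um, x$orientation_deg))
  invisible(x)
}

# unit axis vector (x, y) of the long axis
.axis_vector <- function(geometry) {
  th <- geometry$orientation_deg * pi / 180
  c(cos(th), sin(th))
}

# half-length between the two cap centers, in pixels
.axis_half_length_px <- function(geometry) {
  (geometry$length_um / 2 - geometry$radius_um) / geometry$pixel_size_um
}

.radius_px <- function(geometry) geometry$radius_um / geometry$pixel_size_um

# Vectorized distance (in px) from points (x, y) to the axis segment of the
# cell centered at center_px = c(x, y).
.dist_to_axis_px <- function(geometry, x, y, center_px) {
  u <- .axis_vector(geometry)
  hl <- .axis_half_length_px(geometry)
  dx <- x - center_px[1]
  dy <- y - center_px[2]
  proj <- pmin(pmax(dx * u[1] + dy * u[2], -hl), hl)
  sqrt((dx - proj * u[1])^2 + (dy - proj * u[2])^2)
}

# TRUE for continuous points inside the spherocylinder outline
.inside_cell <- function(geometry, x, y, center_px) {
  .dist_to_axis_px(geometry, x, y, center_px) <= .radius_px(geometry)
}

# signed axial coordinate (px along the long axis, 0 at cell center);
# ranges over [-L/2, L/2] in px units for points inside the cell
.axial_coord_px <- function(geometry, x, y, center_px) {
  u <- .axis_vector(geometry)
  (x - center_px[1]) * u[1] + (y - center_px[2]) * u[2]
}

# default image shape (rows, cols) that fits the cell with margin
.default_image_shape <- function(geometry, margin_px = 8) {
  u <- .axis_vector(geometry)
  hl <- .axis_half_length_px(geometry)
  r <- .radius_px(geometry)
  ext_x <- hl * abs(u[1]) + r
  ext_y <- hl * abs(u[2]) + r
  c(2 * ceiling(ext_y + margin_px) + 1, 2 * ceiling(ext_x + margin_px) + 1)
}

#' Rasterize a cell outline into a binary mask
#'
#' Renders the spherocylinder as a logical matrix over an image of the given
#' shape: a pixel belongs to the mask when its center lies within
#' `radius_um` of the cell's long-axis segment. The result is a single
#' 8-connected region.
#'
#' @param geometry A [cell_geometry()].
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param center_px Cell center as `c(x, y)` in pixel coordinates; defaults
#'   to the image center.
#' @return Logical matrix of dimension `image_shape`, with attributes
#'   `geometry` and `center_px`.
#' @export
render_cell_mask <- function(geometry, image_shape, center_px = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"),
            length(image_shape) == 2L, all(image_shape >= 1))
  ny <- as.integer(image_shape[1]); nx <- as.integer(image_shape[2])
  if (is.null(center_px)) center_px <- c((nx + 1) / 2, (ny + 1) / 2)
  u <- .axis_vector(geometry)
  hl <- .axis_half_length_px(geometry)
  r <- .radius_px(geometry)
  ext_x <- hl * abs(u[1]) + r
  ext_y <- hl * abs(u[2]) + r
  if (center_px[1] - ext_x < 3 || center_px[1] + ext_x > nx - 2 ||
      center_px[2] - ext_y < 3 || center_px[2] + ext_y > ny - 2)
    stop("cell exceeds image bounds: the outline must fit with >= 2 px margin")
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  mask <- .dist_to_axis_px(geometry, xs, ys, center_px) <= r
  attr(mask, "geometry") <- geometry
  attr(mask, "center_px") <- center_px
  mask
}

# TRUE where continuous point (x, y) rounds onto a TRUE mask pixel
.on_mask <- function(mask, x, y) {
  i <- round(y); j <- round(x)
  ok <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
  out <- logical(length(x))
  out[ok] <- mask[cbind(i[ok], j[ok])]
  out
}
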