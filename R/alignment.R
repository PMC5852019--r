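#' Bead-based two-channel similarity alignment
#'
#' Least-squares 2D similarity transform (translation, proper rotation,
#' single isotropic scale) mapping channel-B bead coordinates onto their
#' matched channel-A partners: `a ~ s R b + t`, solved in closed form via
#' the SVD of the cross-covariance (Umeyama/Procrustes solution with the
#' reflection excluded).
#'
#' @param bead_xy_a,bead_xy_b Matched n x 2 coordinate tables `(x, y)` in
#'   px; n >= 2, not all coincident.
#' @return A `channel_alignment`: list with `shift_px` `(x, y)`,
#'   `rotation_deg`, `magnification`, `rms_residual_px` and the 2 x 2
#'   rotation matrix `rotation`.
#' @export
estimate_channel_alignment <- function(bead_xy_a, bead_xy_b) {
  A <- as.matrix(bead_xy_a); B <- as.matrix(bead_xy_b)
  if (nrow(A) != nrow(B)) stop("bead lists must be matched (equal length)")
  if (nrow(A) < 2) stop("need >= 2 matched bead pairs")
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  A0 <- sweep(A, 2, mu_a); B0 <- sweep(B, 2, mu_b)
  var_b <- mean(rowSums(B0^2))
  if (var_b < 1e-12)
    stop("degenerate bead geometry: channel-B beads are coincident")
  H <- t(B0) %*% A0 / nrow(A)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, d))
  R <- sv$v %*% S %*% t(sv$u)
  s <- sum(diag(S) * sv$d) / var_b
  t_vec <- mu_a - s * as.vector(R %*% mu_b)
  fitted <- s * B %*% t(R) + matrix(t_vec, nrow(B), 2, byrow = TRUE)
  rms <- sqrt(mean(rowSums((A - fitted)^2)))
  structure(list(shift_px = t_vec, rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
                 magnification = s, rms_residual_px = rms, rotation = R),
            class = "channel_alignment")
}

#' Apply an alignment to points
#'
#' @param alignment A `channel_alignment`.
#' @param xy n x 2 matrix of channel-B coordinates.
#' @param inverse Map channel-A coordinates back to channel B instead?
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(alignment, xy, inverse = FALSE) {
  stopifnot(inherits(alignment, "channel_alignment"))
  xy <- as.matrix(xy)
  R <- alignment$rotation; s <- alignment$magnification
  t_vec <- alignment$shift_px
  if (!inverse)
    s * xy %*% t(R) + matrix(t_vec, nrow(xy), 2, byrow = TRUE)
  else
    sweep(xy, 2, t_vec) %*% R / s
}

#' Resample channel B into the channel-A frame
#'
#' Bilinear resampling companion of [estimate_channel_alignment()]: every
#' output pixel (in channel-A coordinates) is filled from the inverse
#' transformed position in channel B; positions outside the source image
#' give 0.
#'
#' @param image_b Channel-B image matrix.
#' @param alignment A `channel_alignment`.
#' @param output_shape `c(rows, cols)` (default: shape of `image_b`).
#' @return Aligned image matrix.
#' @export
apply_channel_alignment <- function(image_b, alignment,
                                    output_shape = dim(image_b)) {
  ny <- output_shape[1]; nx <- output_shape[2]
  xs <- rep(seq_len(nx), each = ny)
  ys <- rep(seq_len(ny), nx)
  src <- transform_points(alignment, cbind(xs, ys), inverse = TRUE)
  vals <- .interp_bilinear(image_b, src[, 1], src[, 2], outside = 0)
  matrix(vals, ny, nx)
}

# bilinear interpolation at continuous (x, y); outside pixels get `outside`
# (or the clamped edge value when outside = "clamp")
.interp_bilinear <- function(img, x, y, outside = 0) {
  ny <- nrow(img); nx <- ncol(img)
  clamp <- identical(outside, "clamp")
  if (clamp) {
    x <- pmin(pmax(x, 1), nx)
    y <- pmin(pmax(y, 1), ny)
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 1), nx); y0 <- pmin(pmax(y0, 1), ny)
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, ny)
  v <- (1 - fx) * (1 - fy) * img[cbind(y0, x0)] +
    fx * (1 - fy) * img[cbind(y0, x1)] +
    (1 - fx) * fy * img[cbind(y1, x0)] +
    fx * fy * img[cbind(y1, x1)]
  if (!clamp) {
    out <- x < 1 | x > nx | y < 1 | y > ny
    v[out] <- outside
  }
  v
}
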