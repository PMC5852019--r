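#' Rectangular region of interest
#'
#' A named axis-aligned rectangle in 1-based pixel coordinates:
#' `(x, y)` is the top-left pixel (column, row), `width` and `height` the
#' extent in pixels.
#'
#' @param name Label for the ROI.
#' @param x,y Top-left pixel (1-based column, row).
#' @param width,height Extent in pixels (>= 1).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, x, y, width, height) {
  stopifnot(is.character(name), length(name) == 1L)
  if (width < 1 || height < 1) stop("width and height must be >= 1")
  if (x < 1 || y < 1) stop("x and y must be >= 1 (1-based pixel coords)")
  structure(list(name = name, x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

#' Row/column index ranges of an ROI, validated against an image shape
#'
#' @param roi An [roi_spec()].
#' @param image_shape `c(rows, cols)`.
#' @return List with integer vectors `rows` and `cols`.
#' @export
roi_bounds <- function(roi, image_shape) {
  stopifnot(inherits(roi, "roi_spec"))
  rows <- roi$y:(roi$y + roi$height - 1L)
  cols <- roi$x:(roi$x + roi$width - 1L)
  if (max(rows) > image_shape[1] || max(cols) > image_shape[2])
    stop("ROI '", roi$name, "' exceeds image bounds")
  list(rows = rows, cols = cols)
}

#' Read a grayscale multi-page TIFF stack
#'
#' Frames are returned in acquisition (page) order as numeric matrices with
#' the raw integer sample values preserved (`as.is = TRUE`).
#'
#' @param path Path to a TIFF file.
#' @return List with `frames` (list of matrices) and `n_frames`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1]
      else stop("format error: multi-channel page; supply grayscale stacks")
    }
    storage.mode(p) <- "double"
    p
  })
  list(frames = frames, n_frames = length(frames))
}

#' Write a grayscale stack as a 16-bit multi-page TIFF
#'
#' Camera counts are rounded to integers and stored as 16-bit unsigned
#' grayscale, so integer-valued stacks round-trip exactly through
#' [read_stack()]. Values are clamped to `[0, 65535]`.
#'
#' @param frames A matrix or list of matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(all(vapply(frames, is.matrix, logical(1))))
  scaled <- lapply(frames, function(f) pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read / write plain-text ROI files
#'
#' One ROI per line, tab-separated columns `name, x, y, width, height`
#' with a header row.
#'
#' @param path File path.
#' @return `read_rois()`: a named list of [roi_spec()]s.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "width", "height")
  if (!all(need %in% names(df))) stop("ROI file must have columns: ",
                                      paste(need, collapse = ", "))
  rois <- lapply(seq_len(nrow(df)), function(i)
    roi_spec(df$name[i], df$x[i], df$y[i], df$width[i], df$height[i]))
  names(rois) <- df$name
  rois
}

#' @param rois A list of [roi_spec()]s.
#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(name = r$name, x = r$x, y = r$y,
               width = r$width, height = r$height)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Shared acquisition constants plus module-specific parameter blocks.
#' Round-trips losslessly through the plain-text `key: value` (YAML) files
#' of [read_run_config()] / [write_run_config()].
#'
#' @param pixel_size_um Pixel size (um/px), default 0.096.
#' @param frame_interval_s Frame interval (s), default 0.033.
#' @param seed Integer RNG seed.
#' @param ... Further named parameter blocks (lists or scalars).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(pixel_size_um = 0.096, frame_interval_s = 0.033,
                       seed = 1L, ...) {
  structure(c(list(pixel_size_um = pixel_size_um,
                   frame_interval_s = frame_interval_s,
                   seed = as.integer(seed)), list(...)),
            class = "run_config")
}

#' @param path File path.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @param config A `run_config`.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Fluorophore labelling efficiency from absorbances
#'
#' Spectrophotometric estimate of fluorophores per protein for
#' maleimide-labelled colicin E9. Dye molarity is `A_dye / eps_dye` with
#' `eps = 90000 cm^-1 M^-1` (Alexa Fluor 594) or `80000` (TMR); protein
#' molarity is `(A280 - c * A_dye) / 46075`, correcting the 280 nm
#' absorbance for the dye contribution with `c = 0.56` (AF594) or `0.3`
#' (TMR); the efficiency is their ratio (typically ~0.8 fluorophores per
#' protein for these preparations).
#'
#' @param a280 Absorbance at 280 nm (>= 0).
#' @param a_dye Absorbance at the dye peak (590 nm AF594, 547 nm TMR).
#' @param dye `"AF594"` or `"TMR"`.
#' @return Fluorophores per protein (numeric scalar).
#' @export
labelling_efficiency <- function(a280, a_dye, dye = c("AF594", "TMR")) {
  dye <- match.arg(dye)
  if (a280 < 0 || a_dye < 0) stop("absorbances must be >= 0")
  eps_dye <- c(AF594 = 90000, TMR = 80000)[[dye]]
  corr <- c(AF594 = 0.56, TMR = 0.3)[[dye]]
  eps_protein <- 46075
  protein_M <- (a280 - corr * a_dye) / eps_protein
  if (protein_M <= 0)
    stop("corrected protein absorbance <= 0; check inputs")
  (a_dye / eps_dye) / protein_M
}
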