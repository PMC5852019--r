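#' FRAP series container
#'
#' An acquired (or simulated) FRAP experiment: an image stack with exactly
#' one pre-bleach frame (`timepoints_s < 0`) followed by post-bleach frames
#' at strictly increasing times, together with the bleach ROI, the
#' measurement box used for intensity readout, the cell mask and a
#' background rectangle outside all cells.
#'
#' @param frames List of image matrices, one per timepoint.
#' @param timepoints_s Acquisition times (s); exactly one negative
#'   (pre-bleach) entry, in position 1.
#' @param bleach_roi,measure_box [roi_spec()] rectangles.
#' @param cell_mask Logical matrix, same shape as the frames.
#' @param background_region [roi_spec()] rectangle outside the cell mask.
#' @return An object of class `frap_series`.
#' @export
frap_series <- function(frames, timepoints_s, bleach_roi, measure_box,
                        cell_mask, background_region) {
  stopifnot(is.list(frames), length(frames) == length(timepoints_s),
            inherits(bleach_roi, "roi_spec"),
            inherits(measure_box, "roi_spec"),
            inherits(background_region, "roi_spec"),
            is.matrix(cell_mask))
  if (sum(timepoints_s < 0) != 1L || timepoints_s[1] >= 0)
    stop("exactly one pre-bleach frame (timepoint < 0) required, first")
  if (any(diff(timepoints_s) <= 0))
    stop("timepoints_s must be strictly increasing")
  shape <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shape), logical(1))))
    stop("all frames must share dimensions")
  if (!identical(dim(cell_mask), shape))
    stop("cell_mask must match frame dimensions")
  mb <- roi_bounds(measure_box, shape)
  if (!any(cell_mask[mb$rows, mb$cols]))
    stop("measure_box does not overlap the cell mask")
  bgb <- roi_bounds(background_region, shape)
  if (any(cell_mask[bgb$rows, bgb$cols]))
    stop("background_region must be disjoint from the cell mask")
  structure(list(frames = frames, timepoints_s = timepoints_s,
                 bleach_roi = bleach_roi, measure_box = measure_box,
                 cell_mask = cell_mask,
                 background_region = background_region),
            class = "frap_series")
}

#' Double-normalized FRAP recovery curve
#'
#' For every frame, the background mean (outside cells) is subtracted from
#' both the measurement-box mean and the whole-cell mean; the
#' background-corrected box mean is divided by the background-corrected
#' whole-cell mean, which compensates the gradual acquisition
#' photobleaching; finally the ratio is divided by the same ratio on the
#' pre-bleach frame. The pre-bleach value is therefore exactly 1.
#'
#' @param series A [frap_series()].
#' @return A `recovery_curve`: data.frame `(time_s, normalized_intensity)`
#'   over all timepoints including the pre-bleach one, with attribute
#'   `n_cells = 1`.
#' @export
double_normalize <- function(series) {
  stopifnot(inherits(series, "frap_series"))
  shape <- dim(series$frames[[1]])
  mb <- roi_bounds(series$measure_box, shape)
  bgb <- roi_bounds(series$background_region, shape)
  mask <- series$cell_mask
  ratio <- vapply(series$frames, function(f) {
    bg <- mean(f[bgb$rows, bgb$cols])
    roi <- mean(f[mb$rows, mb$cols]) - bg
    cell <- mean(f[mask]) - bg
    if (cell <= 0)
      stop("degenerate signal: background-corrected whole-cell mean <= 0")
    roi / cell
  }, numeric(1))
  curve <- data.frame(time_s = series$timepoints_s,
                      normalized_intensity = ratio / ratio[1])
  class(curve) <- c("recovery_curve", "data.frame")
  attr(curve, "n_cells") <- 1L
  curve
}

#' Average recovery curves across cells
#'
#' Pointwise mean of per-cell double-normalized curves sharing identical
#' timepoints, with the pointwise standard error.
#'
#' @param curves List of `recovery_curve` objects.
#' @return A `recovery_curve` with columns `time_s`,
#'   `normalized_intensity`, `se`, and attribute `n_cells`.
#' @export
average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  t0 <- curves[[1]]$time_s
  for (cv in curves)
    if (!isTRUE(all.equal(cv$time_s, t0)))
      stop("all curves must share identical timepoints")
  vals <- vapply(curves, function(cv) cv$normalized_intensity,
                 numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  n <- length(curves)
  out <- data.frame(time_s = t0,
                    normalized_intensity = rowMeans(vals),
                    se = if (n > 1) apply(vals, 1, stats::sd) / sqrt(n)
                         else rep(NA_real_, length(t0)))
  class(out) <- c("recovery_curve", "data.frame")
  attr(out, "n_cells") <- n
  out
}

#' Fit single-exponential recovery kinetics
#'
#' Least-squares fit of `I(t) = I0 + A * (1 - exp(-k * t))` to the
#' post-bleach points of a recovery curve (time measured from the bleach at
#' t = 0). The mobile fraction is `A / (1 - I0)`: 0 for an immobile
#' population (flat curve), 1 when recovery returns to the pre-bleach
#' plateau. Non-convergence is reported in the result (`converged = FALSE`
#' with residual diagnostics), never as an exception.
#'
#' @param curve A `recovery_curve` (from [double_normalize()] or
#'   [average_curves()]).
#' @return An object of class `recovery_fit` with fields `i0`, `amplitude`,
#'   `rate_per_s`, `half_time_s` (`log(2)/rate`), `mobile_fraction`
#'   (clamped to `[0, 1]`; `mobile_fraction_raw` unclamped),
#'   `residual_rms`, `converged`.
#' @export
fit_recovery <- function(curve) {
  stopifnot(inherits(curve, "recovery_curve"))
  post <- curve$time_s >= 0
  t <- curve$time_s[post]
  v <- curve$normalized_intensity[post]
  if (length(t) < 4L) stop("need >= 4 post-bleach points to fit recovery")

  flat_fit <- function(converged) {
    i0 <- mean(v)
    structure(list(i0 = i0, amplitude = 0, rate_per_s = NA_real_,
                   half_time_s = NA_real_, mobile_fraction = 0,
                   mobile_fraction_raw = 0,
                   residual_rms = sqrt(mean((v - i0)^2)),
                   converged = converged),
              class = "recovery_fit")
  }
  if (stats::sd(v) < 1e-12) return(flat_fit(TRUE))

  i0s <- min(v)
  as_ <- max(max(v) - i0s, 1e-6)
  half_target <- i0s + as_ / 2
  ks <- log(2) / max(t[which.min(abs(v - half_target))], t[1])
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(v ~ i0 + A * (1 - exp(-k * t)),
                        start = list(i0 = i0s, A = as_, k = ks),
                        lower = c(i0 = -0.1, A = 0, k = 1e-6),
                        upper = c(i0 = 2, A = 2, k = 100),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(flat_fit(FALSE))
  # a rise term is only reported when it beats the constant model: a flat
  # noisy curve can otherwise be mimicked by an unidentifiable fast rise
  rss_exp <- sum(stats::resid(fit)^2)
  rss_flat <- sum((v - mean(v))^2)
  n_post <- length(v)
  f_stat <- ((rss_flat - rss_exp) / 2) / (rss_exp / max(n_post - 3, 1) + 1e-300)
  if (rss_exp > 1e-24 &&
      stats::pf(f_stat, 2, max(n_post - 3, 1), lower.tail = FALSE) >= 0.05)
    return(flat_fit(TRUE))
  cf <- stats::coef(fit)
  i0 <- unname(cf["i0"]); A <- unname(cf["A"]); k <- unname(cf["k"])
  mf_raw <- if (1 - i0 > 1e-6) A / (1 - i0) else NA_real_
  structure(list(i0 = i0, amplitude = A, rate_per_s = k,
                 half_time_s = log(2) / k,
                 mobile_fraction = if (is.na(mf_raw)) NA_real_
                                   else min(max(mf_raw, 0), 1),
                 mobile_fraction_raw = mf_raw,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(paste0("<recovery_fit> mobile fraction %.3f, rate %.4g /s ",
                     "(t1/2 %.3g s), I0 %.3f, rms %.2e%s\n"),
              x$mobile_fraction, x$rate_per_s, x$half_time_s, x$i0,
              x$residual_rms,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}
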