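#' 8-connected component labeling
#'
#' Labels connected regions of a binary image under 8-connectivity by
#' iterative minimum-label propagation (exact; suited to the modest image
#' sizes of single-cell scenes). Labels are renumbered 1..n in raster
#' order of each region's first pixel; background is 0.
#'
#' @param binary Logical (or 0/1) matrix.
#' @return Integer matrix of the same shape.
#' @export
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  b <- binary != 0
  ny <- nrow(b); nx <- ncol(b)
  lab <- matrix(Inf, ny, nx)
  lab[b] <- which(b)           # unique seed label per foreground pixel
  pad <- function(m) { p <- matrix(Inf, ny + 2L, nx + 2L)
                       p[2:(ny + 1), 2:(nx + 1)] <- m; p }
  repeat {
    p <- pad(lab)
    nb <- pmin(p[1:ny, 1:nx], p[1:ny, 2:(nx + 1)], p[1:ny, 3:(nx + 2)],
               p[2:(ny + 1), 1:nx], p[2:(ny + 1), 3:(nx + 2)],
               p[3:(ny + 2), 1:nx], p[3:(ny + 2), 2:(nx + 1)],
               p[3:(ny + 2), 3:(nx + 2)])
    new_lab <- pmin(lab, nb)
    new_lab[!b] <- Inf
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  out <- matrix(0L, ny, nx)
  if (any(b)) {
    ids <- sort(unique(lab[b]))
    out[b] <- match(lab[b], ids)
  }
  out
}

#' Relative intensity (clustering heterogeneity index)
#'
#' Ratio of the maximum to the mean intensity within a cell after
#' background subtraction. Equals 1 for a perfectly homogeneous
#' distribution and grows with fluorescence heterogeneity (clustering).
#'
#' @param image Image matrix.
#' @param cell_mask Logical matrix marking the cell.
#' @param background Either `NULL` (no background, i.e. 0), a numeric
#'   scalar, or a logical matrix selecting background pixels whose mean is
#'   used.
#' @return List with `value` (the ratio) and `background_mean`.
#' @export
relative_intensity <- function(image, cell_mask, background = NULL) {
  stopifnot(is.matrix(image), is.matrix(cell_mask),
            identical(dim(image), dim(cell_mask)))
  if (!any(cell_mask)) stop("cell mask is empty")
  bg <- if (is.null(background)) 0
        else if (is.matrix(background)) mean(image[background])
        else as.numeric(background)
  vals <- image[cell_mask] - bg
  m <- mean(vals)
  if (m <= 0)
    stop("degenerate signal: in-cell mean does not exceed background")
  list(value = max(vals) / m, background_mean = bg)
}

#' Segment fluorescent clusters inside a cell
#'
#' Pixels above `median + threshold_sd * MAD` of the background intensity
#' (pixels outside the cell mask, or a supplied background region) are
#' marked, 8-connected components are labeled, and components smaller than
#' `min_cluster_px` pixels are removed.
#'
#' @param image Image matrix.
#' @param cell_mask Logical matrix.
#' @param threshold_sd Threshold in robust MAD units (default 3).
#' @param min_cluster_px Minimum component size kept (default 4).
#' @param background Optional logical matrix of background pixels; default
#'   uses everything outside `cell_mask`.
#' @return A `cluster_map`: list with `labels` (integer matrix),
#'   `n_clusters`, `threshold_used`, `min_cluster_px`, `sizes_px`.
#' @export
segment_clusters <- function(image, cell_mask, threshold_sd = 3,
                             min_cluster_px = 4L, background = NULL) {
  stopifnot(is.matrix(image), identical(dim(image), dim(cell_mask)))
  if (!any(cell_mask)) stop("cell mask is empty")
  bgpx <- if (is.null(background)) image[!cell_mask] else image[background]
  thr <- stats::median(bgpx) + threshold_sd * stats::mad(bgpx)
  binary <- image > thr & cell_mask
  lab <- label_components(binary)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_cluster_px)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      lab[lab > 0] <- match(lab[lab > 0], keep)
    }
  }
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  structure(list(labels = lab, n_clusters = max(lab),
                 threshold_used = thr,
                 min_cluster_px = as.integer(min_cluster_px),
                 sizes_px = sizes),
            class = "cluster_map")
}

#' Build a cluster map from known centers (rasterized discs)
#'
#' Places circular clusters of a fixed radius at the given centers; used by
#' the Monte-Carlo random-placement null and for ground-truth-based
#' co-clustering. Discs keep their own labels even where they overlap
#' (later discs overwrite earlier pixels).
#'
#' @param centers Two-column matrix/data.frame of `(x, y)` centers (px).
#' @param radius_px Disc radius in pixels.
#' @param image_shape `c(rows, cols)`.
#' @return A `cluster_map`.
#' @export
disc_cluster_map <- function(centers, radius_px, image_shape) {
  centers <- as.matrix(centers)
  ny <- image_shape[1]; nx <- image_shape[2]
  lab <- matrix(0L, ny, nx)
  if (nrow(centers)) {
    w <- ceiling(radius_px)
    off <- expand.grid(dy = -w:w, dx = -w:w)
    off <- off[off$dx^2 + off$dy^2 <= radius_px^2, ]
    for (k in seq_len(nrow(centers))) {
      py <- round(centers[k, 2]) + off$dy
      px <- round(centers[k, 1]) + off$dx
      ok <- py >= 1 & py <= ny & px >= 1 & px <= nx
      lab[cbind(py[ok], px[ok])] <- k
    }
  }
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0], nbins = nrow(centers))
           else integer(0)
  structure(list(labels = lab, n_clusters = nrow(centers),
                 threshold_used = NA_real_, min_cluster_px = 1L,
                 sizes_px = sizes),
            class = "cluster_map")
}

#' Co-clustering fraction between two channels
#'
#' For each channel-A cluster, counts the pixels it shares with any
#' channel-B cluster; an A cluster co-clusters when it shares at least
#' `min_shared` pixels (default 3). Returns the percentage of A clusters
#' that do.
#'
#' @param a,b `cluster_map` objects on the same pixel grid.
#' @param min_shared Minimum shared pixels (default 3).
#' @return A `co_cluster_result`: list with `pct_a_overlapping_b`,
#'   `min_shared` and a per-cluster `overlap` data.frame
#'   `(cluster_a, size_px, shared_px, co_clustered)`.
#' @export
co_cluster_fraction <- function(a, b, min_shared = 3L) {
  stopifnot(inherits(a, "cluster_map"), inherits(b, "cluster_map"),
            identical(dim(a$labels), dim(b$labels)))
  ids <- setdiff(unique(as.vector(a$labels)), 0L)
  if (!length(ids))
    stop("undefined percentage: channel A has no clusters")
  ids <- sort(ids)
  b_occ <- b$labels > 0L
  shared <- vapply(ids, function(i) sum(b_occ[a$labels == i]), integer(1))
  size <- vapply(ids, function(i) sum(a$labels == i), integer(1))
  co <- shared >= min_shared
  structure(list(pct_a_overlapping_b = 100 * mean(co),
                 min_shared = as.integer(min_shared),
                 overlap = data.frame(cluster_a = ids, size_px = size,
                                      shared_px = shared,
                                      co_clustered = co)),
            class = "co_cluster_result")
}

#' Monte-Carlo random-placement overlap null
#'
#' Repeatedly places `n_clusters_a` + `n_clusters_b` circular clusters of
#' radius `cluster_radius_px` with centers uniformly at random over the
#' mask pixels (discs are clipped at the image border) and computes, per
#' replicate, the percentage of A clusters sharing fewer than `min_shared`
#' pixels with the B map — the fraction expected to be called "not
#' co-clustered" for free, non-coupled molecules at this density. The
#' cluster radius must be feasible: at least one disc position must fit
#' entirely inside the mask.
#'
#' @param n_clusters_a,n_clusters_b Cluster counts per channel.
#' @param cluster_radius_px Disc radius (px).
#' @param mask Logical cell mask.
#' @param n_sim Number of Monte-Carlo replicates (default 1000).
#' @param min_shared Shared-pixel criterion (default 3).
#' @param seed Optional RNG seed.
#' @return List with `pct_share_below` (length `n_sim`), `mean_pct`,
#'   and the simulation parameters.
#' @export
random_null_overlap <- function(n_clusters_a, n_clusters_b,
                                cluster_radius_px, mask, n_sim = 1000L,
                                min_shared = 3L, seed = NULL) {
  stopifnot(is.matrix(mask))
  if (!is.null(seed)) set.seed(seed)
  ny <- nrow(mask); nx <- ncol(mask)
  w <- ceiling(cluster_radius_px)
  off <- expand.grid(dy = -w:w, dx = -w:w)
  off <- off[off$dx^2 + off$dy^2 <= cluster_radius_px^2, ]
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask is empty")
  # feasibility: the disc must fit inside the mask at some position
  fits_somewhere <- any(vapply(seq_len(nrow(idx)), function(i) {
    py <- idx[i, 1] + off$dy; px <- idx[i, 2] + off$dx
    all(py >= 1 & py <= ny & px >= 1 & px <= nx) &&
      all(mask[cbind(py, px)])
  }, logical(1)))
  if (!fits_somewhere)
    stop("no placement site: clusters of this radius do not fit in the mask")
  clip <- function(py, px) {
    ok <- py >= 1 & py <= ny & px >= 1 & px <= nx
    cbind(py[ok], px[ok])
  }
  pct <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    ca <- idx[sample.int(nrow(idx), n_clusters_a, replace = TRUE), ,
              drop = FALSE]
    b_occ <- matrix(FALSE, ny, nx)
    if (n_clusters_b > 0) {
      cb <- idx[sample.int(nrow(idx), n_clusters_b, replace = TRUE), ,
                drop = FALSE]
      for (k in seq_len(n_clusters_b))
        b_occ[clip(cb[k, 1] + off$dy, cb[k, 2] + off$dx)] <- TRUE
    }
    shared <- vapply(seq_len(n_clusters_a), function(k)
      sum(b_occ[clip(ca[k, 1] + off$dy, ca[k, 2] + off$dx)]), integer(1))
    pct[s] <- 100 * mean(shared < min_shared)
  }
  list(pct_share_below = pct, mean_pct = mean(pct), n_sim = n_sim,
       n_clusters_a = n_clusters_a, n_clusters_b = n_clusters_b,
       cluster_radius_px = cluster_radius_px, min_shared = min_shared)
}

#' Yellow-pixel colocalization ratio
#'
#' Classifies every pixel of an overlapped two-channel image: yellow when
#' above both channel thresholds, red when above the red threshold only,
#' green when above the green threshold only. The colocalization ratio is
#' `yellow / (yellow + red + green)`; pixels below both thresholds are
#' ignored.
#'
#' @param red,green Image matrices of identical shape.
#' @param threshold_red,threshold_green Channel thresholds; `NULL` selects
#'   an automatic Otsu level for that channel.
#' @param mask Optional logical matrix restricting the evaluated pixels.
#' @return A `coloc_result`: list with `coloc_ratio`, per-class pixel
#'   `counts`, and the `thresholds` used.
#' @export
colocalization_ratio <- function(red, green, threshold_red = NULL,
                                 threshold_green = NULL, mask = NULL) {
  stopifnot(is.matrix(red), is.matrix(green),
            identical(dim(red), dim(green)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(red), ncol(red))
  tr <- if (is.null(threshold_red)) .otsu_level(red[mask]) else threshold_red
  tg <- if (is.null(threshold_green)) .otsu_level(green[mask]) else threshold_green
  r_on <- red > tr & mask
  g_on <- green > tg & mask
  yellow <- sum(r_on & g_on)
  red_only <- sum(r_on & !g_on)
  green_only <- sum(!r_on & g_on)
  tot <- yellow + red_only + green_only
  if (tot == 0)
    stop("undefined ratio: no pixel above either threshold")
  structure(list(coloc_ratio = yellow / tot,
                 counts = c(yellow = yellow, red = red_only,
                            green = green_only),
                 thresholds = c(red = tr, green = tg)),
            class = "coloc_result")
}

# Otsu threshold on raw intensities via EBImage (which expects [0,1])
.otsu_level <- function(v) {
  rg <- range(v)
  if (diff(rg) <= 0) return(rg[1])
  EBImage::otsu(matrix((v - rg[1]) / diff(rg), nrow = 1), range = c(0, 1)) *
    diff(rg) + rg[1]
}

#' Shared-pixel overlap fraction for known disc clusters
#'
#' Counting rule shared with [random_null_overlap()]: every channel-A disc
#' is compared against the union occupancy of the channel-B discs, and the
#' percentage of A discs sharing at least `min_shared` pixels is returned.
#' Used to evaluate realized two-channel scenes from their ground-truth
#' cluster centers with exactly the null's statistic.
#'
#' @param centers_a,centers_b Two-column `(x, y)` center tables (px).
#' @param radius_px Disc radius (px).
#' @param image_shape `c(rows, cols)`.
#' @param min_shared Shared-pixel criterion (default 3).
#' @return Percentage (0-100) of A discs sharing >= `min_shared` pixels.
#' @export
disc_overlap_fraction <- function(centers_a, centers_b, radius_px,
                                  image_shape, min_shared = 3L) {
  centers_a <- as.matrix(centers_a); centers_b <- as.matrix(centers_b)
  ny <- image_shape[1]; nx <- image_shape[2]
  w <- ceiling(radius_px)
  off <- expand.grid(dy = -w:w, dx = -w:w)
  off <- off[off$dx^2 + off$dy^2 <= radius_px^2, ]
  clip <- function(py, px) {
    ok <- py >= 1 & py <= ny & px >= 1 & px <= nx
    cbind(py[ok], px[ok])
  }
  b_occ <- matrix(FALSE, ny, nx)
  for (k in seq_len(nrow(centers_b)))
    b_occ[clip(round(centers_b[k, 2]) + off$dy,
               round(centers_b[k, 1]) + off$dx)] <- TRUE
  shared <- vapply(seq_len(nrow(centers_a)), function(k)
    sum(b_occ[clip(round(centers_a[k, 2]) + off$dy,
                   round(centers_a[k, 1]) + off$dx)]), integer(1))
  100 * mean(shared >= min_shared)
}
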