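# shared scene builders for the test suite; everything is generated in code

std_geometry <- function(...) cell_geometry(length_um = 3, radius_um = 0.5,
                                            pixel_size_um = 0.096, ...)

quiet_camera <- function(seed = 1L, ...) {
  camera_model(photons_per_frame = 3000, psf_sigma_px = 1.3,
               background_level = 10, read_noise_sd = 1, seed = seed, ...)
}

noiseless_camera <- function(seed = 1L, ...) {
  camera_model(photons_per_frame = 3000, psf_sigma_px = 1.3,
               background_level = 0, read_noise_sd = 0, shot_noise = FALSE,
               seed = seed, ...)
}

# exhaustive matching oracle: among all pairings within max_disp, first
# maximize the number of matched pairs, then minimize total squared distance
oracle_pairs <- function(xa, ya, xb, yb, max_disp) {
  na <- length(xa); nb <- length(xb)
  d2 <- outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2
  feasible <- d2 <= max_disp^2
  best <- list(n = -1L, cost = Inf, pairs = matrix(integer(0), 0, 2))
  # enumerate all injective partial assignments a -> b
  recurse <- function(i, used_b, pairs, cost) {
    if (i > na) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used_b, pairs, cost)          # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (used_b[j] || !feasible[i, j]) next
      ub <- used_b; ub[j] <- TRUE
      recurse(i + 1L, ub, rbind(pairs, c(i, j)), cost + d2[i, j])
    }
  }
  recurse(1L, logical(nb), matrix(integer(0), 0, 2), 0)
  p <- best$pairs
  p[order(p[, 1]), , drop = FALSE]
}

# brute-force all-pairs diameter of a pixel region; ties resolved exactly
# like the documented rule (pole1 = smallest (row, col), then pole2)
oracle_poles <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  best <- -1; best_key <- NULL
  for (i in seq_len(nrow(idx) - 1)) {
    for (j in (i + 1):nrow(idx)) {
      d2 <- sum((idx[i, ] - idx[j, ])^2)
      a <- idx[i, ]; b <- idx[j, ]
      key <- if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) c(a, b) else c(b, a)
      if (d2 > best + 1e-9) { best <- d2; best_key <- key }
      else if (abs(d2 - best) <= 1e-9 &&
               !is.null(best_key) &&
               (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2]) ||
                (key[1] == best_key[1] && key[2] == best_key[2] &&
                 (key[3] < best_key[3] ||
                  (key[3] == best_key[3] && key[4] < best_key[4])))))
        best_key <- key
    }
  }
  list(separation_px = sqrt(best),
       pole1 = c(x = unname(best_key[2]), y = unname(best_key[1])),
       pole2 = c(x = unname(best_key[4]), y = unname(best_key[3])))
}
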