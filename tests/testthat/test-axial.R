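test_that("thresholding and cleaning behave like a binary 3x3 median", {
  img <- matrix(10, 20, 20)
  res <- binarize_and_clean(img, 5)
  expect_true(all(res$mask))
  expect_equal(res$n_regions, 1L)
  # a single isolated bright pixel is removed by the majority filter
  img2 <- matrix(0, 20, 20); img2[10, 10] <- 50
  expect_error(binarize_and_clean(img2, 40), "empty mask")
  # rendered cell + salt noise cleans back to the noiseless mask
  g <- std_geometry()
  mask <- render_cell_mask(g, c(64, 64))
  base <- matrix(0, 64, 64); base[mask] <- 100
  clean <- binarize_and_clean(base, 50)$mask
  set.seed(61)
  # salt pixels at least 3 px away from the cell so majority votes at the
  # rim are untouched
  far <- which(!mask)
  rc <- arrayInd(far, dim(mask))
  cell <- which(mask, arr.ind = TRUE)
  dmin <- vapply(seq_len(nrow(rc)), function(i)
    min(pmax(abs(cell[, 1] - rc[i, 1]), abs(cell[, 2] - rc[i, 2]))),
    numeric(1))
  salt <- base
  salt[far[sample(which(dmin > 2), 25)]] <- 120
  cleaned <- binarize_and_clean(salt, 50)$mask
  expect_identical(cleaned, clean)
  expect_error(binarize_and_clean(base, 1000), "intensity range")
})

test_that("poles of a thin segment are its endpoints", {
  m <- matrix(FALSE, 10, 60)
  m[5, 6:55] <- TRUE
  pp <- find_poles(m)
  expect_equal(pp$separation_px, 49)
  expect_equal(unname(pp$pole1_px), c(6, 5))
  expect_equal(unname(pp$pole2_px), c(55, 5))
  expect_equal(cell_length(pp, 0.096), 4.704)
  expect_error(find_poles(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)),
               ">= 2 pixels")
})

test_that("pole separation of a rendered cell matches its length", {
  for (ang in c(0, 17, 63)) {
    g <- cell_geometry(3, 0.5, 0.096, orientation_deg = ang)
    mask <- render_cell_mask(g, c(64, 64))
    pp <- find_poles(mask)
    expect_lt(abs(pp$separation_px - 3 / 0.096), 1.5,
              label = paste("angle", ang))
    expect_lt(abs(cell_length(pp, 0.096) - 3), 0.15)
  }
})

test_that("find_poles equals the brute-force all-pairs oracle", {
  set.seed(62)
  for (rep in 1:12) {
    ny <- sample(8:40, 1); nx <- sample(8:40, 1)
    m <- matrix(runif(ny * nx) < 0.3, ny, nx)
    if (sum(m) < 2) next
    pp <- find_poles(m)
    or <- oracle_poles(m)
    expect_equal(pp$separation_px, or$separation_px)
    expect_equal(pp$pole1_px, or$pole1)
    expect_equal(pp$pole2_px, or$pole2)
  }
})

test_that("axial profiles are flat for uniform cells and peak where emitters sit", {
  g <- std_geometry()
  mask <- render_cell_mask(g, c(64, 64))
  uni <- matrix(0, 64, 64); uni[mask] <- 42
  pp <- find_poles(mask)
  prof <- extract_axial_profile(uni, pp, mask = mask)
  inner <- prof$intensity[prof$position_pct >= 15 & prof$position_pct <= 85]
  expect_lt(max(abs(inner - 42)) / 42, 0.25)  # interpolation at the rim only
  expect_equal(nrow(prof), 101L)
  # septal band peaks at mid-cell
  sp_s <- scene_spec(g, emitter_distribution("septal", 600,
                                             septal_sigma_frac = 0.04),
                     motion_model(0), noiseless_camera(seed = 63),
                     image_shape = c(64, 64))
  img_s <- render_movie(sp_s)$frames[[1]]
  prof_s <- extract_axial_profile(img_s, pp, mask = mask)
  expect_lt(abs(prof_s$position_pct[which.max(prof_s$intensity)] - 50), 2)
  # polar distribution peaks near both ends
  sp_p <- scene_spec(g, emitter_distribution("polar", 600,
                                             polar_sigma_frac = 0.03),
                     motion_model(0), noiseless_camera(seed = 64),
                     image_shape = c(64, 64))
  img_p <- render_movie(sp_p)$frames[[1]]
  prof_p <- extract_axial_profile(img_p, pp, mask = mask)
  mid <- mean(prof_p$intensity[abs(prof_p$position_pct - 50) <= 10])
  left <- max(prof_p$intensity[prof_p$position_pct <= 10])
  right <- max(prof_p$intensity[prof_p$position_pct >= 90])
  expect_gt(left, 2 * mid)
  expect_gt(right, 2 * mid)
})

test_that("profiles are rotation-invariant and mirror correctly", {
  # deterministic analytic pattern: a Gaussian mid-cell band evaluated at
  # pixel centers for the same cell at different orientations
  band_image <- function(ang) {
    g <- cell_geometry(3, 0.5, 0.096, orientation_deg = ang)
    mask <- render_cell_mask(g, c(73, 73))
    th <- ang * pi / 180
    xs <- matrix(rep(1:73, each = 73), 73, 73)
    ys <- matrix(rep(1:73, 73), 73, 73)
    ax <- (xs - 37) * cos(th) + (ys - 37) * sin(th)
    img <- 100 * exp(-ax^2 / (2 * 4^2)) + 20
    list(img = img, mask = mask)
  }
  prof_of_angle <- function(ang) {
    b <- band_image(ang)
    pp <- find_poles(b$mask)
    extract_axial_profile(b$img, pp, mask = b$mask)$intensity
  }
  p0 <- prof_of_angle(0)
  p35 <- prof_of_angle(35)
  rms_rel <- sqrt(mean((p0 - p35)^2)) / sqrt(mean(p0^2))
  expect_lt(rms_rel, 0.02)
  # mirrored image gives the reversed profile; a thin-segment mask keeps
  # the pole pair unambiguous so the axes mirror onto each other exactly
  mask2 <- matrix(FALSE, 33, 65)
  mask2[17, 10:56] <- TRUE
  xs2 <- matrix(rep(1:65, each = 33), 33, 65)
  ys2 <- matrix(rep(1:33, 65), 33, 65)
  img2 <- 50 + 30 * sin(xs2 / 7) + 5 * cos(ys2 / 3) + 0.4 * xs2
  pp2 <- find_poles(mask2)
  prof2 <- extract_axial_profile(img2, pp2, mask = mask2)
  img2_m <- img2[, ncol(img2):1]
  mask2_m <- mask2[, ncol(mask2):1]
  pp2_m <- find_poles(mask2_m)
  prof2_m <- extract_axial_profile(img2_m, pp2_m, mask = mask2_m)
  expect_equal(prof2_m$intensity, rev(prof2$intensity), tolerance = 1e-9)
})

test_that("distribution indices formalize septal vs polar patterns", {
  flat <- structure(data.frame(position_pct = seq(0, 100, 1),
                               intensity = rep(7, 101)),
                    class = c("axial_profile", "data.frame"))
  st <- distribution_stats(flat)
  expect_identical(st$septal_index, 1)
  expect_identical(st$polar_index, 1)
  central_only <- flat
  central_only$intensity <- ifelse(abs(flat$position_pct - 50) <= 10, 10, 0)
  expect_equal(distribution_stats(central_only)$polar_index, 0)
  # generator-backed ordering: septal scenes score higher septal index
  g <- std_geometry()
  mask <- render_cell_mask(g, c(64, 64))
  pp <- find_poles(mask)
  prof_of <- function(mode, seed) {
    sp <- scene_spec(g, emitter_distribution(mode, 500,
                                             septal_sigma_frac = 0.05,
                                             polar_sigma_frac = 0.05),
                     motion_model(0), noiseless_camera(seed = seed),
                     image_shape = c(64, 64))
    extract_axial_profile(render_movie(sp)$frames[[1]], pp, mask = mask)
  }
  st_s <- distribution_stats(prof_of("septal", 67))
  st_p <- distribution_stats(prof_of("polar", 68))
  expect_gt(st_s$septal_index, st_p$septal_index)
  expect_gt(st_p$polar_index, st_s$polar_index)
  expect_gt(st_s$septal_index, 1)
  expect_gt(st_p$polar_index, 1)
})
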