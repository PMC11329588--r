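make_ball_volume <- function(n, spacing, radius_mm, center_off = c(0, 0, 0)) {
  coord <- (seq_len(n) - (n + 1) / 2) * spacing
  dx <- array(coord, c(n, n, n)) - center_off[1]
  dy <- aperm(array(coord, c(n, n, n)), c(2, 1, 3)) - center_off[2]
  dz <- aperm(array(coord, c(n, n, n)), c(3, 2, 1)) - center_off[3]
  mask <- array(as.integer(dx^2 + dy^2 + dz^2 <= radius_mm^2), c(n, n, n))
  labeled_volume(mask * 80 + 20, mask, spacing_mm = spacing)
}

test_that("resampling to the same grid is the identity", {
  vol <- make_ball_volume(32, 2, 20)
  out <- resample_isotropic(vol, grid_spec(32, 2))
  expect_identical(out$intensity, vol$intensity)
  expect_identical(out$mask, vol$mask)
})

test_that("upsampling a ball preserves its volume within 2%", {
  vol <- make_ball_volume(64, 1, 20)
  out <- resample_isotropic(vol, grid_spec(128, 0.5))
  v_in <- tongue_volume(vol)
  v_out <- tongue_volume(out)
  expect_lt(abs(v_out - v_in) / v_in, 0.02)
})

test_that("anisotropic input is brought to an isotropic grid with the physical extent preserved", {
  n <- 32L
  arr <- array(0, c(n, n, n / 2))
  mask <- array(0L, c(n, n, n / 2))
  # ball of radius 10 mm on a (1, 1, 2) mm grid
  coord1 <- (seq_len(n) - (n + 1) / 2) * 1
  coord3 <- (seq_len(n / 2) - (n / 2 + 1) / 2) * 2
  for (k in seq_len(n / 2)) {
    d2 <- outer(coord1^2, coord1^2, "+") + coord3[k]^2
    mask[, , k] <- as.integer(d2 <= 100)
  }
  vol <- labeled_volume(mask * 50, mask, spacing_mm = c(1, 1, 2))
  out <- resample_isotropic(vol, grid_spec(n, 1))
  expect_equal(dim(out$intensity), rep(n, 3))
  expect_equal(out$spacing_mm, rep(1, 3))
  expect_lt(abs(tongue_volume(out) - tongue_volume(vol)) / tongue_volume(vol), 0.05)
})

test_that("reorientation translates the landmark to the matrix center", {
  vol <- make_ball_volume(32, 2, 12)
  center <- dim(vol$intensity) %/% 2L + 1L
  expect_identical(reorient_center(vol, center)$intensity, vol$intensity)

  shifted <- reorient_center(vol, center + c(10L, 0L, 0L))
  # landmark right of center => content moves 10 voxels toward lower indices
  expect_equal(shifted$intensity[5, 16, 16], vol$intensity[15, 16, 16])
  c0 <- mask_centroid(vol)
  c1 <- mask_centroid(shifted)
  expect_equal(c1[1], c0[1] - 10, tolerance = 0.2)

  expect_error(reorient_center(vol, c(0L, 1L, 1L)), "outside")
})

test_that("an off-center phantom tongue is recentered to within one voxel", {
  vol <- make_ball_volume(48, 2, 20, center_off = c(10, -6, 4))
  out <- reorient_center(vol, round(mask_centroid(vol)))
  center <- dim(out$intensity) %/% 2L + 1L
  expect_true(all(abs(mask_centroid(out) - center) <= 1))
})

test_that("cohort statistics are the mean and sample sd of per-subject ROI means", {
  mk <- function(value) labeled_volume(array(value, c(16, 16, 16)), spacing_mm = 8)
  stats <- compute_cohort_stats(list(mk(90), mk(100), mk(110)),
                                roi = grid_spec(16, 4))
  expect_equal(stats$M, 100)
  expect_equal(stats$S, 10)
  expect_equal(stats$per_subject_roi_means, c(90, 100, 110))

  expect_error(compute_cohort_stats(list(mk(5)), roi = grid_spec(16, 4)),
               "at least 2")
  expect_error(compute_cohort_stats(list(mk(5), mk(5), mk(5)),
                                    roi = grid_spec(16, 4)), "zero")
})

test_that("cohort statistics match an independent two-pass computation", {
  vols <- tiny_cohort(n = 3L, grid = 32L)
  roi <- grid_spec(16, 2)   # central 32 mm cube on the 4 mm grid -> 8 voxels
  stats <- compute_cohort_stats(vols, roi)
  n <- dim(vols[[1]]$intensity)[1]
  rv <- round(16 * 2 / vols[[1]]$spacing_mm[1])
  lo <- (n - rv) %/% 2 + 1; hi <- lo + rv - 1
  means <- sapply(vols, function(v) mean(v$intensity[lo:hi, lo:hi, lo:hi]))
  expect_equal(stats$M, mean(means))
  expect_equal(stats$S, sd(means))
})

test_that("z-score normalization maps M to 0 and M + S to 1 and leaves the mask alone", {
  stats <- structure(list(per_subject_roi_means = c(90, 110), M = 100, S = 10,
                          roi_shape = c(8L, 8L, 8L)),
                     class = "normalization_stats")
  vol <- labeled_volume(array(100, c(8, 8, 8)), random_binary(c(8, 8, 8), seed = 1),
                        spacing_mm = 2)
  out <- znormalize(vol, stats)
  expect_true(all(out$intensity == 0))
  expect_identical(out$mask, vol$mask)
  vol$intensity[] <- 110
  expect_true(all(znormalize(vol, stats)$intensity == 1))
})

test_that("self-normalized cohort ROI means have mean 0 and sd 1 to 1e-10", {
  vols <- tiny_cohort(n = 4L, grid = 32L)
  roi <- grid_spec(16, 2)
  stats <- compute_cohort_stats(vols, roi)
  normed <- lapply(vols, znormalize, stats = stats)
  stats2_means <- sapply(normed, function(v) {
    n <- dim(v$intensity)[1]; rv <- 8L
    lo <- (n - rv) %/% 2 + 1; hi <- lo + rv - 1
    mean(v$intensity[lo:hi, lo:hi, lo:hi])
  })
  expect_equal(mean(stats2_means), 0, tolerance = 1e-10)
  expect_equal(sd(stats2_means), 1, tolerance = 1e-10)
})

test_that("normalization is invariant to affine intensity changes of the cohort", {
  vols <- tiny_cohort(n = 3L, grid = 32L)
  roi <- grid_spec(16, 2)
  scaled <- lapply(vols, function(v) { v$intensity <- 3.7 * v$intensity + 42; v })
  n1 <- lapply(vols, znormalize, stats = compute_cohort_stats(vols, roi))
  n2 <- lapply(scaled, znormalize, stats = compute_cohort_stats(scaled, roi))
  for (i in seq_along(n1))
    expect_equal(n1[[i]]$intensity, n2[[i]]$intensity, tolerance = 1e-10)
})

test_that("segmentation-grid cropping doubles resolution over the central half", {
  # working 64 mm cube at 2 mm; segmentation 32 mm cube at 1 mm
  vol <- make_ball_volume(32, 2, 12)
  seg <- to_segmentation_grid(vol, grid_spec(32, 1))
  expect_equal(dim(seg$intensity), rep(32L, 3))
  expect_equal(seg$spacing_mm, rep(1, 3))
  expect_lt(abs(tongue_volume(seg) - tongue_volume(vol)) / tongue_volume(vol), 0.02)
  # identity segmentation grid
  same <- to_segmentation_grid(vol, grid_spec(32, 2))
  expect_identical(same$intensity, vol$intensity)
  # over-large segmentation extent is rejected
  expect_error(to_segmentation_grid(vol, grid_spec(80, 1)), "exceeds")
  # inverse mapping returns to the working grid
  back <- from_segmentation_grid(seg, grid_spec(32, 2))
  expect_equal(dim(back$intensity), rep(32L, 3))
  expect_lt(abs(tongue_volume(back) - tongue_volume(vol)) / tongue_volume(vol), 0.05)
})

test_that("the full preprocessing chain conserves the true tongue volume within 2%", {
  spec <- phantom_spec(volume_scale = 0.8, seed = 21L)
  vol <- generate_phantom(spec)
  truth <- attr(vol, "true_volume_cm3")
  prep <- preprocess_cohort(list(a = vol, b = generate_phantom(phantom_spec(volume_scale = 0.82, seed = 22L))),
                            working = grid_spec(64, 2), seg = grid_spec(64, 1),
                            roi = grid_spec(32, 2))
  expect_lt(abs(tongue_volume(prep$vols$a) - truth) / truth, 0.02)
})

test_that("normalization stats survive a JSON round trip", {
  vols <- tiny_cohort(n = 3L, grid = 32L)
  stats <- compute_cohort_stats(vols, grid_spec(16, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization_stats(stats, path)
  rt <- read_normalization_stats(path)
  expect_equal(rt$M, stats$M)
  expect_equal(rt$S, stats$S)
  expect_equal(rt$per_subject_roi_means, stats$per_subject_roi_means)
})
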