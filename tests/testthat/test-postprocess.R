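# Axial-profile splitting and morphological smoothing.

test_that("IR profile reads shell geometry: low mid-nucleus, >1 at a stacked interface", {
  sc <- generate_scene(scene_spec(n_nuclei = 2, field_um = c(30, 30, 40),
                                  mode = "stacked", seed = 5,
                                  radius_range = c(4, 4.5)))
  # merge the stacked pair into one volume
  merged <- sc$labels
  merged$data[merged$data == 2L] <- 1L
  v <- volume_from_labels(merged, 1L)
  pr <- intensity_ratio_profile(v, sc$intensity)
  expect_equal(attr(pr, "kind"), "IR")
  n <- nrow(pr)
  mid_lo <- sort(pr$value)[1:3]
  expect_lt(max(mid_lo), 0.6)         # interior dim vs bright rim
  # interface plane is envelope material through the centre: IR rises
  # far above the mid-nucleus level
  expect_gt(max(pr$value[3:(n - 2)]), 1.5 * min(pr$value))
})

test_that("IR splitting cuts a stacked pair near the interface and spares clean nuclei", {
  sc <- generate_scene(scene_spec(n_nuclei = 2, field_um = c(30, 30, 40),
                                  mode = "stacked", seed = 5,
                                  radius_range = c(4, 4.5)))
  merged <- sc$labels
  merged$data[merged$data == 2L] <- 1L
  v <- volume_from_labels(merged, 1L)
  pr <- intensity_ratio_profile(v, sc$intensity)
  p <- seg_params()
  parts <- split_by_intensity(v, pr, p, sc$labels$calibration)
  expect_length(parts, 2L)
  # true interface: last plane of nucleus 1
  iface <- max(which(apply(sc$labels$data == 1L, 3, any)))
  cut_gap <- setdiff(v$planes, c(parts[[1]]$planes, parts[[2]]$planes))
  expect_lte(min(abs(cut_gap - iface)), 1)

  # a clean single nucleus is never split
  sc1 <- generate_scene(scene_spec(n_nuclei = 1, field_um = c(25, 25, 25),
                                   mode = "sparse", seed = 6))
  v1 <- volume_from_labels(sc1$labels, 1L)
  pr1 <- intensity_ratio_profile(v1, sc1$intensity)
  expect_length(split_by_intensity(v1, pr1, p, sc1$labels$calibration), 1L)
})

test_that("uniform-intensity volumes have IR about 1 everywhere", {
  lab <- array(0L, c(20, 20, 7)); lab[5:15, 5:15, 2:6] <- 1L
  lv <- label_volume(lab)
  v <- volume_from_labels(lv, 1L)
  flat <- intensity_volume(array(100, c(20, 20, 7)), calibration = c(1, 1, 1))
  pr <- intensity_ratio_profile(v, flat)
  expect_equal(pr$value, rep(1, 5), tolerance = 1e-9)
})

test_that("CD profile is flat for a cylinder and peaks at a lateral jump", {
  mk_vol <- function(centres) {
    masks <- list(); cents <- NULL
    for (c_ in centres) {
      xs <- matrix(1:40, 40, 40); ys <- t(xs)
      masks[[length(masks) + 1L]] <- which((xs - c_)^2 + (ys - 20)^2 <= 25)
      cents <- rbind(cents, c(c_, 20))
    }
    v <- list(id = 1L, planes = seq_along(masks), masks = masks,
              centroids_px = cents, volume_um3 = sum(lengths(masks)),
              oversized = FALSE)
    class(v) <- "NucleusVolume"
    v
  }
  cyl <- mk_vol(rep(20, 8))
  pr <- centroid_displacement_profile(cyl, c(1, 1, 1))
  expect_true(all(pr$value < 1e-9))
  expect_length(split_by_displacement(cyl, pr, seg_params(min_volume = 1)), 1L)

  fused <- mk_vol(c(rep(14, 5), rep(22, 5)))   # 8 um lateral jump at plane 6
  prf <- centroid_displacement_profile(fused, c(1, 1, 1))
  expect_equal(which.max(prf$value), 6L)
  expect_equal(max(prf$value), 8, tolerance = 1e-9)
  parts <- split_by_displacement(fused, prf, seg_params(min_volume = 1))
  expect_length(parts, 2L)
  expect_equal(parts[[1]]$planes, 1:5)
  expect_equal(parts[[2]]$planes, 6:10)

  # a helix drifting 1 px/plane has no isolated peak: never split
  helix <- mk_vol(seq(12, 26, by = 2))
  prh <- centroid_displacement_profile(helix, c(1, 1, 1))
  expect_length(split_by_displacement(helix, prh, seg_params(min_volume = 1)), 1L)

  # 2-plane volumes fall under the span precondition
  two <- mk_vol(c(14, 22))
  prt <- centroid_displacement_profile(two, c(1, 1, 1))
  expect_length(split_by_displacement(two, prt, seg_params(min_volume = 1)), 1L)
})

test_that("splitting conserves voxels up to the interface plane", {
  sc <- generate_scene(scene_spec(n_nuclei = 2, field_um = c(30, 30, 40),
                                  mode = "stacked", seed = 8,
                                  radius_range = c(4, 4.5)))
  merged <- sc$labels
  merged$data[merged$data == 2L] <- 1L
  v <- volume_from_labels(merged, 1L)
  pr <- intensity_ratio_profile(v, sc$intensity)
  parts <- split_by_intensity(v, pr, seg_params(), sc$labels$calibration)
  if (length(parts) == 2L) {
    got <- sum(lengths(parts[[1]]$masks)) + sum(lengths(parts[[2]]$masks))
    dropped <- setdiff(v$planes, c(parts[[1]]$planes, parts[[2]]$planes))
    lost <- sum(lengths(v$masks[match(dropped, v$planes)]))
    expect_equal(got + lost, sum(lengths(v$masks)))
    expect_lte(length(dropped), 1L)
  }
})

test_that("morphological smoothing removes a lateral spur and is near-idempotent", {
  lab <- array(0L, c(30, 30, 12))
  xs <- matrix(1:30, 30, 30); ys <- t(xs)
  for (z in 3:10) lab[, , z][(xs - 15)^2 + (ys - 15)^2 <= 36] <- 1L
  lab[22, 15, 6] <- 1L; lab[23, 15, 6] <- 1L   # 2-px lateral spur
  v <- volume_from_labels(label_volume(lab), 1L)
  sm <- smooth_volume(v, c(30L, 30L, 12L), c(1, 1, 1))
  vox <- function(v) sum(lengths(v$masks))
  k6 <- match(6L, sm$planes)
  expect_false(nucridge:::lin_idx(23L, 15L, 30L) %in% sm$masks[[k6]])
  # near-idempotence
  sm2 <- smooth_volume(sm, c(30L, 30L, 12L), c(1, 1, 1))
  expect_lt(abs(vox(sm2) - vox(sm)) / vox(sm), 0.01)

  # an already smooth ellipsoid barely changes
  el <- array(0L, c(30, 30, 16))
  for (z in 1:16) {
    r2 <- 36 * (1 - ((z - 8.5) / 6.5)^2)
    if (r2 > 0) el[, , z][(xs - 15)^2 + (ys - 15)^2 <= r2] <- 1L
  }
  ve <- volume_from_labels(label_volume(el), 1L)
  sme <- smooth_volume(ve, c(30L, 30L, 16L), c(1, 1, 1))
  expect_lt(abs(vox(sme) - vox(ve)) / vox(ve), 0.05)
})
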