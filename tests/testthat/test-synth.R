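# Synthetic scene generator and degradation operations.

test_that("scene generation honours counts, modes and seeds", {
  s0 <- generate_scene(scene_spec(n_nuclei = 0, seed = 1))
  expect_true(all(s0$labels$data == 0L))
  expect_true(all(s0$intensity$data == 150))

  sp <- scene_spec(n_nuclei = 10, field_um = c(70, 70, 30), mode = "sparse", seed = 2)
  s1 <- generate_scene(sp)
  ids <- setdiff(unique(as.vector(s1$labels$data)), 0L)
  expect_length(ids, 10L)
  # sparse nuclei are pairwise non-adjacent: no two labels touch
  d <- s1$labels$data
  touching <- FALSE
  for (sh in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    a <- d[1:(dim(d)[1] - sh[1]), 1:(dim(d)[2] - sh[2]), 1:(dim(d)[3] - sh[3])]
    b <- d[(1 + sh[1]):dim(d)[1], (1 + sh[2]):dim(d)[2], (1 + sh[3]):dim(d)[3]]
    touching <- touching || any(a > 0 & b > 0 & a != b)
  }
  expect_false(touching)
  # identical seed, identical scene
  s2 <- generate_scene(sp)
  expect_identical(s1$intensity$data, s2$intensity$data)
  expect_identical(s1$labels$data, s2$labels$data)
})

test_that("a single sphere's GT volume matches the analytic value", {
  sp <- scene_spec(n_nuclei = 1, field_um = c(20, 20, 20), calibration = c(1, 1, 1),
                   radius_range = c(5, 5), axis_ratio_range = c(1, 1), seed = 3)
  s <- generate_scene(sp)
  vx <- sum(s$labels$data == 1L)
  expect_equal(vx, 4 / 3 * pi * 125, tolerance = 0.05)
})

test_that("shell intensities wrap a dimmer interior", {
  sp <- scene_spec(n_nuclei = 1, field_um = c(24, 24, 24), calibration = c(0.5, 0.5, 1),
                   radius_range = c(5, 5), seed = 4)
  s <- generate_scene(sp)
  mid <- round(s$intensity$shape[3] / 2)
  pl <- get_plane(s$intensity, mid)
  lab <- s$labels$data[, , mid]
  expect_true(any(pl == 3000))
  inner <- pl[lab == 1L & pl < 3000]
  expect_true(all(inner %in% c(600)))
})

test_that("noise addition is calibrated, clipped and seed-reproducible", {
  v <- intensity_volume(array(1000, c(50, 50, 8)), bit_depth = 12)
  expect_identical(add_noise(v, 0, 1)$data, v$data)
  n1 <- add_noise(v, 50, seed = 42)
  expect_equal(sd(n1$data), 50, tolerance = 0.05)
  expect_true(all(n1$data >= 0 & n1$data <= 4095))
  n2 <- add_noise(v, 50, seed = 42)
  expect_identical(n1$data, n2$data)
  expect_error(add_noise(v, -1), class = "nucridge_bad_params")
})

test_that("z resampling decimates exactly and preserves label volumes approximately", {
  a <- array(sample(0:100, 16 * 16 * 8, TRUE), c(16, 16, 8))
  v <- intensity_volume(a, calibration = c(1, 1, 0.5))
  expect_identical(resample_z(v, 0.5), v)
  half <- resample_z(v, 1)
  expect_equal(half$shape[3], 4L)
  expect_equal(half$calibration[3], 1)
  for (k in 1:4) expect_true(any(vapply(1:8, function(z)
    identical(half$data[, , k], a[, , z]), logical(1))))

  # sphere GT resampled 0.5 -> 2.0 keeps its volume within 15%
  sp <- scene_spec(n_nuclei = 1, field_um = c(16, 16, 16), calibration = c(0.5, 0.5, 0.5),
                   radius_range = c(5, 5), axis_ratio_range = c(1, 1), seed = 5)
  s <- generate_scene(sp)
  lab2 <- resample_z(s$labels, 2)
  vol0 <- sum(s$labels$data == 1L) * prod(s$labels$calibration)
  vol2 <- sum(lab2$data == 1L) * prod(lab2$calibration)
  expect_equal(vol2, vol0, tolerance = 0.15)
  expect_error(resample_z(v, 0), class = "nucridge_bad_params")
})

test_that("bit-depth reduction maps the full range linearly", {
  v <- intensity_volume(array(c(0, 4095, 2048), c(3, 1, 1)), bit_depth = 12)
  expect_identical(reduce_bit_depth(v, 12), v)
  v8 <- reduce_bit_depth(v, 8)
  expect_equal(as.vector(v8$data[, 1, 1]), c(0, 255, 128))
  ramp <- intensity_volume(array(0:4095, c(4096, 1, 1)), bit_depth = 12)
  r8 <- reduce_bit_depth(ramp, 8)$data
  expect_true(all(diff(r8[, 1, 1]) >= 0))
  expect_true(all(diff(r8[, 1, 1]) <= 1))
  expect_error(reduce_bit_depth(v, 10), class = "nucridge_bad_params")
})

test_that("axial falloff dims deep planes while GT is untouched", {
  sp0 <- scene_spec(n_nuclei = 1, field_um = c(24, 24, 24), radius_range = c(5, 5),
                    mode = "sparse", seed = 6, falloff = 0)
  spf <- scene_spec(n_nuclei = 1, field_um = c(24, 24, 24), radius_range = c(5, 5),
                    mode = "sparse", seed = 6, falloff = 0.1)
  s0 <- generate_scene(sp0); sf <- generate_scene(spf)
  expect_identical(s0$labels$data, sf$labels$data)
  zs <- which(apply(sf$labels$data == 1L, 3, any))
  shallow <- max(get_plane(sf$intensity, zs[2]))
  deep <- max(get_plane(sf$intensity, zs[length(zs) - 1]))
  expect_lt(deep, shallow)
})

test_that("scenes round-trip to disk with a JSON sidecar", {
  sp <- scene_spec(n_nuclei = 2, field_um = c(20, 20, 16), seed = 7)
  s <- generate_scene(sp)
  pre <- file.path(withr::local_tempdir(), "scene")
  files <- write_scene(s, sp, pre)
  v <- read_volume(files["intensity"])
  expect_identical(v$data, s$intensity$data)
  l <- read_label_volume(files["labels"])
  expect_identical(l$data, s$labels$data)
  js <- jsonlite::read_json(files["spec"])
  expect_equal(js$n_nuclei, 2L)
  expect_equal(js$mode, "sparse")
})
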