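# Error taxonomy, metrics and the brute-force matching oracle.

test_that("a perfect segmentation is all accurate with unit metrics", {
  gt <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:8, y = 3:8, z = 2:4),
    list(id = 2L, x = 12:17, y = 12:17, z = 3:5)))
  rep <- benchmark_segmentation(gt, gt)
  expect_equal(unname(rep$counts["accurate"]), 2)
  expect_equal(sum(rep$counts[c("merge", "miss", "split", "spurious")]), 0)
  expect_equal(rep$precision, 1); expect_equal(rep$recall, 1)
  expect_equal(rep$f_measure, 1); expect_equal(rep$mean_ji, 1)
})

test_that("one test instance covering two GT nuclei is a merge", {
  gt <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:8, y = 3:8, z = 2:4),
    list(id = 2L, x = 10:15, y = 3:8, z = 2:4)))
  te <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:15, y = 3:8, z = 2:4)))
  m <- match_instances(gt, te)
  expect_equal(m$gt$class, c("merge", "merge"))
  expect_equal(m$test$class, "merge")
  rep <- compute_metrics(m)
  expect_equal(unname(rep$counts["accurate"]), 0)
  expect_equal(unname(rep$counts["merge"]), 2)
})

test_that("a split GT plus a blob in empty space is one split and one spurious", {
  gt <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:12, y = 3:12, z = 2:5)))
  te <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:7, y = 3:12, z = 2:5),     # half A
    list(id = 2L, x = 8:12, y = 3:12, z = 2:5),    # half B
    list(id = 3L, x = 16:19, y = 16:19, z = 2:5))) # blob in empty space
  m <- match_instances(gt, te)
  expect_equal(m$gt$class, "split")
  expect_equal(sort(m$test$class), c("split", "split", "spurious"))
  # exhaustive overlap oracle agrees
  bf <- brute_force_match(gt, te)
  expect_equal(m$gt$class, bf$gt)
  expect_equal(m$test$class, bf$test)
})

test_that("metric formulas follow the counts", {
  # 9 accurate of 10 GT, 1 miss, nothing else
  boxes <- lapply(1:10, function(i)
    list(id = i, x = ((i - 1) %% 5) * 6 + 1:4, y = ((i - 1) %/% 5) * 8 + 1:4, z = 1:3))
  gt <- toy_labels(c(32L, 18L, 4L), boxes)
  te <- toy_labels(c(32L, 18L, 4L), boxes[1:9])
  rep <- benchmark_segmentation(gt, te)
  expect_equal(rep$recall, 0.9)
  expect_equal(rep$precision, 1)
  expect_equal(rep$f_measure, 2 * 0.9 / 1.9)
  # zero accurate: F = 0
  te0 <- toy_labels(c(32L, 18L, 4L), list(list(id = 1L, x = 29:32, y = 15:18, z = 4)))
  rep0 <- benchmark_segmentation(gt, te0)
  expect_equal(rep0$f_measure, 0)
  # empty GT: warning and NaN recall
  empty <- toy_labels(c(32L, 18L, 4L), list())
  expect_warning(repE <- compute_metrics(match_instances(empty, te0)), "recall")
  expect_true(is.nan(repE$recall))
})

test_that("classification equals the brute-force oracle on random toys", {
  fails <- 0L
  for (seed in 1:60) {
    toy <- random_toy_pair(seed)
    m <- match_instances(toy$gt, toy$test)
    bf <- brute_force_match(toy$gt, toy$test)
    expect_equal(m$gt$class, bf$gt, info = paste("seed", seed))
    expect_equal(m$test$class, bf$test, info = paste("seed", seed))
    # conservation: every GT instance classified exactly once
    expect_equal(sum(m$gt$class %in% c("accurate", "merge", "split", "miss")),
                 nrow(m$gt))
  }
})

test_that("swapping GT and test exchanges miss/spurious and merge/split", {
  gt <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:8, y = 3:8, z = 2:4),
    list(id = 2L, x = 10:15, y = 3:8, z = 2:4),
    list(id = 3L, x = 3:8, y = 12:17, z = 2:4)))
  te <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:15, y = 3:8, z = 2:4)))   # merges 1+2, misses 3
  f <- compute_metrics(match_instances(gt, te))
  b <- compute_metrics(match_instances(te, gt))
  expect_equal(unname(f$counts["merge"]), 2)
  expect_equal(unname(b$counts["split"]), 1)
  expect_equal(unname(f$counts["miss"]), 1)
  expect_equal(unname(b$counts["spurious"]), 1)
})

test_that("the jaccard matching dialect is selectable", {
  gt <- toy_labels(c(20L, 20L, 4L), list(list(id = 1L, x = 3:10, y = 3:10, z = 1:3)))
  te <- toy_labels(c(20L, 20L, 4L), list(list(id = 1L, x = 5:12, y = 3:10, z = 1:3)))
  mj <- match_instances(gt, te, rule = "jaccard", cut = 0.65)
  mm <- match_instances(gt, te, rule = "majority")
  expect_equal(mj$gt$class, "miss")       # JI = 144/240 = 0.6 < 0.65
  expect_equal(mm$gt$class, "accurate")   # mutual majority holds
})

test_that("error maps carry the class codes and a legend sidecar", {
  gt <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:8, y = 3:8, z = 2:4),
    list(id = 2L, x = 10:15, y = 3:8, z = 2:4),
    list(id = 3L, x = 3:8, y = 12:17, z = 2:4)))
  te <- toy_labels(c(20L, 20L, 6L), list(
    list(id = 1L, x = 3:15, y = 3:8, z = 2:4)))
  m <- match_instances(gt, te)
  f <- withr::local_tempfile(fileext = ".tif")
  write_error_map(m, gt, te, f)
  map <- read_label_volume(f)
  expect_setequal(setdiff(unique(as.vector(map$data)), 0L), c(2L, 5L))
  expect_true(file.exists(paste0(f, ".legend.txt")))
  # all-accurate map carries only code 1
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_error_map(match_instances(gt, gt), gt, gt, f2)
  expect_setequal(setdiff(unique(as.vector(read_label_volume(f2)$data)), 0L), 1L)
})

test_that("batch mode writes Summary.tsv and per-image maps", {
  gt <- toy_labels(c(16L, 16L, 4L), list(list(id = 1L, x = 3:8, y = 3:8, z = 1:3)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  write_label_volume(gt, file.path(d1, "img1.tif"))
  write_label_volume(gt, file.path(d2, "img1.tif"))
  df <- benchmark_batch(d1, d2, d3)
  expect_equal(nrow(df), 1L)
  expect_equal(df$f_measure, 1)
  expect_true(file.exists(file.path(d3, "Summary.tsv")))
  expect_true(file.exists(file.path(d3, "errormap_img1.tif")))
})
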