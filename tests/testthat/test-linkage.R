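# 2D -> 3D linkage: Jaccard arithmetic, link-graph rules, ambiguity
# resolution and JI-ordered labelling.

disc_px <- function(cx, cy, r, nx = 40) {
  xs <- matrix(seq_len(nx), nx, nx); ys <- t(xs)
  which((xs - cx)^2 + (ys - cy)^2 <= r^2)
}

mk_area <- function(id, plane, px, nx = 40, posterior = 0.9) {
  list(id = id, plane = plane, px = px,
       centroid = nucridge:::px_centroid(px, nx),
       area = length(px), posterior = posterior)
}

test_that("jaccard index matches counted overlaps", {
  a <- disc_px(15, 15, 5)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, disc_px(32, 32, 4)), 0)
  expect_equal(jaccard(integer(0), integer(0)), 0)
  # two 10x10 squares overlapping in a 10x5 half
  sq <- function(x0, y0) as.vector(outer(x0:(x0 + 9), (y0:(y0 + 9) - 1) * 40, "+"))
  expect_equal(jaccard(sq(5, 5), sq(5, 10)), 50 / 150)
})

test_that("identical discs across planes form a single chain", {
  px <- disc_px(20, 20, 6)
  areas <- lapply(1:5, function(z) mk_area(z, z, px))
  p <- seg_params(max_jump = 1)
  g <- build_link_graph(areas, p)
  expect_equal(nrow(g), 4L)
  expect_true(all(g$dplanes == 1L))
  expect_true(all(g$ji == 1))
  lv <- label_volumes(areas, g, p, c(1, 1, 1), c(40L, 40L, 5L))
  expect_length(lv$volumes, 1L)
})

test_that("max_jump bridges a missing plane with one longer edge", {
  px <- disc_px(20, 20, 6)
  areas <- lapply(c(1, 2, 4, 5), function(z) mk_area(z, z, px))
  g1 <- build_link_graph(areas, seg_params(max_jump = 1))
  expect_equal(nrow(g1), 2L)   # 1-2 and 4-5 only
  g2 <- build_link_graph(areas, seg_params(max_jump = 2))
  expect_equal(nrow(g2), 3L)
  expect_equal(sort(unique(g2$dplanes)), c(1L, 2L))
  # the area already linked at dplanes 1 receives no longer-jump edge
  expect_equal(sum(g2$dplanes == 2L), 1L)
})

test_that("overlap and centroid-distance thresholds gate edges", {
  a1 <- mk_area(1, 1, disc_px(20, 20, 8))
  a2 <- mk_area(2, 2, disc_px(24, 20, 4))   # small disc inside reach
  p <- seg_params(overlap_threshold = 0.5, max_intercentroid_distance = 5)
  g <- build_link_graph(list(a1, a2), p)
  expect_equal(nrow(g), 1L)   # overlap of a2 within a1 is large (max rule)
  # with the min dialect the small fraction of a1 fails the cut
  pmin_ <- seg_params(overlap_threshold = 0.5, overlap_mode = "min",
                      max_intercentroid_distance = 5)
  expect_equal(nrow(build_link_graph(list(a1, a2), pmin_)), 0L)
  # centroid gate
  pfar <- seg_params(overlap_threshold = 0.1, max_intercentroid_distance = 1)
  expect_equal(nrow(build_link_graph(list(a1, a2), pfar)), 0L)
})

test_that("a merged co-section is divided between its two partners", {
  # planes 1 and 3: two separate discs; plane 2: one merged blob
  left <- disc_px(14, 20, 5); right <- disc_px(26, 20, 5)
  merged <- union(disc_px(14, 20, 5), union(disc_px(26, 20, 5), disc_px(20, 20, 4)))
  areas <- list(mk_area(1, 1, left), mk_area(2, 1, right),
                mk_area(3, 2, merged),
                mk_area(4, 3, left), mk_area(5, 3, right))
  p <- seg_params(max_jump = 1, overlap_threshold = 0.3, min_volume = 10)
  res <- resolve_ambiguities(areas, p, c(1, 1, 1), 40)
  lv <- label_volumes(res$areas, res$graph, p, c(1, 1, 1), c(40L, 40L, 3L))
  expect_length(lv$volumes, 2L)
  # each output volume spans all three planes
  expect_true(all(vapply(lv$volumes, function(v) length(v$planes), numeric(1)) == 3))
  # and the merged plane's pixels are split disjointly
  z2 <- lv$labels$data[, , 2]
  expect_setequal(which(z2 > 0), merged)
})

test_that("a weak competing edge is pruned, keeping the max-JI partner", {
  big <- disc_px(20, 20, 7)
  off <- disc_px(25, 25, 3)   # small overlap with big
  areas <- list(mk_area(1, 1, big), mk_area(2, 1, off),
                mk_area(3, 2, big))
  p <- seg_params(max_jump = 1, overlap_threshold = 0.05,
                  max_intercentroid_distance = 30, min_volume = 1)
  g0 <- build_link_graph(areas, p)
  expect_equal(nrow(g0), 2L)   # both plane-1 areas point at big@2
  res <- resolve_ambiguities(areas, p, c(1, 1, 1), 40)
  keep <- res$graph
  expect_equal(nrow(keep), 1L)
  expect_equal(keep$src, 1)    # the identical disc wins
})

test_that("single in-edges pass through resolution unchanged", {
  px <- disc_px(20, 20, 6)
  areas <- list(mk_area(1, 1, px), mk_area(2, 2, px))
  p <- seg_params()
  res <- resolve_ambiguities(areas, p, c(1, 1, 1), 40)
  expect_equal(nrow(res$graph), 1L)
})

test_that("volume constraints drop specks and flag oversized chains", {
  speck <- mk_area(1, 1, disc_px(10, 10, 1.2))
  tower <- lapply(1:30, function(z) mk_area(z + 1, z, disc_px(25, 25, 8)))
  areas <- c(list(speck), tower)
  p <- seg_params(min_volume = 40, max_volume = 500)
  res <- resolve_ambiguities(areas, p, c(1, 1, 1), 40)
  lv <- label_volumes(res$areas, res$graph, p, c(1, 1, 1), c(40L, 40L, 31L))
  expect_length(lv$volumes, 1L)          # speck dropped
  expect_true(lv$volumes[[1]]$oversized) # tower flagged for splitting
})

test_that("labelling is stable under node insertion order (up to renumbering)", {
  pxA <- disc_px(14, 14, 5); pxB <- disc_px(28, 28, 5)
  mk <- function(ord) {
    areas <- list()
    for (z in 1:4) {
      areas <- c(areas, list(mk_area(length(areas) + 1, z, pxA),
                             mk_area(length(areas) + 2, z, pxB)))
    }
    areas[ord]
  }
  p <- seg_params(min_volume = 1)
  run <- function(areas) {
    for (i in seq_along(areas)) areas[[i]]$id <- i
    res <- resolve_ambiguities(areas, p, c(1, 1, 1), 40)
    lv <- label_volumes(res$areas, res$graph, p, c(1, 1, 1), c(40L, 40L, 4L))
    lv$labels$data
  }
  l1 <- run(mk(1:8))
  l2 <- run(mk(8:1))
  # same partition of voxels into instances
  key1 <- paste(l1[l1 > 0], collapse = ",")
  tab <- table(l1, l2)
  expect_true(all(rowSums(tab > 0)[-1] == 1))  # bijection between labels
  expect_equal(sum(l1 > 0), sum(l2 > 0))
})

test_that("a corrupted merged plane between correct neighbours is rescued into two volumes", {
  left <- disc_px(14, 20, 5); right <- disc_px(27, 20, 5)
  merged <- union(disc_px(14, 20, 5.5), disc_px(27, 20, 5.5))
  areas <- list()
  for (z in c(1, 2)) areas <- c(areas, list(mk_area(length(areas) + 1, z, left),
                                            mk_area(length(areas) + 2, z, right)))
  areas <- c(areas, list(mk_area(length(areas) + 1, 3, merged)))
  for (z in c(4, 5)) areas <- c(areas, list(mk_area(length(areas) + 1, z, left),
                                            mk_area(length(areas) + 2, z, right)))
  p <- seg_params(max_jump = 2, overlap_threshold = 0.3, min_volume = 10)
  res <- resolve_ambiguities(areas, p, c(1, 1, 1), 40)
  lv <- label_volumes(res$areas, res$graph, p, c(1, 1, 1), c(40L, 40L, 5L))
  expect_length(lv$volumes, 2L)
  spans <- vapply(lv$volumes, function(v) length(v$planes), numeric(1))
  expect_true(all(spans == 5))
})
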