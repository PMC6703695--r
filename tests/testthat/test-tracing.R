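# Ridge tracing on drawn geometries with known pixel structure.

ridge_of <- function(plane, scale = 1) ridge_nms(steerable_ridge_response(plane, scale))

test_that("a clean circle closes into a loop at the origin (stop code O)", {
  # a 2-px-thick ring, as an imaged envelope appears
  p <- draw_circle_plane(40, 40, 20, 20, 12) +
    draw_circle_plane(40, 40, 20, 20, 12.8)
  tree <- build_tree(ridge_of(p), list(x = 32, y = 20), fixture_params())
  codes <- vapply(tree$ridglets, `[[`, character(1), "stop")
  expect_true(any(codes %in% c("O", "L")))
  cands <- enumerate_candidates(tree)
  expect_gte(length(cands), 1L)
  # the loop candidate recovers >= 95% of the enclosed disc (Jaccard)
  ras <- rasterize(cands[[1]]$contour, 40, 40)
  xs <- matrix(1:40, 40, 40); ys <- t(xs)
  disc <- which((xs - 20)^2 + (ys - 20)^2 <= 12.9^2)
  got <- c(ras$outline, ras$interior)
  expect_gte(jaccard(got, disc), 0.95)
})

test_that("a seed on background yields an empty tree", {
  p <- draw_circle_plane(40, 40, 20, 20, 12)
  tree <- build_tree(ridge_of(p), list(x = 5, y = 5), fixture_params())
  expect_length(tree$ridglets, 0)
})

test_that("tracing a straight ridge reproduces its pixel run and stops by distance", {
  p <- matrix(0, 80, 20); p[5:75, 10] <- 100
  pars <- fixture_params(max_trace_distance = 20)
  tree <- build_tree(ridge_of(p), list(x = 40, y = 10), pars)
  codes <- vapply(tree$ridglets, `[[`, character(1), "stop")
  expect_true("D" %in% codes)
  # every traced pixel lies on the drawn line
  for (r in tree$ridglets) expect_true(all(r$path[, 2] == 10))
  # and both directions were followed monotonically
  expect_length(tree$ridglets, 2L)
  dx1 <- diff(tree$ridglets[[1]]$path[, 1])
  expect_true(all(dx1 == dx1[1]))
})

test_that("intensity drop stops the trace where the ridge fades", {
  p <- matrix(0, 60, 20)
  p[5:55, 10] <- c(rep(100, 26), seq(100, 2, length.out = 25))  # fading tail
  pars <- fixture_params(intensity_drop_fraction = 0.3, max_trace_distance = 500)
  tree <- build_tree(ridge_of(p), list(x = 15, y = 10), pars)
  codes <- vapply(tree$ridglets, `[[`, character(1), "stop")
  expect_true("I" %in% codes)
  # the I-stopped ridglet never entered the deep-faded zone
  ri <- tree$ridglets[[which(codes == "I")[1]]]
  expect_true(all(ri$path[, 1] < 52))
})

test_that("a hairpin triggers the sharp-turn stop near the apex", {
  # two near-parallel arms meeting at x = 45 (apex), 3 px apart
  p <- matrix(0, 50, 30)
  p[5:45, 14] <- 100
  p[5:45, 17] <- 100
  for (k in 0:1) p[45 + k, 15:16] <- 100
  pars <- fixture_params(sharp_turn_max_angle = 120, turn_window = 5,
                         max_trace_distance = 500)
  tree <- build_tree(ridge_of(p), list(x = 20, y = 14), pars)
  codes <- vapply(tree$ridglets, `[[`, character(1), "stop")
  expect_true("T" %in% codes)
  rt <- tree$ridglets[[which(codes == "T")[1]]]
  apex_dist <- abs(rt$path[nrow(rt$path), 1] - 45)
  expect_lte(apex_dist, pars$turn_window + 2)
})

test_that("a theta shape produces a branched tree with crossings", {
  p <- draw_circle_plane(50, 50, 25, 25, 15)
  p[11:39, 25] <- 100   # chord through the circle
  tree <- build_tree(ridge_of(p), list(x = 25, y = 10), fixture_params())
  expect_gte(length(tree$leaves), 2L)
  expect_gte(length(tree$crossings), 1L)
  # candidates must include the full disc and at least one sub-shape
  cands <- enumerate_candidates(tree)
  expect_gte(length(cands), 2L)
  xs <- matrix(1:50, 50, 50); ys <- t(xs)
  disc <- which((xs - 25)^2 + (ys - 25)^2 <= 15.5^2)
  jis <- vapply(cands, function(cd) {
    ras <- rasterize(cd$contour, 50, 50)
    if (is.null(ras)) return(0)
    jaccard(c(ras$outline, ras$interior), disc)
  }, numeric(1))
  expect_gte(max(jis), 0.9)
  expect_true(any(jis > 0.2 & jis < 0.75))   # a half-shape exists too
})

test_that("trees are deterministic and bounded", {
  set.seed(77)
  p <- matrix(runif(50 * 50, 0, 10), 50, 50)
  p[draw_circle_plane(50, 50, 25, 25, 12) > 0] <- 100
  pars <- fixture_params()
  rr <- ridge_of(p)
  t1 <- build_tree(rr, list(x = 37, y = 25), pars)
  t2 <- build_tree(rr, list(x = 37, y = 25), pars)
  expect_identical(t1, t2)
  expect_lte(length(t1$claimed), pi * pars$max_trace_distance^2)
  # every ridglet ends with exactly one known stop code
  for (r in t1$ridglets) expect_true(r$stop %in% nucridge:::STOP_CODES)
})

test_that("claimed pixels are unique within a tree", {
  p <- draw_circle_plane(50, 50, 25, 25, 15)
  p[11:39, 25] <- 100
  tree <- build_tree(ridge_of(p), list(x = 40, y = 25), fixture_params())
  expect_false(any(duplicated(tree$claimed)))
})
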