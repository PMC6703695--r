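# Programmatic fixtures shared across the test files. Everything is
# generated in code; nothing is read from disk.

# A 1-px-wide digital circle drawn onto a plane.
draw_circle_plane <- function(nx, ny, cx, cy, r, val = 100) {
  m <- matrix(0, nx, ny)
  th <- seq(0, 2 * pi, length.out = max(64L, ceiling(8 * r)))
  xs <- round(cx + r * cos(th)); ys <- round(cy + r * sin(th))
  m[unique(cbind(xs, ys))] <- val
  m
}

# Ordered pixel chain of a digital circle: the boundary of the digital
# disc, walked by angle (valid 8-connected convex chain).
circle_chain <- function(cx, cy, r) {
  span <- ceiling(r) + 1L
  xs <- (cx - span):(cx + span)
  ys <- (cy - span):(cy + span)
  g <- expand.grid(x = xs, y = ys)
  d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  inside <- d <= r
  onb <- inside & vapply(seq_len(nrow(g)), function(i) {
    any(sqrt((g$x[i] + c(-1, 1, 0, 0) - cx)^2 +
               (g$y[i] + c(0, 0, -1, 1) - cy)^2) > r)
  }, logical(1))
  b <- g[onb, ]
  ord <- order(atan2(b$y - cy, b$x - cx))
  as.matrix(b[ord, c("x", "y")])
}

# Closed pixel chain through a polygon's corners (last -> first closes).
walk_chain <- function(pts) {
  pts <- rbind(pts, pts[1, , drop = FALSE])
  out <- NULL
  for (i in seq_len(nrow(pts) - 1)) {
    s <- bres_seg(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2])
    if (!is.null(out)) s <- s[-1, , drop = FALSE]
    out <- rbind(out, s)
  }
  if (all(out[1, ] == out[nrow(out), ])) out <- out[-nrow(out), , drop = FALSE]
  out
}

# local Bresenham so fixtures do not depend on package internals
bres_seg <- function(x0, y0, x1, y1) {
  n <- max(abs(x1 - x0), abs(y1 - y0)) + 1L
  cbind(round(seq(x0, x1, length.out = n)), round(seq(y0, y1, length.out = n)))
}

# Hand-built ridglet tree: arms fanning from a root, each one leaf.
fan_tree <- function(root, angles, len = 12) {
  ridglets <- lapply(angles, function(a) {
    th <- a * pi / 180
    path <- cbind(round(root[1] + seq(0, len) * cos(th)),
                  round(root[2] - seq(0, len) * sin(th)))
    path <- path[c(TRUE, rowSums(abs(diff(path))) > 0), , drop = FALSE]
    list(path = path, stop = "I", parent = 0L, depth = 1L, branch_idx = 0L)
  })
  structure(list(root = root, ridglets = ridglets,
                 leaves = seq_along(angles), claimed = integer(0),
                 crossings = integer(0)),
            class = "RidgletTree")
}

# Axis-aligned rectangle chain (clockwise), corners included once.
rect_chain <- function(x0, y0, x1, y1) {
  rbind(cbind(x0:x1, y0),
        cbind(x1, (y0 + 1):y1),
        cbind(x1:x0, y1)[-1, , drop = FALSE],
        cbind(x0, y1:(y0 + 1))[-1, , drop = FALSE])
}

# Solid shell ring on a plane: outline at `val_shell`, inside `val_in`,
# background `val_bg`.
draw_shell_plane <- function(nx, ny, cx, cy, r, thick = 2,
                             val_shell = 200, val_in = 40, val_bg = 10) {
  m <- matrix(val_bg, nx, ny)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  m[d <= r] <- val_in
  m[d <= r & d >= r - thick] <- val_shell
  m
}

# Small 3D toy label volume from a list of cuboid specs
# list(id, x0:x1, y0:y1, z0:z1).
toy_labels <- function(shape, boxes, calibration = c(1, 1, 1)) {
  a <- array(0L, shape)
  for (b in boxes) a[b$x, b$y, b$z] <- b$id
  label_volume(a, calibration)
}

# A NucleusVolume built directly from a label id in a LabelVolume.
volume_from_labels <- function(labels, id) {
  shp <- labels$shape
  planes <- which(apply(labels$data == id, 3, any))
  masks <- lapply(planes, function(z) which(labels$data[, , z] == id))
  cents <- t(vapply(masks, nucridge:::px_centroid, numeric(2), nx = shp[1]))
  v <- list(id = 1L, planes = planes, masks = masks, centroids_px = cents,
            volume_um3 = sum(lengths(masks)) * prod(labels$calibration),
            oversized = FALSE)
  class(v) <- "NucleusVolume"
  v
}

# Brute-force benchmark classification used as the oracle for
# match_instances: literal re-statement of the mutual-majority rule with
# direct voxel loops, no shared code with the implementation.
brute_force_match <- function(gt, test, cut = 0.5) {
  gv <- as.vector(gt$data); tv <- as.vector(test$data)
  gids <- sort(setdiff(unique(gv), 0)); tids <- sort(setdiff(unique(tv), 0))
  gclass <- stats::setNames(rep("miss", length(gids)), gids)
  tclass <- stats::setNames(rep("spurious", length(tids)), tids)
  maj_of_g <- stats::setNames(rep(NA_integer_, length(gids)), gids)
  covers <- list()
  for (g in gids) {
    gpx <- which(gv == g)
    best <- NA_integer_
    cov <- integer(0)
    for (t in tids) {
      tpx <- which(tv == t)
      ov <- length(intersect(gpx, tpx))
      if (ov > cut * length(gpx)) best <- t
      if (ov > cut * length(tpx)) cov <- c(cov, t)
    }
    maj_of_g[as.character(g)] <- best
    covers[[as.character(g)]] <- cov
  }
  tt <- table(maj_of_g[!is.na(maj_of_g)])
  merge_targets <- as.integer(names(tt)[tt >= 2])
  for (g in gids) {
    gk <- as.character(g)
    t_ <- maj_of_g[gk]
    if (!is.na(t_) && t_ %in% merge_targets) {
      gclass[gk] <- "merge"; tclass[as.character(t_)] <- "merge"
    } else if (length(covers[[gk]]) >= 2) {
      gclass[gk] <- "split"
      for (t in covers[[gk]])
        if (tclass[as.character(t)] == "spurious") tclass[as.character(t)] <- "split"
    } else if (!is.na(t_) && t_ %in% covers[[gk]]) {
      gclass[gk] <- "accurate"; tclass[as.character(t_)] <- "accurate"
    }
  }
  list(gt = unname(gclass), test = unname(tclass),
       precision = if (length(tids)) sum(gclass == "accurate") / length(tids) else NaN,
       recall = if (length(gids)) sum(gclass == "accurate") / length(gids) else NaN)
}

# Random small toy label pair generator for oracle-equivalence tests.
random_toy_pair <- function(seed) {
  set.seed(seed)
  shape <- c(20L, 20L, 6L)
  mk <- function(n) {
    a <- array(0L, shape)
    for (i in seq_len(n)) {
      cx <- sample(3:18, 1); cy <- sample(3:18, 1); cz <- sample(2:5, 1)
      r <- sample(2:4, 1)
      xs <- max(1, cx - r):min(20, cx + r)
      ys <- max(1, cy - r):min(20, cy + r)
      zs <- max(1, cz - 1):min(6, cz + 1)
      a[xs, ys, zs] <- i
    }
    a
  }
  ng <- sample(1:5, 1); nt <- sample(1:5, 1)
  g <- mk(ng)
  # test volume: derived from gt with random perturbations, or fresh
  t <- if (stats::runif(1) < 0.5) {
    tt <- g
    if (ng >= 2 && stats::runif(1) < 0.5) tt[tt == ng] <- ng - 1L  # merge
    tt
  } else mk(nt)
  list(gt = label_volume(g), test = label_volume(t))
}

# Shared small scenes for pipeline-level tests (built once per run).
fixture_env <- new.env(parent = emptyenv())

fixture_sparse_scene <- function() {
  if (is.null(fixture_env$sparse)) {
    fixture_env$sparse <- generate_scene(scene_spec(
      n_nuclei = 6, field_um = c(40, 40, 24), mode = "sparse", seed = 7))
  }
  fixture_env$sparse
}

fixture_params <- function(...) seg_params(seed_threshold = 150, ...)

fixture_classifier <- function() {
  if (is.null(fixture_env$classifier)) {
    tsc <- generate_scene(scene_spec(
      n_nuclei = 8, field_um = c(45, 45, 26), mode = "touching", seed = 21))
    tabs <- lapply(c(0, 0.12, 0.25), function(frac) {
      ti <- add_noise(tsc$intensity, frac * 2850, seed = 31)
      make_training_table(ti, tsc$labels, fixture_params(),
                          n_per_class = 10, planes = seq(3, 23, by = 3))
    })
    fixture_env$train_scene <- tsc
    fixture_env$train_table <- do.call(rbind, tabs)
    fixture_env$classifier <- train_classifier(fixture_env$train_table)
  }
  fixture_env$classifier
}
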