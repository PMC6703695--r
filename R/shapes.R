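# Candidate 2D nucleus shapes from ridglet trees.
#
# Every unordered pair of tree leaves defines a candidate: the two
# root-to-leaf ridge paths, closed by the shortest pixel segment between
# the leaf termini. Candidates are rasterised (outline + interior),
# described by intensity and chain-code curvature features, and ranked by
# a Gaussian naive Bayes classifier; the most probable valid shape wins.

# Root-to-leaf pixel path: concatenated ridglet paths along the lineage.
# Children may attach at any index of their parent's path (branch_idx);
# the parent path is truncated at the attachment point.
leaf_lineage <- function(tree, leaf) {
  chain <- integer(0)
  cur <- leaf
  while (cur != 0L) { chain <- c(cur, chain); cur <- tree$ridglets[[cur]]$parent }
  chain
}

full_path <- function(tree, lineage) {
  out <- NULL
  for (j in seq_along(lineage)) {
    r <- tree$ridglets[[lineage[j]]]
    pj <- r$path
    if (j < length(lineage)) {
      b <- tree$ridglets[[lineage[j + 1L]]]$branch_idx
      if (b >= 1L) pj <- pj[seq_len(b), , drop = FALSE]
    }
    if (!is.null(out) && nrow(pj) && all(pj[1L, ] == out[nrow(out), ]))
      pj <- pj[-1L, , drop = FALSE]
    out <- rbind(out, pj)
  }
  out
}

# Assemble the closed contour for a leaf pair; NULL when not closable.
# The two root-to-leaf paths share a pixel prefix; the contour runs from
# the divergence pixel out along one path, across the shortest pixel
# segment between the two leaf termini, and back along the other.
pair_contour <- function(tree, l1, l2) {
  fp1 <- full_path(tree, leaf_lineage(tree, l1))
  fp2 <- full_path(tree, leaf_lineage(tree, l2))
  n1 <- nrow(fp1); n2 <- nrow(fp2)
  L <- 0L
  while (L < min(n1, n2) && all(fp1[L + 1L, ] == fp2[L + 1L, ])) L <- L + 1L
  if (L >= n1 - 1L || L >= n2 - 1L) return(NULL)  # one path contains the other
  d <- if (L >= 1L) fp1[L, , drop = FALSE] else fp1[1L, , drop = FALSE]
  p1 <- fp1[(L + 1L):n1, , drop = FALSE]
  p2 <- fp2[(L + 1L):n2, , drop = FALSE]
  t1 <- p1[nrow(p1), ]; t2 <- p2[nrow(p2), ]
  seg <- bresenham(t1[1L], t1[2L], t2[1L], t2[2L])
  if (nrow(seg) > 2L) seg <- seg[2:(nrow(seg) - 1L), , drop = FALSE] else seg <- NULL
  contour <- rbind(d, p1, seg, p2[rev(seq_len(nrow(p2))), , drop = FALSE])
  close_and_check(contour)
}

# Excise sub-loops from a pixel walk: when a pixel reappears, the
# detour between its two visits is removed, so a self-touching walk
# collapses to the contour that closes at the intersection.
excise_loops <- function(contour) {
  n <- nrow(contour)
  key <- contour[, 1L] * 100000L + contour[, 2L]
  if (!anyDuplicated(key)) return(contour)
  keep <- rep(TRUE, n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  i <- 1L
  while (i <= n) {
    if (!keep[i]) { i <- i + 1L; next }
    k <- as.character(key[i])
    j <- seen[[k]]
    if (!is.null(j)) {
      # drop the detour j+1 .. i (keep the first visit)
      keep[(j + 1L):i] <- FALSE
    } else seen[[k]] <- i
    i <- i + 1L
  }
  contour[keep, , drop = FALSE]
}

# Validate a closed chain: pairwise distinct, consecutive 8-connected.
# Self-touching walks are first repaired by sub-loop excision.
close_and_check <- function(contour) {
  if (is.null(contour) || nrow(contour) < 8L) return(NULL)
  contour <- excise_loops(contour)
  if (nrow(contour) < 8L) return(NULL)
  d <- pmax(abs(diff(contour[, 1L])), abs(diff(contour[, 2L])))
  dlast <- max(abs(contour[1L, ] - contour[nrow(contour), ]))
  if (any(d != 1L) || dlast > 1L || dlast == 0L) return(NULL)
  contour
}

#' Enumerate candidate closed shapes of a ridglet tree
#'
#' One candidate per unordered leaf pair whose closed contour is a simple
#' 8-connected chain; a ridglet that closed onto the root (stop code O)
#' is itself a candidate. Non-closable pairs are dropped silently.
#'
#' @param tree a `RidgletTree` from [build_tree()].
#' @param max_leaves leaves considered, keeping the longest paths.
#' @return list of candidates: each a list with `contour` (ordered closed
#'   chain), `outline`, `interior` (linear pixel indices), `centroid`,
#'   `area`, and the originating `leaf_pair`.
#' @export
enumerate_candidates <- function(tree, max_leaves = 8L) {
  out <- list()
  if (!length(tree$ridglets)) return(out)
  # closed loops first: O-stops close at the root, L-stops close at the
  # pixel where the trace re-met its own path
  for (li in tree$leaves) {
    r <- tree$ridglets[[li]]
    ctr <- NULL
    if (r$stop == "O") {
      ctr <- close_and_check(full_path(tree, leaf_lineage(tree, li)))
    } else if (r$stop == "L" && !is.null(r$loop_px)) {
      j <- which(r$path[, 1L] == r$loop_px[1L] & r$path[, 2L] == r$loop_px[2L])[1L]
      if (!is.na(j) && nrow(r$path) - j >= 8L)
        ctr <- close_and_check(r$path[j:nrow(r$path), , drop = FALSE])
    }
    if (!is.null(ctr))
      out[[length(out) + 1L]] <- list(contour = ctr, leaf_pair = c(li, li))
  }
  lv <- tree$leaves
  if (length(lv) > max_leaves) {
    plen <- vapply(lv, function(li) nrow(tree$ridglets[[li]]$path), numeric(1))
    lv <- lv[order(-plen)][seq_len(max_leaves)]
  }
  if (length(lv) >= 2L) {
    prs <- utils::combn(sort(lv), 2L)
    for (j in seq_len(ncol(prs))) {
      ctr <- pair_contour(tree, prs[1L, j], prs[2L, j])
      if (!is.null(ctr))
        out[[length(out) + 1L]] <- list(contour = ctr, leaf_pair = prs[, j])
    }
  }
  out
}

#' Rasterise a simple closed contour
#'
#' The outline is the chain itself; the interior is the 4-connected
#' region of the complement not reachable from outside the shape's
#' bounding box (parity-safe: an 8-connected closed chain separates the
#' plane into 4-connected components). Area uses the convention
#' `area = |interior| + |outline|` throughout the package.
#'
#' @param contour ordered closed chain, n x 2 matrix of (x, y).
#' @param nx,ny plane dimensions.
#' @return list with `outline`, `interior` (linear indices), `centroid`,
#'   `area`, or `NULL` for degenerate contours with empty interior.
#' @export
rasterize <- function(contour, nx, ny) {
  if (is.null(contour) || nrow(contour) < 8L) return(NULL)
  x0 <- min(contour[, 1L]) - 1L; x1 <- max(contour[, 1L]) + 1L
  y0 <- min(contour[, 2L]) - 1L; y1 <- max(contour[, 2L]) + 1L
  w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
  blocked <- matrix(FALSE, w, h)
  blocked[cbind(contour[, 1L] - x0 + 1L, contour[, 2L] - y0 + 1L)] <- TRUE
  outside <- outside_fill(blocked)
  interior_loc <- which(!blocked & !outside)
  if (!length(interior_loc)) return(NULL)
  ix <- ((interior_loc - 1L) %% w) + x0
  iy <- ((interior_loc - 1L) %/% w) + y0
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  ix <- ix[keep]; iy <- iy[keep]
  ol_keep <- in_bounds(contour, nx, ny)
  outline <- lin_idx(contour[ol_keep, 1L], contour[ol_keep, 2L], nx)
  interior <- lin_idx(ix, iy, nx)
  allpx <- c(outline, interior)
  list(outline = outline, interior = interior,
       centroid = px_centroid(allpx, nx),
       area = length(allpx))
}

FEATURE_NAMES <- c("o_mean", "o_sd", "i_mean", "i_sd", "oi_ratio", "area",
                   "perimeter", "circularity", "convex_frac", "concave_frac",
                   "curv_low", "curv_med", "curv_high")

#' Intensity and curvature features of a rasterised shape
#'
#' Intensity features are computed separately on outline and interior
#' pixels. Curvature features come from the Freeman chain code of the
#' contour: the signed direction change at each pixel (45 degree units),
#' smoothed over a 5-pixel window, classifies pixels as convex (turning
#' with the overall traversal orientation), concave (against it) or
#' straight; unsmoothed |turn| is binned into three equal-width levels
#' (0, 45, >= 90 degrees).
#'
#' @param shape list with `contour`, `outline`, `interior` (see
#'   [rasterize()]).
#' @param intensity_plane matrix `[x, y]` of envelope intensity.
#' @return named numeric vector over `FEATURE_NAMES`.
#' @export
compute_features <- function(shape, intensity_plane) {
  nx <- nrow(intensity_plane)
  o <- intensity_plane[shape$outline]
  i <- intensity_plane[shape$interior]
  if (!length(i)) stopf("nucridge_empty_interior", "shape has no interior pixels")
  ctr <- shape$contour
  n <- nrow(ctr)
  nxt <- rbind(ctr[-1L, , drop = FALSE], ctr[1L, , drop = FALSE])
  dx <- nxt[, 1L] - ctr[, 1L]; dy <- nxt[, 2L] - ctr[, 2L]
  steps <- sqrt(dx^2 + dy^2)
  perim <- sum(steps)
  # Freeman codes 0..7 matching DIR8 ordering
  code <- integer(n)
  for (k in seq_len(8L)) code[dx == DIR8[k, 1L] & dy == DIR8[k, 2L]] <- k - 1L
  turn <- diff(c(code[n], code))
  turn <- ((turn + 3L) %% 8L) - 3L
  s <- sign(sum(turn))
  if (s == 0) s <- 1
  # net turn over a 5-pixel window; a pixel is convex/concave only when
  # that reaches 90 degrees (staircase wobble of +-45 cancels out)
  sh <- function(v, k) v[((seq_along(v) - 1L + k) %% length(v)) + 1L]
  st <- turn + sh(turn, 1L) + sh(turn, -1L) + sh(turn, 2L) + sh(turn, -2L)
  convex <- sum(st * s >= 2); concave <- sum(st * s <= -2)
  area <- shape$area
  c(o_mean = mean(o), o_sd = stats::sd(o),
    i_mean = mean(i), i_sd = if (length(i) > 1L) stats::sd(i) else 0,
    oi_ratio = mean(o) / max(mean(i), 1e-9),
    area = area, perimeter = perim,
    circularity = 4 * pi * area / perim^2,
    convex_frac = convex / n, concave_frac = concave / n,
    curv_low = mean(abs(turn) == 0L),
    curv_med = mean(abs(turn) == 1L),
    curv_high = mean(abs(turn) >= 2L))
}

#' Pick the most probable valid shape among candidates
#'
#' @param candidates list of candidates carrying a `features` vector.
#' @param classifier a [train_classifier()] model.
#' @param cutoff acceptance threshold on the posterior P(valid).
#' @return the winning candidate with `posterior_valid` attached, or
#'   `NULL` when none passes the cut (the seed is then recorded as
#'   missed, stop code M).
#' @export
select_winner <- function(candidates, classifier, cutoff = 0.5) {
  if (!length(candidates)) return(NULL)
  post <- vapply(candidates, function(cd)
    predict_valid(classifier, cd$features), numeric(1))
  ok <- which(post > cutoff)
  if (!length(ok)) return(NULL)
  w <- ok[which.max(post[ok])]
  cand <- candidates[[w]]
  cand$posterior_valid <- post[w]
  cand
}

#' Reconcile overlapping winners within one plane
#'
#' Trees are traced independently, so duplicate seeds on one envelope can
#' yield near-identical winners. Winners are accepted greedily by
#' descending posterior; one overlapping an already accepted shape by
#' more than half of its own area is discarded, lesser overlaps are
#' trimmed to pixel disjointness.
#'
#' @param winners list of winning candidates (with `posterior_valid`).
#' @param nx,ny plane dimensions.
#' @return list of pairwise pixel-disjoint shapes.
#' @export
resolve_plane_conflicts <- function(winners, nx, ny) {
  if (!length(winners)) return(list())
  post <- vapply(winners, `[[`, numeric(1), "posterior_valid")
  areas <- vapply(winners, `[[`, numeric(1), "area")
  # near-tied posteriors resolve toward the larger shape, so a full
  # envelope beats the two halves a crossing wall can offer
  ord <- order(-round(post / 0.02), -areas)
  occupied <- rep(FALSE, nx * ny)
  out <- list()
  for (i in ord) {
    w <- winners[[i]]
    px <- c(w$outline, w$interior)
    ov <- sum(occupied[px])
    if (ov > 0.5 * length(px)) next
    if (ov > 0L) {
      w$outline <- w$outline[!occupied[w$outline]]
      w$interior <- w$interior[!occupied[w$interior]]
      px <- c(w$outline, w$interior)
      if (length(px) < 9L) next
      w$area <- length(px)
      w$centroid <- px_centroid(px, nx)
    }
    occupied[px] <- TRUE
    out[[length(out) + 1L]] <- w
  }
  out
}
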