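# Linking accepted 2D areas across planes into 3D nucleus instances.
#
# A directed graph connects areas in nearby planes when their centroids
# are close and their masks overlap; competing links (one area claimed
# from several, or claiming several) are arbitrated with the Jaccard
# index, merged-union JI deciding whether an area is in fact the
# co-section of several nuclei and must be divided. Edges are then
# consumed in descending-JI order to propagate instance IDs.

#' Jaccard index of two pixel masks
#'
#' @param maskA,maskB integer vectors of linear pixel indices on the same
#'   grid (or logical vectors of equal length).
#' @return `|A
#' intersect B| / |A union B|`; 0 when both are empty.
#' @export
jaccard <- function(maskA, maskB) {
  if (is.logical(maskA)) maskA <- which(maskA)
  if (is.logical(maskB)) maskB <- which(maskB)
  if (!length(maskA) && !length(maskB)) return(0)
  inter <- length(intersect(maskA, maskB))
  inter / (length(maskA) + length(maskB) - inter)
}

# Areas are stored as a list of lists:
#   list(id, plane, px (linear indices), centroid_px c(x, y), area, posterior)
area_centroid_um <- function(a, cal) c(a$centroid[1L] * cal[1L], a$centroid[2L] * cal[2L])

#' Build the inter-plane link graph
#'
#' An edge `a@p -> b@q` (q > p) exists when `q - p <= max_jump`, the 2D
#' centroid distance is at most `max_intercentroid_distance` um, and the
#' overlap fraction passes `overlap_threshold` (`overlap_mode` selects
#' whether the max or min of the two per-area fractions must pass). An
#' area already linked to a nearer upstream plane receives no
#' longer-jump in-edges.
#'
#' @param areas list of area lists (see source), each with fields `id`,
#'   `plane`, `px`, `centroid`, `area`.
#' @param params a [seg_params()].
#' @param calibration `(dx, dy, dz)` um.
#' @return data.frame of edges: `src`, `dst`, `dplanes`, `dist_um`,
#'   `ov_src`, `ov_dst`, `ji`.
#' @export
build_link_graph <- function(areas, params, calibration = c(1, 1, 1)) {
  empty <- data.frame(src = integer(0), dst = integer(0), dplanes = integer(0),
                      dist_um = numeric(0), ov_src = numeric(0),
                      ov_dst = numeric(0), ji = numeric(0))
  if (length(areas) < 2L) return(empty)
  planes <- vapply(areas, `[[`, numeric(1), "plane")
  ids <- vapply(areas, `[[`, numeric(1), "id")
  by_plane <- split(seq_along(areas), planes)
  rows <- list()
  for (bi in seq_along(areas)) {
    b <- areas[[bi]]
    found <- FALSE
    for (dp in seq_len(params$max_jump)) {
      if (found) break
      srcs <- by_plane[[as.character(b$plane - dp)]]
      if (is.null(srcs)) next
      for (ai in srcs) {
        a <- areas[[ai]]
        d_um <- sqrt(sum(((a$centroid - b$centroid) * calibration[1:2])^2))
        if (d_um > params$max_intercentroid_distance) next
        inter <- length(intersect(a$px, b$px))
        ov_a <- inter / length(a$px); ov_b <- inter / length(b$px)
        ov <- if (params$overlap_mode == "max") max(ov_a, ov_b) else min(ov_a, ov_b)
        if (ov < params$overlap_threshold) next
        rows[[length(rows) + 1L]] <- data.frame(
          src = a$id, dst = b$id, dplanes = dp, dist_um = d_um,
          ov_src = ov_a, ov_dst = ov_b,
          ji = inter / (length(a$px) + length(b$px) - inter))
        found <- TRUE
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# Find ambiguity groups: several edges sharing (dst, source plane) or
# (src, destination plane). Returns a list of groups with merged JI.
find_ambiguities <- function(graph, areas_by_id, planes_by_id) {
  groups <- list()
  if (!nrow(graph)) return(groups)
  gin <- split(seq_len(nrow(graph)),
               paste(graph$dst, planes_by_id[as.character(graph$src)]))
  gout <- split(seq_len(nrow(graph)),
                paste(graph$src, planes_by_id[as.character(graph$dst)]))
  collect <- function(idx, side) {
    if (length(idx) < 2L) return(NULL)
    centre_id <- if (side == "in") graph$dst[idx[1L]] else graph$src[idx[1L]]
    partner_ids <- if (side == "in") graph$src[idx] else graph$dst[idx]
    centre <- areas_by_id[[as.character(centre_id)]]
    union_px <- unique(unlist(lapply(partner_ids, function(id)
      areas_by_id[[as.character(id)]]$px)))
    list(side = side, centre = centre_id, partners = partner_ids,
         edges = idx, merged_ji = jaccard(centre$px, union_px),
         best_single = max(graph$ji[idx]))
  }
  for (idx in gin) { g <- collect(idx, "in"); if (!is.null(g)) groups[[length(groups) + 1L]] <- g }
  for (idx in gout) { g <- collect(idx, "out"); if (!is.null(g)) groups[[length(groups) + 1L]] <- g }
  groups
}

# Divide a co-section area between partner areas: every pixel goes to
# the partner with the nearest centroid (deterministic tie-break on
# partner order).
divide_area <- function(centre, partners, nx, next_id) {
  px <- centre$px
  x <- ((px - 1L) %% nx) + 1L
  y <- ((px - 1L) %/% nx) + 1L
  d2 <- vapply(partners, function(p)
    (x - p$centroid[1L])^2 + (y - p$centroid[2L])^2, numeric(length(px)))
  if (length(px) == 1L) d2 <- matrix(d2, nrow = 1L)
  assign_to <- max.col(-d2, ties.method = "first")
  out <- list()
  for (j in seq_along(partners)) {
    sub <- px[assign_to == j]
    if (length(sub) < 5L) next
    out[[length(out) + 1L]] <- list(id = next_id, plane = centre$plane, px = sub,
                                    centroid = px_centroid(sub, nx),
                                    area = length(sub),
                                    posterior = centre$posterior,
                                    divided_from = centre$id)
    next_id <- next_id + 1L
  }
  out
}

#' Resolve merge/split ambiguities in a link graph
#'
#' Wherever one area holds several in-edges (or out-edges) from the same
#' plane, the JI between that area and the union of its competitors is
#' compared with the best single-partner JI. If the merged union wins,
#' the area is a co-section of several nuclei and is divided between the
#' partners by nearest-centroid pixel assignment; otherwise only the
#' best edge is kept. Groups are processed in descending merged-JI order
#' so that when ambiguities exist on both sides the stronger one
#' dictates the outcome. The graph is rebuilt after each division.
#'
#' @param areas list of areas (see [build_link_graph()]).
#' @param params a [seg_params()].
#' @param calibration voxel size, um.
#' @param nx plane width in px (for pixel arithmetic).
#' @return list with the final `areas` and `graph`.
#' @export
resolve_ambiguities <- function(areas, params, calibration, nx) {
  pruned <- character(0)   # "src>dst" keys of discarded edges
  max_divisions <- length(areas) + 4L
  for (it in seq_len(max_divisions)) {
    graph <- build_link_graph(areas, params, calibration)
    if (nrow(graph)) {
      keys <- paste0(graph$src, ">", graph$dst)
      graph <- graph[!(keys %in% pruned), , drop = FALSE]
    }
    divided <- FALSE
    # edge pruning does not change the node set, so it iterates on the
    # data frame alone; only a division forces a graph rebuild
    repeat {
      if (!nrow(graph)) return(list(areas = areas, graph = graph))
      ids <- vapply(areas, `[[`, numeric(1), "id")
      areas_by_id <- stats::setNames(areas, as.character(ids))
      planes_by_id <- stats::setNames(vapply(areas, `[[`, numeric(1), "plane"),
                                      as.character(ids))
      groups <- find_ambiguities(graph, areas_by_id, planes_by_id)
      if (!length(groups)) return(list(areas = areas, graph = graph))
      g <- groups[[order(-vapply(groups, `[[`, numeric(1), "merged_ji"))[1L]]]
      if (g$merged_ji > g$best_single && length(unique(g$partners)) >= 2L) {
        centre <- areas_by_id[[as.character(g$centre)]]
        partners <- lapply(as.character(unique(g$partners)),
                           function(k) areas_by_id[[k]])
        parts <- divide_area(centre, partners, nx, max(ids) + 1L)
        if (length(parts) >= 2L) {
          areas <- c(areas[ids != g$centre], parts)
          divided <- TRUE
          break
        }
        # degenerate division: fall back to keeping the best edge
      }
      best <- g$edges[order(-graph$ji[g$edges],
                            planes_by_id[as.character(graph$src[g$edges])],
                            graph$src[g$edges])][1L]
      drop <- setdiff(g$edges, best)
      pruned <- c(pruned, paste0(graph$src[drop], ">", graph$dst[drop]))
      graph <- graph[-drop, , drop = FALSE]
    }
    if (!divided) break
  }
  list(areas = areas, graph = graph)
}

#' Label linked areas as 3D nucleus volumes
#'
#' Edges are consumed in descending JI (ties: lower source plane, lower
#' source id); each edge propagates the instance ID of an already
#' labelled endpoint or mints a new one, and chains meeting through a
#' later edge are united. Unlinked areas become single-plane instances.
#' Volumes below `min_volume` are discarded; volumes above `max_volume`
#' are kept and flagged `oversized` for the splitting post-processors.
#'
#' @param areas,graph output of [resolve_ambiguities()].
#' @param params a [seg_params()].
#' @param calibration `(dx, dy, dz)` um.
#' @param shape volume shape `(nx, ny, nz)`.
#' @return list with `volumes` (list of `NucleusVolume`: `id`, `planes`,
#'   `masks`, `centroids_px`, `volume_um3`, `oversized`) and `labels`
#'   (a [label_volume()]).
#' @export
label_volumes <- function(areas, graph, params, calibration, shape) {
  ids <- vapply(areas, `[[`, numeric(1), "id")
  planes <- vapply(areas, `[[`, numeric(1), "plane")
  comp <- stats::setNames(seq_along(areas), as.character(ids))  # union-find
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(graph)) {
    ord <- order(-graph$ji, planes[match(graph$src, ids)], graph$src)
    for (e in ord) {
      a <- find(match(graph$src[e], ids)); b <- find(match(graph$dst[e], ids))
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_along(areas), find, numeric(1))
  vox_um3 <- prod(calibration)
  dz <- calibration[3]
  volumes <- list(); next_label <- 1L
  lab <- array(0L, shape)
  nx <- shape[1]
  for (r in sort(unique(roots))) {
    members <- which(roots == r)
    members <- members[order(planes[members])]
    vol_px <- sum(vapply(members, function(i) length(areas[[i]]$px), numeric(1)))
    vol_um3 <- vol_px * vox_um3
    if (vol_um3 < params$min_volume) next
    if (length(unique(planes[members])) < params$min_span) next
    pl <- planes[members]
    masks <- lapply(members, function(i) areas[[i]]$px)
    cents <- t(vapply(members, function(i) areas[[i]]$centroid, numeric(2)))
    v <- list(id = next_label, planes = pl, masks = masks,
              centroids_px = cents, volume_um3 = vol_um3,
              oversized = vol_um3 > params$max_volume)
    class(v) <- "NucleusVolume"
    volumes[[next_label]] <- v
    for (k in seq_along(members))
      lab[masks[[k]] + (pl[k] - 1L) * shape[1] * shape[2]] <- next_label
    next_label <- next_label + 1L
  }
  list(volumes = volumes, labels = label_volume(lab, calibration))
}
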