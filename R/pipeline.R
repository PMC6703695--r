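# Pipeline orchestration: smooth -> ridge -> seeds -> trace -> shapes
# per plane, then 3D linkage and refinement. Planes are independent of
# one another, so the per-plane stage can run on workers; outputs do not
# depend on the degree of parallelism.

# All shape candidates of one plane, with features attached. When
# smoothing is on the working image is 3D: a [1,2,1]/4 average with the
# neighbouring planes (passed as plane_lo/plane_hi, which fall back to
# the plane itself at stack ends), then an in-plane Gaussian. Adjacent
# planes are structurally almost identical, so the z average buys noise
# suppression that in-plane blurring alone cannot.
plane_candidates <- function(plane, params, nx, ny, collect_winner = FALSE,
                             classifier = NULL,
                             plane_lo = NULL, plane_hi = NULL, iscale = 1) {
  work <- if (params$enable_smoothing && params$smoothing_sigma > 0) {
    base <- if (params$smoothing_z && !is.null(plane_lo))
      (plane_lo + 2 * plane + plane_hi) / 4 else plane
    gaussian_smooth(base, params$smoothing_sigma)
  } else plane
  # intensity features are measured on a bit-depth-normalised image so
  # one trained classifier serves 8-, 12- and 16-bit data alike
  work_norm <- if (iscale != 1) work * iscale else work
  ridge <- steerable_ridge_response(work, params$ridge_scale)
  if (params$response_smooth > 0)
    ridge$response <- gaussian_smooth(ridge$response, params$response_smooth)
  ridge <- ridge_nms(ridge)
  dog <- dog_filter(work, params$dog_sigma_small, params$dog_sigma_large)
  seeds <- detect_maxima(dog, params$seed_threshold, params$min_separation)
  if (nrow(seeds) > params$max_seeds_per_plane)
    seeds <- seeds[seq_len(params$max_seeds_per_plane), ]
  cands <- list()
  winners <- list()
  # seeds are skipped when they fall inside an accepted shape (its wall
  # stays traceable for the neighbouring nucleus) or snap to the root of
  # an already-traced tree (identical trace)
  closed_claim <- rep(FALSE, nx * ny)
  seen_roots <- rep(FALSE, nx * ny)
  traced <- integer(nx * ny)   # how many trees already walked each pixel
  for (si in seq_len(nrow(seeds))) {
    if (closed_claim[lin_idx(seeds$x[si], seeds$y[si], nx)]) next
    rt <- snap_to_crest(ridge$response, seeds$x[si], seeds$y[si])
    rt_i <- lin_idx(rt[1L], rt[2L], nx)
    if (seen_roots[rt_i] || closed_claim[rt_i] || traced[rt_i] >= 2L) next
    seen_roots[rt_i] <- TRUE
    tree <- build_tree(ridge, seeds[si, ], params)
    if (!length(tree$ridglets)) next
    traced[tree$claimed] <- traced[tree$claimed] + 1L
    tc <- enumerate_candidates(tree)
    if (!length(tc)) next
    any_closed <- any(vapply(tree$ridglets, function(r) r$stop == "O", logical(1)))
    got <- list()
    for (cd in tc) {
      ras <- rasterize(cd$contour, nx, ny)
      if (is.null(ras) || length(ras$interior) < 4L) next
      cd[names(ras)] <- ras
      # features are measured on the working image the detector sees
      cd$features <- compute_features(cd, work_norm)
      got[[length(got) + 1L]] <- cd
    }
    if (!length(got)) next
    if (collect_winner) {
      w <- select_winner(got, classifier, params$posterior_cutoff)
      if (!is.null(w)) {
        winners[[length(winners) + 1L]] <- w
        closed_claim[w$interior] <- TRUE
      }
    } else {
      cands <- c(cands, got)
    }
  }
  if (collect_winner) winners else cands
}

# Lazy view of the volume as the pipeline's working image: identical to
# the input when smoothing is off, otherwise each plane is the same
# z-averaged, Gaussian-smoothed plane the detector operates on.
working_volume <- function(volume, params) {
  if (!(params$enable_smoothing && params$smoothing_sigma > 0)) return(volume)
  nz <- volume$shape[3]
  rd <- function(z) {
    p <- get_plane(volume, z)
    if (params$smoothing_z)
      p <- (get_plane(volume, max(1L, z - 1L)) + 2 * p +
              get_plane(volume, min(nz, z + 1L))) / 4
    gaussian_smooth(p, params$smoothing_sigma)
  }
  intensity_volume(reader = rd, shape = volume$shape,
                   calibration = volume$calibration,
                   bit_depth = volume$bit_depth)
}

# Segment one plane into accepted, pairwise disjoint areas.
segment_plane <- function(plane, z, params, classifier, nx, ny,
                          plane_lo = NULL, plane_hi = NULL, iscale = 1) {
  winners <- plane_candidates(plane, params, nx, ny, collect_winner = TRUE,
                              classifier = classifier,
                              plane_lo = plane_lo, plane_hi = plane_hi,
                              iscale = iscale)
  shapes <- resolve_plane_conflicts(winners, nx, ny)
  lapply(shapes, function(s) list(plane = z, px = c(s$outline, s$interior),
                                  centroid = s$centroid, area = s$area,
                                  posterior = s$posterior_valid))
}

#' Segment a 3D volume into labelled nucleus instances
#'
#' Full pipeline: per plane, optional smoothing, ridge enhancement,
#' Difference-of-Gaussian seeding, tree-structured ridge tracing,
#' classifier-ranked shape selection and in-plane reconciliation; then
#' Jaccard-driven linkage across planes, ambiguity resolution, volume
#' constraints and post-hoc refinement (intensity-ratio and
#' centroid-displacement splitting, morphological smoothing). The result
#' is deterministic for fixed inputs and identical for any number of
#' workers.
#'
#' @param volume an [intensity_volume()] (in-memory or streamed).
#' @param params a [seg_params()].
#' @param classifier a [train_classifier()] model (or path to one).
#' @param workers plane-stage workers (forked; > 1 is a speed hint only).
#' @return list with `labels` (a [label_volume()]), `volumes` (list of
#'   `NucleusVolume`), and `table` (per-nucleus data.frame: id, centroid
#'   x/y/z um, volume um3, plane span, mean envelope intensity).
#' @export
segment <- function(volume, params = seg_params(), classifier, workers = 1L) {
  validate_params(params)
  if (is.character(classifier)) classifier <- read_classifier(classifier)
  stopifnot(inherits(classifier, "TrainedClassifier"))
  shp <- volume$shape; nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  iscale <- 1 / (2^volume$bit_depth - 1)
  do_plane <- function(z) segment_plane(
    get_plane(volume, z), z, params, classifier, nx, ny,
    plane_lo = get_plane(volume, max(1L, z - 1L)),
    plane_hi = get_plane(volume, min(nz, z + 1L)), iscale = iscale)
  per_plane <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nz), do_plane, mc.cores = workers)
  } else lapply(seq_len(nz), do_plane)
  areas <- do.call(c, per_plane)
  if (!length(areas)) {
    return(list(labels = label_volume(array(0L, shp), volume$calibration),
                volumes = list(), table = nucleus_table(list(), volume)))
  }
  for (i in seq_along(areas)) areas[[i]]$id <- i
  res <- resolve_ambiguities(areas, params, volume$calibration, nx)
  lv <- label_volumes(res$areas, res$graph, params, volume$calibration, shp)
  vols <- lv$volumes
  if (params$enable_ir_split || params$enable_cd_split)
    vols <- split_volumes(vols, working_volume(volume, params), params)
  if (params$enable_smoothing)
    vols <- lapply(vols, smooth_volume, shape = shp,
                   calibration = volume$calibration)
  # re-apply the volume constraint after refinement and rebuild labels
  vols <- Filter(function(v) v$volume_um3 >= params$min_volume &&
                   length(unique(v$planes)) >= params$min_span, vols)
  lab <- array(0L, shp)
  for (i in seq_along(vols)) {
    vols[[i]]$id <- i
    v <- vols[[i]]
    for (k in seq_along(v$planes))
      lab[v$masks[[k]] + (v$planes[k] - 1L) * nx * ny] <- i
  }
  labels <- label_volume(lab, volume$calibration)
  list(labels = labels, volumes = vols, table = nucleus_table(vols, volume))
}

# Per-nucleus summary table.
nucleus_table <- function(volumes, intensity) {
  cal <- intensity$calibration
  if (!length(volumes))
    return(data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), volume_um3 = numeric(0),
                      plane_min = integer(0), plane_max = integer(0),
                      mean_intensity = numeric(0)))
  rows <- lapply(volumes, function(v) {
    npx <- lengths(v$masks)
    cx <- sum(v$centroids_px[, 1L] * npx) / sum(npx)
    cy <- sum(v$centroids_px[, 2L] * npx) / sum(npx)
    cz <- sum(v$planes * npx) / sum(npx)
    mi <- mean(unlist(lapply(seq_along(v$planes), function(k)
      get_plane(intensity, v$planes[k])[v$masks[[k]]])))
    data.frame(id = v$id, x_um = cx * cal[1], y_um = cy * cal[2],
               z_um = cz * cal[3], volume_um3 = v$volume_um3,
               plane_min = min(v$planes), plane_max = max(v$planes),
               mean_intensity = mi)
  })
  do.call(rbind, rows)
}

#' Segment a time series frame by frame
#'
#' Frames are processed sequentially and independently; memory stays
#' bounded by one frame plus per-plane buffers when `reader` streaming
#' is used.
#'
#' @param frames list of [intensity_volume()]s, or a function
#'   `(t) -> IntensityVolume` together with `n_frames`.
#' @param params,classifier,workers as [segment()].
#' @param n_frames required when `frames` is a function.
#' @param frame_order optional processing order (results are identical
#'   for any order).
#' @return list (indexed by frame) of [segment()] results.
#' @export
segment_timelapse <- function(frames, params = seg_params(), classifier,
                              workers = 1L, n_frames = NULL,
                              frame_order = NULL) {
  getter <- if (is.function(frames)) frames else function(t) frames[[t]]
  nt <- if (is.function(frames)) n_frames else length(frames)
  stopifnot(!is.null(nt))
  if (is.null(frame_order)) frame_order <- seq_len(nt)
  out <- vector("list", nt)
  for (t in frame_order)
    out[[t]] <- segment(getter(t), params, classifier, workers)
  out
}
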