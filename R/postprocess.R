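# Volume refinement: axial profiles detect under-segmentation (two
# nuclei fused along z or laterally) and morphological smoothing removes
# plane-local artifacts.

#' Intensity-ratio profile of a volume
#'
#' Per plane, IR = mean envelope intensity over the central region
#' (pixels within half the equivalent radius of the area centroid)
#' divided by mean intensity over the rim (mask boundary pixels). For a
#' shell-labelled nucleus IR is well below 1 on mid planes; the
#' interface plane between two stacked nuclei is envelope material
#' across the centre, so IR rises above 1 there.
#'
#' @param volume a `NucleusVolume` (see [label_volumes()]).
#' @param intensity an [intensity_volume()] on the same grid.
#' @return data.frame of class profile with columns `z`, `value`
#'   (`kind` attribute `"IR"`).
#' @export
intensity_ratio_profile <- function(volume, intensity) {
  nx <- intensity$shape[1]
  vals <- numeric(length(volume$planes))
  for (k in seq_along(volume$planes)) {
    z <- volume$planes[k]
    plane <- get_plane(intensity, z)
    px <- volume$masks[[k]]
    msk <- matrix(FALSE, nx, intensity$shape[2])
    msk[px] <- TRUE
    rim <- which(mask_boundary(msk))
    if (!length(rim)) stopf("nucridge_empty_rim", "plane %d has an empty rim", z)
    cen <- volume$centroids_px[k, ]
    re <- sqrt(length(px) / pi)
    x <- ((px - 1L) %% nx) + 1L
    y <- ((px - 1L) %/% nx) + 1L
    central <- px[(x - cen[1L])^2 + (y - cen[2L])^2 <= (0.5 * re)^2]
    if (!length(central)) central <- px[which.min((x - cen[1L])^2 + (y - cen[2L])^2)]
    vals[k] <- mean(plane[central]) / max(mean(plane[rim]), 1e-9)
  }
  structure(data.frame(z = volume$planes, value = vals), kind = "IR")
}

#' Centroid-displacement profile of a volume
#'
#' CD at plane z is the Euclidean xy distance (um) between the area
#' centroids at the previous occupied plane and at z; a laterally fused
#' pair of nuclei shows an isolated CD peak at the junction.
#'
#' @param volume a `NucleusVolume`.
#' @param calibration `(dx, dy, dz)` um.
#' @return data.frame with `z`, `value` (`kind` attribute `"CD"`); the
#'   first occupied plane has CD 0.
#' @export
centroid_displacement_profile <- function(volume, calibration = c(1, 1, 1)) {
  n <- length(volume$planes)
  vals <- numeric(n)
  for (k in seq_len(n)[-1L]) {
    d <- (volume$centroids_px[k, ] - volume$centroids_px[k - 1L, ]) * calibration[1:2]
    vals[k] <- sqrt(sum(d^2))
  }
  structure(data.frame(z = volume$planes, value = vals), kind = "CD")
}

# Cut one volume at plane index k (into planes < k and > k when
# drop_cut, else planes < k and >= k).
cut_volume <- function(volume, k, drop_cut, vox_um3_per_px) {
  pick <- function(idx, id) {
    if (!length(idx)) return(NULL)
    v <- list(id = id, planes = volume$planes[idx],
              masks = volume$masks[idx],
              centroids_px = volume$centroids_px[idx, , drop = FALSE],
              volume_um3 = sum(lengths(volume$masks[idx])) * vox_um3_per_px,
              oversized = FALSE)
    class(v) <- "NucleusVolume"
    v
  }
  lo <- pick(seq_len(k - 1L), volume$id)
  hi <- pick(if (drop_cut) setdiff(seq_along(volume$planes), seq_len(k))
             else k:length(volume$planes), -1L)
  list(lo = lo, hi = hi)
}

#' Split a volume at an intensity-ratio peak
#'
#' When the interior maximum of the IR profile exceeds both flanking
#' minima by `params$ir_prominence`, the volume is cut at the peak
#' plane (the envelope interface between two stacked nuclei); the
#' peak plane is assigned to neither half (it is the envelope
#' interface). The cut is only taken when both halves satisfy
#' `min_volume`.
#'
#' @param volume a `NucleusVolume`.
#' @param profile from [intensity_ratio_profile()].
#' @param params a [seg_params()].
#' @param calibration voxel size, um.
#' @return list of 1 or 2 `NucleusVolume`s.
#' @export
split_by_intensity <- function(volume, profile, params, calibration = c(1, 1, 1)) {
  n <- nrow(profile)
  if (n < 3L) return(list(volume))
  v <- profile$value
  interior <- 2:(n - 1L)
  # candidate peaks in descending height; take the first whose flanking
  # minima satisfy the prominence requirement (an axial-tip plateau can
  # tie the interface in height but never in prominence)
  k <- NA_integer_
  for (kk in interior[order(-v[interior])]) {
    left_min <- min(v[seq_len(kk - 1L)]); right_min <- min(v[(kk + 1L):n])
    if (v[kk] >= params$ir_prominence * left_min &&
        v[kk] >= params$ir_prominence * right_min) { k <- kk; break }
  }
  if (is.na(k)) return(list(volume))
  halves <- cut_volume(volume, k, drop_cut = TRUE, prod(calibration))
  if (is.null(halves$lo) || is.null(halves$hi) ||
      halves$lo$volume_um3 < params$min_volume ||
      halves$hi$volume_um3 < params$min_volume) return(list(volume))
  list(halves$lo, halves$hi)
}

#' Split a volume at a centroid-displacement peak
#'
#' The cut is taken between planes k-1 and k when CD(k) exceeds
#' `params$cd_prominence` times the median CD of the volume and an
#' absolute floor of `params$cd_min_peak_px` xy pixels (so digitisation
#' jitter never triggers a split), and both halves satisfy `min_volume`.
#'
#' @inheritParams split_by_intensity
#' @param profile from [centroid_displacement_profile()].
#' @return list of 1 or 2 `NucleusVolume`s.
#' @export
split_by_displacement <- function(volume, profile, params, calibration = c(1, 1, 1)) {
  n <- nrow(profile)
  if (n < 3L) return(list(volume))
  v <- profile$value[-1L]
  k <- which.max(v) + 1L
  peak <- profile$value[k]
  floor_um <- params$cd_min_peak_px * sqrt(calibration[1L] * calibration[2L])
  if (peak < params$cd_prominence * stats::median(v) || peak < floor_um)
    return(list(volume))
  halves <- cut_volume(volume, k, drop_cut = FALSE, prod(calibration))
  if (is.null(halves$lo) || is.null(halves$hi) ||
      halves$lo$volume_um3 < params$min_volume ||
      halves$hi$volume_um3 < params$min_volume) return(list(volume))
  list(halves$lo, halves$hi)
}

# One pass of IR-then-CD splitting over a volume list, iterated until no
# volume changes (handles three or more stacked nuclei).
split_volumes <- function(volumes, intensity, params) {
  cal <- intensity$calibration
  repeat {
    out <- list(); changed <- FALSE
    for (v in volumes) {
      parts <- list(v)
      if (params$enable_ir_split && length(v$planes) >= 3L) {
        pr <- intensity_ratio_profile(v, intensity)
        parts <- split_by_intensity(v, pr, params, cal)
      }
      if (length(parts) == 1L && params$enable_cd_split && length(v$planes) >= 3L) {
        pr <- centroid_displacement_profile(v, cal)
        parts <- split_by_displacement(v, pr, params, cal)
      }
      if (length(parts) > 1L) changed <- TRUE
      out <- c(out, parts)
    }
    volumes <- out
    if (!changed) break
  }
  for (i in seq_along(volumes)) volumes[[i]]$id <- i
  volumes
}

# --- morphological smoothing -------------------------------------------

shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- max(1L, 1L + dx):min(d[1], d[1] + dx)
  ys <- max(1L, 1L + dy):min(d[2], d[2] + dy)
  zs <- max(1L, 1L + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
  out
}

# 3D dilation/erosion with a cross structuring element (in-plane
# 4-neighbours plus z +/- 1 when use_z).
dilate3 <- function(a, use_z = TRUE) {
  out <- a | shift3(a, 1, 0, 0) | shift3(a, -1, 0, 0) |
    shift3(a, 0, 1, 0) | shift3(a, 0, -1, 0)
  if (use_z) out <- out | shift3(a, 0, 0, 1) | shift3(a, 0, 0, -1)
  out
}
erode3 <- function(a, use_z = TRUE) {
  out <- a & shift3(a, 1, 0, 0, TRUE) & shift3(a, -1, 0, 0, TRUE) &
    shift3(a, 0, 1, 0, TRUE) & shift3(a, 0, -1, 0, TRUE)
  if (use_z) out <- out & shift3(a, 0, 0, 1, TRUE) & shift3(a, 0, 0, -1, TRUE)
  out
}

#' Morphologically smooth a nucleus volume
#'
#' Closing then opening with a 1-voxel cross structuring element
#' (anisotropy-aware: the z arms are dropped when dz exceeds twice the
#' xy pixel size), which removes single-plane lateral spikes; an
#' interpolated cap (the eroded terminal area) is added beyond each
#' axial tip whose terminal area exceeds 60% of its neighbour. If the
#' result would change the voxel count by more than 20% the volume is
#' returned unchanged.
#'
#' @param volume a `NucleusVolume`.
#' @param shape volume grid `(nx, ny, nz)`.
#' @param calibration `(dx, dy, dz)` um.
#' @return the smoothed `NucleusVolume`.
#' @export
smooth_volume <- function(volume, shape, calibration = c(1, 1, 1)) {
  nx <- shape[1]; ny <- shape[2]
  use_z <- calibration[3] <= 2 * sqrt(calibration[1] * calibration[2])
  z0 <- max(1L, min(volume$planes) - 2L)
  z1 <- min(shape[3], max(volume$planes) + 2L)
  nzl <- z1 - z0 + 1L
  a <- array(FALSE, c(nx, ny, nzl))
  for (k in seq_along(volume$planes))
    a[volume$masks[[k]] + (volume$planes[k] - z0) * nx * ny] <- TRUE
  n0 <- sum(a)
  # tip extension first: a cap (doubly eroded terminal area) is added
  # beyond each abrupt axial tip. The closing-then-opening that follows
  # is an idempotent morphological filter, so smoothing an already
  # smoothed volume changes nothing further.
  occ <- which(apply(a, 3L, any))
  if (length(occ) >= 2L) {
    er <- function(m) m &
      shift_mat(m, 1L, 0L, FALSE) & shift_mat(m, -1L, 0L, FALSE) &
      shift_mat(m, 0L, 1L, FALSE) & shift_mat(m, 0L, -1L, FALSE)
    for (side in c(1L, -1L)) {
      k <- if (side == 1L) occ[1L] else occ[length(occ)]
      nb <- k + side
      ext <- k - side
      if (nb %in% occ && ext >= 1L && ext <= nzl && !any(a[, , ext])) {
        a_term <- sum(a[, , k]); a_nb <- sum(a[, , nb])
        if (a_nb > 0 && a_term > 0.6 * a_nb) a[, , ext] <- er(er(a[, , k]))
      }
    }
  }
  n_ext <- sum(a)
  b <- erode3(dilate3(a, use_z), use_z)       # closing
  b <- dilate3(erode3(b, use_z), use_z)       # opening
  # the 20% guard constrains the morphological filter; the tip caps are
  # deliberate additions (for a 3-plane nucleus they exceed 20% alone)
  if (sum(b) == 0L || abs(sum(b) - n_ext) > 0.2 * n_ext) b <- a
  n1 <- sum(b)
  if (n1 == 0L) return(volume)
  planes <- z0 - 1L + which(apply(b, 3L, any))
  masks <- lapply(planes, function(z) which(b[, , z - z0 + 1L]))
  cents <- t(vapply(masks, px_centroid, numeric(2), nx = nx))
  out <- list(id = volume$id, planes = planes, masks = masks,
              centroids_px = cents,
              volume_um3 = n1 * prod(calibration), oversized = volume$oversized)
  class(out) <- "NucleusVolume"
  out
}

#' Export IR and CD profiles of volumes as TSV
#' @param volumes list of `NucleusVolume`s.
#' @param intensity the matching [intensity_volume()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(volumes, intensity, path) {
  rows <- list()
  for (v in volumes) {
    if (length(v$planes) < 3L) next
    ir <- intensity_ratio_profile(v, intensity)
    cd <- centroid_displacement_profile(v, intensity$calibration)
    rows[[length(rows) + 1L]] <- data.frame(id = v$id, z = ir$z,
                                            IR = ir$value, CD = cd$value)
  }
  df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(id = integer(0), z = integer(0), IR = numeric(0), CD = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
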