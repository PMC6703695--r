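# Synthetic envelope-labelled scenes with exact ground truth.
#
# Nuclei are rotated ellipsoids rendered as a bright thin shell around a
# dimmer interior on a dark background, packed to the requested crowding
# regime, with optional axial intensity falloff, additive Gaussian noise
# and anisotropic z sampling - the degradation axes along which
# segmentation robustness is probed.

#' Specification of a synthetic scene
#'
#' @param n_nuclei number of nuclei.
#' @param field_um field size `(x, y, z)` in um.
#' @param calibration voxel size `(dx, dy, dz)` um.
#' @param radius_range mean-semi-axis range, um.
#' @param axis_ratio_range per-axis scale factors are drawn from this
#'   range (1 = sphere), so shapes are heterogeneous ellipsoids.
#' @param shell_um envelope shell thickness, um.
#' @param intensity_shell,intensity_interior,intensity_background
#'   pre-noise intensities in the chosen bit depth; shell > interior >
#'   background is required.
#' @param mode crowding regime: `"sparse"`, `"touching"`, `"stacked"`,
#'   or `"offset_fused"`.
#' @param falloff axial intensity falloff coefficient lambda (per um):
#'   intensities above background decay as `exp(-lambda * z_um)`.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param bit_depth 8, 12 or 16.
#' @param seed RNG seed; identical seeds give identical scenes.
#' @return object of class `SceneSpec`.
#' @export
scene_spec <- function(n_nuclei = 10L,
                       field_um = c(60, 60, 30),
                       calibration = c(0.5, 0.5, 1),
                       radius_range = c(3.5, 5),
                       axis_ratio_range = c(0.8, 1.25),
                       shell_um = 1,
                       intensity_shell = 3000,
                       intensity_interior = 600,
                       intensity_background = 150,
                       mode = c("sparse", "touching", "stacked", "offset_fused"),
                       falloff = 0,
                       noise_sd = 0,
                       bit_depth = 12,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(intensity_shell > intensity_interior,
            intensity_interior > intensity_background,
            intensity_shell <= 2^bit_depth - 1,
            all(radius_range > 0), noise_sd >= 0)
  structure(list(n_nuclei = as.integer(n_nuclei), field_um = field_um,
                 calibration = calibration, radius_range = radius_range,
                 axis_ratio_range = axis_ratio_range, shell_um = shell_um,
                 intensity_shell = intensity_shell,
                 intensity_interior = intensity_interior,
                 intensity_background = intensity_background,
                 mode = mode, falloff = falloff, noise_sd = noise_sd,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "SceneSpec")
}

# Random rotation matrix (uniform via QR of Gaussian matrix).
rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Sample nucleus geometries honouring the crowding mode. Returns a list
# of list(centre um, semi_axes um, rot 3x3).
place_nuclei <- function(spec) {
  n <- spec$n_nuclei
  if (n == 0L) return(list())
  f <- spec$field_um
  draw_one <- function() {
    r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    ax <- r * stats::runif(3, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
    list(semi_axes = ax, rot = rand_rotation(), r_eff = max(ax))
  }
  centre_in_field <- function(r) {
    m <- pmin(r + 1, f / 2)
    c(stats::runif(1, m[1], f[1] - m[1]), stats::runif(1, m[2], f[2] - m[2]),
      stats::runif(1, m[3], f[3] - m[3]))
  }
  out <- list()
  if (spec$mode %in% c("sparse", "touching")) {
    gap <- if (spec$mode == "sparse") spec$shell_um + 2 * max(spec$calibration) else 0
    scale <- if (spec$mode == "sparse") 1 else 0.92
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(4000L)) {
        g <- draw_one()
        ctr <- centre_in_field(rep(g$r_eff, 3))
        ok <- TRUE
        for (o in out) {
          lim <- scale * (g$r_eff + o$r_eff) + gap
          if (sqrt(sum((ctr - o$centre)^2)) < lim) { ok <- FALSE; break }
        }
        if (ok) { g$centre <- ctr; out[[i]] <- g; break }
      }
      if (!ok) stopf("nucridge_packing", "could not place nucleus %d of %d", i, n)
    }
  } else {
    # pairs along z (stacked) or along z with a lateral offset (offset_fused)
    npairs <- ceiling(n / 2)
    lat <- if (spec$mode == "offset_fused") 4 else 0
    for (p in seq_len(npairs)) {
      ok <- FALSE
      for (att in seq_len(4000L)) {
        g1 <- draw_one(); g2 <- draw_one()
        span <- g1$semi_axes[3] + g2$semi_axes[3]
        r_pair <- max(g1$r_eff, g2$r_eff) + lat
        ctr <- centre_in_field(c(r_pair, r_pair, span + 2))
        c1 <- ctr - c(0, 0, span / 2)
        c2 <- ctr + c(lat, 0, span / 2) * c(1, 1, 0.96)
        c2[3] <- c1[3] + 0.96 * span
        ok <- TRUE
        for (o in out) {
          lim <- max(g1$r_eff, g2$r_eff) + o$r_eff + lat + 2
          if (sqrt(sum((ctr - o$pair_centre)^2)) < lim) { ok <- FALSE; break }
        }
        if (ok) {
          g1$centre <- c1; g2$centre <- c2
          g1$pair_centre <- g2$pair_centre <- ctr
          out[[length(out) + 1L]] <- g1
          if (length(out) < n) out[[length(out) + 1L]] <- g2
          break
        }
      }
      if (!ok) stopf("nucridge_packing", "could not place pair %d", p)
    }
    out <- out[seq_len(n)]
  }
  out
}

#' Generate a synthetic scene with exact ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `intensity` (an [intensity_volume()]), `labels`
#'   (a [label_volume()] of full ellipsoid solids) and `nuclei` (the
#'   sampled geometries).
#' @export
generate_scene <- function(spec) {
  set.seed(spec$seed)
  cal <- spec$calibration
  shp <- pmax(1L, as.integer(round(spec$field_um / cal)))
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  nuclei <- place_nuclei(spec)
  img <- array(spec$intensity_background, shp)
  lab <- array(0L, shp)
  best_q <- array(Inf, shp)   # nearest-surface tie-break for touching solids
  xs <- (seq_len(nx) - 0.5) * cal[1]
  ys <- (seq_len(ny) - 0.5) * cal[2]
  zs <- (seq_len(nz) - 0.5) * cal[3]
  for (i in seq_along(nuclei)) {
    g <- nuclei[[i]]
    rmax <- max(g$semi_axes) + spec$shell_um
    xi <- which(abs(xs - g$centre[1]) <= rmax)
    yi <- which(abs(ys - g$centre[2]) <= rmax)
    zi <- which(abs(zs - g$centre[3]) <= rmax)
    if (!length(xi) || !length(yi) || !length(zi)) next
    pts <- as.matrix(expand.grid(x = xs[xi], y = ys[yi], z = zs[zi]))
    rel <- t(t(pts) - g$centre) %*% g$rot
    q <- sqrt((rel[, 1] / g$semi_axes[1])^2 + (rel[, 2] / g$semi_axes[2])^2 +
                (rel[, 3] / g$semi_axes[3])^2)
    idx <- as.matrix(expand.grid(x = xi, y = yi, z = zi))
    lin <- (idx[, 3] - 1L) * nx * ny + (idx[, 2] - 1L) * nx + idx[, 1]
    q_in <- 1 - spec$shell_um / mean(g$semi_axes)
    solid <- q <= 1
    win <- solid & q < best_q[lin]
    best_q[lin[win]] <- q[win]
    lab[lin[win]] <- i
    shell <- solid & q >= q_in
    img[lin[shell]] <- pmax(img[lin[shell]], spec$intensity_shell)
    interior <- q < q_in
    # interiors never overwrite another nucleus' shell
    int_t <- lin[interior][img[lin[interior]] < spec$intensity_interior]
    img[int_t] <- spec$intensity_interior
  }
  if (spec$falloff > 0) {
    bg <- spec$intensity_background
    for (k in seq_len(nz))
      img[, , k] <- bg + (img[, , k] - bg) * exp(-spec$falloff * zs[k])
  }
  img <- round(img)
  vol <- intensity_volume(img, shape = shp, calibration = cal,
                          bit_depth = spec$bit_depth)
  if (spec$noise_sd > 0)
    vol <- add_noise(vol, spec$noise_sd, seed = spec$seed + 1L)
  list(intensity = vol, labels = label_volume(lab, cal), nuclei = nuclei)
}

#' Add clipped Gaussian noise
#'
#' @param volume an [intensity_volume()].
#' @param sd noise standard deviation, intensity units.
#' @param seed RNG seed; same seed, same noise.
#' @return the noisy volume (rounded, clipped to the bit-depth range).
#' @export
add_noise <- function(volume, sd, seed = 1L) {
  if (sd < 0) stopf("nucridge_bad_params", "noise sd must be >= 0")
  if (sd == 0) return(volume)
  volume <- materialise(volume)
  set.seed(seed)
  top <- 2^volume$bit_depth - 1
  d <- volume$data + stats::rnorm(length(volume$data), 0, sd)
  volume$data <- array(pmin(pmax(round(d), 0), top), dim(volume$data))
  volume
}

#' Resample a volume to a new z step
#'
#' Nearest-neighbour plane selection (pure decimation when `new_dz` is a
#' multiple of the current dz); works for intensity and label volumes
#' alike and updates the calibration.
#'
#' @param volume an [intensity_volume()] or [label_volume()].
#' @param new_dz target z step, um.
#' @return resampled volume of the same class.
#' @export
resample_z <- function(volume, new_dz) {
  if (new_dz <= 0) stopf("nucridge_bad_params", "new_dz must be > 0")
  dz <- volume$calibration[3]
  if (new_dz == dz) return(volume)
  nz <- volume$shape[3]
  old_z <- (seq_len(nz) - 0.5) * dz
  new_centres <- seq(new_dz / 2, nz * dz - new_dz / 2 + 1e-9, by = new_dz)
  src <- vapply(new_centres, function(zc) which.min(abs(old_z - zc)), integer(1))
  cal <- volume$calibration; cal[3] <- new_dz
  if (inherits(volume, "LabelVolume")) {
    label_volume(volume$data[, , src, drop = FALSE], cal)
  } else {
    volume <- materialise(volume)
    intensity_volume(volume$data[, , src, drop = FALSE],
                     calibration = cal, bit_depth = volume$bit_depth)
  }
}

#' Convert a volume to a lower (or equal) bit depth
#'
#' Linear rescale of the full input range `[0, 2^in - 1]` to
#' `[0, 2^bits - 1]`, rounded; the 12-bit maximum 4095 maps to 255 at
#' 8 bits.
#'
#' @param volume an [intensity_volume()].
#' @param bits target depth, one of 8, 12, 16.
#' @return converted volume.
#' @export
reduce_bit_depth <- function(volume, bits) {
  if (!bits %in% c(8, 12, 16))
    stopf("nucridge_bad_params", "bits must be 8, 12 or 16")
  if (bits == volume$bit_depth) return(volume)
  volume <- materialise(volume)
  scale <- (2^bits - 1) / (2^volume$bit_depth - 1)
  intensity_volume(array(round(volume$data * scale), dim(volume$data)),
                   calibration = volume$calibration, bit_depth = bits)
}

#' Write a scene to disk (intensity + GT TIFFs + JSON spec sidecar)
#' @param scene from [generate_scene()].
#' @param spec the [scene_spec()] used.
#' @param prefix output path prefix.
#' @return named character vector of the three files, invisibly.
#' @export
write_scene <- function(scene, spec, prefix) {
  fi <- paste0(prefix, "_intensity.tif")
  fl <- paste0(prefix, "_labels.tif")
  fs <- paste0(prefix, "_spec.json")
  write_volume(scene$intensity, fi)
  write_label_volume(scene$labels, fl)
  jsonlite::write_json(unclass(spec), fs, auto_unbox = TRUE, digits = NA)
  invisible(c(intensity = fi, labels = fl, spec = fs))
}
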