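#' Calibrated intensity volume
#'
#' Container for one channel/timepoint of a 3D fluorescence image. Planes
#' are accessed through [get_plane()], either from an in-memory array or
#' lazily from a multi-page TIFF on disk, so arbitrarily large stacks can
#' be processed one plane at a time.
#'
#' @param data numeric array `[x, y, z]`, or `NULL` for a streamed volume.
#' @param reader function `(z) -> matrix [x, y]` used when `data` is `NULL`.
#' @param shape integer vector `(nx, ny, nz)` in voxels.
#' @param calibration numeric `(dx, dy, dz)` in micrometres per voxel.
#' @param bit_depth one of 8, 12, 16.
#' @param channel_index,time_index 1-based indices this volume was read from.
#' @return An object of class `IntensityVolume`.
#' @export
intensity_volume <- function(data = NULL, reader = NULL, shape = NULL,
                             calibration = c(1, 1, 1), bit_depth = 16,
                             channel_index = 1L, time_index = 1L) {
  if (is.null(shape)) {
    if (is.null(data)) stop("shape required for streamed volumes")
    shape <- dim(data)
    if (length(shape) == 2L) { dim(data) <- c(shape, 1L); shape <- dim(data) }
  }
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(calibration) == 3L, all(calibration > 0),
            bit_depth %in% c(8, 12, 16))
  structure(list(data = data, reader = reader,
                 shape = as.integer(shape), calibration = as.numeric(calibration),
                 bit_depth = as.integer(bit_depth),
                 channel_index = as.integer(channel_index),
                 time_index = as.integer(time_index)),
            class = "IntensityVolume")
}

#' Labelled instance volume
#'
#' Integer array on the same grid as an [intensity_volume()]: 0 is
#' background, each positive value one nucleus instance.
#'
#' @param data integer array `[x, y, z]` of non-negative labels.
#' @param calibration numeric `(dx, dy, dz)` micrometres per voxel.
#' @return An object of class `LabelVolume`.
#' @export
label_volume <- function(data, calibration = c(1, 1, 1)) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, all(data >= 0), all(calibration > 0))
  structure(list(data = array(as.integer(round(data)), dim(data)),
                 shape = dim(data), calibration = as.numeric(calibration)),
            class = "LabelVolume")
}

#' @export
print.IntensityVolume <- function(x, ...) {
  cat(sprintf("IntensityVolume %d x %d x %d voxels, %g x %g x %g um, %d-bit%s\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$calibration[1], x$calibration[2], x$calibration[3], x$bit_depth,
              if (is.null(x$data)) " (streamed)" else ""))
  invisible(x)
}

#' @export
print.LabelVolume <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$data)), 0L)
  cat(sprintf("LabelVolume %d x %d x %d voxels, %d instances\n",
              x$shape[1], x$shape[2], x$shape[3], length(ids)))
  invisible(x)
}

#' Random access to one z plane
#'
#' Reading the same plane twice yields identical values whether the volume
#' is in memory or streamed from disk.
#'
#' @param vol an [intensity_volume()] or [label_volume()].
#' @param z 1-based plane index.
#' @return numeric matrix `[x, y]`.
#' @export
get_plane <- function(vol, z) {
  z <- as.integer(z)
  if (z < 1L || z > vol$shape[3])
    stopf("nucridge_plane_oob", "plane %d out of range 1..%d", z, vol$shape[3])
  if (!is.null(vol$data)) return(vol$data[, , z])
  vol$reader(z)
}

#' Materialise a streamed volume in memory
#' @param vol an [intensity_volume()].
#' @return the same volume with `data` populated.
#' @export
materialise <- function(vol) {
  if (!is.null(vol$data)) return(vol)
  a <- array(0, vol$shape)
  for (z in seq_len(vol$shape[3])) a[, , z] <- vol$reader(z)
  vol$data <- a
  vol
}

# --- TIFF I/O -----------------------------------------------------------

# Page layout for >3D stacks written by this package: channel fastest,
# then z, then time. Axis/calibration metadata travels in a plain-text
# sidecar (<path>.meta) because the available TIFF writer cannot embed
# description tags; absent a sidecar, pages are assumed to be z planes.
page_index <- function(z, c, t, nz, nc) ((t - 1L) * nz + (z - 1L)) * nc + c

meta_path <- function(path) paste0(path, ".meta")

write_meta <- function(path, nx, ny, nz, nc, nt, cal, bits) {
  writeLines(sprintf(
    "nucridge nx=%d ny=%d nz=%d nc=%d nt=%d dx=%.9g dy=%.9g dz=%.9g bits=%d order=CZT",
    nx, ny, nz, nc, nt, cal[1], cal[2], cal[3], bits), meta_path(path))
}

read_meta <- function(path) {
  mp <- meta_path(path)
  if (!file.exists(mp)) return(NULL)
  ln <- readLines(mp, n = 1L, warn = FALSE)
  if (!grepl("^nucridge ", ln)) return(NULL)
  kv <- regmatches(ln, gregexpr("[a-z]+=[-0-9.eE+]+", ln))[[1]]
  vals <- as.numeric(sub("^[a-z]+=", "", kv))
  names(vals) <- sub("=.*$", "", kv)
  vals
}

#' Read a calibrated volume from a multi-page TIFF
#'
#' Axis order is taken from the description string written by
#' [write_volume()] when present; otherwise pages are assumed to be z
#' planes (ZYX order) and this assumption is reported. Missing spatial
#' calibration falls back to 1 um isotropic with a warning.
#'
#' @param path TIFF file.
#' @param channel,timepoint 1-based hyperslab indices.
#' @param stream if `TRUE`, planes are read from disk on demand.
#' @param calibration optional `(dx, dy, dz)` um override.
#' @return an [intensity_volume()].
#' @export
read_volume <- function(path, channel = 1L, timepoint = 1L, stream = FALSE,
                        calibration = NULL) {
  if (!file.exists(path)) stopf("nucridge_missing_file", "no such file: %s", path)
  first <- tiff::readTIFF(path, all = 1, info = TRUE)
  if (is.list(first)) first <- first[[1]]
  meta <- read_meta(path)
  if (is.null(meta)) {
    nc <- 1L; nt <- 1L
    nz <- length(tiff::readTIFF(path, all = TRUE))
    bits <- if (!is.null(attr(first, "bits.per.sample"))) attr(first, "bits.per.sample") else 16L
    cal <- NULL
  } else {
    nc <- as.integer(meta["nc"]); nt <- as.integer(meta["nt"]); nz <- as.integer(meta["nz"])
    if (anyNA(c(nc, nt, nz)) || nc < 1L || nt < 1L || nz < 1L)
      stopf("nucridge_bad_axes", "unresolvable axis layout in %s", meta_path(path))
    bits <- as.integer(meta["bits"])
    cal <- unname(meta[c("dx", "dy", "dz")])
  }
  if (channel < 1L || channel > nc)
    stopf("nucridge_channel_oob", "channel %d out of range 1..%d", channel, nc)
  if (timepoint < 1L || timepoint > nt)
    stopf("nucridge_timepoint_oob", "timepoint %d out of range 1..%d", timepoint, nt)
  if (is.null(cal)) {
    if (is.null(calibration)) {
      warnf("no calibration metadata in %s; assuming 1 um isotropic voxels", basename(path))
      cal <- c(1, 1, 1)
    } else cal <- calibration
  } else if (!is.null(calibration)) cal <- calibration
  scale <- 65535
  ny <- nrow(first); nx <- ncol(first)  # readTIFF returns [row=y, col=x]
  pages <- vapply(seq_len(nz), page_index, integer(1),
                  c = as.integer(channel), t = as.integer(timepoint),
                  nz = nz, nc = nc)
  rd <- function(z) {
    m <- tiff::readTIFF(path, all = pages[z])
    if (is.list(m)) m <- m[[1]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    t(round(m * scale))
  }
  vol <- intensity_volume(reader = rd, shape = c(nx, ny, nz), calibration = cal,
                          bit_depth = if (bits %in% c(8, 12, 16)) bits else 16,
                          channel_index = channel, time_index = timepoint)
  if (!stream) vol <- materialise(vol)
  vol
}

#' Write a volume (optionally multi-channel / multi-timepoint) as TIFF
#'
#' Intensity values must be integers within the bit-depth range; they are
#' stored as 16-bit samples so read/write round-trips are voxel-exact.
#'
#' @param data array `[x, y, z]`, `[x, y, z, c]`, or `[x, y, z, c, t]`, or
#'   an [intensity_volume()].
#' @param path destination file.
#' @param calibration `(dx, dy, dz)` um per voxel.
#' @param bit_depth nominal bit depth recorded in metadata.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, calibration = c(1, 1, 1), bit_depth = 16) {
  if (inherits(data, "IntensityVolume")) {
    calibration <- data$calibration; bit_depth <- data$bit_depth
    data <- materialise(data)$data
  }
  d <- dim(data)
  if (length(d) == 2L) d <- c(d, 1L)
  d <- c(d, rep(1L, 5L - length(d)))
  dim(data) <- d
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]; nt <- d[5]
  if (max(data) > 65535 || min(data) < 0)
    stopf("nucridge_intensity_range", "values outside [0, 65535] cannot be stored")
  pages <- vector("list", nz * nc * nt)
  for (t in seq_len(nt)) for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    pages[[page_index(z, ch, t, nz, nc)]] <- t(data[, , z, ch, t]) / 65535
  }
  tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
    write_meta(path, nx, ny, nz, nc, nt, calibration, bit_depth)
  }, error = function(e) stopf("nucridge_unwritable", "cannot write %s: %s",
                               path, conditionMessage(e)),
  warning = function(w) stopf("nucridge_unwritable", "cannot write %s: %s",
                              path, conditionMessage(w)))
  invisible(path)
}

#' Write a label image as 16-bit TIFF
#'
#' @param labels a [label_volume()] or integer array.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  cal <- c(1, 1, 1)
  if (inherits(labels, "LabelVolume")) { cal <- labels$calibration; labels <- labels$data }
  if (max(labels) >= 65536)
    stopf("nucridge_label_overflow", "max label %d exceeds 16-bit range", max(labels))
  write_volume(labels, path, calibration = cal, bit_depth = 16)
}

#' Read a label image written by [write_label_volume()]
#' @param path TIFF file.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path) {
  v <- read_volume(path)
  label_volume(v$data, v$calibration)
}
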