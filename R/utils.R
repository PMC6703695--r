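# Low-level pixel helpers shared across modules.
#
# Plane convention: a plane is a numeric matrix indexed [x, y] with x the
# fast (first) dimension; a volume is an array [x, y, z]. Coordinates are
# 1-based in R code; exported tables use 0-based coordinates where noted.

# 8-neighbourhood in clockwise order starting East (y grows "down").
DIR8 <- cbind(dx = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
              dy = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
DIR8_ANGLE <- atan2(DIR8[, "dy"], DIR8[, "dx"])  # radians
DIR8_LEN <- sqrt(rowSums(DIR8^2))

lin_idx <- function(x, y, nx) (y - 1L) * nx + x

#' @noRd
pix_dist <- function(a, b) sqrt(sum((a - b)^2))

# Minimal signed angular difference a - b wrapped to (-pi, pi].
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# 8-connected digital line between two pixels (inclusive), Bresenham.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  n <- max(dx, dy) + 1L
  out <- matrix(0L, n, 2L)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    if (x == x1 && y == y1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  out
}

# Shift a matrix by (dx, dy), filling exposed cells.
shift_mat <- function(m, dx, dy, fill = 0) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  xs <- max(1L, 1L + dx):min(nx, nx + dx)
  ys <- max(1L, 1L + dy):min(ny, ny + dy)
  if (length(xs) && length(ys))
    out[xs, ys] <- m[xs - dx, ys - dy]
  out
}

# Logical mask of strict in-bound pixels of a pixel matrix (n x 2).
in_bounds <- function(px, nx, ny) {
  px[, 1L] >= 1L & px[, 1L] <= nx & px[, 2L] >= 1L & px[, 2L] <= ny
}

# Region of the complement of `blocked` 4-connected to the matrix border.
# Returns a logical matrix. Used to find shape interiors: an 8-connected
# closed chain separates the plane into 4-connected components.
outside_fill <- function(blocked) {
  nx <- nrow(blocked); ny <- ncol(blocked)
  open <- !blocked
  out <- matrix(FALSE, nx, ny)
  out[1L, ] <- open[1L, ]; out[nx, ] <- open[nx, ]
  out[, 1L] <- out[, 1L] | open[, 1L]; out[, ny] <- out[, ny] | open[, ny]
  repeat {
    grown <- out |
      shift_mat(out, 1L, 0L, FALSE) | shift_mat(out, -1L, 0L, FALSE) |
      shift_mat(out, 0L, 1L, FALSE) | shift_mat(out, 0L, -1L, FALSE)
    grown <- grown & open
    if (identical(grown, out)) break
    out <- grown
  }
  out
}

# Boundary pixels of a logical mask (mask pixels with a 4-neighbour off it).
mask_boundary <- function(mask) {
  inner <- mask &
    shift_mat(mask, 1L, 0L, FALSE) & shift_mat(mask, -1L, 0L, FALSE) &
    shift_mat(mask, 0L, 1L, FALSE) & shift_mat(mask, 0L, -1L, FALSE)
  mask & !inner
}

# Centroid (x, y) of a set of linear pixel indices on an nx-wide grid.
px_centroid <- function(idx, nx) {
  x <- ((idx - 1L) %% nx) + 1L
  y <- ((idx - 1L) %/% nx) + 1L
  c(mean(x), mean(y))
}

stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "nucridge_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
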