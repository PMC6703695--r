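# Plane-wise ridge enhancement of the nuclear envelope.
#
# The ridge strength is the maximal negative eigenvalue of the
# scale-normalised Hessian of Gaussian; the ridge tangent is the
# eigenvector of the complementary eigenvalue. Borders are handled by
# symmetric (reflective) padding.

# 1D Gaussian and derivative kernels sampled on [-r, r], r = 6 sigma so
# truncation error is negligible relative to the tolerances used in tests.
gauss_kernels <- function(sigma) {
  r <- max(2L, ceiling(6 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g2 <- g * ((x^2 - sigma^2) / sigma^4)
  list(g = g,
       g1 = g * (-x / sigma^2),
       g2 = g2 - mean(g2),   # zero DC: constants map to exactly zero
       r = r)
}

# Separable convolution with symmetric padding, exact at 1e-12 level.
conv2_sep <- function(m, kx, ky) {
  m <- conv_dim(m, kx, 1L)
  conv_dim(m, ky, 2L)
}

conv_dim <- function(m, k, dim) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(m)[dim]
  pre <- pmax(1L, pmin(n, (r:1)))
  post <- pmax(1L, pmin(n, (n:(n - r + 1L))))
  if (dim == 1L) {
    mp <- rbind(m[pre, , drop = FALSE], m, m[post, , drop = FALSE])
    # band operator: row i of output = sum_j k[j] * mp[i + j - 1, ]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[(j):(j + n - 1L), , drop = FALSE]
    out
  } else {
    mp <- cbind(m[, pre, drop = FALSE], m, m[, post, drop = FALSE])
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k)) out <- out + k[j] * mp[, (j):(j + n - 1L), drop = FALSE]
    out
  }
}

#' Gaussian smoothing of one plane
#'
#' Normalised separable Gaussian with reflective borders; `sigma = 0`
#' returns the input unchanged.
#'
#' @param plane numeric matrix `[x, y]`.
#' @param sigma standard deviation in px, >= 0.
#' @return smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(plane, sigma) {
  if (sigma < 0) stopf("nucridge_bad_sigma", "sigma must be >= 0")
  if (sigma == 0) return(plane)
  k <- gauss_kernels(sigma)
  conv2_sep(plane, k$g, k$g)
}

#' Steerable ridge response and orientation
#'
#' Second-order ridge detector: at each pixel the Hessian of the
#' Gaussian-smoothed plane (scale-normalised by `scale^2`) is
#' diagonalised; the response is the magnitude of its negative eigenvalue
#' (0 where none), and the orientation is the ridge tangent in `[0, pi)`.
#' Bright curvilinear structures of width about `2 * scale` respond most
#' strongly along their centre line. Adding a constant to the input does
#' not change the response.
#'
#' @param plane numeric matrix `[x, y]`.
#' @param scale filter scale in px (> 0), about the ridge half-width.
#' @return list of class `RidgeResponse` with `response`, `orientation`
#'   (radians in `[0, pi)`) and `scale`.
#' @export
steerable_ridge_response <- function(plane, scale) {
  if (scale <= 0) stopf("nucridge_bad_sigma", "scale must be > 0")
  k <- gauss_kernels(scale)
  hxx <- conv2_sep(plane, k$g2, k$g)
  hyy <- conv2_sep(plane, k$g, k$g2)
  hxy <- conv2_sep(plane, k$g1, k$g1)
  s2 <- scale^2
  tr <- hxx + hyy
  dd <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
  lmin <- (tr - dd) / 2
  resp <- matrix(pmax(0, -lmin), nrow(plane), ncol(plane)) * s2
  # tangent = eigenvector of the larger eigenvalue
  ori <- 0.5 * atan2(2 * hxy, hxx - hyy)
  ori <- ori %% pi
  structure(list(response = resp, orientation = ori, scale = scale),
            class = "RidgeResponse")
}

#' Thin a ridge response to its crest lines
#'
#' Non-maximum suppression across the local ridge normal: a pixel
#' survives only if its response is at least that of its two neighbours
#' along the normal direction. Thick ridge bands (an envelope is 2-4 px
#' wide) collapse to 1-px crest curves, which is what the tracer
#' follows.
#'
#' @param rr a `RidgeResponse`.
#' @return the `RidgeResponse` with suppressed pixels set to 0.
#' @export
ridge_nms <- function(rr) {
  resp <- rr$response
  normal <- rr$orientation + pi / 2
  ndx <- round(cos(normal)); ndy <- round(sin(normal))
  keep <- matrix(TRUE, nrow(resp), ncol(resp))
  for (sx in -1:1) for (sy in -1:1) {
    if (sx == 0 && sy == 0) next
    sel <- ndx == sx & ndy == sy
    if (!any(sel)) next
    up <- shift_mat(resp, sx, sy, 0)     # neighbour at -(sx,sy)
    dn <- shift_mat(resp, -sx, -sy, 0)   # neighbour at +(sx,sy)
    keep[sel] <- resp[sel] >= up[sel] & resp[sel] >= dn[sel]
  }
  rr$response <- resp * keep
  rr
}
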