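# Per-plane seed detection: Difference-of-Gaussian band-pass on the
# envelope intensity, then thresholded strict local maxima. Seeds are the
# starting points of ridge tracing.

#' Difference-of-Gaussian filter
#'
#' `G(sigma_small) * plane - G(sigma_large) * plane`, both blurs with
#' normalised kernels and reflective borders.
#'
#' @param plane numeric matrix `[x, y]`.
#' @param sigma_small,sigma_large Gaussian sigmas in px, small < large.
#' @return response matrix of the same size.
#' @export
dog_filter <- function(plane, sigma_small, sigma_large) {
  if (!(sigma_small > 0 && sigma_small < sigma_large))
    stopf("nucridge_bad_sigma", "need 0 < sigma_small < sigma_large")
  gaussian_smooth(plane, sigma_small) - gaussian_smooth(plane, sigma_large)
}

#' Thresholded local maxima of a response plane
#'
#' Returns pixels that are maxima of their 8-neighbourhood with score at
#' least `threshold`, greedily thinned so no two returned points lie
#' closer than `min_separation`, sorted by descending score. On a plateau
#' of equal maxima the lexicographically smallest pixel is returned, so
#' the output is deterministic.
#'
#' @param dog_plane response matrix `[x, y]` (any filter output).
#' @param threshold minimum score.
#' @param min_separation minimum Euclidean distance between seeds, px.
#' @param plane_index z index stored with the seeds.
#' @return data.frame with columns `x`, `y`, `z`, `score` (possibly empty).
#' @export
detect_maxima <- function(dog_plane, threshold, min_separation = 0,
                          plane_index = 1L) {
  nx <- nrow(dog_plane); ny <- ncol(dog_plane)
  is_max <- dog_plane >= threshold
  for (k in seq_len(8L)) {
    nb <- shift_mat(dog_plane, DIR8[k, 1L], DIR8[k, 2L], -Inf)
    is_max <- is_max & (dog_plane >= nb)
  }
  idx <- which(is_max)
  if (!length(idx))
    return(data.frame(x = integer(0), y = integer(0), z = integer(0),
                      score = numeric(0)))
  idx <- reduce_plateaus(idx, dog_plane, nx)
  if (!length(idx))
    return(data.frame(x = integer(0), y = integer(0), z = integer(0),
                      score = numeric(0)))
  x <- ((idx - 1L) %% nx) + 1L
  y <- ((idx - 1L) %/% nx) + 1L
  sc <- dog_plane[idx]
  ord <- order(-sc, x, y)
  x <- x[ord]; y <- y[ord]; sc <- sc[ord]
  if (min_separation > 0 && length(x) > 1L) {
    keep <- logical(length(x))
    kx <- numeric(0); ky <- numeric(0)
    ms2 <- min_separation^2
    for (i in seq_along(x)) {
      if (!length(kx) || all((kx - x[i])^2 + (ky - y[i])^2 >= ms2)) {
        keep[i] <- TRUE
        kx <- c(kx, x[i]); ky <- c(ky, y[i])
      }
    }
    x <- x[keep]; y <- y[keep]; sc <- sc[keep]
  }
  data.frame(x = x, y = y, z = as.integer(plane_index), score = sc)
}

# Keep only the lexicographically smallest pixel of each connected
# plateau (8-adjacent qualifying pixels of equal value).
reduce_plateaus <- function(idx, plane, nx) {
  if (length(idx) < 2L) return(idx)
  ny <- ncol(plane)
  inset <- new.env(hash = TRUE, parent = emptyenv())
  for (i in idx) assign(as.character(i), TRUE, envir = inset)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  keep <- integer(0)
  for (i in idx) {
    if (!is.null(seen[[as.character(i)]])) next
    # BFS over equal-valued qualifying neighbours; a plateau is a true
    # regional maximum only when bounded by strictly smaller pixels
    comp <- i; queue <- i; seen[[as.character(i)]] <- TRUE
    v <- plane[i]
    has_lower <- FALSE
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      cx <- ((cur - 1L) %% nx) + 1L; cy <- ((cur - 1L) %/% nx) + 1L
      for (k in seq_len(8L)) {
        px <- cx + DIR8[k, 1L]; py <- cy + DIR8[k, 2L]
        if (px < 1L || px > nx || py < 1L || py > ny) next
        j <- lin_idx(px, py, nx)
        if (plane[j] < v) { has_lower <- TRUE; next }
        if (is.null(inset[[as.character(j)]]) || !is.null(seen[[as.character(j)]])) next
        if (plane[j] == v) {
          seen[[as.character(j)]] <- TRUE
          comp <- c(comp, j); queue <- c(queue, j)
        }
      }
    }
    if (length(comp) > 1L && !has_lower) next
    cxs <- ((comp - 1L) %% nx) + 1L; cys <- ((comp - 1L) %/% nx) + 1L
    keep <- c(keep, comp[order(cxs, cys)][1L])
  }
  sort(keep)
}

#' Export a seed table as TSV
#' @param seeds data.frame from [detect_maxima()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  utils::write.table(seeds, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
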