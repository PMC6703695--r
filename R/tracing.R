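# Tree-structured ridge tracing.
#
# From each seed the envelope is followed pixel by pixel, always stepping
# to the brightest admissible 8-neighbour of the ridge response. Two
# ridglets grow in opposite directions from the root (phase 1); further
# child ridglets are spawned where a trace is obstructed (phase 2). Each
# ridglet terminates with exactly one stop code:
#   C  own-tree path crossing      CP parent crossing point
#   D  distance stop               I  intensity drop
#   L  loop to self                O  origin reached (closed loop)
#   P  path to parent node         T  sharp turn
#   M  assigned post hoc to seeds whose tree yields no accepted shape
STOP_CODES <- c("C", "CP", "D", "I", "L", "M", "O", "P", "T")

# Neighbour scan order: clockwise starting from the previous direction so
# tie-breaking is deterministic and does not bias straight-line tracing.
scan_order <- function(prev_dir) {
  if (is.na(prev_dir)) return(seq_len(8L))
  ((prev_dir - 1L + 0:7) %% 8L) + 1L
}

# Probe for a 2-px forward jump over a 1-px crest gap: a free,
# positive-response pixel at Chebyshev distance 2 within 45 degrees of
# the travel direction, reached through a free midpoint.
bridge_target <- function(resp, env, own, cur, prev_dir, nx, ny) {
  base <- DIR8_ANGLE[prev_dir]
  best <- NULL; best_v <- 0
  for (k in seq_len(8L)) {
    if (abs(ang_diff(DIR8_ANGLE[k], base)) > pi / 4 + 1e-9) next
    tx <- cur[1L] + 2L * DIR8[k, 1L]; ty <- cur[2L] + 2L * DIR8[k, 2L]
    if (tx < 1L || tx > nx || ty < 1L || ty > ny) next
    ti <- lin_idx(tx, ty, nx)
    if (resp[ti] <= best_v) next
    if (own[ti] || env$owner[ti] != 0L) next
    mx <- cur[1L] + DIR8[k, 1L]; my <- cur[2L] + DIR8[k, 2L]
    mi <- lin_idx(mx, my, nx)
    if (own[mi] || env$owner[mi] != 0L) next
    best_v <- resp[ti]
    best <- list(list(px = c(mx, my), i = mi, k = k),
                 list(px = c(tx, ty), i = ti, k = k))
  }
  best
}

# Snap a seed to the strongest response pixel within a 5x5 window
# (ties: first in scan order, deterministic).
snap_to_crest <- function(resp, sx, sy) {
  nx <- nrow(resp); ny <- ncol(resp)
  best <- c(sx, sy); best_v <- resp[sx, sy]
  for (ddy in -2:2) for (ddx in -2:2) {
    px <- sx + ddx; py <- sy + ddy
    if (px < 1L || px > nx || py < 1L || py > ny) next
    if (resp[px, py] > best_v) { best_v <- resp[px, py]; best <- c(px, py) }
  }
  best
}

# Trace one ridglet. `owner` is the per-tree claim matrix (integer ridglet
# id, 0 free); `ancestors` a logical vector marking the root-to-parent
# path; `crossings` a logical vector of recorded crossing points.
# Returns list(path = n x 2 matrix, stop = code, claimed pixels updated in env).
trace_ridglet <- function(env, start, first_dir, id, ancestors, params) {
  resp <- env$resp; nx <- env$nx; ny <- env$ny
  root_resp <- env$root_resp
  drop_level <- params$intensity_drop_fraction * root_resp
  max_len <- params$max_trace_distance
  K <- params$turn_window
  max_turn <- params$sharp_turn_max_angle * pi / 180
  path <- matrix(0L, 256L, 2L)
  path[1L, ] <- start
  npix <- 1L
  cur <- start
  len <- 0
  prev_dir <- first_dir
  turns <- numeric(0)         # signed per-step direction changes
  last_angle <- NA_real_
  loop_px <- NULL             # own-path pixel met at an L stop
  bridges <- 0L               # crest-gap jumps taken
  stop_code <- NULL
  own <- rep(FALSE, nx * ny)  # pixels of this ridglet
  own[lin_idx(start[1L], start[2L], nx)] <- TRUE
  forced <- first_dir   # the spawn direction is taken, not re-chosen
  repeat {
    ord <- if (!is.na(forced) && npix == 1L) forced else scan_order(prev_dir)
    best_k <- 0L; best_v <- -Inf; best_px <- NULL; best_i <- 0L
    for (k in ord) {
      px <- cur[1L] + DIR8[k, 1L]; py <- cur[2L] + DIR8[k, 2L]
      if (px < 1L || px > nx || py < 1L || py > ny) next
      i <- lin_idx(px, py, nx)
      # never step back onto the tail, and never reverse by more than
      # 90 degrees in a single step (that is a jump across the ridge,
      # not a continuation of it)
      if (npix > 1L && px == path[npix - 1L, 1L] && py == path[npix - 1L, 2L]) next
      if (npix > 2L && px == path[npix - 2L, 1L] && py == path[npix - 2L, 2L]) next
      if (!is.na(prev_dir) && npix > 1L &&
          abs(ang_diff(DIR8_ANGLE[k], DIR8_ANGLE[prev_dir])) > pi / 2 + 1e-9) next
      v <- resp[i]
      if (v > best_v) { best_v <- v; best_k <- k; best_px <- c(px, py); best_i <- i }
    }
    if ((best_k == 0L || best_v <= 0) && !is.na(prev_dir) && bridges < 12L) {
      # crest gap: jump 2 px forward within +/-45 deg of travel if a
      # positive-response pixel sits there, claiming the midpoint too
      jump <- bridge_target(resp, env, own, cur, prev_dir, nx, ny)
      if (!is.null(jump)) {
        bridges <- bridges + 1L
        for (stp in jump) {   # midpoint then target
          npix <- npix + 1L
          if (npix > nrow(path)) path <- rbind(path, matrix(0L, nrow(path), 2L))
          path[npix, ] <- stp$px
          own[stp$i] <- TRUE
          env$owner[stp$i] <- id
          len <- len + 1
        }
        cur <- jump[[length(jump)]]$px
        prev_dir <- jump[[length(jump)]]$k
        next
      }
    }
    if (best_k == 0L || best_v <= 0) { stop_code <- "C"; break }   # dead end
    step_len <- DIR8_LEN[best_k]
    if (len + step_len > max_len) { stop_code <- "D"; break }
    if (best_v < drop_level) { stop_code <- "I"; break }
    if (best_i == env$root_i) {
      if (npix >= 8L) { stop_code <- "O"; break }
      # too short to be a loop: treat root as blocked, look elsewhere
      resp_saved <- resp[best_i]; resp[best_i] <- 0; env$resp <- resp
      next
    }
    if (own[best_i]) { stop_code <- "L"; loop_px <- best_px; break }
    if (env$crossings[best_i]) { stop_code <- "CP"; env$crossings[best_i] <- TRUE; break }
    if (ancestors[best_i]) { stop_code <- "P"; env$crossings[best_i] <- TRUE; break }
    if (env$owner[best_i] > 0L) { stop_code <- "C"; env$crossings[best_i] <- TRUE; break }
    # take the step
    npix <- npix + 1L
    if (npix > nrow(path)) path <- rbind(path, matrix(0L, nrow(path), 2L))
    path[npix, ] <- best_px
    own[best_i] <- TRUE
    env$owner[best_i] <- id
    len <- len + step_len
    cur <- best_px
    ang <- DIR8_ANGLE[best_k]
    if (!is.na(last_angle)) turns <- c(turns, ang_diff(ang, last_angle))
    last_angle <- ang
    prev_dir <- best_k
    nt <- length(turns)
    if (nt >= K) {
      # net signed turn over the window; digitisation zigzag cancels
      if (abs(sum(turns[(nt - K + 1L):nt])) > max_turn) { stop_code <- "T"; break }
    }
  }
  list(path = path[seq_len(npix), , drop = FALSE], stop = stop_code,
       loop_px = loop_px)
}

#' Grow a ridglet tree from one seed
#'
#' Phase 1 snaps the seed to the strongest response pixel in its
#' 3x3 neighbourhood and grows two ridglets in opposite directions from
#' that root. Phase 2 spawns child ridglets (up to `params$branch_depth`
#' generations) at termini whose trace was obstructed (stop codes C, CP,
#' P, T), exploring the branches of envelope junctions. Every pixel
#' belongs to at most one ridglet of the tree; crossings are recorded as
#' annotations, not tree edges, so the result is acyclic.
#'
#' @param response a `RidgeResponse` from [steerable_ridge_response()].
#' @param seed one-row data.frame (or list) with `x`, `y` in px.
#' @param params a [seg_params()] object.
#' @return object of class `RidgletTree`: list with `root` (x, y),
#'   `ridglets` (each: `path`, `stop`, `parent`, `depth`), `leaves`
#'   (ridglet indices), and `claimed` (linear pixel indices).
#' @export
build_tree <- function(response, seed, params) {
  resp <- response$response
  nx <- nrow(resp); ny <- ncol(resp)
  root <- snap_to_crest(resp, as.integer(seed$x), as.integer(seed$y))
  best_v <- resp[root[1L], root[2L]]
  tree <- structure(list(root = root, ridglets = list(), leaves = integer(0),
                         claimed = integer(0)), class = "RidgletTree")
  if (best_v <= 0) return(tree)

  env <- new.env(parent = emptyenv())
  env$resp <- resp; env$nx <- nx; env$ny <- ny
  env$owner <- integer(nx * ny)
  env$crossings <- rep(FALSE, nx * ny)
  env$root_i <- lin_idx(root[1L], root[2L], nx)
  env$root_resp <- best_v
  env$owner[env$root_i] <- 1L

  # phase 1: strongest neighbour sets the first direction; the second
  # ridglet starts at least 90 degrees away from it.
  nb_v <- rep(-Inf, 8L)
  for (k in seq_len(8L)) {
    px <- root[1L] + DIR8[k, 1L]; py <- root[2L] + DIR8[k, 2L]
    if (px >= 1L && px <= nx && py >= 1L && py <= ny) nb_v[k] <- resp[px, py]
  }
  dA <- which.max(nb_v)
  ridglets <- list()
  if (nb_v[dA] > 0) {
    rA <- trace_ridglet(env, root, dA, 2L, rep(FALSE, nx * ny), params)
    rA$parent <- 0L; rA$depth <- 1L; rA$branch_idx <- 0L
    ridglets[[1L]] <- rA
    opp <- which(abs(ang_diff(DIR8_ANGLE, DIR8_ANGLE[dA])) >= pi / 2 - 1e-9)
    opp_free <- vapply(opp, function(k) {
      px <- root[1L] + DIR8[k, 1L]; py <- root[2L] + DIR8[k, 2L]
      px >= 1L && px <= nx && py >= 1L && py <= ny &&
        env$owner[lin_idx(px, py, nx)] == 0L
    }, logical(1))
    opp <- opp[nb_v[opp] > 0 & opp_free]
    if (rA$stop != "O" && length(opp)) {
      dB <- opp[which.max(nb_v[opp])]
      rB <- trace_ridglet(env, root, dB, 3L, rep(FALSE, nx * ny), params)
      rB$parent <- 0L; rB$depth <- 1L; rB$branch_idx <- 0L
      ridglets[[2L]] <- rB
    }
  }

  # phase 2: child ridglets spawn (a) at obstructed termini and (b) at
  # path intersections - path pixels with a strong unclaimed ridge
  # neighbour, e.g. where a second envelope wall meets the traced one.
  # Each spawn pixel is recorded as a crossing point.
  next_id <- length(ridglets) + 2L
  max_ridglets <- 16L
  queue <- seq_along(ridglets)
  while (length(queue)) {
    pi_ <- queue[1L]; queue <- queue[-1L]
    if (length(ridglets) >= max_ridglets) break
    par <- ridglets[[pi_]]
    if (par$depth >= params$branch_depth + 1L) next
    n_par <- nrow(par$path)
    if (n_par < 3L) next
    # ancestor mask: all pixels from root through this ridglet
    anc <- rep(FALSE, nx * ny)
    pp <- pi_
    while (pp != 0L) {
      p_ <- ridglets[[pp]]$path
      anc[lin_idx(p_[, 1L], p_[, 2L], nx)] <- TRUE
      pp <- ridglets[[pp]]$parent
    }
    anc[env$root_i] <- TRUE
    spawn_sites <- list()
    # (a) terminus, when the stop was an obstruction
    if (par$stop %in% c("C", "CP", "P", "T", "L")) {
      term <- par$path[n_par, ]
      inc_dir <- atan2(term[2L] - par$path[n_par - 1L, 2L],
                       term[1L] - par$path[n_par - 1L, 1L])
      for (k in seq_len(8L)) {
        px <- term[1L] + DIR8[k, 1L]; py <- term[2L] + DIR8[k, 2L]
        if (px < 1L || px > nx || py < 1L || py > ny) next
        i <- lin_idx(px, py, nx)
        if (env$owner[i] != 0L || resp[i] <= 0) next
        if (abs(ang_diff(DIR8_ANGLE[k], inc_dir)) > 3 * pi / 4 + 1e-9) next
        spawn_sites[[length(spawn_sites) + 1L]] <-
          list(at = n_par, k = k, v = resp[i])
      }
    }
    # (b) mid-path intersections with a strong unclaimed ridge (only on
    # first-generation ridglets; deeper scans add little but cost much)
    branch_level <- 0.5 * env$root_resp
    if (par$depth == 1L && n_par >= 7L) {
      mid <- seq(3L, n_par - 2L)
      for (k in seq_len(8L)) {
        px <- par$path[mid, 1L] + DIR8[k, 1L]
        py <- par$path[mid, 2L] + DIR8[k, 2L]
        okb <- px >= 1L & px <= nx & py >= 1L & py <= ny
        if (!any(okb)) next
        i <- lin_idx(px[okb], py[okb], nx)
        hit <- env$owner[i] == 0L & resp[i] >= branch_level
        for (j in which(hit))
          spawn_sites[[length(spawn_sites) + 1L]] <-
            list(at = mid[okb][j], k = k, v = resp[i[j]])
      }
    }
    if (!length(spawn_sites)) next
    ord <- order(-vapply(spawn_sites, `[[`, numeric(1), "v"))
    taken <- 0L
    for (s in spawn_sites[ord]) {
      if (taken >= 4L) break
      at_px <- par$path[s$at, ]
      tgt <- at_px + DIR8[s$k, ]
      if (env$owner[lin_idx(tgt[1L], tgt[2L], nx)] != 0L) next
      rc <- trace_ridglet(env, at_px, s$k, next_id, anc, params)
      if (nrow(rc$path) < 3L) next
      rc$parent <- pi_; rc$depth <- par$depth + 1L; rc$branch_idx <- s$at
      env$crossings[lin_idx(at_px[1L], at_px[2L], nx)] <- TRUE
      ridglets[[length(ridglets) + 1L]] <- rc
      queue <- c(queue, length(ridglets))
      next_id <- next_id + 1L
      taken <- taken + 1L
    }
  }

  tree$ridglets <- ridglets
  tree$crossings <- which(env$crossings)
  tree$leaves <- which(vapply(ridglets, function(r) nrow(r$path) >= 3L, logical(1)))
  tree$claimed <- which(env$owner > 0L)
  tree
}

#' Stop-code tally of a tree
#' @param tree a `RidgletTree`.
#' @return named integer vector over the stop codes present.
#' @export
stop_codes <- function(tree) {
  codes <- vapply(tree$ridglets, `[[`, character(1), "stop")
  table(factor(codes, levels = STOP_CODES))
}
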