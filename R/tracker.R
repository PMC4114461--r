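# Plan-view particle-filter person tracker ------------------------------------
#
# Depth-only background subtraction; foreground pixels are back-projected to
# 3D, expressed in the camera's floor-anchored tracking frame, gated by the
# plan-view height cut-off and accumulated into height/occupancy (and
# optionally colour) maps; each person is tracked by an independent particle
# filter with a first-order linear dynamic model and a Gaussian-mixture
# observation likelihood over the feature maps.

#' Depth-only background subtraction
#'
#' A pixel is foreground iff it is valid in the frame and closer to the
#' camera than the background by more than `tau`. Invalid pixels (depth 0)
#' are never foreground; pixels with no background reference are foreground
#' when valid (an object in front of out-of-range background).
#'
#' @param frame Depth matrix (mm, 0 = invalid).
#' @param bg Background depth matrix of identical dimensions (mm).
#' @param tau Subtraction threshold (m).
#' @return Logical matrix, `TRUE` = foreground.
#' @export
subtract_background <- function(frame, bg, tau = 0.10) {
  if (!all(dim(frame) == dim(bg))) {
    stop("frame and background dimensions differ", call. = FALSE)
  }
  idx <- .fg_indices(frame, bg, tau * 1000)
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  mask[idx] <- TRUE
  mask
}

#' Create / update the depth background model
#'
#' The model is refreshed only when no tracked objects are present: eligible
#' frames are buffered and, once `k` frames at least `period` seconds after
#' the last refresh have been collected, the per-pixel median replaces the
#' reference depth.
#'
#' @param frame Initial (or new) depth frame (mm matrix).
#' @param t Frame time (s).
#' @param period Minimum seconds between refreshes.
#' @param k Number of buffered frames in the median.
#' @return A list of class `"background_model"` with `depth`, `last_update`,
#'   `buffer`, `period`, `k`.
#' @export
background_model <- function(frame, t = 0, period = 120, k = 5) {
  structure(list(depth = frame, last_update = t, buffer = list(),
                 period = period, k = k),
            class = "background_model")
}

#' @rdname background_model
#' @param bg A `"background_model"`.
#' @param active_tracks Number of currently tracked objects.
#' @export
update_background <- function(bg, frame, active_tracks, t) {
  if (active_tracks > 0) {
    bg$buffer <- list()
    return(bg)
  }
  if (t - bg$last_update < bg$period) return(bg)
  bg$buffer[[length(bg$buffer) + 1L]] <- frame
  if (length(bg$buffer) >= bg$k) {
    arr <- simplify2array(bg$buffer)
    med <- apply(arr, c(1, 2), stats::median)
    bg$depth <- med
    bg$last_update <- t
    bg$buffer <- list()
  }
  bg
}

#' Build plan-view feature maps from foreground points
#'
#' Points below the height cut-off are discarded; surviving points are binned
#' on a floor grid (half-open cells `[k*cell, (k+1)*cell)`), recording the
#' per-cell maximum height, the summed occupancy weight and, when colours are
#' supplied, the mean colour. With unit weights the total occupancy equals
#' the number of surviving points.
#'
#' @param points n x 3 matrix of tracking-frame points: x, y (m) and height
#'   above the floor (m).
#' @param cell Cell size (m); must be positive.
#' @param cutoff Height cut-off (m); points below are discarded. Use 0 to
#'   disable.
#' @param bounds Numeric `c(x0, x1, y0, y1)` grid extent (m); defaults to the
#'   point bounding box.
#' @param weights Optional per-point occupancy weights (e.g. the pixel
#'   footprint area in cell units); default 1.
#' @param color Optional n x 3 matrix of point colours.
#' @return List of class `"plan_view_maps"`: matrices `height`, `occupancy`
#'   (nx x ny, x indexes rows) and optional `color`, plus `x0, y0, cell, nx,
#'   ny` and `n_points` (surviving point count).
#' @export
build_plan_view_maps <- function(points, cell = 0.05, cutoff = 1.0,
                                 bounds = NULL, weights = NULL, color = NULL) {
  if (!is.numeric(cell) || cell <= 0) stop("cell size must be positive", call. = FALSE)
  points <- rbind(points)
  keep <- if (nrow(points)) points[, 3] >= cutoff else logical(0)
  pts <- points[keep, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(pts)) else weights[keep]
  col <- if (is.null(color)) NULL else color[keep, , drop = FALSE]
  if (is.null(bounds)) {
    bounds <- if (nrow(pts)) {
      c(floor(min(pts[, 1]) / cell) * cell, ceiling(max(pts[, 1]) / cell + 1) * cell,
        floor(min(pts[, 2]) / cell) * cell, ceiling(max(pts[, 2]) / cell + 1) * cell)
    } else c(0, cell, 0, cell)
  }
  nx <- max(1L, as.integer(ceiling((bounds[2] - bounds[1]) / cell)))
  ny <- max(1L, as.integer(ceiling((bounds[4] - bounds[3]) / cell)))
  H <- matrix(0, nx, ny)
  O <- matrix(0, nx, ny)
  n_pts <- 0L
  if (nrow(pts)) {
    ix <- as.integer(floor((pts[, 1] - bounds[1]) / cell)) + 1L
    iy <- as.integer(floor((pts[, 2] - bounds[3]) / cell)) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    ix <- ix[ok]; iy <- iy[ok]
    h <- pts[ok, 3]; ww <- w[ok]
    n_pts <- sum(ok)
    if (n_pts) {
      lin <- ix + nx * (iy - 1L)
      os <- rowsum(ww, lin)
      O[as.integer(rownames(os))] <- os
      # per-cell max height: ascending writes leave the maximum in place
      o <- order(h)
      H[lin[o]] <- h[o]
    }
  }
  out <- list(height = H, occupancy = O, x0 = bounds[1], y0 = bounds[3],
              cell = cell, nx = nx, ny = ny, n_points = n_pts)
  if (!is.null(col) && nrow(pts)) {
    C <- array(0, c(nx, ny, 3))
    if (n_pts) {
      cnt <- rowsum(rep(1, n_pts), lin)
      for (ch in 1:3) {
        cs <- rowsum(col[ok, ch], lin) / cnt
        M <- matrix(0, nx, ny); M[as.integer(rownames(cs))] <- cs
        C[, , ch] <- M
      }
    }
    out$color <- C
  }
  structure(out, class = "plan_view_maps")
}

# Radial surface-to-axis correction: a depth camera samples only the
# camera-facing surface of a person, so back-projected points sit about half
# a torso depth closer to the camera than the body axis. Points are shifted
# outward from the tracking-frame origin (the floor point under the camera)
# by `offset` metres before binning.
.shift_from_camera <- function(Pt, offset) {
  if (offset <= 0 || !nrow(Pt)) return(Pt)
  r <- sqrt(Pt[, 1]^2 + Pt[, 2]^2)
  f <- (r + offset) / pmax(r, 1e-6)
  Pt[, 1] <- Pt[, 1] * f
  Pt[, 2] <- Pt[, 2] * f
  Pt
}

# cell centre coordinates of nonzero occupancy cells
.occupied_cells <- function(maps) {
  idx <- which(maps$occupancy > 0)
  if (!length(idx)) return(NULL)
  ix <- (idx - 1L) %% maps$nx + 1L
  iy <- (idx - 1L) %/% maps$nx + 1L
  cbind(
    x = maps$x0 + (ix - 0.5) * maps$cell,
    y = maps$y0 + (iy - 0.5) * maps$cell,
    occ = maps$occupancy[idx],
    h = maps$height[idx]
  )
}

#' Create a person track
#'
#' @param id Track identifier.
#' @param seed_pos Length-2 initial position (tracking frame, m).
#' @param n Number of particles.
#' @param pos_spread,vel_spread Initial particle spread (m, m/s).
#' @return List of class `"person_track"`: `particles` (n x 4: x, y, vx, vy),
#'   normalized `weights`, `status` and bookkeeping counters.
#' @export
person_track <- function(id, seed_pos, n = 300L, pos_spread = 0.1,
                         vel_spread = 0.3) {
  particles <- cbind(
    rnorm(n, seed_pos[1], pos_spread), rnorm(n, seed_pos[2], pos_spread),
    rnorm(n, 0, vel_spread), rnorm(n, 0, vel_spread)
  )
  structure(list(id = id, particles = particles, weights = rep(1 / n, n),
                 status = "tentative", hits = 0L, misses = 0L),
            class = "person_track")
}

#' Particle filter prediction step
#'
#' First-order linear dynamic model with additive Gaussian noise:
#' `x += v dt + eps_pos`, `v += eta_vel`. Weights are unchanged.
#'
#' @param track A `"person_track"`.
#' @param dt Time step (s); must be positive.
#' @param q_pos Position noise std per step (m).
#' @param q_vel Velocity noise std per step (m/s).
#' @return The advanced track.
#' @export
pf_predict <- function(track, dt, q_pos = 0.03, q_vel = 0.25) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  p <- track$particles
  n <- nrow(p)
  p[, 1] <- p[, 1] + p[, 3] * dt + rnorm(n, 0, q_pos)
  p[, 2] <- p[, 2] + p[, 4] * dt + rnorm(n, 0, q_pos)
  p[, 3] <- p[, 3] + rnorm(n, 0, q_vel)
  p[, 4] <- p[, 4] + rnorm(n, 0, q_vel)
  track$particles <- p
  track
}

# Gaussian-mixture observation likelihood of particle positions
.pf_likelihood <- function(px, py, maps, sigma = 0.08, w_occ = 0.625,
                           w_h = 0.375, h_mu = 1.65, h_sd = 0.4,
                           floor_lik = 1e-4) {
  cells <- .occupied_cells(maps)
  if (is.null(cells)) return(rep(floor_lik, length(px)))
  occ_n <- cells[, "occ"] / max(cells[, "occ"])
  h_sc <- exp(-0.5 * ((cells[, "h"] - h_mu) / h_sd)^2)
  score <- w_occ * occ_n + w_h * h_sc
  d2 <- outer(px, cells[, "x"], "-")^2 + outer(py, cells[, "y"], "-")^2
  as.numeric(exp(-d2 / (2 * sigma^2)) %*% score) + floor_lik
}

#' Particle filter correction step
#'
#' Particle weights are multiplied by a Gaussian-mixture likelihood over the
#' plan-view maps (kernel-smoothed occupancy and height-plausibility scores;
#' the colour term is dropped when no colour map is present) and
#' renormalized; systematic resampling is applied when the effective sample
#' size falls below half the particle count. If the total likelihood mass is
#' at the floor everywhere, weights are reset to uniform and the track is
#' flagged as missing its observation.
#'
#' @param track A `"person_track"`.
#' @param maps A `"plan_view_maps"`.
#' @param sigma Kernel bandwidth (m).
#' @param floor_lik Floor likelihood for out-of-support particles.
#' @return The corrected track; attribute `observed` reports whether the
#'   observation supported the track.
#' @export
pf_correct <- function(track, maps, sigma = 0.08, floor_lik = 1e-4) {
  p <- track$particles
  lik <- .pf_likelihood(p[, 1], p[, 2], maps, sigma = sigma, floor_lik = floor_lik)
  w <- track$weights * lik
  observed <- max(lik) > 10 * floor_lik
  if (!observed || sum(w) <= 0) {
    track$weights <- rep(1 / nrow(p), nrow(p))
    track$misses <- track$misses + 1L
    attr(track, "observed") <- FALSE
    return(track)
  }
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  if (ess < nrow(p) / 2) {
    idx <- systematic_resample(w, runif(1))
    track$particles <- p[idx, , drop = FALSE]
    track$weights <- rep(1 / nrow(p), nrow(p))
  } else {
    track$weights <- w
  }
  track$hits <- track$hits + 1L
  track$misses <- 0L
  if (track$status == "tentative" && track$hits >= 3L) track$status <- "confirmed"
  attr(track, "observed") <- TRUE
  track
}

#' Systematic resampling
#'
#' @param w Normalized weights.
#' @param u Single uniform draw in `[0, 1)`.
#' @return Integer indices of the resampled particles (ties broken by index).
#' @export
systematic_resample <- function(w, u = runif(1)) {
  n <- length(w)
  positions <- (seq_len(n) - 1 + u) / n
  findInterval(positions, cumsum(w), left.open = TRUE) + 1L
}

#' Posterior position estimate of a track
#'
#' @param track A `"person_track"` with normalized weights.
#' @return Length-2 weighted-mean position (m).
#' @export
estimate_position <- function(track) {
  c(sum(track$particles[, 1] * track$weights),
    sum(track$particles[, 2] * track$weights))
}

#' Detect new persons in the plan-view maps
#'
#' Connected components of occupied cells whose summed occupancy and maximum
#' height exceed person thresholds, farther than an exclusion radius from any
#' existing track, are returned as seed positions for new tentative tracks.
#'
#' @param maps A `"plan_view_maps"`.
#' @param tracks List of existing `"person_track"` objects.
#' @param min_occ Minimum summed occupancy of a component.
#' @param min_height Minimum component height (m).
#' @param exclusion Exclusion radius around existing tracks (m).
#' @return Matrix with one seed `c(x, y)` per row (possibly 0 rows).
#' @export
detect_new_persons <- function(maps, tracks = list(), min_occ = 50,
                               min_height = 1.3, exclusion = 0.5) {
  cells <- .occupied_cells(maps)
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (is.null(cells)) return(empty)
  lab <- EBImage::bwlabel(maps$occupancy > 0)
  idx <- which(maps$occupancy > 0)
  comp <- lab[idx]
  occ <- maps$occupancy[idx]
  hgt <- maps$height[idx]
  ix <- (idx - 1L) %% maps$nx + 1L
  iy <- (idx - 1L) %/% maps$nx + 1L
  cx <- maps$x0 + (ix - 0.5) * maps$cell
  cy <- maps$y0 + (iy - 0.5) * maps$cell
  seeds <- list()
  for (k in unique(comp)) {
    m <- comp == k
    if (sum(occ[m]) < min_occ || max(hgt[m]) < min_height) next
    sx <- sum(cx[m] * occ[m]) / sum(occ[m])
    sy <- sum(cy[m] * occ[m]) / sum(occ[m])
    near <- FALSE
    for (tr in tracks) {
      pos <- estimate_position(tr)
      if (sqrt((pos[1] - sx)^2 + (pos[2] - sy)^2) < exclusion) { near <- TRUE; break }
    }
    if (!near) seeds[[length(seeds) + 1L]] <- c(sx, sy)
  }
  if (!length(seeds)) return(empty)
  do.call(rbind, seeds)
}

# Tracker state over one camera ------------------------------------------------

#' Initialize a per-camera tracker
#'
#' @param cam A `"depth_camera"`.
#' @param bg_frame Depth frame of the empty scene used to seed the background
#'   model (mm matrix).
#' @param config A `"sim_config"` (cell size, cut-off, particle count, tau).
#' @param bounds Plan-view grid extent in tracking coordinates
#'   `c(x0, x1, y0, y1)`.
#' @param north_deg Magnetic North heading used for the rig angle psi.
#' @return List of class `"plan_view_tracker"`.
#' @export
plan_view_tracker <- function(cam, bg_frame, config = sim_config(),
                              bounds = c(-3.2, 3.2, 0.5, 6.2),
                              north_deg = 0) {
  structure(list(
    cam = cam,
    frame = camera_tracking_frame(cam, north_deg),
    bg = background_model(bg_frame),
    bounds = bounds,
    tracks = list(),
    next_id = 1L,
    config = config,
    t_prev = NA_real_
  ), class = "plan_view_tracker")
}

#' Advance a tracker by one depth frame
#'
#' Runs background subtraction, plan-view map construction, the particle
#' filter predict/correct cycle for every track, new-person detection and
#' track status bookkeeping.
#'
#' @param tk A `"plan_view_tracker"`.
#' @param depth Depth frame (mm matrix).
#' @param t Frame time (s).
#' @param tau Background subtraction threshold (m).
#' @return The updated tracker; attribute `positions` holds a tibble of
#'   confirmed track positions (tracking frame and world frame).
#' @export
tracker_step <- function(tk, depth, t, tau = 0.10) {
  cfg <- tk$config
  idx <- .fg_indices(depth, tk$bg$depth, tau * 1000)
  maps <- if (length(idx)) {
    vv <- (idx - 1L) %% tk$cam$height
    uu <- (idx - 1L) %/% tk$cam$height
    z <- depth[idx]
    Pw <- backproject_pixels(tk$cam, uu, vv, z)
    Pt <- .shift_from_camera(to_tracking(tk$frame, Pw), cfg$surface_offset)
    # occupancy weight: physical pixel footprint in cell-area units
    w <- (z / 1000)^2 / (tk$cam$fx * tk$cam$fy * cfg$cell^2)
    build_plan_view_maps(Pt, cell = cfg$cell, cutoff = cfg$height_cutoff,
                         bounds = tk$bounds, weights = w)
  } else {
    build_plan_view_maps(matrix(numeric(0), 0, 3), cell = cfg$cell,
                         cutoff = cfg$height_cutoff, bounds = tk$bounds)
  }
  dt <- if (is.na(tk$t_prev)) 1 / cfg$fps else max(t - tk$t_prev, 1e-3)
  tk$t_prev <- t
  keep <- list()
  for (tr in tk$tracks) {
    tr <- pf_predict(tr, dt)
    tr <- pf_correct(tr, maps)
    if (tr$misses < 5L) keep[[length(keep) + 1L]] <- tr
  }
  tk$tracks <- keep
  seeds <- detect_new_persons(maps, tk$tracks)
  if (nrow(seeds)) {
    for (i in seq_len(nrow(seeds))) {
      tk$tracks[[length(tk$tracks) + 1L]] <-
        person_track(tk$next_id, seeds[i, ], n = cfg$n_particles)
      tk$next_id <- tk$next_id + 1L
    }
  }
  tk$bg <- update_background(tk$bg, depth, length(tk$tracks), t)
  conf <- Filter(function(tr) tr$status == "confirmed", tk$tracks)
  pos <- lapply(conf, function(tr) {
    p <- estimate_position(tr)
    pw <- from_tracking(tk$frame, c(p[1], p[2], 0))
    c(tr$id, p[1], p[2], pw[1], pw[2])
  })
  M <- if (length(pos)) do.call(rbind, pos) else matrix(numeric(0), 0, 5)
  attr(tk, "positions") <- tibble::new_tibble(list(
    t = rep(t, nrow(M)), track_id = as.integer(M[, 1]),
    x = M[, 2], y = M[, 3], x_world = M[, 4], y_world = M[, 5],
    status = rep("confirmed", nrow(M))
  ), nrow = nrow(M))
  attr(tk, "maps") <- maps
  tk
}
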