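# Synthetic sensor-data generator -------------------------------------------
#
# Emulates the laboratory accuracy-assessment protocol: an 8 x 5 m walking
# area on a 0.5 m grid, two overhead depth cameras (2.25 m height, 25 degree
# downward pitch, 640x480, 57 degree horizontal field of view) covering the
# area in non-overlapping halves, and a waist-worn MARG device sampled at
# 100 Hz. Every output is a deterministic function of (config, seed).

#' Pinhole depth camera description
#'
#' Camera frame follows the computer-vision convention: x right, y down,
#' z forward along the optical axis. The pose is given by a world position,
#' a yaw (heading of the optical axis ground projection, degrees CCW from
#' the world x-axis) and a downward pitch.
#'
#' @param position Length-3 world position (m); z is the mounting height.
#' @param yaw_deg Heading of the optical axis projection (degrees).
#' @param pitch_deg Downward pitch (degrees).
#' @param fx,fy,cx,cy Intrinsics (pixels). Defaults approximate a Kinect:
#'   57 degree horizontal field of view at 640x480.
#' @param width,height Image size (pixels).
#' @param range_m Valid depth range (m); measurements outside are invalid (0).
#' @return List of class `"depth_camera"`.
#' @export
depth_camera <- function(position, yaw_deg, pitch_deg = 25,
                         fx = 575, fy = 575, cx = 319.5, cy = 239.5,
                         width = 640L, height = 480L,
                         range_m = c(0.4, 6.0)) {
  yaw <- yaw_deg * pi / 180
  pitch <- pitch_deg * pi / 180
  fwd <- c(cos(pitch) * cos(yaw), cos(pitch) * sin(yaw), -sin(pitch))
  right <- c(sin(yaw), -cos(yaw), 0)
  down <- pracma_cross(fwd, right)
  structure(list(
    position = position, yaw_deg = yaw_deg, pitch_deg = pitch_deg,
    fx = fx, fy = fy, cx = cx, cy = cy,
    width = as.integer(width), height = as.integer(height),
    range_m = range_m,
    R = cbind(right, down, fwd, deparse.level = 0)  # columns: camera axes in world
  ), class = "depth_camera")
}

#' Tracking frame of a camera over the floor plane z = 0
#'
#' @param cam A `"depth_camera"`.
#' @param north_deg World heading of magnetic North (degrees CCW from the
#'   world x-axis); used to fill the rig angle psi.
#' @return A `"tracking_frame"` (see [make_tracking_frame()]).
#' @export
camera_tracking_frame <- function(cam, north_deg = 0) {
  plane <- structure(list(normal = c(0, 0, 1), offset = 0), class = "floor_plane")
  fr <- make_tracking_frame(plane, cam$position, cam$R[, 3])
  fr$psi_deg <- wrap_heading(cam$yaw_deg - north_deg)
  fr
}

#' Project world points into a depth camera
#'
#' @param cam A `"depth_camera"`.
#' @param P n x 3 matrix of world points (m).
#' @return List with integer pixel coordinates `u`, `v` (0-based), depth `z`
#'   (m, along the optical axis) and logical `ok` (inside image, z > 0).
#' @export
project_points <- function(cam, P) {
  pc <- sweep(P, 2, cam$position) %*% cam$R
  z <- pc[, 3]
  u <- as.integer(floor(cam$fx * pc[, 1] / z + cam$cx + 0.5))
  v <- as.integer(floor(cam$fy * pc[, 2] / z + cam$cy + 0.5))
  ok <- z > 1e-6 & u >= 0L & u < cam$width & v >= 0L & v < cam$height
  list(u = u, v = v, z = z, ok = ok)
}

#' Back-project depth pixels to world points
#'
#' @param cam A `"depth_camera"`.
#' @param u,v Pixel coordinates (0-based).
#' @param z_mm Depth values (mm, along the optical axis).
#' @return n x 3 matrix of world points (m).
#' @export
backproject_pixels <- function(cam, u, v, z_mm) {
  z <- z_mm / 1000
  pc <- cbind((u - cam$cx) / cam$fx * z, (v - cam$cy) / cam$fy * z, z)
  sweep(pc %*% t(cam$R), 2, cam$position, "+")
}

#' Analytic depth image of the bare floor
#'
#' Intersects every pixel ray with the plane z = 0; depths outside the valid
#' range are invalid (0). Used both as the simulated empty scene and as the
#' reference for the background model.
#'
#' @param cam A `"depth_camera"`.
#' @return `height x width` numeric matrix of depths in mm (0 = invalid).
#' @export
floor_depth_image <- function(cam) {
  u <- matrix(0:(cam$width - 1L), cam$height, cam$width, byrow = TRUE)
  v <- matrix(0:(cam$height - 1L), cam$height, cam$width)
  dx <- (u - cam$cx) / cam$fx
  dy <- (v - cam$cy) / cam$fy
  # world z-component of each ray direction
  dz_w <- cam$R[3, 1] * dx + cam$R[3, 2] * dy + cam$R[3, 3]
  tt <- -cam$position[3] / dz_w
  depth <- tt * 1000
  depth[!(dz_w < 0) | tt < cam$range_m[1] | tt > cam$range_m[2]] <- 0
  depth
}

# Body model ------------------------------------------------------------------

#' Synthetic standing body model
#'
#' A vertical trunk with an elliptical cross-section (narrower front-to-back
#' than side-to-side), a narrower leg section, and a head sphere offset
#' toward the ventral side; the offset makes front and back visually
#' distinguishable in plan view, as real bodies are. The body-local frame
#' has x ventral (forward), y left, z up. Bodies are rendered by exact
#' per-pixel ray casting against these primitives.
#'
#' @param height Standing height (m).
#' @param shoulder_width Lateral trunk diameter at the shoulders (m).
#' @param chest_depth Front-to-back trunk diameter (m).
#' @param head_forward_offset Ventral offset of the head centre (m).
#' @return List of class `"body_model"`.
#' @export
body_model <- function(height = 1.742, shoulder_width = 0.45,
                       chest_depth = 0.26, head_forward_offset = 0.04) {
  stopifnot(height > 0, shoulder_width > chest_depth)
  r_head <- 0.095
  structure(list(
    height = height, shoulder_width = shoulder_width,
    chest_depth = chest_depth, head_forward_offset = head_forward_offset,
    r_head = r_head,
    # primitives in the body-local frame
    legs = list(a = 0.45 * chest_depth / 2, b = 0.45 * shoulder_width / 2,
                z0 = 0.05 * height, z1 = 0.50 * height),
    torso = list(a = chest_depth / 2, b = shoulder_width / 2,
                 z0 = 0.50 * height, z1 = height - 2 * r_head),
    head = list(cx = head_forward_offset, cz = height - r_head - 0.01, r = r_head)
  ), class = "body_model")
}

# Per-camera ray-direction cache: world-frame direction d with camera-frame
# z component 1, so the ray parameter equals the measured depth.
.ray_cache <- new.env(parent = emptyenv())

.camera_rays <- function(cam) {
  key <- paste(c(cam$position, cam$yaw_deg, cam$pitch_deg, cam$fx, cam$width),
               collapse = "_")
  if (!is.null(.ray_cache[[key]])) return(.ray_cache[[key]])
  u <- matrix(0:(cam$width - 1L), cam$height, cam$width, byrow = TRUE)
  v <- matrix(0:(cam$height - 1L), cam$height, cam$width)
  dx <- (u - cam$cx) / cam$fx
  dy <- (v - cam$cy) / cam$fy
  rays <- list(
    Dx = cam$R[1, 1] * dx + cam$R[1, 2] * dy + cam$R[1, 3],
    Dy = cam$R[2, 1] * dx + cam$R[2, 2] * dy + cam$R[2, 3],
    Dz = cam$R[3, 1] * dx + cam$R[3, 2] * dy + cam$R[3, 3]
  )
  .ray_cache[[key]] <- rays
  rays
}

# entering intersection of rays with an elliptic cylinder segment
.ray_cylinder <- function(ox, oy, oz, dx, dy, dz, a, b, z0, z1) {
  qa <- dx^2 / a^2 + dy^2 / b^2
  qb <- 2 * (ox * dx / a^2 + oy * dy / b^2)
  qc <- ox^2 / a^2 + oy^2 / b^2 - 1
  disc <- qb^2 - 4 * qa * qc
  t <- rep(Inf, length(dx))
  ok <- disc > 0 & qa > 0
  tt <- (-qb[ok] - sqrt(disc[ok])) / (2 * qa[ok])
  zz <- oz + tt * dz[ok]
  good <- tt > 0 & zz >= z0 & zz <= z1
  t[ok][good] <- tt[good]
  t
}

.ray_sphere <- function(ox, oy, oz, dx, dy, dz, cx, cy, cz, r) {
  ox <- ox - cx; oy <- oy - cy; oz <- oz - cz
  qa <- dx^2 + dy^2 + dz^2
  qb <- 2 * (ox * dx + oy * dy + oz * dz)
  qc <- ox^2 + oy^2 + oz^2 - r^2
  disc <- qb^2 - 4 * qa * qc
  t <- rep(Inf, length(dx))
  ok <- disc > 0
  tt <- (-qb[ok] - sqrt(disc[ok])) / (2 * qa[ok])
  t[ok][tt > 0] <- tt[tt > 0]
  t
}

#' Render one synthetic depth frame
#'
#' Ray-casts the body primitives (leg and torso elliptic cylinders, head
#' sphere) at full pixel resolution over the analytic floor image, adds
#' range-dependent depth noise `sigma(z) = noise_coef * z^2` to the body
#' pixels, and invalidates measurements beyond the camera range. The set of
#' pixels where the body is visible is returned as the ground-truth
#' silhouette.
#'
#' @param body A `"body_model"`, or `NULL` for a floor-only frame.
#' @param pose Length-3 numeric: `x`, `y` (m, world) and `heading` (degrees,
#'   CCW from the world x-axis).
#' @param cam A `"depth_camera"`.
#' @param floor_bg Optional precomputed [floor_depth_image()] for `cam`.
#' @param noise_coef Depth noise coefficient (m noise std per m^2 of range).
#' @param clutter Optional list of static boxes, each `c(x, y, wx, wy, h)`
#'   (centre, footprint, height), ray-cast like the body.
#' @return List with `depth` (mm matrix, 0 = invalid) and logical
#'   `silhouette` matrix.
#' @export
render_depth_frame <- function(body, pose, cam, floor_bg = NULL,
                               noise_coef = 0.0019, clutter = NULL) {
  if (is.null(floor_bg)) floor_bg <- floor_depth_image(cam)
  depth <- floor_bg
  sil <- matrix(FALSE, cam$height, cam$width)
  rays <- .camera_rays(cam)

  cast_region <- function(center_xy, radius, z_top, hit_fun, mark_sil, noisy) {
    # pixel bounding box from the projected corners of the object's cylinder
    ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
    corners <- rbind(
      cbind(center_xy[1] + radius * cos(ang), center_xy[2] + radius * sin(ang), 0),
      cbind(center_xy[1] + radius * cos(ang), center_xy[2] + radius * sin(ang), z_top)
    )
    pr <- project_points(cam, corners)
    vis <- pr$z > 0.05
    if (!any(vis)) return(invisible())
    u0 <- max(0L, min(pr$u[vis]) - 2L); u1 <- min(cam$width - 1L, max(pr$u[vis]) + 2L)
    v0 <- max(0L, min(pr$v[vis]) - 2L); v1 <- min(cam$height - 1L, max(pr$v[vis]) + 2L)
    if (u1 < u0 || v1 < v0) return(invisible())
    rr <- (v0 + 1L):(v1 + 1L); cc <- (u0 + 1L):(u1 + 1L)
    idx <- rep(rr, length(cc)) + cam$height * rep(cc - 1L, each = length(rr))
    t <- hit_fun(rays$Dx[idx], rays$Dy[idx], rays$Dz[idx])
    hit <- is.finite(t) & t >= cam$range_m[1] & t <= cam$range_m[2]
    if (!any(hit)) return(invisible())
    z <- t[hit]
    if (noisy && noise_coef > 0) z <- z + rnorm(length(z), 0, noise_coef * z^2)
    hidx <- idx[hit]
    zmm <- z * 1000
    cur <- depth[hidx]
    win <- cur == 0 | zmm < cur
    depth[hidx[win]] <<- zmm[win]
    if (mark_sil) sil[hidx[win]] <<- TRUE
    invisible()
  }

  C <- cam$position
  if (!is.null(clutter)) {
    for (b in clutter) {
      bx <- b[1]; by <- b[2]; wx <- b[3]; wy <- b[4]; hz <- b[5]
      cast_region(c(bx, by), sqrt(wx^2 + wy^2) / 2, hz, function(dx, dy, dz) {
        # box as the intersection of slabs (axis-aligned)
        ox <- C[1] - bx; oy <- C[2] - by; oz <- C[3]
        .ray_box(ox, oy, oz, dx, dy, dz, wx / 2, wy / 2, 0, hz)
      }, mark_sil = FALSE, noisy = TRUE)
    }
  }
  if (!is.null(body)) {
    h <- pose[3] * pi / 180
    ch <- cos(h); sh <- sin(h)
    # camera origin and ray directions in the body-local frame
    oxw <- C[1] - pose[1]; oyw <- C[2] - pose[2]
    ox <- ch * oxw + sh * oyw
    oy <- -sh * oxw + ch * oyw
    oz <- C[3]
    radius <- max(body$torso$b, body$head$r + abs(body$head$cx)) + 0.02
    cast_region(c(pose[1], pose[2]), radius, body$height, function(dx, dy, dz) {
      bx <- ch * dx + sh * dy
      by <- -sh * dx + ch * dy
      .cast_body(c(ox, oy, oz), bx, by, dz,
                 c(body$legs$a, body$legs$b, body$legs$z0, body$legs$z1),
                 c(body$torso$a, body$torso$b, body$torso$z0, body$torso$z1),
                 c(body$head$cx, body$head$cz, body$head$r))
    }, mark_sil = TRUE, noisy = TRUE)
  }
  list(depth = depth, silhouette = sil)
}

# slab-method ray/axis-aligned-box intersection (body-local axes)
.ray_box <- function(ox, oy, oz, dx, dy, dz, hx, hy, z0, z1) {
  n <- length(dx)
  tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
  slab <- function(o, d, lo, hi, tmin, tmax) {
    t1 <- (lo - o) / d; t2 <- (hi - o) / d
    lo_t <- pmin(t1, t2); hi_t <- pmax(t1, t2)
    list(tmin = pmax(tmin, lo_t), tmax = pmin(tmax, hi_t))
  }
  s <- slab(ox, dx, -hx, hx, tmin, tmax)
  s <- slab(oy, dy, -hy, hy, s$tmin, s$tmax)
  s <- slab(oz, dz, z0, z1, s$tmin, s$tmax)
  t <- rep(Inf, n)
  ok <- s$tmax >= s$tmin & s$tmin > 0
  t[ok] <- s$tmin[ok]
  t
}

# Simulation configuration -----------------------------------------------------

#' Configuration of the synthetic replication
#'
#' Defaults reproduce the stated study conditions: two cameras at 2.25 m with
#' 25 degree pitch covering an 8 x 5 m area, 100 Hz MARG sampling, 3 s stops,
#' mount offset 0 for Position1 and uniform 50-60 degrees (clockwise, toward
#' the front of the body) for Position2.
#'
#' @param cameras List of `"depth_camera"` objects.
#' @param north_deg World heading of magnetic North (degrees).
#' @param mag_dip_deg Geomagnetic inclination (degrees below horizontal).
#' @param fps Tracker frame rate (Hz).
#' @param imu_rate IMU sampling rate (Hz).
#' @param walk_speed Walking speed between markers (m/s).
#' @param turn_rate On-the-spot turning rate (deg/s).
#' @param stop_duration Stop duration at each marker (s).
#' @param depth_noise_coef Depth noise std coefficient (m per m^2).
#' @param accel_noise,gyro_noise,mag_noise Per-axis measurement noise std
#'   (m/s^2, rad/s, relative units).
#' @param gyro_bias_sd Std of the constant per-axis gyro bias (rad/s).
#' @param mount_tilt_sd Std of the small random mounting tilt (deg).
#' @param pos_jitter_sd,heading_jitter_sd Participant stop placement jitter
#'   (m, deg).
#' @param mount_offset_range Position2 mount rotation range (deg, clockwise).
#' @param cell Plan-view cell size (m).
#' @param height_cutoff Plan-view height cut-off (m).
#' @param surface_offset Radial shift (m) applied to back-projected
#'   foreground points away from the camera, compensating the fact that a
#'   depth sensor sees only the camera-facing body surface (about half a
#'   torso depth).
#' @param n_particles Particles per track.
#' @param seed Base seed; all randomness derives from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(cameras = NULL, north_deg = 0, mag_dip_deg = 67,
                       fps = 15, imu_rate = 100,
                       walk_speed = 1.0, turn_rate = 120, stop_duration = 3,
                       depth_noise_coef = 0.0019,
                       accel_noise = 0.05, gyro_noise = 0.005,
                       mag_noise = 0.01, gyro_bias_sd = 0.002,
                       mount_tilt_sd = 2,
                       pos_jitter_sd = 0.05, heading_jitter_sd = 3,
                       mount_offset_range = c(50, 60),
                       cell = 0.05, height_cutoff = 1.0, surface_offset = 0.10,
                       n_particles = 300L, seed = 1L) {
  if (is.null(cameras)) {
    cameras <- list(
      depth_camera(position = c(-2, 3, 2.25), yaw_deg = 0),
      depth_camera(position = c(10, 2, 2.25), yaw_deg = 180)
    )
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Marker layout and walk scripts of the stop-point protocol
#'
#' Twelve numbered reference poses on the 0.5 m grid of the 8 x 5 m area,
#' split over two walks (one starting from the left side, one from the
#' right); three physical markers are revisited in the second walk under a
#' new number, matching the published reference table.
#'
#' @return Tibble with columns `walk` ("L"/"R"), `point_id`, `x`, `y`
#'   (m, world), `heading` (deg) and the walk start positions as attribute
#'   `starts`.
#' @export
fog_walk_scripts <- function() {
  pts <- tibble::tribble(
    ~walk, ~point_id, ~x, ~y, ~heading,
    "L", 1L, 2.25, 1.75, 270,
    "L", 2L, 3.25, 1.75, 0,
    "L", 3L, 5.75, 3.00, 30,
    "L", 4L, 3.25, 4.25, 180,
    "L", 5L, 1.25, 4.25, 225,
    "L", 6L, 1.75, 2.75, 330,
    "R", 7L, 6.25, 1.75, 270,
    "R", 8L, 4.75, 1.75, 180,
    "R", 9L, 1.75, 2.75, 150,
    "R", 10L, 1.25, 4.25, 45,
    "R", 11L, 3.25, 4.25, 0,
    "R", 12L, 6.75, 2.25, 330
  )
  attr(pts, "starts") <- list(L = c(0.75, 0.25), R = c(7.75, 0.25))
  pts
}

#' Instantiate one walk for one participant
#'
#' Adds the participant's stop placement jitter (people stop near, not on,
#' the marker) and heading jitter to the nominal script.
#'
#' @param script Rows of [fog_walk_scripts()] for one walk.
#' @param start Walk start position (length-2).
#' @param config A `"sim_config"`.
#' @return Tibble with nominal (`ref_*`) and actual (`x`, `y`, `heading`)
#'   stop poses.
#' @keywords internal
instantiate_walk <- function(script, start, config) {
  n <- nrow(script)
  tibble(
    point_id = script$point_id,
    ref_x = script$x, ref_y = script$y, ref_heading = script$heading,
    x = script$x + rnorm(n, 0, config$pos_jitter_sd),
    y = script$y + rnorm(n, 0, config$pos_jitter_sd),
    heading = wrap_heading(script$heading + rnorm(n, 0, config$heading_jitter_sd)),
    start_x = start[1], start_y = start[2]
  )
}

#' Simulate the ground-truth trajectory of one walk
#'
#' The participant walks straight legs between stops at constant speed,
#' turning on the spot (at `turn_rate`) to the marked orientation at each
#' stop and back toward the next leg, and stands still for `stop_duration`
#' at every marker.
#'
#' @param walk Output of `instantiate_walk()`.
#' @param config A `"sim_config"`.
#' @return List with `traj` (tibble `t, x, y, heading, speed, phase,
#'   point_id` at the IMU rate) and `stops` (truth table rows with
#'   `t_start`, `t_end`).
#' @export
simulate_trajectory <- function(walk, config) {
  dt <- 1 / config$imu_rate
  keys <- list()  # keyframes: t, x, y, h (unwrapped)
  pos <- c(walk$start_x[1], walk$start_y[1])
  leg0 <- c(walk$x[1] - pos[1], walk$y[1] - pos[2])
  h <- heading_of(leg0[1], leg0[2])
  tt <- 0
  add <- function(t, x, y, h, phase, pid) {
    keys[[length(keys) + 1L]] <<- c(t, x, y, h, phase, pid)
  }
  add(0, pos[1], pos[2], h, 0, NA)
  stops <- list()
  n <- nrow(walk)
  for (i in seq_len(n)) {
    tgt <- c(walk$x[i], walk$y[i])
    d <- sqrt(sum((tgt - pos)^2))
    bear <- heading_of(tgt[1] - pos[1], tgt[2] - pos[2])
    # turn toward the leg (no-op on the first leg)
    dh <- signed_angle_diff(bear, wrap_heading(h))
    if (abs(dh) > 1e-6) {
      tt <- tt + abs(dh) / config$turn_rate
      h <- h + dh
      add(tt, pos[1], pos[2], h, 1, NA)
    }
    if (d > 1e-9) {
      tt <- tt + d / config$walk_speed
      pos <- tgt
      add(tt, pos[1], pos[2], h, 2, NA)
    }
    # turn to the marked stop orientation
    dh <- signed_angle_diff(walk$heading[i], wrap_heading(h))
    if (abs(dh) > 1e-6) {
      tt <- tt + abs(dh) / config$turn_rate
      h <- h + dh
      add(tt, pos[1], pos[2], h, 1, NA)
    }
    t0 <- tt
    tt <- tt + config$stop_duration
    add(tt, pos[1], pos[2], h, 3, walk$point_id[i])
    stops[[i]] <- tibble(
      point_id = walk$point_id[i], t_start = t0, t_end = tt,
      x = pos[1], y = pos[2], heading = wrap_heading(h),
      ref_x = walk$ref_x[i], ref_y = walk$ref_y[i],
      ref_heading = walk$ref_heading[i]
    )
  }
  K <- do.call(rbind, keys)
  times <- seq(0, tt, by = dt)
  x <- stats::approx(K[, 1], K[, 2], times, rule = 2)$y
  y <- stats::approx(K[, 1], K[, 3], times, rule = 2)$y
  hh <- stats::approx(K[, 1], K[, 4], times, rule = 2)$y
  # phase of the segment ending at the next keyframe
  seg <- pmin(findInterval(times, K[, 1], left.open = TRUE) + 1L, nrow(K))
  phase <- c("start", "turn", "walk", "stop")[K[seg, 5] + 1L]
  pid <- K[seg, 6]
  spd <- c(sqrt(diff(x)^2 + diff(y)^2) / dt, 0)
  list(
    traj = tibble(t = times, x = x, y = y, heading = wrap_heading(hh),
                  heading_unwrapped = hh, speed = spd, phase = phase,
                  point_id = as.integer(pid)),
    stops = dplyr::bind_rows(stops)
  )
}

#' Simulate a 100 Hz MARG stream for a walked trajectory
#'
#' The device is worn at the waist with its x-axis up, y-axis along the
#' wearer's forward (dorsoventral) axis and z-axis pointing left, rotated
#' clockwise (viewed from above) by `mount_offset_deg` about the body
#' vertical axis, with a small random mounting tilt. The accelerometer sees
#' gravity plus trajectory acceleration plus a step-frequency bounce while
#' walking; the gyroscope sees the turning rate plus noise and a constant
#' bias; the magnetometer sees the Earth field direction.
#'
#' @param traj Trajectory tibble from [simulate_trajectory()].
#' @param mount_offset_deg Clockwise device rotation about the body vertical
#'   axis (deg); 0 for the expected mounting.
#' @param config A `"sim_config"`.
#' @return Tibble `t, gx, gy, gz, ax, ay, az, mx, my, mz` plus attribute
#'   `mount_offset_deg`.
#' @export
simulate_imu <- function(traj, mount_offset_deg = 0, config = sim_config()) {
  dt <- 1 / config$imu_rate
  n <- nrow(traj)
  g <- 9.81
  # smoothed velocities -> linear acceleration (moving-average over 0.2 s)
  k <- 21
  sm <- function(v) as.numeric(stats::filter(v, rep(1 / k, k), sides = 2)) |>
    (\(z) { z[is.na(z)] <- v[is.na(z)]; z })()
  vx <- sm(c(diff(traj$x), 0) / dt)
  vy <- sm(c(diff(traj$y), 0) / dt)
  axl <- c(diff(vx), 0) / dt
  ayl <- c(diff(vy), 0) / dt
  hr <- traj$heading_unwrapped * pi / 180
  omega <- sm(c(diff(hr), 0) / dt)
  walking <- traj$speed > 0.2
  step_f <- 1.9
  bob_v <- 1.5 * sin(2 * pi * step_f * traj$t) * walking
  bob_f <- 0.8 * sin(2 * pi * step_f * traj$t + pi / 3) * walking
  fwd_x <- cos(hr); fwd_y <- sin(hr)
  fx_w <- axl + bob_f * fwd_x
  fy_w <- ayl + bob_f * fwd_y
  fz_w <- g + bob_v
  # device yaw (clockwise mount offset reduces the CCW heading)
  thd <- hr - mount_offset_deg * pi / 180
  # mounting tilt: small fixed rotation applied in the device frame
  tilt <- quat_mul(
    quat_from_axis_angle(c(0, 1, 0), rnorm(1, 0, config$mount_tilt_sd)),
    quat_from_axis_angle(c(0, 0, 1), rnorm(1, 0, config$mount_tilt_sd))
  )
  Rt <- quat_to_matrix(quat_normalize(tilt))
  ct <- cos(thd); st <- sin(thd)
  # ideal device axes in world: x up, y forward(thd), z left
  # R_dw = [x_dev | y_dev | z_dev]; measured = Rt' %*% R_dw' %*% world
  mag_w <- c(cos(config$mag_dip_deg * pi / 180), 0, -sin(config$mag_dip_deg * pi / 180))
  nd <- config$north_deg * pi / 180
  mag_w <- c(cos(nd) * mag_w[1], sin(nd) * mag_w[1], mag_w[3])
  dev <- function(wx, wy, wz) {
    # world -> ideal device frame (rows of R_dw')
    dx <- wz
    dy <- ct * wx + st * wy
    dz <- -st * wx + ct * wy
    cbind(dx, dy, dz) %*% Rt  # then into the tilted frame: Rt' %*% v, as rows
  }
  Fd <- dev(fx_w, fy_w, fz_w)
  # gyro: world rate (0,0,omega) seen in the device frame
  Gd <- dev(0, 0, omega)
  Md <- dev(rep(mag_w[1], n), rep(mag_w[2], n), rep(mag_w[3], n))
  bias <- rnorm(3, 0, config$gyro_bias_sd)
  out <- tibble(
    t = traj$t,
    gx = Gd[, 1] + bias[1] + rnorm(n, 0, config$gyro_noise),
    gy = Gd[, 2] + bias[2] + rnorm(n, 0, config$gyro_noise),
    gz = Gd[, 3] + bias[3] + rnorm(n, 0, config$gyro_noise),
    ax = Fd[, 1] + rnorm(n, 0, config$accel_noise),
    ay = Fd[, 2] + rnorm(n, 0, config$accel_noise),
    az = Fd[, 3] + rnorm(n, 0, config$accel_noise),
    mx = Md[, 1] + rnorm(n, 0, config$mag_noise),
    my = Md[, 2] + rnorm(n, 0, config$mag_noise),
    mz = Md[, 3] + rnorm(n, 0, config$mag_noise)
  )
  attr(out, "mount_offset_deg") <- mount_offset_deg
  out
}

#' Generate the full synthetic experiment
#'
#' Replicates the stop-point protocol: `n_participants` simulated
#' participants (heights drawn from Normal(1.742, 0.088) m), each walking the
#' left-start and right-start scripts once per sensor-mount condition
#' (Position1: expected mounting; Position2: mount rotated 50-60 degrees),
#' yielding `n_participants x 12 x 2` ground-truth stop events.
#'
#' @param n_participants Number of simulated participants.
#' @param config A `"sim_config"`; `config$seed` drives all randomness.
#' @param conditions Character subset of `c("Position1", "Position2")`.
#' @return List of class `"fog_experiment"`: `participants` (tibble of body
#'   parameters), `runs` (tibble, one row per participant x condition x walk
#'   with list-columns `traj` and `imu`), `truth` (stop table) and `config`.
#' @export
generate_experiment <- function(n_participants = 12,
                                config = sim_config(),
                                conditions = c("Position1", "Position2")) {
  stopifnot(n_participants >= 1)
  scripts <- fog_walk_scripts()
  starts <- attr(scripts, "starts")
  set.seed(config$seed)
  participants <- tibble(
    participant = seq_len(n_participants),
    height = pmin(pmax(rnorm(n_participants, 1.742, 0.088), 1.45), 2.05),
    shoulder_width = rnorm(n_participants, 0.45, 0.02),
    chest_depth = rnorm(n_participants, 0.26, 0.015),
    mount_offset_p2 = runif(n_participants, config$mount_offset_range[1],
                            config$mount_offset_range[2])
  )
  runs <- list(); truth <- list()
  for (p in seq_len(n_participants)) {
    for (cond in conditions) {
      offset <- if (cond == "Position1") 0 else participants$mount_offset_p2[p]
      for (wk in c("L", "R")) {
        run_seed <- config$seed + 7919L * p + 101L * (cond == "Position2") + 11L * (wk == "R")
        set.seed(run_seed)
        inst <- instantiate_walk(scripts[scripts$walk == wk, ], starts[[wk]], config)
        sim <- simulate_trajectory(inst, config)
        imu <- simulate_imu(sim$traj, offset, config)
        runs[[length(runs) + 1L]] <- tibble(
          participant = p, condition = cond, walk = wk,
          mount_offset = offset, run_seed = run_seed,
          traj = list(sim$traj), imu = list(imu)
        )
        truth[[length(truth) + 1L]] <- dplyr::mutate(
          sim$stops, participant = p, condition = cond, walk = wk,
          .before = 1
        )
      }
    }
  }
  structure(list(
    participants = participants,
    runs = dplyr::bind_rows(runs),
    truth = dplyr::bind_rows(truth),
    config = config
  ), class = "fog_experiment")
}

# Depth frame I/O --------------------------------------------------------------

#' Write / read a depth frame as a 16-bit PGM raster
#'
#' @param depth Numeric matrix of depths in mm (0 = invalid).
#' @param path File path.
#' @param ascii Write plain-text (P2) instead of binary (P5) PGM.
#' @return `read_depth_pgm()` returns the depth matrix (mm).
#' @export
write_depth_pgm <- function(depth, path, ascii = FALSE) {
  d <- round(pmin(pmax(depth, 0), 65535))
  h <- nrow(d); w <- ncol(d)
  if (ascii) {
    con <- file(path, "w")
    writeLines(c("P2", paste(w, h), "65535"), con)
    write(t(d), con, ncolumns = w)
    close(con)
  } else {
    con <- file(path, "wb")
    writeLines(c("P5", paste(w, h), "65535"), con)
    writeBin(as.integer(t(d)), con, size = 2, endian = "big")
    close(con)
  }
  invisible(path)
}

#' @rdname write_depth_pgm
#' @export
read_depth_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  dims <- scan(text = readLines(con, 1), quiet = TRUE)
  maxv <- scan(text = readLines(con, 1), quiet = TRUE)
  w <- dims[1]; h <- dims[2]
  if (magic == "P5") {
    vals <- readBin(con, "integer", n = w * h, size = 2, signed = FALSE, endian = "big")
  } else if (magic == "P2") {
    vals <- scan(con, quiet = TRUE)
  } else stop("not a PGM file", call. = FALSE)
  matrix(vals, h, w, byrow = TRUE)
}
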