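#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif sd setNames coef lm median
NULL

# Orientation filters --------------------------------------------------------
#
# Both filters carry a unit quaternion q (device -> world) and advance it by
# numerical integration of the gyroscope rate, corrected by one normalized
# gradient-descent step toward the orientation implied by the reference
# vector(s): gravity alone (GROE, yaw unobservable) or gravity plus the
# Earth's magnetic field (AOE, absolute).
#
# World frame conventions: z up (gravity reference +z for the specific
# force), x along the horizontal component of magnetic North, y completing a
# right-handed triad (90 deg counterclockwise from North viewed from above).

# predicted gravity direction error and its gradient (shared by both filters)
.grav_terms <- function(q, a) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  f1 <- 2 * (x * z - w * y) - a[1]
  f2 <- 2 * (w * x + y * z) - a[2]
  f3 <- 1 - 2 * (x * x + y * y) - a[3]
  c(-2 * y * f1 + 2 * x * f2,
    2 * z * f1 + 2 * w * f2 - 4 * x * f3,
    -2 * w * f1 + 2 * z * f2 - 4 * y * f3,
    2 * x * f1 + 2 * y * f2)
}

.gyro_qdot <- function(q, g) {
  0.5 * c(
    -q[2] * g[1] - q[3] * g[2] - q[4] * g[3],
    q[1] * g[1] + q[3] * g[3] - q[4] * g[2],
    q[1] * g[2] - q[2] * g[3] + q[4] * g[1],
    q[1] * g[3] + q[2] * g[2] - q[3] * g[1]
  )
}

.groe_update <- function(q, gyr, acc, beta, dt) {
  qdot <- .gyro_qdot(q, gyr)
  an <- sqrt(sum(acc^2))
  if (an > 0) {
    s <- .grav_terms(q, acc / an)
    sn <- sqrt(sum(s^2))
    if (sn > 1e-12) qdot <- qdot - beta * s / sn
  }
  q <- q + qdot * dt
  q / sqrt(sum(q^2))
}

.aoe_update <- function(q, gyr, acc, mag, beta, dt) {
  qdot <- .gyro_qdot(q, gyr)
  an <- sqrt(sum(acc^2))
  mn <- sqrt(sum(mag^2))
  if (an > 0 && mn > 0) {
    a <- acc / an
    m <- mag / mn
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    s <- .grav_terms(q, a)
    # Earth field reference (bx, 0, bz) from the measurement rotated to world
    hx <- m[1] * (1 - 2 * (y * y + z * z)) + m[2] * 2 * (x * y - w * z) + m[3] * 2 * (x * z + w * y)
    hy <- m[1] * 2 * (x * y + w * z) + m[2] * (1 - 2 * (x * x + z * z)) + m[3] * 2 * (y * z - w * x)
    hz <- m[1] * 2 * (x * z - w * y) + m[2] * 2 * (y * z + w * x) + m[3] * (1 - 2 * (x * x + y * y))
    bx <- sqrt(hx * hx + hy * hy)
    bz <- hz
    f4 <- 2 * bx * (0.5 - y * y - z * z) + 2 * bz * (x * z - w * y) - m[1]
    f5 <- 2 * bx * (x * y - w * z) + 2 * bz * (w * x + y * z) - m[2]
    f6 <- 2 * bx * (w * y + x * z) + 2 * bz * (0.5 - x * x - y * y) - m[3]
    s <- s + c(
      -2 * bz * y * f4 + (-2 * bx * z + 2 * bz * x) * f5 + 2 * bx * y * f6,
      2 * bz * z * f4 + (2 * bx * y + 2 * bz * w) * f5 + (2 * bx * z - 4 * bz * x) * f6,
      (-4 * bx * y - 2 * bz * w) * f4 + (2 * bx * x + 2 * bz * z) * f5 + (2 * bx * w - 4 * bz * y) * f6,
      (-4 * bx * z + 2 * bz * x) * f4 + (-2 * bx * w + 2 * bz * y) * f5 + 2 * bx * x * f6
    )
    sn <- sqrt(sum(s^2))
    if (sn > 1e-12) qdot <- qdot - beta * s / sn
  }
  q <- q + qdot * dt
  q / sqrt(sum(q^2))
}

#' Single step of the gravity-relative orientation filter (GROE)
#'
#' Advances a device-to-world orientation estimate by one IMU sample:
#' gyroscope integration plus one normalized gradient-descent correction
#' toward the accelerometer-implied gravity direction. The yaw component is
#' unconstrained (gauge freedom); only tilt is observable.
#'
#' @param est List with unit quaternion `q` (w, x, y, z) and time `t` (s).
#' @param sample One IMU sample: list/row with `t` (s), `gx, gy, gz`
#'   (rad/s, device frame) and `ax, ay, az` (specific force, m/s^2).
#' @param beta Filter gain (rad/s); default 0.1.
#' @return Updated estimate, a list with `q` and `t`.
#' @export
groe_step <- function(est, sample, beta = 0.1) {
  dt <- sample$t - est$t
  if (!is.finite(dt) || dt <= 0) stop("sample time must advance (dt > 0)", call. = FALSE)
  q <- .groe_update(est$q, c(sample$gx, sample$gy, sample$gz),
                    c(sample$ax, sample$ay, sample$az), beta, dt)
  list(q = structure(q, class = "quat"), t = sample$t)
}

#' Single step of the absolute orientation filter (AOE)
#'
#' MARG (gyroscope + accelerometer + magnetometer) variant: the
#' gradient-descent correction uses gravity and the Earth's magnetic field
#' jointly, so the full 3D orientation toward the gravity / magnetic-North
#' world frame is observable.
#'
#' @inheritParams groe_step
#' @param sample As for [groe_step()] plus `mx, my, mz` (magnetic field,
#'   any consistent units; normalized internally).
#' @param beta Filter gain (rad/s); default 0.041.
#' @return Updated estimate, a list with `q` and `t`.
#' @export
aoe_step <- function(est, sample, beta = 0.041) {
  dt <- sample$t - est$t
  if (!is.finite(dt) || dt <= 0) stop("sample time must advance (dt > 0)", call. = FALSE)
  m <- c(sample$mx, sample$my, sample$mz)
  if (any(is.na(m)) || sum(m^2) == 0) {
    stop("sample has no magnetic field; use groe_step() for IMU-only streams",
         call. = FALSE)
  }
  q <- .aoe_update(est$q, c(sample$gx, sample$gy, sample$gz),
                   c(sample$ax, sample$ay, sample$az), m, beta, dt)
  list(q = structure(q, class = "quat"), t = sample$t)
}

#' Run an orientation filter over a whole IMU/MARG stream
#'
#' @param imu Tibble of samples with columns `t, gx, gy, gz, ax, ay, az` and,
#'   for `method = "aoe"`, `mx, my, mz`. `t` must be strictly increasing.
#' @param method `"groe"` or `"aoe"`.
#' @param beta Filter gain; defaults 0.1 (GROE) / 0.041 (AOE).
#' @param q0 Initial quaternion (device -> world); identity by default.
#' @return Tibble with columns `t, qw, qx, qy, qz`, one row per sample.
#' @export
run_orientation_filter <- function(imu, method = c("groe", "aoe"), beta = NULL,
                                   q0 = c(1, 0, 0, 0)) {
  method <- match.arg(method)
  if (is.null(beta)) beta <- if (method == "groe") 0.1 else 0.041
  t <- imu$t
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  n <- length(t)
  G <- cbind(imu$gx, imu$gy, imu$gz)
  A <- cbind(imu$ax, imu$ay, imu$az)
  use_mag <- method == "aoe"
  if (use_mag) {
    if (is.null(imu$mx) || anyNA(imu$mx)) {
      stop("AOE requires magnetometer columns mx, my, mz", call. = FALSE)
    }
    M <- cbind(imu$mx, imu$my, imu$mz)
  }
  Q <- matrix(NA_real_, n, 4)
  q <- q0 / sqrt(sum(q0^2))
  tp <- t[1] - (if (n > 1) t[2] - t[1] else 0.01)
  for (i in seq_len(n)) {
    dt <- t[i] - tp
    q <- if (use_mag) {
      .aoe_update(q, G[i, ], A[i, ], M[i, ], beta, dt)
    } else {
      .groe_update(q, G[i, ], A[i, ], beta, dt)
    }
    Q[i, ] <- q
    tp <- t[i]
  }
  tibble(t = t, qw = Q[, 1], qx = Q[, 2], qy = Q[, 3], qz = Q[, 4])
}

# Floor-plane axis projection -------------------------------------------------

#' Project the device y and z axes onto the floor plane
#'
#' Expresses the device axes in the filter's world frame, projects them
#' orthogonally onto the horizontal (floor) plane and normalizes. `theta_i`
#' is the heading of the projected y-axis, counterclockwise from the world
#' (or supplied tracking-frame) x-axis.
#'
#' @param est Orientation estimate (list with unit quaternion `q`), e.g. from
#'   [run_orientation_filter()] rows via [orientation_at()].
#' @param frame Optional `"tracking_frame"`, accepted for interface symmetry
#'   and unused in the angle itself: the filter world is gravity-aligned, so
#'   theta_i is measured against the filter world x-axis and callers add the
#'   (frame-dependent) in-plane rotation offset where needed. For the
#'   gravity-relative filter the world x-axis is an arbitrary gauge that the
#'   downstream correction angle absorbs.
#' @return List with unit 3-vectors `y_prime`, `z_prime` (in-plane) and
#'   `theta_i` (degrees, `[0, 360)`).
#' @export
project_device_axes <- function(est, frame = NULL) {
  q <- est$q
  yw <- quat_rotate(q, c(0, 1, 0))
  zw <- quat_rotate(q, c(0, 0, 1))
  hy <- sqrt(yw[1]^2 + yw[2]^2)
  if (hy < sin(5 * pi / 180)) {
    stop("device y-axis within 5 degrees of the floor normal: degenerate projection",
         call. = FALSE)
  }
  yp <- c(yw[1], yw[2], 0) / hy
  hz <- sqrt(zw[1]^2 + zw[2]^2)
  zp <- if (hz > 1e-9) c(zw[1], zw[2], 0) / hz else c(NA_real_, NA_real_, 0)
  list(
    y_prime = yp, z_prime = zp,
    theta_i = heading_of(yp[1], yp[2])
  )
}

#' Device compass heading alpha from an absolute (AOE) orientation
#'
#' The angle between the floor-plane projection of the device y-axis and
#' magnetic North, measured counterclockwise viewed from above, in
#' `[0, 360)`. Requires an absolute (MARG/AOE) orientation estimate, whose
#' world x-axis is magnetic North.
#'
#' @param est Orientation estimate (list with unit quaternion `q`).
#' @return Heading alpha in degrees.
#' @export
device_heading_alpha <- function(est) {
  project_device_axes(est)$theta_i
}

#' Extract the orientation estimate at (or nearest before) a time
#'
#' @param qtbl Output of [run_orientation_filter()].
#' @param t Time in seconds.
#' @return List with `q` (unit quaternion) and `t`.
#' @export
orientation_at <- function(qtbl, t) {
  i <- findInterval(t, qtbl$t)
  i <- max(1L, i)
  list(q = structure(c(qtbl$qw[i], qtbl$qx[i], qtbl$qy[i], qtbl$qz[i]), class = "quat"),
       t = qtbl$t[i])
}

#' Headings of the projected device y-axis for every sample of a filter run
#'
#' Vectorized version of [project_device_axes()] over a quaternion track;
#' samples whose device y-axis is within 5 degrees of vertical yield `NA`.
#'
#' @param qtbl Output of [run_orientation_filter()].
#' @return Numeric vector of headings (degrees, `[0, 360)`), one per row.
#' @export
projected_heading_track <- function(qtbl) {
  w <- qtbl$qw; x <- qtbl$qx; y <- qtbl$qy; z <- qtbl$qz
  # world components of the device y-axis: R %*% (0,1,0) = second column of R
  yx <- 2 * (x * y - w * z)
  yy <- 1 - 2 * (x * x + z * z)
  yz <- 2 * (y * z + w * x)
  h <- sqrt(yx^2 + yy^2)
  out <- wrap_heading(atan2(yy, yx) * 180 / pi)
  out[h < sin(5 * pi / 180)] <- NA_real_
  out
}

# IMU stream I/O ---------------------------------------------------------------

#' Read / write IMU sample streams as CSV
#'
#' Columns: `t` (s), `gx, gy, gz` (rad/s), `ax, ay, az` (m/s^2) and optional
#' `mx, my, mz` (normalized magnetic field; empty for IMU-only streams).
#'
#' @param path File path.
#' @param imu Tibble of samples.
#' @return `read_imu_csv()` returns a tibble.
#' @export
read_imu_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_imu_csv
#' @export
write_imu_csv <- function(imu, path) {
  readr::write_csv(imu, path)
  invisible(path)
}
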