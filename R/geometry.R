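#' Wrap a heading angle into [0, 360)
#'
#' All headings in fogtrack are measured in degrees, counterclockwise when the
#' floor is viewed from above, from the x-axis of the relevant reference frame
#' (tracking frame, world frame, or magnetic North for compass angles).
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector with each element reduced modulo 360 into `[0, 360)`.
#' @examples
#' wrap_heading(c(370, -90, 360))
#' @export
wrap_heading <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric", call. = FALSE)
  }
  angle %% 360
}

#' Minimal signed difference between two headings
#'
#' Computes `a - b` wrapped into the half-open interval `(-180, 180]`; the
#' antipodal case returns +180.
#'
#' @param a,b Numeric vectors of headings in degrees (recycled).
#' @return Signed angular difference in degrees, in `(-180, 180]`.
#' @examples
#' signed_angle_diff(10, 350)   # 20
#' signed_angle_diff(0, 180)    # 180
#' @export
signed_angle_diff <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("headings must be finite", call. = FALSE)
  }
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# ---- quaternions ------------------------------------------------------------
# A quaternion is a plain numeric length-4 vector c(w, x, y, z). The scalar
# part comes first; the identity is c(1, 0, 0, 0). Device-to-world orientation
# quaternions rotate device-frame vectors into the world frame via
# v_w = q (0,v) q*.

#' Construct a quaternion
#'
#' @param w,x,y,z Components; scalar part first.
#' @param normalize If `TRUE` (default) the result is scaled to unit norm.
#' @return Numeric vector of length 4 with class `"quat"`.
#' @export
quat <- function(w = 1, x = 0, y = 0, z = 0, normalize = TRUE) {
  q <- c(w, x, y, z)
  if (any(!is.finite(q))) stop("quaternion components must be finite", call. = FALSE)
  if (normalize) q <- quat_normalize(q)
  structure(q, class = "quat")
}

#' @rdname quat
#' @param q Numeric length-4 quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-12) stop("cannot normalize zero quaternion", call. = FALSE)
  structure(q / n, class = "quat")
}

#' Quaternion product
#'
#' Hamilton product `a` then `b` applied in the usual composition order:
#' rotating by `quat_mul(a, b)` equals rotating first by `b`, then by `a`.
#'
#' @param a,b Length-4 quaternions.
#' @return Length-4 quaternion (not re-normalized).
#' @export
quat_mul <- function(a, b) {
  structure(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ), class = "quat")
}

#' @rdname quat_mul
#' @param q Length-4 quaternion.
#' @export
quat_conj <- function(q) structure(c(q[1], -q[2], -q[3], -q[4]), class = "quat")

#' Axis-angle quaternion
#'
#' @param axis Length-3 rotation axis (any nonzero length).
#' @param angle_deg Rotation angle in degrees (right-hand rule about `axis`).
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero", call. = FALSE)
  half <- angle_deg * pi / 360
  quat_normalize(c(cos(half), sin(half) * axis / n))
}

#' Rotation matrix of a unit quaternion
#'
#' @param q Unit quaternion (device-to-world).
#' @return 3x3 rotation matrix `R` with `R %*% v_device = v_world`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a 3-vector by a unit quaternion
#'
#' @param q Unit quaternion (norm within 1e-6 of 1).
#' @param v Length-3 vector.
#' @return The rotated vector, same length as `v`.
#' @export
quat_rotate <- function(q, v) {
  if (abs(sqrt(sum(q * q)) - 1) > 1e-6) {
    stop("`q` must be a unit quaternion", call. = FALSE)
  }
  # q (0,v) q* expanded; cheaper than building the matrix
  qv <- c(q[2], q[3], q[4])
  t2 <- 2 * c(
    qv[2] * v[3] - qv[3] * v[2],
    qv[3] * v[1] - qv[1] * v[3],
    qv[1] * v[2] - qv[2] * v[1]
  )
  v + q[1] * t2 + c(
    qv[2] * t2[3] - qv[3] * t2[2],
    qv[3] * t2[1] - qv[1] * t2[3],
    qv[1] * t2[2] - qv[2] * t2[1]
  )
}

# ---- planes and the tracking frame -----------------------------------------

#' Robust floor-plane fit by random-sample consensus
#'
#' Fits the plane `normal . p + offset = 0` to a 3D point cloud by repeated
#' 3-point consensus sampling followed by a least-squares refinement on the
#' inlier set. The normal is oriented toward the camera (assumed at
#' `camera_origin`), i.e. `normal . camera_origin + offset > 0`.
#'
#' @param points Numeric matrix, one 3D point per row (camera image frame, m).
#' @param inlier_tol Inlier distance tolerance in metres.
#' @param min_inlier_frac Minimum fraction of points that must be inliers for
#'   a consensus to be accepted.
#' @param n_iter Number of consensus sampling rounds.
#' @param camera_origin Point the normal is oriented toward.
#' @param seed Integer seed for the sampling (fixed for reproducibility).
#' @return A list of class `"floor_plane"` with elements `normal` (unit
#'   3-vector), `offset` (m) and `inliers` (logical vector).
#' @export
fit_floor_plane <- function(points, inlier_tol = 0.02, min_inlier_frac = 0.5,
                            n_iter = 200, camera_origin = c(0, 0, 0),
                            seed = 1L) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 3) {
    stop("`points` must be an n x 3 matrix with n >= 3", call. = FALSE)
  }
  n <- nrow(points)
  best <- NULL
  best_count <- -1L
  rs <- local({ set.seed(seed); lapply(seq_len(n_iter), function(i) sample.int(n, 3L)) })
  for (idx in rs) {
    p <- points[idx, , drop = FALSE]
    nv <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-10) next  # collinear sample
    nv <- nv / nn
    d <- -sum(nv * p[1, ])
    resid <- abs(points %*% nv + d)
    count <- sum(resid <= inlier_tol)
    if (count > best_count) {
      best_count <- count
      best <- list(normal = nv, offset = d)
    }
  }
  if (is.null(best)) stop("floor plane fit failed: all samples collinear", call. = FALSE)
  if (best_count < min_inlier_frac * n) {
    stop("floor plane fit failed: no consensus above the minimum inlier fraction",
         call. = FALSE)
  }
  inl <- abs(points %*% best$normal + best$offset) <= inlier_tol
  # least-squares refinement: smallest principal direction of the inlier cloud
  pi_ <- points[inl, , drop = FALSE]
  ctr <- colMeans(pi_)
  sv <- svd(sweep(pi_, 2, ctr))
  nv <- sv$v[, 3]
  d <- -sum(nv * ctr)
  if (sum(nv * camera_origin) + d < 0) { nv <- -nv; d <- -d }
  structure(list(normal = as.numeric(nv), offset = as.numeric(d), inliers = as.vector(inl)),
            class = "floor_plane")
}

# cross product helper (kept internal; base R has no cross())
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Construct the 2D tracking frame at the base of the camera
#'
#' The tracking frame sits on the floor plane directly below the camera. Its
#' y-axis is the in-plane projection of the camera's forward (optical) axis,
#' its z-axis is the floor normal oriented toward the camera, and its x-axis
#' completes a right-handed basis (x cross y = z). Headings are measured
#' counterclockwise from the x-axis viewed from above.
#'
#' @param plane A `"floor_plane"` (normal oriented toward the camera).
#' @param camera_origin Camera position, length-3 (m).
#' @param camera_forward Camera optical axis direction in the same frame.
#' @param psi_deg Optional rig calibration angle: heading of the tracking
#'   y-axis measured counterclockwise from magnetic North (degrees).
#' @return A list of class `"tracking_frame"` with `origin`, unit axes
#'   `x_axis`, `y_axis`, `z_axis`, the 3x3 matrix `R` (columns = axes) and
#'   `psi_deg`.
#' @export
make_tracking_frame <- function(plane, camera_origin, camera_forward,
                                psi_deg = NA_real_) {
  n <- plane$normal
  h <- sum(n * camera_origin) + plane$offset
  if (abs(h) < 1e-9) stop("camera origin lies on the floor plane", call. = FALSE)
  origin <- camera_origin - h * n
  fwd <- camera_forward - sum(camera_forward * n) * n
  fn <- sqrt(sum(fwd^2))
  if (fn < 1e-9) {
    stop("camera forward axis is parallel to the floor normal", call. = FALSE)
  }
  y <- fwd / fn
  z <- n
  x <- pracma_cross(y, z)  # x cross y = z for right-handed (x, y, z)
  structure(list(
    origin = as.numeric(origin), x_axis = as.numeric(x), y_axis = as.numeric(y),
    z_axis = as.numeric(z), R = cbind(x, y, z, deparse.level = 0),
    psi_deg = psi_deg
  ), class = "tracking_frame")
}

#' Transform points between the camera and tracking frames
#'
#' `to_tracking()` maps camera-frame points to tracking coordinates, where the
#' third coordinate is the height above the floor; `from_tracking()` is the
#' inverse rigid transform.
#'
#' @param frame A `"tracking_frame"`.
#' @param p Numeric matrix (n x 3) or length-3 vector.
#' @return Matrix/vector of the same shape in the other frame.
#' @export
to_tracking <- function(frame, p) {
  one <- is.null(dim(p))
  p <- rbind(p)
  out <- sweep(p, 2, frame$origin) %*% frame$R
  if (one) out[1, ] else out
}

#' @rdname to_tracking
#' @export
from_tracking <- function(frame, p) {
  one <- is.null(dim(p))
  p <- rbind(p)
  out <- sweep(p %*% t(frame$R), 2, frame$origin, "+")
  if (one) out[1, ] else out
}

#' Read / write a plain-text rig calibration file
#'
#' Key-value format (`key: v1 v2 v3` per line) holding the floor plane, the
#' camera pose and the rig angle psi.
#'
#' @param path File path.
#' @param plane,camera_origin,camera_forward,psi_deg Rig description.
#' @return `read_rig_calibration()` returns a list with the same elements.
#' @export
write_rig_calibration <- function(path, plane, camera_origin, camera_forward,
                                  psi_deg) {
  lines <- c(
    paste("plane_normal:", paste(format(plane$normal, digits = 12), collapse = " ")),
    paste("plane_offset:", format(plane$offset, digits = 12)),
    paste("camera_origin:", paste(format(camera_origin, digits = 12), collapse = " ")),
    paste("camera_forward:", paste(format(camera_forward, digits = 12), collapse = " ")),
    paste("psi_deg:", format(psi_deg, digits = 12))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rig_calibration
#' @export
read_rig_calibration <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- list()
  for (e in kv) {
    key <- trimws(e[[1]])
    out[[key]] <- as.numeric(strsplit(trimws(e[[2]]), "\\s+")[[1]])
  }
  list(
    plane = structure(list(normal = out$plane_normal, offset = out$plane_offset),
                      class = "floor_plane"),
    camera_origin = out$camera_origin,
    camera_forward = out$camera_forward,
    psi_deg = out$psi_deg
  )
}

#' Unit quaternion from a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return Unit quaternion (w, x, y, z) with non-negative scalar part.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Heading of a 2D direction vector
#'
#' @param vx,vy Vector components in the frame of interest.
#' @return Heading in degrees, counterclockwise from the x-axis, in `[0, 360)`.
#' @keywords internal
heading_of <- function(vx, vy) wrap_heading(atan2(vy, vx) * 180 / pi)
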