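# Vision-inertial heading fusion ----------------------------------------------
#
# Method1: absolute device orientation (AOE) plus two static rig angles. The
# device compass heading alpha is corrected for the rig angle psi between
# the camera forward (y_c) axis and magnetic North, and rotated by +90
# degrees because headings are expressed against the tracking x-axis.
# Assumes the device is worn in the predetermined orientation (no offset
# between device y-axis and the wearer's forward axis).
#
# Method2: gravity-relative orientation (GROE) plus an external heading
# reference from the vision system. When the classifier's static heading and
# the track's dynamic heading agree within a bound for several consecutive
# frames, the static heading is confirmed as the external reference theta_s;
# the correction angle delta_c between the inertially projected device-axis
# angle theta_i and theta_s is then subtracted from theta_i on every later
# frame. delta_c absorbs both the unknown mount rotation and the arbitrary
# yaw gauge of the gravity-relative filter.

#' Method1 heading from the device compass angle
#'
#' `theta = wrap(alpha - psi + 90)`: the device heading alpha (degrees CCW
#' from magnetic North) corrected for the rig angle psi (heading of the
#' camera y-axis from North) gives the heading against the camera y-axis;
#' adding 90 degrees re-expresses it against the tracking x-axis.
#'
#' @param alpha Device compass heading (degrees).
#' @param psi Rig calibration angle (degrees).
#' @return Heading theta in the tracking frame (degrees, `[0, 360)`).
#' @export
method1_heading <- function(alpha, psi) {
  wrap_heading(alpha - psi + 90)
}

#' Dynamic heading from track position history
#'
#' Fits least-squares lines to the x(t) and y(t) positions inside the window
#' and returns the heading of the fitted velocity vector, or `NA` when the
#' fitted speed is below the gate (the velocity direction is meaningless
#' when standing).
#'
#' @param t,x,y Position samples (tracking or world frame, m).
#' @param min_speed Speed gate (m/s).
#' @return Heading (degrees, `[0, 360)`) or `NA`.
#' @export
dynamic_heading <- function(t, x, y, min_speed = 0.3) {
  if (length(t) < 2L) return(NA_real_)
  tc <- t - mean(t)
  den <- sum(tc^2)
  if (den <= 0) return(NA_real_)
  vx <- sum(tc * (x - mean(x))) / den
  vy <- sum(tc * (y - mean(y))) / den
  if (sqrt(vx^2 + vy^2) < min_speed) return(NA_real_)
  heading_of(vx, vy)
}

#' Confirm the external heading reference
#'
#' The static (classifier) heading is confirmed as the external reference
#' theta_s on every frame completing `k` consecutive frames in which both
#' headings exist and their angular difference is within `bound`; the
#' counter resets on any violation or missing value.
#'
#' @param static_heading,dyn_heading Time-aligned per-frame headings
#'   (degrees; NA = unavailable).
#' @param bound Agreement bound (degrees).
#' @param k Required consecutive frames.
#' @return Numeric vector: theta_s on confirmation frames, NA elsewhere.
#' @export
confirm_external_reference <- function(static_heading, dyn_heading,
                                       bound = 15, k = 3L) {
  n <- length(static_heading)
  out <- rep(NA_real_, n)
  run <- 0L
  for (i in seq_len(n)) {
    ok <- !is.na(static_heading[i]) && !is.na(dyn_heading[i]) &&
      abs(signed_angle_diff(static_heading[i], dyn_heading[i])) <= bound
    run <- if (ok) run + 1L else 0L
    if (run >= k) out[i] <- static_heading[i]
  }
  out
}

#' Correction angle between the projected device axis and the reference
#'
#' @param theta_i Heading of the projected device y-axis (degrees).
#' @param theta_s Confirmed external heading reference (degrees).
#' @return delta_c in degrees, `(-180, 180]`.
#' @export
compute_correction <- function(theta_i, theta_s) {
  signed_angle_diff(theta_i, theta_s)
}

#' Create an empty Method2 heading state
#'
#' @return List of class `"heading_state"` with unset correction angle.
#' @export
heading_state <- function() {
  structure(list(delta_c = NA_real_, last_theta = NA_real_,
                 reference_confirmed_at = NA_real_),
            class = "heading_state")
}

#' Method2 heading for one frame
#'
#' Subtracts the correction angle from the observed projected-axis angle.
#' Before the first confirmed reference the heading is undefined and an
#' error is raised; callers withhold heading output in that case.
#'
#' @param theta_i Projected device-axis angle for the frame (degrees).
#' @param state A `"heading_state"` with `delta_c` set.
#' @return Heading theta (degrees, `[0, 360)`).
#' @export
method2_heading <- function(theta_i, state) {
  if (is.na(state$delta_c)) {
    stop("no external heading reference confirmed yet", call. = FALSE)
  }
  wrap_heading(theta_i - state$delta_c)
}

#' Run the Method2 fusion over an aligned frame sequence
#'
#' Per frame: on a confirmation frame the correction angle is (re)computed
#' from that frame's theta_i and theta_s (latest confirmation wins, so slow
#' mount drift is absorbed); on other frames the current correction is
#' subtracted from theta_i. Frames before the first confirmation yield NA.
#'
#' @param theta_i Per-frame projected device-axis angles (degrees).
#' @param theta_s Per-frame confirmed references from
#'   [confirm_external_reference()] (NA on non-confirmation frames).
#' @param state Optional initial `"heading_state"` (e.g. carried over from
#'   an earlier sequence).
#' @return Tibble with `theta` (degrees or NA) and `delta_c` per frame;
#'   attribute `state` holds the final heading state.
#' @export
run_method2 <- function(theta_i, theta_s, state = heading_state()) {
  n <- length(theta_i)
  theta <- rep(NA_real_, n)
  dc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(theta_s[i]) && !is.na(theta_i[i])) {
      state$delta_c <- compute_correction(theta_i[i], theta_s[i])
      state$reference_confirmed_at <- i
    }
    if (!is.na(state$delta_c) && !is.na(theta_i[i])) {
      theta[i] <- method2_heading(theta_i[i], state)
      state$last_theta <- theta[i]
    }
    dc[i] <- state$delta_c
  }
  out <- tibble(theta = theta, delta_c = dc)
  attr(out, "state") <- state
  out
}
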