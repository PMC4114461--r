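# Stop-window evaluation -------------------------------------------------------
#
# The accuracy protocol: each time a participant stands still on a marked
# point, a window of about one second is extracted from the estimate stream;
# windows whose per-coordinate standard deviation exceeds the acceptance
# gate are rejected as unstable. Accepted window means are compared with the
# ground truth and aggregated per point (across participants) and per
# participant (across that participant's points).

#' Circular mean of headings
#'
#' @param deg Headings in degrees.
#' @param na.rm Drop missing values.
#' @return Mean direction in degrees, `[0, 360)`; `NA` if empty.
#' @export
circular_mean <- function(deg, na.rm = TRUE) {
  if (na.rm) deg <- deg[!is.na(deg)]
  if (!length(deg)) return(NA_real_)
  r <- deg * pi / 180
  wrap_heading(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

# circular standard deviation about the circular mean (degrees)
circular_sd_about_mean <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (length(deg) < 2L) return(0)
  m <- circular_mean(deg)
  sqrt(mean(signed_angle_diff(deg, m)^2))
}

#' Segment stop windows from an estimate stream
#'
#' For every ground-truth stop, extracts the samples inside a window of
#' `window` seconds centred in the stop interval and computes the window
#' mean (circular for headings). Position windows are accepted when both
#' per-coordinate standard deviations are below `pos_sd_max`; heading
#' windows when the circular standard deviation is below `heading_sd_max`.
#' Rejected or empty windows are recorded as missing.
#'
#' @param estimates Tibble with column `t` plus `x`, `y` (m) and/or
#'   `heading` (degrees; NA allowed).
#' @param truth Ground-truth stop table (columns `participant`, `condition`,
#'   `walk`, `point_id`, `t_start`, `t_end`, `x`, `y`, `heading`, `ref_*`).
#'   For multi-run evaluation, pass per-run estimates and the matching truth
#'   rows.
#' @param window Window length (s).
#' @param pos_sd_max Position acceptance gate (m).
#' @param heading_sd_max Heading acceptance gate (degrees).
#' @param min_samples Minimum samples per accepted window.
#' @return Tibble, one row per truth stop, with window means, standard
#'   deviations, acceptance flags and the truth/reference values.
#' @export
segment_stops <- function(estimates, truth, window = 1.0,
                          pos_sd_max = 0.04, heading_sd_max = 15,
                          min_samples = 3L) {
  has_pos <- all(c("x", "y") %in% names(estimates))
  has_head <- "heading" %in% names(estimates)
  if (!nrow(truth) || !nrow(estimates) ||
      max(estimates$t) < min(truth$t_start) ||
      min(estimates$t) > max(truth$t_end)) {
    warning("estimate stream does not overlap the truth intervals")
  }
  rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    mid <- (tr$t_start + tr$t_end) / 2
    sel <- estimates$t >= mid - window / 2 & estimates$t <= mid + window / 2
    e <- estimates[sel, ]
    out <- tibble(
      participant = tr$participant, condition = tr$condition, walk = tr$walk,
      point_id = tr$point_id,
      true_x = tr$x, true_y = tr$y, true_heading = tr$heading,
      ref_x = tr$ref_x, ref_y = tr$ref_y, ref_heading = tr$ref_heading
    )
    if (has_pos) {
      xs <- e$x[!is.na(e$x)]; ys <- e$y[!is.na(e$y)]
      n <- min(length(xs), length(ys))
      sdx <- if (length(xs) > 1) sd(xs) else Inf
      sdy <- if (length(ys) > 1) sd(ys) else Inf
      out$n_pos <- n
      out$x_hat <- if (n) mean(xs) else NA_real_
      out$y_hat <- if (n) mean(ys) else NA_real_
      out$sd_x <- ifelse(is.finite(sdx), sdx, NA_real_)
      out$sd_y <- ifelse(is.finite(sdy), sdy, NA_real_)
      out$accepted_pos <- n >= min_samples && is.finite(sdx) && is.finite(sdy) &&
        sdx < pos_sd_max && sdy < pos_sd_max
    }
    if (has_head) {
      hs <- e$heading[!is.na(e$heading)]
      out$n_heading <- length(hs)
      out$heading_hat <- circular_mean(hs)
      out$sd_heading <- if (length(hs) > 1) circular_sd_about_mean(hs) else NA_real_
      out$accepted_heading <- length(hs) >= min_samples &&
        circular_sd_about_mean(hs) < heading_sd_max
    }
    out
  })
  dplyr::bind_rows(rows)
}

# internal: signed errors of accepted windows
.pos_errors <- function(windows) {
  w <- windows[windows$accepted_pos %in% TRUE, ]
  tibble(
    participant = rep(w$participant, 2), point_id = rep(w$point_id, 2),
    condition = rep(w$condition, 2),
    coordinate = rep(c("x", "y"), each = nrow(w)),
    ref = c(w$ref_x, w$ref_y),
    value = c(w$x_hat, w$y_hat),
    error = c(w$x_hat - w$true_x, w$y_hat - w$true_y)
  )
}

.heading_errors <- function(windows) {
  w <- windows[windows$accepted_heading %in% TRUE & !is.na(windows$heading_hat), ]
  tibble(
    participant = w$participant, point_id = w$point_id, condition = w$condition,
    ref = w$ref_heading, value = w$heading_hat,
    error = signed_angle_diff(w$heading_hat, w$true_heading)
  )
}

#' Per-point accuracy statistics
#'
#' Aggregates accepted stop windows per reference point (across
#' participants): average value, mean signed error, RMSE and maximum
#' absolute error. Position tables carry one row per point and coordinate;
#' heading tables use circular means and signed angular differences.
#'
#' @param windows Output of [segment_stops()] (rows from all runs).
#' @param type `"position"` or `"heading"`.
#' @return Tibble of statistics rows; points with no accepted window are
#'   flagged `missing`.
#' @export
per_point_stats <- function(windows, type = c("position", "heading")) {
  type <- match.arg(type)
  if (type == "position") {
    err <- .pos_errors(windows)
    out <- err |>
      dplyr::group_by(.data$point_id, .data$coordinate) |>
      dplyr::summarise(
        ref = mean(.data$ref), avg = mean(.data$value),
        mean_error = mean(.data$error),
        rmse = sqrt(mean(.data$error^2)),
        max_error = max(abs(.data$error)),
        n = dplyr::n(), .groups = "drop"
      )
  } else {
    err <- .heading_errors(windows)
    out <- err |>
      dplyr::group_by(.data$point_id) |>
      dplyr::summarise(
        ref = mean(.data$ref), avg = circular_mean(.data$value),
        mean_error = mean(.data$error),
        rmse = sqrt(mean(.data$error^2)),
        max_error = max(abs(.data$error)),
        n = dplyr::n(), .groups = "drop"
      )
  }
  all_pts <- tibble(point_id = sort(unique(windows$point_id)))
  out <- dplyr::left_join(all_pts, out, by = "point_id")
  out$missing <- is.na(out$n)
  out
}

#' Per-participant accuracy statistics
#'
#' Aggregates each participant's accepted stop windows (their 12 points in
#' the full protocol) into a mean signed error and RMSE.
#'
#' @inheritParams per_point_stats
#' @return Tibble with one row per participant.
#' @export
per_participant_stats <- function(windows, type = c("position", "heading")) {
  type <- match.arg(type)
  err <- if (type == "position") .pos_errors(windows) else .heading_errors(windows)
  out <- err |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      mean_error = mean(.data$error),
      rmse = sqrt(mean(.data$error^2)),
      max_error = max(abs(.data$error)),
      n = dplyr::n(), .groups = "drop"
    )
  all_p <- tibble(participant = sort(unique(windows$participant)))
  out <- dplyr::left_join(all_p, out, by = "participant")
  out$missing <- is.na(out$n)
  out
}

#' Overall per-coordinate position RMSE over accepted windows
#'
#' @param windows Output of [segment_stops()].
#' @return Named vector with the x and y RMSE (m) and `worst`, their
#'   maximum.
#' @export
overall_position_rmse <- function(windows) {
  err <- .pos_errors(windows)
  rx <- sqrt(mean(err$error[err$coordinate == "x"]^2))
  ry <- sqrt(mean(err$error[err$coordinate == "y"]^2))
  c(x = rx, y = ry, worst = max(rx, ry))
}
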