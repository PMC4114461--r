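# End-to-end pose pipeline and experiment replication -------------------------

#' Initial orientation from the first MARG samples
#'
#' Closed-form attitude initialization: gravity alone gives the minimal
#' rotation aligning the measured specific force with the world vertical
#' (tilt only, arbitrary yaw); with a magnetometer the gravity/North vector
#' pair fixes the full 3D orientation.
#'
#' @param imu IMU tibble; the first `n_avg` samples are averaged.
#' @param use_mag Use the magnetometer (absolute initialization).
#' @param n_avg Number of samples averaged.
#' @return Unit quaternion (device -> world).
#' @export
init_orientation <- function(imu, use_mag = TRUE, n_avg = 20L) {
  n <- min(n_avg, nrow(imu))
  a <- c(mean(imu$ax[1:n]), mean(imu$ay[1:n]), mean(imu$az[1:n]))
  a <- a / sqrt(sum(a^2))
  if (use_mag && !is.null(imu$mx) && !anyNA(imu$mx[1:n])) {
    m <- c(mean(imu$mx[1:n]), mean(imu$my[1:n]), mean(imu$mz[1:n]))
    m <- m / sqrt(sum(m^2))
    t2d <- pracma_cross(a, m)
    t2d <- t2d / sqrt(sum(t2d^2))
    t3d <- pracma_cross(a, t2d)
    D <- cbind(a, t2d, t3d)
    # world counterparts: vertical, (z x North) = world y, and their cross
    W <- cbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))
    quat_from_matrix(W %*% t(D))
  } else {
    z <- c(0, 0, 1)
    axis <- pracma_cross(a, z)
    s <- sqrt(sum(axis^2))
    if (s < 1e-9) return(quat(1, 0, 0, 0))
    ang <- atan2(s, sum(a * z)) * 180 / pi
    quat_from_axis_angle(axis, ang)
  }
}

# world-heading offset of a camera's tracking frame (tracking -> world)
.cam_rot_deg <- function(cam) cam$yaw_deg - 90

#' Run the pose pipeline on one simulated walk
#'
#' Renders depth frames at the tracker rate for whichever camera sees the
#' participant, runs the per-camera plan-view trackers, classifies height
#' templates at the tracked position, derives static/dynamic headings,
#' confirms the external reference and produces Method2 headings, and runs
#' the AOE filter + static frame corrections for Method1. All headings in
#' the output are expressed in the world frame.
#'
#' @param traj Ground-truth trajectory (only used to place the simulated
#'   body in front of the virtual cameras; the tracker never reads it).
#' @param imu Simulated MARG stream for the walk.
#' @param body The participant's `"body_model"`.
#' @param classifier A trained `"heading_classifier"`.
#' @param config A `"sim_config"`.
#' @param floor_bgs Optional precomputed floor depth images per camera.
#' @param clutter Optional static clutter boxes passed to the renderer.
#' @return List: `pose` (per-frame tibble `t, x, y, theta_m2, static,
#'   dynamic, theta_s, cam, class, quality`), `m1` (100 Hz tibble
#'   `t, heading`) and `n_confirmations`.
#' @export
run_pose_pipeline <- function(traj, imu, body, classifier,
                              config = sim_config(), floor_bgs = NULL,
                              clutter = NULL) {
  cams <- config$cameras
  if (is.null(floor_bgs)) floor_bgs <- lapply(cams, floor_depth_image)
  # time alignment guard: depth and IMU clocks must interleave within 10 ms
  ft <- seq(0, max(traj$t), by = 1 / config$fps)
  gap <- max(abs(ft - imu$t[pmax(1L, findInterval(ft, imu$t))]))
  if (gap > 0.010 + 1e-9) stop("depth and IMU streams are not synchronized", call. = FALSE)
  trackers <- lapply(seq_along(cams), function(j) {
    plan_view_tracker(cams[[j]], floor_bgs[[j]], config,
                      north_deg = config$north_deg)
  })
  rots <- vapply(cams, .cam_rot_deg, numeric(1))
  if (any(abs(rots %% 45) > 1e-6)) {
    stop("camera yaw must keep the tracking frame on the 45-degree class grid",
         call. = FALSE)
  }
  tx <- stats::approx(traj$t, traj$x, ft, rule = 2)$y
  ty <- stats::approx(traj$t, traj$y, ft, rule = 2)$y
  th <- stats::approx(traj$t, traj$heading_unwrapped, ft, rule = 2)$y
  nf <- length(ft)
  out_x <- rep(NA_real_, nf); out_y <- rep(NA_real_, nf)
  out_cam <- rep(NA_integer_, nf)
  cls_w <- rep(NA_integer_, nf); qual <- rep(NA_real_, nf)
  dyn <- rep(NA_real_, nf)
  hist_t <- numeric(0); hist_x <- numeric(0); hist_y <- numeric(0)
  for (i in seq_len(nf)) {
    pose_i <- c(tx[i], ty[i], wrap_heading(th[i]))
    vis <- vapply(seq_along(cams), function(j) {
      pr <- project_points(cams[[j]], rbind(c(pose_i[1], pose_i[2], 1.2)))
      pr$ok[1] && pr$z[1] >= 1.0 && pr$z[1] <= cams[[j]]$range_m[2] + 0.3
    }, logical(1))
    best <- NULL
    for (j in seq_along(cams)) {
      has_tracks <- length(trackers[[j]]$tracks) > 0
      if (!vis[j] && !has_tracks) next
      depth <- if (vis[j]) {
        render_depth_frame(body, pose_i, cams[[j]], floor_bgs[[j]],
                           config$depth_noise_coef, clutter = clutter)$depth
      } else floor_bgs[[j]]
      trackers[[j]] <- tracker_step(trackers[[j]], depth, ft[i])
      pos <- attr(trackers[[j]], "positions")
      if (nrow(pos)) {
        cand <- pos[1, ]
        if (is.null(best)) best <- list(j = j, pos = cand)
      }
    }
    if (!is.null(best)) {
      j <- best$j
      out_x[i] <- best$pos$x_world; out_y[i] <- best$pos$y_world
      out_cam[i] <- j
      hist_t <- c(hist_t, ft[i]); hist_x <- c(hist_x, out_x[i]); hist_y <- c(hist_y, out_y[i])
      keep <- hist_t >= ft[i] - 0.55
      hist_t <- hist_t[keep]; hist_x <- hist_x[keep]; hist_y <- hist_y[keep]
      maps <- attr(trackers[[j]], "maps")
      in_bounds <- best$pos$x >= maps$x0 && best$pos$x < maps$x0 + maps$nx * maps$cell &&
        best$pos$y >= maps$y0 && best$pos$y < maps$y0 + maps$ny * maps$cell
      tpl <- if (in_bounds) extract_height_template(maps, c(best$pos$x, best$pos$y))
             else list(nonzero_count = 0L)
      if (tpl$nonzero_count > 0L) {
        cl <- classify_heading(classifier, tpl)
        cls_w[i] <- as.integer(round(wrap_heading(cl$heading + rots[j]) / 45)) %% 8L
        qual[i] <- cl$quality
      }
      dyn[i] <- dynamic_heading(hist_t, hist_x, hist_y, min_speed = 0.3)
    }
  }
  static_w <- confirm_static_heading(cls_w, qual) # world-frame class headings
  theta_s <- confirm_external_reference(static_w, dyn, bound = 15, k = 3L)
  # GROE -> projected device-axis angle theta_i at the tracker rate
  groe <- run_orientation_filter(imu, "groe", q0 = init_orientation(imu, use_mag = FALSE))
  theta_i_full <- projected_heading_track(groe)
  theta_i <- theta_i_full[pmax(1L, findInterval(ft, groe$t))]
  m2 <- run_method2(theta_i, theta_s)
  # Method1: AOE alpha + static frame corrections, at the IMU rate
  aoe <- run_orientation_filter(imu, "aoe", q0 = init_orientation(imu, use_mag = TRUE))
  alpha <- projected_heading_track(aoe)
  psi1 <- wrap_heading(cams[[1]]$yaw_deg - config$north_deg)
  m1 <- tibble(
    t = aoe$t,
    heading = wrap_heading(method1_heading(alpha, psi1) + rots[1])
  )
  list(
    pose = tibble(
      t = ft, x = out_x, y = out_y, cam = out_cam,
      class_world = cls_w, quality = qual,
      static = static_w, dynamic = dyn, theta_s = theta_s,
      theta_i = theta_i, heading = m2$theta, delta_c = m2$delta_c
    ),
    m1 = m1,
    n_confirmations = sum(!is.na(theta_s))
  )
}

#' Train the replication's heading classifier
#'
#' Builds four synthetic trainer bodies of different heights, renders a
#' labelled template set across the first camera's coverage at the eight
#' principal orientations (with heading jitter, since real walkers never
#' stand exactly on a class centre) and trains the 443-25-8 network.
#'
#' @param config A `"sim_config"`.
#' @param repeats Renders per (body, position, class) for training.
#' @param jitter_deg Training heading jitter half-width (degrees).
#' @param epochs,lr Training schedule.
#' @return List with `model`, the training tibble dimensions and the trainer
#'   body heights.
#' @export
train_replication_classifier <- function(config = sim_config(), repeats = 2L,
                                         jitter_deg = 10, epochs = 200L,
                                         lr = 0.01) {
  set.seed(config$seed + 211L)
  heights <- c(1.60, 1.70, 1.79, 1.88)
  bodies <- lapply(heights, function(h)
    body_model(height = h, shoulder_width = rnorm(1, 0.45, 0.015),
               chest_depth = rnorm(1, 0.26, 0.01)))
  train <- generate_template_dataset(bodies, config$cameras[[1]],
                                     config = config, repeats = repeats,
                                     jitter_deg = jitter_deg)
  model <- train_heading_classifier(
    as.matrix(train[, paste0("f", 1:443)]), train$label,
    epochs = epochs, lr = lr, seed = config$seed + 1L
  )
  list(model = model, n_train = nrow(train), heights = heights)
}

#' Held-out classification accuracy of a heading classifier
#'
#' Renders fresh templates (new bodies drawn from the population height
#' distribution, new noise) at the eight trained orientations and reports
#' the fraction classified correctly.
#'
#' @param model A `"heading_classifier"`.
#' @param config A `"sim_config"`.
#' @param n_test Number of held-out templates evaluated.
#' @return List with `accuracy` (fraction), `n` and the per-template tibble.
#' @export
evaluate_classifier_holdout <- function(model, config = sim_config(),
                                        n_test = 100L) {
  set.seed(config$seed + 409L)
  heights <- rnorm(4, 1.742, 0.088)
  bodies <- lapply(heights, function(h) body_model(height = h))
  test <- generate_template_dataset(bodies, config$cameras[[1]],
                                    config = config, repeats = 1L,
                                    jitter_deg = 0)
  test <- test[sample.int(nrow(test), min(n_test, nrow(test))), ]
  pred <- predict_heading(model, as.matrix(test[, paste0("f", 1:443)]))
  acc <- mean(pred$class == test$label)
  list(accuracy = acc, n = nrow(test),
       results = tibble(label = test$label, class = pred$class,
                        quality = pred$quality))
}

#' Replicate the full accuracy-assessment experiment
#'
#' Simulates the stop-point protocol, runs the complete pipeline (depth
#' rendering, plan-view tracking, classifier, both heading methods) on every
#' walk, segments the stop windows and produces the per-point and
#' per-participant statistics tables.
#'
#' @param config A `"sim_config"`; `config$seed` drives everything.
#' @param n_participants Number of simulated participants.
#' @param conditions Mount conditions to run.
#' @param classifier Optional pre-trained `"heading_classifier"`; trained
#'   from scratch when `NULL`.
#' @param verbose Print progress.
#' @return Object of class `"fog_replication"`: stop-window tibbles, the
#'   statistics tables (per-point position; per-point and per-participant
#'   heading for both methods and conditions) and headline summaries.
#' @export
run_experiment_replication <- function(config = sim_config(),
                                       n_participants = 12,
                                       conditions = c("Position1", "Position2"),
                                       classifier = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  if (is.null(classifier)) {
    if (verbose) message("training heading classifier ...")
    classifier <- train_replication_classifier(config)$model
  }
  exper <- generate_experiment(n_participants, config, conditions)
  floor_bgs <- lapply(config$cameras, floor_depth_image)
  bodies <- lapply(seq_len(n_participants), function(p)
    body_model(height = exper$participants$height[p],
               shoulder_width = exper$participants$shoulder_width[p],
               chest_depth = exper$participants$chest_depth[p]))
  win_pos <- list(); win_m1 <- list(); win_m2 <- list()
  n_conf <- 0L
  for (r in seq_len(nrow(exper$runs))) {
    run <- exper$runs[r, ]
    truth_r <- exper$truth[exper$truth$participant == run$participant &
                             exper$truth$condition == run$condition &
                             exper$truth$walk == run$walk, ]
    set.seed(run$run_seed + 31L)
    res <- run_pose_pipeline(run$traj[[1]], run$imu[[1]],
                             bodies[[run$participant]], classifier,
                             config, floor_bgs)
    n_conf <- n_conf + res$n_confirmations
    est_pos <- res$pose[, c("t", "x", "y")]
    win_pos[[r]] <- segment_stops(est_pos, truth_r)
    win_m1[[r]] <- segment_stops(res$m1, truth_r)
    win_m2[[r]] <- segment_stops(res$pose[, c("t", "heading")], truth_r)
    if (verbose) {
      message(sprintf("run %d/%d (participant %d, %s, walk %s): %d confirmations",
                      r, nrow(exper$runs), run$participant, run$condition,
                      run$walk, res$n_confirmations))
    }
  }
  win_pos <- dplyr::bind_rows(win_pos)
  win_m1 <- dplyr::bind_rows(win_m1)
  win_m2 <- dplyr::bind_rows(win_m2)
  p1 <- function(w) w[w$condition == "Position1", ]
  p2 <- function(w) w[w$condition == "Position2", ]
  has1 <- "Position1" %in% conditions
  has2 <- "Position2" %in% conditions
  tables <- list(
    position_per_point = per_point_stats(win_pos, "position"),
    m1_per_point = if (has1) per_point_stats(p1(win_m1), "heading"),
    m1_per_participant = list(
      Position1 = if (has1) per_participant_stats(p1(win_m1), "heading"),
      Position2 = if (has2) per_participant_stats(p2(win_m1), "heading")
    ),
    m2_per_point = if (has1) per_point_stats(p1(win_m2), "heading"),
    m2_per_participant = list(
      Position1 = if (has1) per_participant_stats(p1(win_m2), "heading"),
      Position2 = if (has2) per_participant_stats(p2(win_m2), "heading")
    )
  )
  structure(list(
    config = config, n_participants = n_participants, conditions = conditions,
    classifier = classifier,
    windows_pos = win_pos, windows_m1 = win_m1, windows_m2 = win_m2,
    tables = tables,
    summary = list(
      position_rmse = overall_position_rmse(win_pos),
      m1_max_point_rmse = if (has1) max(tables$m1_per_point$rmse, na.rm = TRUE),
      m2_max_point_rmse = if (has1) max(tables$m2_per_point$rmse, na.rm = TRUE),
      m2_max_participant_rmse_p2 =
        if (has2) max(tables$m2_per_participant$Position2$rmse, na.rm = TRUE),
      n_confirmations = n_conf,
      n_stops = nrow(exper$truth),
      runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    truth = exper$truth,
    participants = exper$participants
  ), class = "fog_replication")
}

#' @export
print.fog_replication <- function(x, ...) {
  s <- x$summary
  cat("Synthetic replication of the stop-point accuracy protocol\n")
  cat(sprintf("  participants: %d, conditions: %s, stops: %d\n",
              x$n_participants, paste(x$conditions, collapse = "+"), s$n_stops))
  cat(sprintf("  position RMSE: x %.3f m, y %.3f m (worst %.3f m)\n",
              s$position_rmse["x"], s$position_rmse["y"], s$position_rmse["worst"]))
  if (!is.null(s$m1_max_point_rmse))
    cat(sprintf("  Method1 max per-point heading RMSE: %.1f deg\n", s$m1_max_point_rmse))
  if (!is.null(s$m2_max_point_rmse))
    cat(sprintf("  Method2 max per-point heading RMSE: %.1f deg\n", s$m2_max_point_rmse))
  if (!is.null(s$m2_max_participant_rmse_p2))
    cat(sprintf("  Method2 max per-participant RMSE (displaced mount): %.1f deg\n",
                s$m2_max_participant_rmse_p2))
  invisible(x)
}

#' Write a trajectory estimate stream as CSV
#'
#' @param pose Pose tibble from [run_pose_pipeline()].
#' @param path File path.
#' @export
write_trajectory_csv <- function(pose, path) {
  readr::write_csv(pose, path)
  invisible(path)
}

#' Serialize the effective configuration as JSON
#'
#' @param config A `"sim_config"`.
#' @param path File path.
#' @export
write_config_json <- function(config, path) {
  cfg <- config
  cfg$cameras <- lapply(cfg$cameras, function(cm) cm[setdiff(names(cm), "R")])
  jsonlite::write_json(cfg, path, digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(path)
}
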