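test_that("background subtraction applies the closer-than-tau and validity rules", {
  bg <- matrix(3000, 10, 10)
  expect_false(any(subtract_background(bg, bg, 0.10)))
  fr <- bg
  fr[2, 2] <- 2800   # 0.2 m closer -> foreground
  fr[3, 3] <- 2950   # 0.05 m closer -> not beyond tau
  fr[4, 4] <- 0      # invalid, never foreground
  m <- subtract_background(fr, bg, 0.10)
  expect_true(m[2, 2]); expect_false(m[3, 3]); expect_false(m[4, 4])
  expect_equal(sum(m), 1)
  # valid measurement where the background has no reference
  bg2 <- bg; bg2[5, 5] <- 0; fr2 <- bg; fr2[5, 5] <- 2500
  expect_true(subtract_background(fr2, bg2, 0.10)[5, 5])
  expect_error(subtract_background(matrix(0, 2, 2), bg, 0.1), "dimensions")
})

test_that("a rendered person is segmented with IoU >= 0.9 against the true silhouette", {
  cfg <- sim_config(seed = 31L)
  cam <- cfg$cameras[[1]]
  fb <- floor_depth_image(cam)
  set.seed(31)
  fr <- render_depth_frame(body_model(), c(1.5, 2.5, 90), cam, fb,
                           cfg$depth_noise_coef)
  m <- subtract_background(fr$depth, fb, 0.10)
  iou <- sum(m & fr$silhouette) / sum(m | fr$silhouette)
  expect_gte(iou, 0.9)
})

test_that("background model updates only in empty scenes and converges", {
  f0 <- matrix(3000, 5, 5)
  bg <- background_model(f0, t = 0, period = 10, k = 3)
  # active tracks gate the update
  bg1 <- update_background(bg, f0 - 500, active_tracks = 1, t = 20)
  expect_equal(bg1$depth, f0)
  # median of k buffered frames replaces the reference
  frames <- lapply(c(2900, 3000, 3100), function(v) matrix(v, 5, 5))
  for (i in 1:3) bg <- update_background(bg, frames[[i]], 0, t = 10 + i)
  expect_equal(bg$depth, matrix(3000, 5, 5))
  expect_equal(length(bg$buffer), 0)
  # end-to-end: after convergence the static scene yields an empty mask
  expect_false(any(subtract_background(matrix(3000, 5, 5), bg$depth, 0.1)))
})

test_that("plan-view maps bin points, apply the height cut-off and conserve counts", {
  m <- build_plan_view_maps(rbind(c(1.00, 2.00, 1.70)), cell = 0.05, cutoff = 1,
                            bounds = c(0, 3, 0, 3))
  expect_equal(sum(m$occupancy > 0), 1)
  expect_equal(max(m$height), 1.70)
  expect_equal(sum(m$occupancy), 1)
  ix <- as.integer(1.00 / 0.05) + 1L; iy <- as.integer(2.00 / 0.05) + 1L
  expect_equal(m$occupancy[ix, iy], 1)

  # everything below the cut-off is discarded
  set.seed(32)
  low <- cbind(runif(200, 0, 3), runif(200, 0, 3), 0.8)
  m2 <- build_plan_view_maps(low, cell = 0.05, cutoff = 1.0, bounds = c(0, 3, 0, 3))
  expect_equal(sum(m2$occupancy), 0)
  expect_equal(m2$n_points, 0L)

  # occupancy total equals the surviving point count (unit weights)
  pts <- cbind(runif(500, 0, 3), runif(500, 0, 3), runif(500, 0.5, 2))
  m3 <- build_plan_view_maps(pts, cell = 0.05, cutoff = 1.0, bounds = c(0, 3, 0, 3))
  expect_equal(sum(m3$occupancy), sum(pts[, 3] >= 1.0))
  expect_equal(m3$n_points, sum(pts[, 3] >= 1.0))
  expect_error(build_plan_view_maps(pts, cell = 0), "positive")
})

test_that("plan-view centroid of a rendered person lands within 0.15 m of the body axis", {
  cfg <- sim_config(seed = 33L)
  cam <- cfg$cameras[[1]]
  fb <- floor_depth_image(cam)
  frame <- camera_tracking_frame(cam, 0)
  set.seed(33)
  for (pose in list(c(1.5, 2.8, 0), c(2.5, 3.5, 135))) {
    fr <- render_depth_frame(body_model(), pose, cam, fb, cfg$depth_noise_coef)
    idx <- which(subtract_background(fr$depth, fb, 0.10))
    vv <- (idx - 1) %% cam$height; uu <- (idx - 1) %/% cam$height
    Pt <- fogtrack:::.shift_from_camera(
      to_tracking(frame, backproject_pixels(cam, uu, vv, fr$depth[idx])), 0.10)
    w <- (fr$depth[idx] / 1000)^2 / (cam$fx * cam$fy * 0.05^2)
    m <- build_plan_view_maps(Pt, cell = 0.05, cutoff = 1, bounds = c(-3.2, 3.2, 0.5, 6.2),
                              weights = w)
    cells <- fogtrack:::.occupied_cells(m)
    ctr <- c(sum(cells[, "x"] * cells[, "occ"]), sum(cells[, "y"] * cells[, "occ"])) /
      sum(cells[, "occ"])
    truth <- to_tracking(frame, c(pose[1], pose[2], 0))[1:2]
    expect_lt(sqrt(sum((ctr - truth)^2)), 0.15)
  }
})

test_that("pf_predict advances the linear model and leaves weights untouched", {
  set.seed(34)
  tr <- person_track(1, c(0, 0), n = 2000L, pos_spread = 0, vel_spread = 0)
  tr$particles[, 3] <- 1  # vx = 1 m/s
  w0 <- tr$weights
  tr2 <- pf_predict(tr, dt = 1 / 30, q_pos = 0, q_vel = 0)
  expect_equal(mean(tr2$particles[, 1]), 1 / 30, tolerance = 1e-12)
  expect_identical(tr2$weights, w0)

  tr3 <- person_track(1, c(0, 0), n = 20000L, pos_spread = 0, vel_spread = 0)
  tr3$particles[, 3:4] <- 0
  tr3 <- pf_predict(tr3, dt = 1, q_pos = 0.05, q_vel = 0)
  expect_equal(stats::var(tr3$particles[, 1]), 0.05^2, tolerance = 0.1)
  expect_error(pf_predict(tr, dt = 0), "positive")
})

test_that("pf_correct sharpens the posterior onto the observed blob", {
  set.seed(35)
  # occupancy concentrated in one cell
  maps <- maps_from_points(rbind(c(1.02, 1.02, 1.7)), cell = 0.05,
                           bounds = c(0, 2, 0, 2))
  tr <- person_track(1, c(1, 1), n = 500L, pos_spread = 0.3, vel_spread = 0.1)
  for (i in 1:3) tr <- pf_correct(tr, maps)
  est <- estimate_position(tr)
  expect_lt(max(abs(est - c(1.025, 1.025))), 0.05)

  # uniform maps leave weights unchanged up to renormalization
  u_pts <- cbind(rep(seq(0.025, 1.975, by = 0.05), 40),
                 rep(seq(0.025, 1.975, by = 0.05), each = 40), 1.65)
  mu <- maps_from_points(u_pts, cell = 0.05, bounds = c(0, 2, 0, 2))
  tr2 <- person_track(2, c(1, 1), n = 300L, pos_spread = 0.1)
  w_before <- tr2$weights
  # keep particles well inside the grid so every particle sees the same field
  tr2$particles[, 1] <- pmin(pmax(tr2$particles[, 1], 0.5), 1.5)
  tr2$particles[, 2] <- pmin(pmax(tr2$particles[, 2], 0.5), 1.5)
  tr3 <- pf_correct(tr2, mu)
  expect_equal(tr3$weights, w_before / sum(w_before), tolerance = 0.02)

  # empty maps: weights reset to uniform and the track counts a miss
  me <- maps_from_points(matrix(numeric(0), 0, 3), bounds = c(0, 2, 0, 2))
  tr4 <- pf_correct(person_track(3, c(1, 1), n = 100L), me)
  expect_false(attr(tr4, "observed"))
  expect_equal(tr4$weights, rep(1 / 100, 100))
  expect_equal(tr4$misses, 1L)
})

test_that("posterior concentrates on the blob nearest the prior", {
  set.seed(36)
  pts <- rbind(
    cbind(rnorm(60, 0.5, 0.02), rnorm(60, 1.0, 0.02), 1.7),
    cbind(rnorm(60, 1.5, 0.02), rnorm(60, 1.0, 0.02), 1.7)
  )
  maps <- maps_from_points(pts, cell = 0.05, bounds = c(0, 2, 0, 2))
  tr <- person_track(1, c(0.55, 1.0), n = 600L, pos_spread = 0.08, vel_spread = 0)
  for (i in 1:2) tr <- pf_correct(tr, maps)
  mass_near <- sum(tr$weights[abs(tr$particles[, 1] - 0.5) < 0.3])
  expect_gt(mass_near, 0.8)
})

test_that("particle filter matches a dense-grid Bayes filter within 1.5 cells", {
  set.seed(37)
  cell <- 0.05
  pts <- cbind(rnorm(80, 1.12, 0.04), rnorm(80, 0.93, 0.04), runif(80, 1.5, 1.8))
  maps <- maps_from_points(pts, cell = cell, bounds = c(0, 2, 0, 2))
  # independent oracle: dense-grid Bayesian filter with the documented
  # observation model (kernel-smoothed occupancy/height mixture)
  cells <- fogtrack:::.occupied_cells(maps)
  occ_n <- cells[, "occ"] / max(cells[, "occ"])
  h_sc <- exp(-0.5 * ((cells[, "h"] - 1.65) / 0.4)^2)
  score <- 0.625 * occ_n + 0.375 * h_sc
  gx <- seq(0.025, 1.975, by = cell)
  G <- expand.grid(x = gx, y = gx)
  lik <- sapply(seq_len(nrow(cells)), function(k) {
    exp(-((G$x - cells[k, "x"])^2 + (G$y - cells[k, "y"])^2) / (2 * 0.08^2)) * score[k]
  })
  lik <- rowSums(lik) + 1e-4
  prior <- exp(-((G$x - 1.0)^2 + (G$y - 1.0)^2) / (2 * 0.2^2))
  post <- prior * lik          # one static Bayes update
  post <- post / sum(post)
  oracle <- c(sum(G$x * post), sum(G$y * post))

  tr <- person_track(1, c(1.0, 1.0), n = 4000L, pos_spread = 0.2, vel_spread = 0)
  tr <- pf_correct(tr, maps)
  est <- estimate_position(tr)
  expect_lt(sqrt(sum((est - oracle)^2)), 1.5 * cell)
})

test_that("new-person detection seeds on qualifying components only", {
  empty <- maps_from_points(matrix(numeric(0), 0, 3), bounds = c(0, 3, 0, 3))
  expect_equal(nrow(detect_new_persons(empty)), 0)

  set.seed(38)
  pts <- cbind(rnorm(200, 1.5, 0.05), rnorm(200, 1.5, 0.05), runif(200, 1.2, 1.75))
  maps <- maps_from_points(pts, cell = 0.05, bounds = c(0, 3, 0, 3))
  seeds <- detect_new_persons(maps, min_occ = 50, min_height = 1.3)
  expect_equal(nrow(seeds), 1)
  expect_lt(sqrt(sum((seeds[1, ] - c(1.5, 1.5))^2)), 0.2)

  # overlap with an existing track suppresses the seed
  tr <- person_track(1, c(1.5, 1.5), n = 50L, pos_spread = 0.01)
  expect_equal(nrow(detect_new_persons(maps, list(tr))), 0)

  # low component (below person height) never seeds
  low <- cbind(rnorm(200, 1.5, 0.05), rnorm(200, 1.5, 0.05), runif(200, 1.0, 1.2))
  maps_low <- maps_from_points(low, cell = 0.05, bounds = c(0, 3, 0, 3))
  expect_equal(nrow(detect_new_persons(maps_low)), 0)
})

test_that("estimate_position is the weighted particle mean", {
  tr <- person_track(1, c(0, 0), n = 2L, pos_spread = 0)
  tr$particles[1, 1:2] <- c(0, 0)
  tr$particles[2, 1:2] <- c(2, 0)
  tr$weights <- c(0.5, 0.5)
  expect_equal(estimate_position(tr), c(1, 0))
  tr$weights <- c(1, 0)
  expect_equal(estimate_position(tr), c(0, 0))
  set.seed(39)
  tr$particles <- matrix(rnorm(8), 2, 4)
  tr$weights <- c(0.3, 0.7)
  expect_equal(estimate_position(tr),
               c(sum(tr$particles[, 1] * tr$weights),
                 sum(tr$particles[, 2] * tr$weights)), tolerance = 1e-12)
})

test_that("systematic resampling is deterministic given the uniform draw", {
  w <- c(0.7, 0.2, 0.1)
  idx <- systematic_resample(w, u = 0.25)
  expect_equal(idx, systematic_resample(w, u = 0.25))
  expect_equal(sort(unique(idx)), sort(unique(c(1, idx))))  # heavy particle kept
  big <- systematic_resample(rep(1 / 4, 4), u = 0)
  expect_equal(length(big), 4)
})

test_that("clutter below the height cut-off does not disturb tracking", {
  cfg <- sim_config(seed = 40L)
  cam <- cfg$cameras[[1]]
  fb <- floor_depth_image(cam)
  clutter <- list(c(1.0, 2.2, 0.5, 0.5, 0.8), c(2.0, 3.6, 0.6, 0.4, 0.9))
  body <- body_model()
  run_track <- function(with_clutter) {
    set.seed(99)
    tk <- plan_view_tracker(cam, fb, cfg)
    est <- NULL
    for (i in 1:25) {
      fr <- render_depth_frame(body, c(1.6, 2.9, 45), cam, fb,
                               cfg$depth_noise_coef,
                               clutter = if (with_clutter) clutter)
      tk <- tracker_step(tk, fr$depth, i / 15)
      p <- attr(tk, "positions")
      if (nrow(p)) est <- rbind(est, c(p$x[1], p$y[1]))
    }
    est
  }
  e0 <- run_track(FALSE)
  e1 <- run_track(TRUE)
  n <- min(nrow(e0), nrow(e1))
  rms <- sqrt(mean((e0[seq_len(n), ] - e1[seq_len(n), ])^2))
  expect_lt(rms, 0.02)
})

test_that("a stationary person is tracked with low jitter anywhere in range", {
  cfg <- sim_config(seed = 41L)
  cam <- cfg$cameras[[1]]
  fb <- floor_depth_image(cam)
  frame <- camera_tracking_frame(cam, 0)
  body <- body_model()
  set.seed(41)
  for (pose in list(c(0.2, 3.0, 0), c(2.8, 3.3, 200))) {  # near and far
    tk <- plan_view_tracker(cam, fb, cfg)
    est <- NULL
    for (i in 1:20) {
      fr <- render_depth_frame(body, pose, cam, fb, cfg$depth_noise_coef)
      tk <- tracker_step(tk, fr$depth, i / 15)
      p <- attr(tk, "positions")
      if (nrow(p)) est <- rbind(est, c(p$x_world[1], p$y_world[1]))
    }
    expect_gt(nrow(est), 10)
    err <- sweep(est, 2, pose[1:2])
    expect_lt(sqrt(mean(err^2)), 0.16)
    expect_lt(max(apply(est, 2, sd)), 0.04)
  }
})

test_that("depth PGM files round-trip in both encodings", {
  set.seed(42)
  d <- matrix(sample(0:6000, 60), 6, 10)
  f1 <- withr::local_tempfile(fileext = ".pgm")
  write_depth_pgm(d, f1)
  expect_equal(read_depth_pgm(f1), d)
  f2 <- withr::local_tempfile(fileext = ".pgm")
  write_depth_pgm(d, f2, ascii = TRUE)
  expect_equal(read_depth_pgm(f2), d)
})
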