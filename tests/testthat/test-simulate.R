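test_that("floor-only frames reproduce the background and respect the range cap", {
  cfg <- sim_config(seed = 70L)
  cam <- cfg$cameras[[1]]
  fb <- floor_depth_image(cam)
  fr <- render_depth_frame(NULL, c(0, 0, 0), cam, fb, noise_coef = 0)
  expect_identical(fr$depth, fb)
  expect_false(any(fr$silhouette))
  # all valid depths within the camera range
  v <- fb[fb > 0]
  expect_true(all(v >= cam$range_m[1] * 1000 & v <= cam$range_m[2] * 1000))

  # a body beyond 6 m leaves no valid pixels
  far <- render_depth_frame(body_model(), c(8.5, 3, 0), cam, fb, noise_coef = 0)
  expect_false(any(far$silhouette & far$depth > 0 & far$depth != fb))
  expect_equal(sum(far$silhouette), 0)
})

test_that("projection and back-projection invert each other", {
  cfg <- sim_config(seed = 71L)
  cam <- cfg$cameras[[1]]
  set.seed(71)
  P <- cbind(runif(50, 0, 3), runif(50, 1, 5), runif(50, 0, 2))
  pr <- project_points(cam, P)
  keep <- pr$ok
  back <- backproject_pixels(cam, pr$u[keep], pr$v[keep], pr$z[keep] * 1000)
  # pixel quantization bounds the round-trip error
  expect_lt(max(abs(back - P[keep, ])), 0.02)
})

test_that("rendered foreground centroid projects near the true floor point", {
  cfg <- sim_config(seed = 72L)
  cam <- cfg$cameras[[1]]
  fb <- floor_depth_image(cam)
  frame <- camera_tracking_frame(cam, 0)
  set.seed(72)
  fr <- render_depth_frame(body_model(), c(1.0, 2.0, 30), cam, fb,
                           cfg$depth_noise_coef)
  idx <- which(fr$silhouette)
  vv <- (idx - 1) %% cam$height; uu <- (idx - 1) %/% cam$height
  Pt <- fogtrack:::.shift_from_camera(
    to_tracking(frame, backproject_pixels(cam, uu, vv, fr$depth[idx])), 0.10)
  ctr <- colMeans(Pt[Pt[, 3] > 1.0, 1:2])
  truth <- to_tracking(frame, c(1.0, 2.0, 0))[1:2]
  expect_lt(sqrt(sum((ctr - truth)^2)), 0.15)
})

test_that("the compiled body ray-caster matches the reference quadric solvers", {
  set.seed(78)
  body <- body_model()
  o <- c(1.4, -0.8, 2.25)
  n <- 500
  D <- cbind(runif(n, -0.9, -0.3), runif(n, 0.1, 0.5), runif(n, -0.9, -0.3))
  t_cpp <- fogtrack:::.cast_body(o, D[, 1], D[, 2], D[, 3],
    c(body$legs$a, body$legs$b, body$legs$z0, body$legs$z1),
    c(body$torso$a, body$torso$b, body$torso$z0, body$torso$z1),
    c(body$head$cx, body$head$cz, body$head$r))
  t_ref <- pmin(
    fogtrack:::.ray_cylinder(o[1], o[2], o[3], D[, 1], D[, 2], D[, 3],
                             body$legs$a, body$legs$b, body$legs$z0, body$legs$z1),
    fogtrack:::.ray_cylinder(o[1], o[2], o[3], D[, 1], D[, 2], D[, 3],
                             body$torso$a, body$torso$b, body$torso$z0, body$torso$z1),
    fogtrack:::.ray_sphere(o[1], o[2], o[3], D[, 1], D[, 2], D[, 3],
                           body$head$cx, 0, body$head$cz, body$head$r))
  expect_gt(sum(is.finite(t_ref)), 20)  # the bundle actually hits the body
  expect_equal(t_cpp, t_ref, tolerance = 1e-12)
})

test_that("simulated IMU streams reproduce gravity, turn rate and mount offset", {
  cfg <- sim_config(seed = 73L)
  scripts <- fog_walk_scripts()
  set.seed(73)
  inst <- fogtrack:::instantiate_walk(scripts[scripts$walk == "L", ],
                                      attr(scripts, "starts")$L, cfg)
  sim <- simulate_trajectory(inst, cfg)
  imu <- simulate_imu(sim$traj, 0, cfg)
  # standing still at the first stop: specific force = gravity
  s <- sim$stops[1, ]
  sel <- imu$t > s$t_start + 0.5 & imu$t < s$t_end - 0.5
  mag <- sqrt(imu$ax[sel]^2 + imu$ay[sel]^2 + imu$az[sel]^2)
  expect_equal(mean(mag), 9.81, tolerance = 0.05)
  # during an on-the-spot turn the device-vertical rate matches the turn rate
  turning <- which(sim$traj$phase == "turn")
  runs <- split(turning, cumsum(c(1, diff(turning) != 1)))
  long <- runs[[which.max(lengths(runs))]]
  mid <- long[seq(10, length(long) - 10)]
  # device x is (close to) the body vertical: compare |gx| with 120 deg/s
  expect_equal(mean(abs(imu$gx[mid])), cfg$turn_rate * pi / 180, tolerance = 0.1)

  # a 55 deg mount rotation shifts the AOE compass heading by 55 deg
  cfg0 <- noise_free_config(seed = 73L)
  sim0 <- simulate_trajectory(inst, cfg0)
  imu55 <- simulate_imu(sim0$traj, 55, cfg0)
  aoe <- run_orientation_filter(imu55, "aoe", q0 = init_orientation(imu55))
  alpha <- projected_heading_track(aoe)
  s2 <- sim0$stops[3, ]
  sel2 <- imu55$t >= (s2$t_start + s2$t_end) / 2 - 0.5 &
    imu55$t <= (s2$t_start + s2$t_end) / 2 + 0.5
  d <- signed_angle_diff(circular_mean(alpha[sel2]), s2$heading)
  expect_equal(d, -55, tolerance = 0.5)
})

test_that("trajectories stand still for the scripted stop duration", {
  cfg <- sim_config(seed = 74L)
  scripts <- fog_walk_scripts()
  set.seed(74)
  inst <- fogtrack:::instantiate_walk(scripts[scripts$walk == "R", ],
                                      attr(scripts, "starts")$R, cfg)
  sim <- simulate_trajectory(inst, cfg)
  expect_equal(nrow(sim$stops), 6L)
  expect_equal(sim$stops$t_end - sim$stops$t_start, rep(3, 6))
  for (i in seq_len(nrow(sim$stops))) {
    s <- sim$stops[i, ]
    sel <- sim$traj$t >= s$t_start & sim$traj$t <= s$t_end
    expect_lt(max(abs(sim$traj$x[sel] - s$x)), 1e-9)
    expect_lt(max(sim$traj$speed[sel][-sum(sel)]), 1e-6)
  }
})

test_that("the generated experiment matches the protocol counts and layout", {
  cfg <- sim_config(seed = 75L)
  ex <- generate_experiment(12, cfg)
  # 12 participants x 12 reference points x 2 sensor positions
  expect_equal(nrow(ex$truth), 288L)
  expect_equal(nrow(ex$runs), 12 * 2 * 2)
  expect_equal(sort(unique(ex$truth$point_id)), 1:12)
  # reference coordinates live on the 0.5 m marker grid
  expect_true(all(ex$truth$ref_x %% 0.25 == 0))
  expect_true(all(ex$truth$ref_y %% 0.25 == 0))
  expect_true(all(ex$truth$ref_x[ex$truth$point_id == 1] == 2.25))
  expect_true(all(ex$truth$ref_y[ex$truth$point_id == 1] == 1.75))
  # Position2 mount offsets drawn from 50-60 degrees
  expect_true(all(ex$participants$mount_offset_p2 >= 50 &
                    ex$participants$mount_offset_p2 <= 60))
  expect_true(all(ex$runs$mount_offset[ex$runs$condition == "Position1"] == 0))
  # heights drawn from the participant population
  expect_equal(mean(ex$participants$height), 1.742, tolerance = 0.08)
})

test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(seed = 76L)
  e1 <- generate_experiment(2, cfg, conditions = "Position1")
  e2 <- generate_experiment(2, cfg, conditions = "Position1")
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$runs$imu[[1]], e2$runs$imu[[1]])
  expect_identical(e1$runs$traj[[3]], e2$runs$traj[[3]])
  # rendering is deterministic under an explicit seed
  cam <- cfg$cameras[[1]]
  fb <- floor_depth_image(cam)
  set.seed(9); f1 <- render_depth_frame(body_model(), c(1.5, 2.5, 0), cam, fb)
  set.seed(9); f2 <- render_depth_frame(body_model(), c(1.5, 2.5, 0), cam, fb)
  expect_identical(f1$depth, f2$depth)
})
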