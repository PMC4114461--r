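test_that("GROE aligns the upright device with gravity within 0.5 deg in 5 s", {
  # expected waist mounting: device x up, so gravity lies along device -x and
  # the accelerometer reads +g on x
  imu <- tibble::tibble(t = seq(0.01, 5, by = 0.01), gx = 0, gy = 0, gz = 0,
                        ax = 9.81, ay = 0, az = 0)
  out <- run_orientation_filter(imu, "groe", beta = 0.5)
  xw <- quat_rotate(quat_normalize(last_quat(out)), c(1, 0, 0))
  tilt <- acos(min(1, xw[3])) * 180 / pi   # angle of device x from vertical
  expect_lt(tilt, 0.5)
})

test_that("with beta = 0 the filter reduces to gyro integration", {
  omega <- 0.7  # rad/s about the device z axis
  dt <- 0.005
  imu <- tibble::tibble(t = seq(dt, 2, by = dt), gx = 0, gy = 0, gz = omega,
                        ax = 0, ay = 0, az = 0)
  out <- run_orientation_filter(imu, "groe", beta = 0)
  q_true <- quat_from_axis_angle(c(0, 0, 1), omega * 2 * 180 / pi)
  ang <- rot_angle_deg(quat_to_matrix(quat_normalize(last_quat(out))),
                       quat_to_matrix(q_true))
  expect_lt(ang, 0.5)  # integration error O(dt)
})

test_that("GROE tilt RMSE under accelerometer noise stays below 1 deg", {
  set.seed(10)
  q_true <- quat_from_axis_angle(c(0, 1, 0), 25)  # known static tilt
  Rdw <- quat_to_matrix(q_true)
  g_dev <- as.numeric(t(Rdw) %*% c(0, 0, 9.81))
  n <- 1500
  imu <- tibble::tibble(t = seq_len(n) / 100, gx = 0, gy = 0, gz = 0,
                        ax = g_dev[1] + rnorm(n, 0, 0.05),
                        ay = g_dev[2] + rnorm(n, 0, 0.05),
                        az = g_dev[3] + rnorm(n, 0, 0.05))
  out <- run_orientation_filter(imu, "groe", beta = 0.1)
  # converged tail: compare predicted gravity direction with truth
  tail_idx <- seq(n - 500, n)
  errs <- vapply(tail_idx, function(i) {
    q <- quat_normalize(c(out$qw[i], out$qx[i], out$qy[i], out$qz[i]))
    zhat <- quat_rotate(q, g_dev / sqrt(sum(g_dev^2)))
    acos(min(1, zhat[3])) * 180 / pi
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 1)
})

test_that("AOE converges to the TRIAD closed-form attitude within 1 deg", {
  set.seed(11)
  # random attitudes, filter started from the closed-form initialization
  for (i in 1:5) {
    q_true <- quat_normalize(rnorm(4))
    Rdw <- quat_to_matrix(q_true)
    imu <- static_marg_stream(Rdw, duration = 8)
    out <- run_orientation_filter(imu, "aoe", beta = 0.3,
                                  q0 = init_orientation(imu))
    R_triad <- triad_oracle(c(imu$ax[1], imu$ay[1], imu$az[1]),
                            c(imu$mx[1], imu$my[1], imu$mz[1]))
    ang <- rot_angle_deg(quat_to_matrix(quat_normalize(last_quat(out))), R_triad)
    expect_lt(ang, 1)
  }
  # gradient descent also converges from an uninformed identity start
  q_true <- quat_from_axis_angle(c(1, 0.3, 0.2), 120)
  imu <- static_marg_stream(quat_to_matrix(q_true), duration = 40)
  out <- run_orientation_filter(imu, "aoe", beta = 0.5)
  R_triad <- triad_oracle(c(imu$ax[1], imu$ay[1], imu$az[1]),
                          c(imu$mx[1], imu$my[1], imu$mz[1]))
  expect_lt(rot_angle_deg(quat_to_matrix(quat_normalize(last_quat(out))), R_triad), 1)
})

test_that("rotating the magnetic input horizontally shifts the AOE heading equally", {
  q_up <- quat(1, 0, 0, 0)  # device frame = world frame
  imu1 <- static_marg_stream(quat_to_matrix(q_up), duration = 8)
  # same device, but the field rotated 90 deg in the horizontal plane
  imu2 <- imu1
  mh <- cos(67 * pi / 180)
  imu2$mx <- 0; imu2$my <- mh  # North component moved to +y
  o1 <- run_orientation_filter(imu1, "aoe", beta = 0.3)
  o2 <- run_orientation_filter(imu2, "aoe", beta = 0.3)
  h1 <- projected_heading_track(o1)
  h2 <- projected_heading_track(o2)
  d <- abs(signed_angle_diff(h2[length(h2)], h1[length(h1)]))
  expect_equal(d, 90, tolerance = 1)
})

test_that("AOE bounds gyro-bias heading drift that pure integration accumulates", {
  bias <- 0.02  # rad/s about the vertical axis
  n <- 6000     # 60 s at 100 Hz
  imu <- static_marg_stream(diag(3), duration = 60)
  imu$gz <- imu$gz + bias
  aoe <- run_orientation_filter(imu, "aoe", beta = 0.041)
  pure <- run_orientation_filter(imu, "groe", beta = 0)
  h_aoe <- projected_heading_track(aoe)
  h_pure <- projected_heading_track(pure)
  err_aoe <- abs(signed_angle_diff(h_aoe[n], 90))   # device y starts at +y (heading 90)
  err_pure <- abs(signed_angle_diff(h_pure[n], 90))
  expect_lt(err_aoe, 5)
  expect_gt(err_pure, 55)  # ~69 deg drift expected from 0.02 rad/s over 60 s
})

test_that("projected device axes follow the documented conventions", {
  # device upright (x up), y along the frame y-axis (heading 90)
  Rdw <- cbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))
  est <- list(q = quat_from_matrix(Rdw))
  pr <- project_device_axes(est)
  expect_equal(pr$theta_i, 90, tolerance = 1e-9)
  expect_equal(sqrt(sum(pr$y_prime^2)), 1, tolerance = 1e-12)
  expect_equal(pr$y_prime[3], 0)

  # tilting about the projected y axis leaves the projection direction intact
  tilt <- quat_from_axis_angle(c(0, 1, 0), 10)
  est2 <- list(q = quat_normalize(quat_mul(tilt, quat_from_matrix(Rdw))))
  pr2 <- project_device_axes(est2)
  expect_equal(pr2$theta_i, 90, tolerance = 1e-6)

  # degenerate: device y within 5 deg of vertical
  Rdeg <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  expect_error(project_device_axes(list(q = quat_from_matrix(Rdeg))), "degenerate")
})

test_that("theta_i matches a brute-force project-and-normalize oracle", {
  set.seed(12)
  for (i in 1:100) {
    q <- quat_normalize(rnorm(4))
    yw <- rotmat_oracle(q) %*% c(0, 1, 0)
    if (sqrt(sum(yw[1:2]^2)) < 0.1) next
    ref <- (atan2(yw[2], yw[1]) * 180 / pi) %% 360
    expect_equal(project_device_axes(list(q = q))$theta_i, ref, tolerance = 1e-6)
  }
})

test_that("device compass heading alpha follows the frame conventions", {
  # device y pointing North (world x): alpha = 0
  Rn <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  expect_equal(device_heading_alpha(list(q = quat_from_matrix(Rn))), 0, tolerance = 1e-9)
  # device y pointing East (90 deg clockwise from North viewed from above,
  # i.e. -90 counterclockwise): alpha = 270 under the CCW convention
  Re <- cbind(c(0, 0, 1), c(0, -1, 0), c(1, 0, 0))
  expect_equal(device_heading_alpha(list(q = quat_from_matrix(Re))), 270, tolerance = 1e-9)
})

test_that("filters preserve quaternion norm and GROE is yaw-gauge invariant", {
  set.seed(13)
  imu <- static_marg_stream(diag(3), duration = 3, accel_sd = 0.05,
                            gyro_sd = 0.01, mag_sd = 0.01)
  out <- run_orientation_filter(imu, "aoe")
  norms <- sqrt(out$qw^2 + out$qx^2 + out$qy^2 + out$qz^2)
  expect_true(all(abs(norms - 1) < 1e-9))

  # pre-rotating the initial quaternion about the vertical changes no tilt
  tilt_of <- function(q0) {
    o <- run_orientation_filter(imu[, 1:7], "groe", beta = 0.2, q0 = q0)
    q <- quat_normalize(last_quat(o))
    zd <- quat_rotate(quat_conj(q), c(0, 0, 1))
    acos(min(1, zd[3])) * 180 / pi
  }
  g1 <- tilt_of(c(1, 0, 0, 0))
  g2 <- tilt_of(as.numeric(quat_from_axis_angle(c(0, 0, 1), 123)))
  expect_equal(g1, g2, tolerance = 1e-6)
})

test_that("AOE static fixed point: consistent inputs leave the estimate unchanged", {
  q <- quat_from_axis_angle(c(1, 1, 0), 30)
  Rdw <- quat_to_matrix(q)
  g_dev <- as.numeric(t(Rdw) %*% c(0, 0, 1))
  m_w <- c(cos(67 * pi / 180), 0, -sin(67 * pi / 180))
  m_dev <- as.numeric(t(Rdw) %*% m_w)
  est <- list(q = q, t = 0)
  s <- list(t = 0.01, gx = 0, gy = 0, gz = 0,
            ax = g_dev[1], ay = g_dev[2], az = g_dev[3],
            mx = m_dev[1], my = m_dev[2], mz = m_dev[3])
  out <- aoe_step(est, s, beta = 0.5)
  expect_equal(as.numeric(out$q), as.numeric(q), tolerance = 1e-6)
})

test_that("step functions validate their inputs", {
  est <- list(q = quat(1, 0, 0, 0), t = 1)
  s <- list(t = 0.5, gx = 0, gy = 0, gz = 0, ax = 0, ay = 0, az = 9.81,
            mx = NA, my = NA, mz = NA)
  expect_error(groe_step(est, s), "dt > 0")
  s$t <- 1.5
  expect_error(aoe_step(est, s), "groe_step")
  # zero specific force: gyro-only integration, no error
  s0 <- list(t = 1.5, gx = 0, gy = 0, gz = 0.1, ax = 0, ay = 0, az = 0)
  expect_silent(groe_step(est, s0))
})

test_that("AOE recovers headings on noisy simulated MARG walks within 2 deg RMSE", {
  cfg <- sim_config(seed = 21L)
  scripts <- fog_walk_scripts()
  set.seed(21)
  inst <- fogtrack:::instantiate_walk(scripts[scripts$walk == "L", ],
                                      attr(scripts, "starts")$L, cfg)
  sim <- simulate_trajectory(inst, cfg)
  imu <- simulate_imu(sim$traj, 0, cfg)
  aoe <- run_orientation_filter(imu, "aoe", q0 = init_orientation(imu))
  alpha <- projected_heading_track(aoe)
  errs <- vapply(seq_len(nrow(sim$stops)), function(i) {
    s <- sim$stops[i, ]
    sel <- imu$t >= (s$t_start + s$t_end) / 2 - 0.5 &
      imu$t <= (s$t_start + s$t_end) / 2 + 0.5
    signed_angle_diff(circular_mean(alpha[sel]), s$heading)
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 2)
})

test_that("IMU CSV streams round-trip", {
  imu <- static_marg_stream(diag(3), duration = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_imu_csv(imu, f)
  back <- read_imu_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(imu), tolerance = 1e-12)
})
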