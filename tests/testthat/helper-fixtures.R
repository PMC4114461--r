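# Shared fixtures: everything is generated in code, cached once per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A quickly trained classifier for unit tests (small grid, short schedule);
# the acceptance suite trains the full one separately.
small_classifier <- function() {
  fixture("small_classifier", function() {
    cfg <- sim_config(seed = 11L)
    set.seed(77)
    bodies <- lapply(c(1.62, 1.75, 1.88), function(h) body_model(height = h))
    gx <- seq(-1.5, 1.5, by = 0.75)
    gy <- seq(2.5, 5.0, by = 0.75)
    pos <- cbind(rep(gx, length(gy)), rep(gy, each = length(gx)))
    train <- generate_template_dataset(bodies, cfg$cameras[[1]], positions = pos,
                                       config = cfg, repeats = 1L, jitter_deg = 8)
    model <- train_heading_classifier(as.matrix(train[, paste0("f", 1:443)]),
                                      train$label, epochs = 80L, seed = 5L)
    list(model = model, train = train, config = cfg)
  })
}

# rotation-matrix oracle for quaternion rotation
rotmat_oracle <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# independent TRIAD attitude solution from a gravity/field vector pair,
# written directly from the vector algebra (not via package helpers)
triad_oracle <- function(a_dev, m_dev, mag_dip_deg = 67) {
  norm <- function(v) v / sqrt(sum(v * v))
  crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  t1d <- norm(a_dev)
  t2d <- norm(crossp(t1d, norm(m_dev)))
  t3d <- crossp(t1d, t2d)
  g_w <- c(0, 0, 1)
  m_w <- c(cos(mag_dip_deg * pi / 180), 0, -sin(mag_dip_deg * pi / 180))
  t1w <- g_w
  t2w <- norm(crossp(t1w, m_w))
  t3w <- crossp(t1w, t2w)
  cbind(t1w, t2w, t3w) %*% t(cbind(t1d, t2d, t3d))  # device -> world
}

# angle (deg) between two rotations given as device->world matrices
rot_angle_deg <- function(R1, R2) {
  R <- t(R1) %*% R2
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# synthetic MARG stream for a device held at a fixed device->world rotation
static_marg_stream <- function(Rdw, duration = 5, rate = 100, accel_sd = 0,
                               mag_sd = 0, gyro_sd = 0, mag_dip_deg = 67) {
  n <- duration * rate
  g_dev <- as.numeric(t(Rdw) %*% c(0, 0, 9.81))
  m_w <- c(cos(mag_dip_deg * pi / 180), 0, -sin(mag_dip_deg * pi / 180))
  m_dev <- as.numeric(t(Rdw) %*% m_w)
  tibble::tibble(
    t = seq_len(n) / rate,
    gx = rnorm(n, 0, gyro_sd), gy = rnorm(n, 0, gyro_sd), gz = rnorm(n, 0, gyro_sd),
    ax = g_dev[1] + rnorm(n, 0, accel_sd),
    ay = g_dev[2] + rnorm(n, 0, accel_sd),
    az = g_dev[3] + rnorm(n, 0, accel_sd),
    mx = m_dev[1] + rnorm(n, 0, mag_sd),
    my = m_dev[2] + rnorm(n, 0, mag_sd),
    mz = m_dev[3] + rnorm(n, 0, mag_sd)
  )
}

last_quat <- function(qtbl) {
  n <- nrow(qtbl)
  c(qtbl$qw[n], qtbl$qx[n], qtbl$qy[n], qtbl$qz[n])
}

# noise-free simulation configuration
noise_free_config <- function(seed = 1L) {
  sim_config(accel_noise = 0, gyro_noise = 0, mag_noise = 0, gyro_bias_sd = 0,
             mount_tilt_sd = 0, pos_jitter_sd = 0, heading_jitter_sd = 0,
             depth_noise_coef = 0, seed = seed)
}

# plan-view maps built directly from a point list (tracking frame)
maps_from_points <- function(pts, cell = 0.05, cutoff = 0,
                             bounds = c(0, 2, 0, 2), weights = NULL) {
  build_plan_view_maps(pts, cell = cell, cutoff = cutoff, bounds = bounds,
                       weights = weights)
}
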