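# Independent oracles used across test files. Kept free of any package
# internals they are checking against.

G0 <- 9.80665

# --- quaternion integration oracle (attitude from gyro only) ---------------

qmul <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}

qconj <- function(q) c(q[1], -q[2:4])

# rotate vector v by quaternion q
qrot <- function(q, v) {
  qmul(qmul(q, c(0, v)), qconj(q))[2:4]
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# integrate body angular rates (deg/s, N x 3) from initial quaternion
# q0 (world-from-body); returns the body-frame "up" trace (world +z seen
# from the body) as an N x 3 matrix
quat_up_trace <- function(t, gyro_dps, q0 = c(1, 0, 0, 0)) {
  n <- length(t)
  up <- matrix(0, n, 3)
  q <- q0
  up[1, ] <- qrot(qconj(q), c(0, 0, 1))
  for (i in 2:n) {
    w <- 0.5 * (gyro_dps[i - 1, ] + gyro_dps[i, ]) * pi / 180
    wn <- sqrt(sum(w^2))
    dt <- t[i] - t[i - 1]
    if (wn * dt > 0)
      q <- qmul(q, quat_from_axis_angle(w / wn, wn * dt))
    up[i, ] <- qrot(qconj(q), c(0, 0, 1))
  }
  up
}

# --- misc helpers -----------------------------------------------------------

random_rotation <- function() {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# wide cohort-style table with gaussian features (never trips cleaning)
make_plain_cohort <- function(n = 20, seed = 1) {
  set.seed(seed)
  vars <- c("ah_rms", "av_rms", "wh_rms", "wv_rms", "alpha_rom", "gamma_rom")
  d <- data.frame(subject_id = sprintf("S%02d", seq_len(n)))
  for (v in vars)
    for (ph in c("pt", "s", "rm"))
      d[[paste(v, ph, sep = "_")]] <- rnorm(n, mean = 10, sd = 2)
  d$fear_pt <- rnorm(n, 9, 2)
  d$fear_at <- rnorm(n, 8, 2)
  d
}
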