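#' Estimate torso orientation from fused accelerometer and gyroscope data
#'
#' Tracks the gravity direction in the sensor frame with a complementary
#' filter: each step propagates the estimate by the gyroscope rotation
#' (exact Rodrigues update on the trapezoidal mean rate) and then blends
#' it toward the normalized accelerometer vector with per-step weight
#' `gain`. From the gravity estimate it derives the tilt angle `alpha`
#' (angle between the estimated up direction and the sensor axis
#' designated "up", in degrees, in \[0, 180\]) and the yaw angle `gamma`
#' (time integral of the angular-rate component along the vertical,
#' anchored at 0 at the first sample). Without a magnetometer the yaw
#' zero is arbitrary; only its range of motion is meaningful downstream.
#'
#' Samples with zero-norm accelerometer readings skip the blend
#' (gyro-only propagation) and are counted in the `n_blend_skipped`
#' attribute.
#'
#' @param rec An [imu_recording()].
#' @param gain Blend weight per sample, in (0, 1\]. The default 0.02 is
#'   chosen for 100 Hz data (time constant about 0.5 s).
#' @param up_axis Sensor axis pointing up when the wearer stands
#'   upright: one of `"+x","-x","+y","-y","+z","-z"` or a unit 3-vector.
#'   Belt mounting determines this; `"+z"` by default.
#' @param prefilter Optional low-pass prefilter applied to accelerometer
#'   and gyro before fusion: `NULL` (default, off) or a list
#'   `list(cutoff_hz =, order =)` for a zero-phase Butterworth filter.
#' @return An object of class `orientation_trace` with fields `t`,
#'   `alpha` (deg), `gamma` (deg, continuous), and `g_hat` (N x 3 unit
#'   vectors, estimated gravity --- i.e. down --- direction in the sensor
#'   frame).
#' @export
#' @examples
#' rec <- simulate_fixture("tilted_static", list(tilt_deg = 30))
#' orient <- estimate_orientation(rec)
#' range(orient$alpha)
estimate_orientation <- function(rec, gain = 0.02, up_axis = "+z",
                                 prefilter = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!(is.numeric(gain) && length(gain) == 1 && gain > 0 && gain <= 1))
    stop("gain must be a single number in (0, 1]")
  up <- parse_axis(up_axis)
  accel <- rec$accel
  gyro <- rec$gyro
  if (!is.null(prefilter)) {
    accel <- apply_lowpass(accel, rec$sample_rate, prefilter)
    gyro <- apply_lowpass(gyro, rec$sample_rate, prefilter)
  }
  U <- comp_filter_up(accel, gyro, rec$t, gain, up)
  n_skipped <- sum(rowSums(accel^2) <= 1e-18)
  if (n_skipped > 0)
    message("estimate_orientation: ", n_skipped,
            " zero-norm accelerometer samples (blend skipped)")
  alpha <- deg(acos(pmin(1, pmax(-1, as.numeric(U %*% up)))))
  w_v <- rowSums(gyro * U)
  gamma <- cumtrapz1(rec$t, w_v)
  structure(
    list(t = rec$t, alpha = alpha, gamma = gamma, g_hat = -U,
         n_blend_skipped = n_skipped),
    class = "orientation_trace"
  )
}

#' @export
print.orientation_trace <- function(x, ...) {
  cat(sprintf("<orientation_trace> %d samples; alpha [%.2f, %.2f] deg; gamma range %.2f deg\n",
              length(x$t), min(x$alpha), max(x$alpha), rom(x$gamma)))
  invisible(x)
}

# zero-phase Butterworth low-pass on each column
apply_lowpass <- function(m, fs, prefilter) {
  cutoff <- prefilter$cutoff_hz
  order <- prefilter$order %||% 4
  stopifnot(is.numeric(cutoff), cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  apply(m, 2, function(x) signal::filtfilt(bf, x))
}

#' Decompose motion into vertical and horizontal components
#'
#' Projects sensor-frame acceleration and angular rate onto the estimated
#' vertical: with u the estimated up direction (`-g_hat`),
#' `a_v = accel . u - g0` (gravity-compensated vertical acceleration),
#' `a_h = || accel - (accel . u) u ||` (horizontal-plane acceleration
#' magnitude), `w_v = gyro . u` (turning rate about the vertical) and
#' `w_h = || gyro - w_v u ||` (tilting rate magnitude), with
#' g0 = 9.80665 m/s^2.
#'
#' @param rec An [imu_recording()].
#' @param orient The matching [estimate_orientation()] output (same time
#'   base).
#' @return An object of class `decomposed_motion` with fields `t`, `a_v`,
#'   `a_h` (m/s^2), `w_v`, `w_h` (deg/s); `a_h` and `w_h` are
#'   nonnegative.
#' @export
decompose_motion <- function(rec, orient) {
  stopifnot(inherits(rec, "imu_recording"),
            inherits(orient, "orientation_trace"))
  if (length(rec$t) != length(orient$t) ||
      max(abs(rec$t - orient$t)) > 1e-9)
    stop("recording and orientation trace do not share a time base")
  U <- -orient$g_hat
  a_up <- rowSums(rec$accel * U)
  a_v <- a_up - .g0
  a_h <- sqrt(pmax(0, rowSums(rec$accel^2) - a_up^2))
  w_v <- rowSums(rec$gyro * U)
  w_h <- sqrt(pmax(0, rowSums(rec$gyro^2) - w_v^2))
  structure(
    list(t = rec$t, a_v = a_v, a_h = a_h, w_v = w_v, w_h = w_h),
    class = "decomposed_motion"
  )
}
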