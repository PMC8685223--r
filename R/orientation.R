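#' Complementary orientation update
#'
#' One step of a drift-stable accelerometer/gyroscope fusion: the
#' previous orientation is propagated by strap-down integration of the
#' angular rate and then tilted toward the measured gravity direction by
#' a small complementary gain. The correction axis is horizontal, so the
#' heading (yaw) is never constrained and drifts slowly, as expected
#' without a magnetometer.
#'
#' @param prev_q unit quaternion, sensor to global.
#' @param acc sensor-frame specific force, m/s^2 (gravity included).
#' @param gyro sensor-frame angular rate, rad/s.
#' @param dt time step, s.
#' @param tau_acc accelerometer correction time constant, s. The static
#'   tilt error decays with this constant; the default 0.5 s gives
#'   convergence in about 2 s. Use `Inf` for pure gyro integration.
#' @param acc_gate correction is applied only when the specific-force
#'   norm is within `acc_gate` (m/s^2) of gravity, so that linear
#'   accelerations during swing do not tilt the estimate; `Inf`
#'   disables the gate.
#' @param g gravity magnitude used by the gate, m/s^2.
#' @return unit quaternion.
#' @export
update_orientation <- function(prev_q, acc, gyro, dt, tau_acc = 0.5,
                               acc_gate = 0.5, g = 9.81) {
  stopifnot(dt > 0)
  wnorm <- sqrt(sum(gyro^2))
  q <- if (wnorm * dt > 1e-12) {
    quat_multiply(prev_q, quat_from_axis_angle(gyro, wnorm * dt))
  } else prev_q
  anorm <- sqrt(sum(acc^2))
  if (is.finite(tau_acc) && anorm > 1e-6 && abs(anorm - g) < acc_gate) {
    k <- dt / tau_acc
    v <- quat_rotate(q, acc / anorm)      # measured gravity dir, global frame
    axis <- c(v[2], -v[1], 0)             # v x e_z: horizontal, yaw-free
    s <- sqrt(sum(axis^2))
    if (s > 1e-12) {
      angle <- atan2(s, v[3])
      q <- quat_multiply(quat_from_axis_angle(axis, k * angle), q)
    }
  }
  quat_normalize(q)
}

#' Transform a sample into the global frame and detrend it
#'
#' Rotates acceleration and angular rate into the global frame, removes
#' gravity `(0, 0, g)` from the acceleration, and subtracts the
#' rest-phase offsets from the vectors and from the Euler angles.
#'
#' @param acc,gyro sensor-frame sample.
#' @param q orientation quaternion for this sample.
#' @param offsets a [rest_offsets()] object (zero before the first rest).
#' @param g gravity magnitude, m/s^2.
#' @return list with `a_g`, `w_g` (global, gravity-free acceleration),
#'   `a_dg`, `w_dg` (detrended), `euler`, `euler_d` (radians,
#'   `c(yaw, pitch, roll)`).
#' @export
transform_and_detrend <- function(acc, gyro, q, offsets = rest_offsets(),
                                  g = 9.81) {
  a_g <- quat_rotate(q, acc) - c(0, 0, g)
  w_g <- quat_rotate(q, gyro)
  eul <- quat_to_euler(q)
  list(a_g = a_g, w_g = w_g,
       a_dg = a_g - offsets$acc_offset,
       w_dg = w_g - offsets$gyro_offset,
       euler = eul,
       euler_d = eul - offsets$euler_offset)
}

#' Rest-phase offsets
#'
#' Moving-average offsets of the global-frame acceleration (after
#' gravity removal), angular rate, and Euler angles, estimated only
#' while the state machine is in the rest phase and frozen otherwise.
#'
#' @param acc_offset,gyro_offset,euler_offset 3-vectors.
#' @param window moving-average window length in samples.
#' @return object of class `rest_offsets` holding the offsets and the
#'   internal sample buffers.
#' @export
rest_offsets <- function(acc_offset = c(0, 0, 0), gyro_offset = c(0, 0, 0),
                         euler_offset = c(0, 0, 0), window = 10L) {
  structure(list(acc_offset = acc_offset, gyro_offset = gyro_offset,
                 euler_offset = euler_offset, window = as.integer(window),
                 buf_acc = NULL, buf_gyro = NULL, buf_euler = NULL),
            class = "rest_offsets")
}

#' Update rest offsets with one sample
#'
#' While `in_rest`, the offsets become the mean of the last `window`
#' global-frame samples (fewer if the rest phase is younger than the
#' window); outside rest the offsets are frozen and the buffers cleared.
#'
#' @param offsets a [rest_offsets()] object.
#' @param a_g,w_g,euler global-frame sample (gravity-free acceleration,
#'   angular rate, Euler angles).
#' @param in_rest logical flag from the state machine.
#' @return updated `rest_offsets`.
#' @export
update_rest_offsets <- function(offsets, a_g, w_g, euler, in_rest) {
  if (!in_rest) {
    offsets$buf_acc <- offsets$buf_gyro <- offsets$buf_euler <- NULL
    return(offsets)
  }
  n <- offsets$window
  offsets$buf_acc <- rbind(offsets$buf_acc, a_g)
  offsets$buf_gyro <- rbind(offsets$buf_gyro, w_g)
  offsets$buf_euler <- rbind(offsets$buf_euler, euler)
  if (nrow(offsets$buf_acc) > n) {
    keep <- (nrow(offsets$buf_acc) - n + 1L):nrow(offsets$buf_acc)
    offsets$buf_acc <- offsets$buf_acc[keep, , drop = FALSE]
    offsets$buf_gyro <- offsets$buf_gyro[keep, , drop = FALSE]
    offsets$buf_euler <- offsets$buf_euler[keep, , drop = FALSE]
  }
  offsets$acc_offset <- colMeans(offsets$buf_acc)
  offsets$gyro_offset <- colMeans(offsets$buf_gyro)
  offsets$euler_offset <- colMeans(offsets$buf_euler)
  offsets
}

#' Jerk norm by backward difference
#'
#' @param a_dg_prev,a_dg_curr consecutive detrended global acceleration
#'   vectors, m/s^2.
#' @param dt time step, s.
#' @return jerk norm, m/s^3.
#' @export
compute_jerk <- function(a_dg_prev, a_dg_curr, dt) {
  stopifnot(dt > 0)
  sqrt(sum((a_dg_curr - a_dg_prev)^2)) / dt
}

#' Run the orientation pipeline over a whole recording
#'
#' Sequentially applies [update_orientation()] and
#' [transform_and_detrend()] with rest-gated offset estimation driven by
#' a caller-supplied rest flag (or with frozen zero offsets when
#' `in_rest = NULL`). Mainly a building block for [segment_recording()],
#' exposed for testing and debugging.
#'
#' @param series an [imu_series()].
#' @param in_rest logical vector (one per sample) or `NULL`.
#' @param params a [gpd_params()] (for the offset window `n_d`).
#' @param tau_acc see [update_orientation()].
#' @param g gravity magnitude, m/s^2.
#' @return data.frame with per-sample quaternion, Euler angles,
#'   detrended vectors and jerk norm.
#' @export
estimate_kinematics <- function(series, in_rest = NULL, params = gpd_params(),
                                tau_acc = 0.5, g = 9.81) {
  n <- length(series$t)
  dt <- 1 / series$fs
  q <- quat_from_accel(series$acc[1, ])
  off <- rest_offsets(window = params$n_d)
  out <- matrix(NA_real_, n, 17L)
  colnames(out) <- c("qw", "qx", "qy", "qz", "yaw", "pitch", "roll",
                     "yaw_d", "pitch_d", "roll_d",
                     "adgx", "adgy", "adgz", "wdgx", "wdgy", "wdgz", "jerk")
  prev_adg <- NULL
  for (i in seq_len(n)) {
    if (i > 1L) {
      gyro_mid <- 0.5 * (series$gyro[i - 1L, ] + series$gyro[i, ])
      q <- update_orientation(q, series$acc[i, ], gyro_mid, dt, tau_acc)
    }
    k <- transform_and_detrend(series$acc[i, ], series$gyro[i, ], q, off, g)
    rest_i <- if (is.null(in_rest)) FALSE else isTRUE(in_rest[i])
    off <- update_rest_offsets(off, k$a_g, k$w_g, k$euler, rest_i)
    jerk <- if (is.null(prev_adg)) 0 else compute_jerk(prev_adg, k$a_dg, dt)
    prev_adg <- k$a_dg
    out[i, ] <- c(q, k$euler, k$euler_d, k$a_dg, k$w_dg, jerk)
  }
  cbind(data.frame(t = series$t), as.data.frame(out))
}
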