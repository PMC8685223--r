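# Quaternion helpers. Convention: q = (w, x, y, z), unit norm, maps
# sensor-frame vectors into the global frame.

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps) stop("zero-norm quaternion", call. = FALSE)
  q / n
}

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(c(1, 0, 0, 0))
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

# Rotate a sensor-frame vector into the global frame.
quat_rotate <- function(q, v) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  # R(q) %*% v, expanded
  c((1 - 2 * (y^2 + z^2)) * v[1] + 2 * (x * y - w * z) * v[2] + 2 * (x * z + w * y) * v[3],
    2 * (x * y + w * z) * v[1] + (1 - 2 * (x^2 + z^2)) * v[2] + 2 * (y * z - w * x) * v[3],
    2 * (x * z - w * y) * v[1] + 2 * (y * z + w * x) * v[2] + (1 - 2 * (x^2 + y^2)) * v[3])
}

quat_rotate_inverse <- function(q, v) quat_rotate(quat_conjugate(q), v)

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Euler angles of a foot orientation quaternion
#'
#' Decomposes the rotation as intrinsic z-x'-y'': yaw about the vertical
#' axis, pitch about the mediolateral (sensor x) axis, roll about the
#' foot's long (sensor y) axis. With the sensor mounted z-up and y
#' pointing against the walking direction, pitch is positive when the
#' heel is above the toes.
#'
#' @param q unit quaternion `c(w, x, y, z)` mapping sensor to global frame.
#' @return named numeric vector `c(yaw, pitch, roll)` in radians.
#' @export
quat_to_euler <- function(q) {
  R <- quat_to_matrix(q)
  s2 <- max(-1, min(1, R[3, 2]))
  pitch <- asin(s2)
  yaw <- atan2(-R[1, 2], R[2, 2])
  roll <- atan2(-R[3, 1], R[3, 3])
  c(yaw = yaw, pitch = pitch, roll = roll)
}

# Quaternion for intrinsic z-x'-y'' angles (inverse of quat_to_euler).
euler_to_quat <- function(yaw, pitch, roll) {
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw)
  qx <- quat_from_axis_angle(c(1, 0, 0), pitch)
  qy <- quat_from_axis_angle(c(0, 1, 0), roll)
  quat_multiply(quat_multiply(qz, qx), qy)
}

# Tilt-only quaternion aligning the measured specific force (sensor
# frame, gravity included) with the global +z axis. Yaw is left at zero.
quat_from_accel <- function(acc) {
  n <- sqrt(sum(acc^2))
  if (n < .Machine$double.eps) return(c(1, 0, 0, 0))
  u <- acc / n
  ez <- c(0, 0, 1)
  axis <- c(u[2] * 1 - u[3] * 0, u[3] * 0 - u[1] * 1, u[1] * 0 - u[2] * 0) # u x ez
  ca <- max(-1, min(1, u[3]))
  angle <- acos(ca)
  if (sqrt(sum(axis^2)) < 1e-12) {
    if (ca > 0) return(c(1, 0, 0, 0))
    return(c(0, 1, 0, 0)) # upside down: 180 deg about x
  }
  quat_from_axis_angle(axis, angle)
}
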