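# Rotation conventions used throughout the package.
#
# Orientation is stored as Tait-Bryan angles (yaw, pitch, roll) in degrees,
# composed intrinsically in Z-Y'-X'' order: R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll).
# Body axes: x forward, y left, z up.  Consequences of the sign conventions:
#   * positive yaw   = left turn (counter-clockwise seen from above),
#   * positive pitch = head down (nose rotates towards -z),
#   * positive roll  = right/clockwise roll seen from behind.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# world-from-body rotation matrix for angles in degrees
euler_to_matrix <- function(yaw, pitch, roll) {
  rot_z(deg2rad(yaw)) %*% rot_y(deg2rad(pitch)) %*% rot_x(deg2rad(roll))
}

# inverse of euler_to_matrix; returns c(yaw, pitch, roll) in degrees.
# Gimbal lock (|pitch| = 90 deg) resolved by assigning roll = 0.
matrix_to_euler <- function(R) {
  sp <- -R[3, 1]
  sp <- min(1, max(-1, sp))
  pitch <- asin(sp)
  if (abs(sp) > 1 - 1e-12) {
    yaw <- atan2(-R[1, 2], R[2, 2])
    roll <- 0
  } else {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  }
  rad2deg(c(yaw = yaw, pitch = pitch, roll = roll))
}

# Rotation-vector (axis * angle, radians) to rotation matrix (Rodrigues).
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) {
    K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
    return(diag(3) + K)
  }
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Matrix logarithm of a rotation: rotation vector in radians.
matrix_to_rotvec <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  th <- acos(ca)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (th < 1e-7) {
    # first-order: R ~ I + [w]_x
    return(v / 2)
  }
  v * th / (2 * sin(th))
}

# Vectorised world-from-body rotation entries for angle vectors (degrees).
# Returns a list of nine numeric vectors R11..R33 (row, column indexing).
euler_to_matrix_vec <- function(yaw, pitch, roll) {
  cy <- cos(deg2rad(yaw));  sy <- sin(deg2rad(yaw))
  cp <- cos(deg2rad(pitch)); sp <- sin(deg2rad(pitch))
  cr <- cos(deg2rad(roll)); sr <- sin(deg2rad(roll))
  list(
    R11 = cy * cp, R12 = cy * sp * sr - sy * cr, R13 = cy * sp * cr + sy * sr,
    R21 = sy * cp, R22 = sy * sp * sr + cy * cr, R23 = sy * sp * cr - cy * sr,
    R31 = -sp,     R32 = cp * sr,                R33 = cp * cr
  )
}
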