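# Vectorized 3x3 rotation algebra over time series.
#
# A "rotation track" is a list of nine numeric vectors r11..r33 holding the
# entries of R(t) (body -> world, active, right-handed) for every sample.
# Keeping components as flat vectors lets whole recordings be composed and
# differentiated without per-sample loops.

rot_identity <- function(n) {
  z <- rep(0, n); o <- rep(1, n)
  list(r11 = o, r12 = z, r13 = z,
       r21 = z, r22 = o, r23 = z,
       r31 = z, r32 = z, r33 = o)
}

rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a); z <- rep(0, length(a)); o <- rep(1, length(a))
  list(r11 = o, r12 = z,  r13 = z,
       r21 = z, r22 = c_, r23 = -s_,
       r31 = z, r32 = s_, r33 = c_)
}

rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a); z <- rep(0, length(a)); o <- rep(1, length(a))
  list(r11 = c_,  r12 = z, r13 = s_,
       r21 = z,   r22 = o, r23 = z,
       r31 = -s_, r32 = z, r33 = c_)
}

rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a); z <- rep(0, length(a)); o <- rep(1, length(a))
  list(r11 = c_, r12 = -s_, r13 = z,
       r21 = s_, r22 = c_,  r23 = z,
       r31 = z,  r32 = z,   r33 = o)
}

rot_mult <- function(a, b) {
  list(
    r11 = a$r11 * b$r11 + a$r12 * b$r21 + a$r13 * b$r31,
    r12 = a$r11 * b$r12 + a$r12 * b$r22 + a$r13 * b$r32,
    r13 = a$r11 * b$r13 + a$r12 * b$r23 + a$r13 * b$r33,
    r21 = a$r21 * b$r11 + a$r22 * b$r21 + a$r23 * b$r31,
    r22 = a$r21 * b$r12 + a$r22 * b$r22 + a$r23 * b$r32,
    r23 = a$r21 * b$r13 + a$r22 * b$r23 + a$r23 * b$r33,
    r31 = a$r31 * b$r11 + a$r32 * b$r21 + a$r33 * b$r31,
    r32 = a$r31 * b$r12 + a$r32 * b$r22 + a$r33 * b$r32,
    r33 = a$r31 * b$r13 + a$r32 * b$r23 + a$r33 * b$r33
  )
}

# Rotate world-frame vector components into the body frame: v_body = R^T v.
rot_apply_t <- function(r, vx, vy, vz) {
  list(x = r$r11 * vx + r$r21 * vy + r$r31 * vz,
       y = r$r12 * vx + r$r22 * vy + r$r32 * vz,
       z = r$r13 * vx + r$r23 * vy + r$r33 * vz)
}

# Rotate body-frame components into the world frame: v_world = R v.
rot_apply <- function(r, vx, vy, vz) {
  list(x = r$r11 * vx + r$r12 * vy + r$r13 * vz,
       y = r$r21 * vx + r$r22 * vy + r$r23 * vz,
       z = r$r31 * vx + r$r32 * vy + r$r33 * vz)
}

# Central difference with one-sided differences at the ends.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  num <- x[c(2:n, n)] - x[c(1L, 1:(n - 1L))]
  den <- dt * c(1, rep(2, max(n - 2L, 0L)), 1)
  num / den
}

# Body-frame angular velocity (rad/s) recovered from a rotation track via the
# kinematic identity skew(omega) = R^T dR/dt, differentiated numerically.
rot_to_angular_velocity <- function(r, fs) {
  dt <- 1 / fs
  d <- lapply(r, central_diff, dt = dt)
  list(
    x = r$r13 * d$r12 + r$r23 * d$r22 + r$r33 * d$r32,
    y = r$r11 * d$r13 + r$r21 * d$r23 + r$r31 * d$r33,
    z = r$r12 * d$r11 + r$r22 * d$r21 + r$r32 * d$r31
  )
}

# Single fixed rotation (3x3 matrix) from XYZ Euler angles in radians.
rot_matrix_xyz <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}
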