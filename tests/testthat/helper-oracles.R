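# Independent geometric oracles, written directly from textbook formulas so
# they share no code with the package internals.

# 3x3 rotation matrix from axis + angle via the Rodrigues formula
oracle_rotmat <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# 3x3 rotation matrix of a unit quaternion (standard expansion)
oracle_quat_to_rotmat <- function(q) {
  q <- unclass(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_quat <- function(unit = TRUE) {
  q <- stats::rnorm(4)
  if (unit) q <- q / sqrt(sum(q^2))
  quaternion(q[1], q[2], q[3], q[4])
}

# apply a fixed rotation matrix to every sample of a trace
rotate_trace <- function(trace, R) {
  A <- cbind(trace$ax, trace$ay, trace$az) %*% t(R)
  accel_trace(trace$t, A[, 1], A[, 2], A[, 3], trace$sample_rate)
}

# a short trace that is constant at the given axis vector
constant_trace <- function(v, duration_s = 2, fs = 100) {
  n <- duration_s * fs
  accel_trace((seq_len(n) - 1) / fs, rep(v[1], n), rep(v[2], n),
              rep(v[3], n), sample_rate = fs)
}
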