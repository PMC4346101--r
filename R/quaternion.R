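#' Construct a quaternion
#'
#' A quaternion \eqn{Q = q_0 + q_1 i + q_2 j + q_3 k} stored scalar-first.
#' Unit quaternions encode 3-D rotations: a rotation by angle \eqn{\theta}
#' about a unit axis \eqn{(x, y, z)} is
#' \eqn{\cos(\theta/2) + \sin(\theta/2)(x i + y j + z k)}.
#'
#' @param q0 scalar part.
#' @param q1,q2,q3 vector parts along i, j, k.
#' @return An object of class `"quaternion"` (a named numeric vector of
#'   length 4).
#' @examples
#' quaternion(1, 0, 0, 0)            # identity rotation
#' quat_axis_angle(c(0, 0, 1), 90)   # 90 degrees about k
#' @export
quaternion <- function(q0, q1 = 0, q2 = 0, q3 = 0) {
  if (length(q0) == 4 && missing(q1)) {
    q <- as.numeric(q0)
  } else {
    q <- c(q0, q1, q2, q3)
  }
  stopifnot(length(q) == 4, is.numeric(q), all(is.finite(q)))
  structure(unname(as.numeric(q)), class = "quaternion")
}

#' @export
print.quaternion <- function(x, digits = 6, ...) {
  v <- signif(unclass(x), digits)
  cat(sprintf("<quaternion> %g %+gi %+gj %+gk  (|Q| = %g)\n",
              v[1], v[2], v[3], v[4], signif(quat_norm(x), digits)))
  invisible(x)
}

#' Quaternion magnitude
#'
#' \eqn{\|Q\| = \sqrt{q_0^2 + q_1^2 + q_2^2 + q_3^2}}.
#'
#' @param q a [quaternion()].
#' @return Non-negative scalar.
#' @export
quat_norm <- function(q) {
  sqrt(sum(unclass(q)^2))
}

#' Quaternion conjugate
#'
#' \eqn{Q^* = q_0 - q_1 i - q_2 j - q_3 k}. For any quaternion,
#' \eqn{Q \otimes Q^*} has scalar part \eqn{\|Q\|^2} and zero vector part.
#'
#' @param q a [quaternion()].
#' @return The conjugate quaternion.
#' @export
quat_conjugate <- function(q) {
  q <- unclass(q)
  quaternion(q[1], -q[2], -q[3], -q[4])
}

#' Hamilton product of two quaternions
#'
#' Computes \eqn{a \otimes b}. Equivalent to applying the 4x4 left-product
#' matrix of `a` (see [quat_matrix()]) to `b` viewed as a 4-vector.
#'
#' @param a,b quaternions.
#' @return The product quaternion.
#' @examples
#' i <- quaternion(0, 1, 0, 0); j <- quaternion(0, 0, 1, 0)
#' quat_multiply(i, j)  # = k
#' @export
quat_multiply <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  quaternion(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Left-multiplication matrix of a quaternion
#'
#' The 4x4 matrix \eqn{M(Q)} such that \eqn{Q \otimes P = M(Q) \, P} when
#' `P` is treated as the column vector \eqn{(p_0, p_1, p_2, p_3)^T}:
#' \deqn{M(Q) = \begin{pmatrix}
#'   q_0 & -q_1 & -q_2 & -q_3 \\
#'   q_1 &  q_0 & -q_3 &  q_2 \\
#'   q_2 &  q_3 &  q_0 & -q_1 \\
#'   q_3 & -q_2 &  q_1 &  q_0 \end{pmatrix}}
#'
#' @param q a [quaternion()].
#' @return A 4x4 numeric matrix.
#' @export
quat_matrix <- function(q) {
  q <- unclass(q)
  matrix(c(q[1], -q[2], -q[3], -q[4],
           q[2],  q[1], -q[4],  q[3],
           q[3],  q[4],  q[1], -q[2],
           q[4], -q[3],  q[2],  q[1]),
         nrow = 4, byrow = TRUE)
}

#' Unit quaternion from axis and angle
#'
#' @param axis numeric length-3 rotation axis (normalised internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return A unit [quaternion()].
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis must be non-zero")
  axis <- axis / n
  h <- angle_deg * pi / 360  # half angle in radians
  quaternion(cos(h), sin(h) * axis[1], sin(h) * axis[2], sin(h) * axis[3])
}

#' Rotation angle of a unit quaternion
#'
#' \eqn{\theta = 2 \arctan(\sqrt{q_1^2 + q_2^2 + q_3^2} / q_0)}, in degrees.
#' The arctangent is evaluated with the signed scalar part, so quaternions
#' with \eqn{q_0 < 0} yield negative angles; the quaternion sign is not
#' canonicalised. \eqn{q_0 = 0} returns exactly 180 (the limit case).
#'
#' @param q a unit [quaternion()].
#' @return Signed angle in degrees, in the interval (-180, 180].
#' @export
quat_angle <- function(q) {
  q <- unclass(q)
  m <- sqrt(q[2]^2 + q[3]^2 + q[4]^2)
  if (q[1] == 0) return(180)
  2 * atan(m / q[1]) * 180 / pi
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Sandwich product \eqn{v' = Q \otimes v \otimes Q^*}, with `v` embedded as
#' the pure quaternion \eqn{0 + v_x i + v_y j + v_z k}. Preserves the vector
#' magnitude.
#'
#' @param q a unit [quaternion()].
#' @param v numeric length-3 vector, or a [gravity_vector()].
#' @return A rotated object of the same kind as `v`.
#' @export
quat_rotate <- function(q, v) {
  gv <- inherits(v, "gravity_vector")
  vv <- if (gv) unclass(v)[1:3] else as.numeric(v)
  stopifnot(length(vv) == 3)
  p <- quat_multiply(quat_multiply(q, quaternion(0, vv[1], vv[2], vv[3])),
                     quat_conjugate(q))
  out <- unclass(p)[2:4]
  if (gv) gravity_vector(out[1], out[2], out[3]) else unname(out)
}

#' Construct a gravity vector
#'
#' The gravity estimate extracted from an accelerometer while the wearer is
#' still, in g-units. Represented for quaternion algebra as the pure
#' quaternion \eqn{g = 0 + g_x i + g_y j + g_z k}. Its direction encodes the
#' body orientation; its magnitude is close to 1 g when the wearer is truly
#' still.
#'
#' @param gx,gy,gz components in g-units.
#' @param source_window optional numeric length-2 `(start, end)` time window
#'   (seconds) the estimate was captured from.
#' @return An object of class `"gravity_vector"`.
#' @export
gravity_vector <- function(gx, gy, gz, source_window = NULL) {
  if (length(gx) == 3 && missing(gy)) {
    v <- as.numeric(gx)
  } else {
    v <- c(gx, gy, gz)
  }
  stopifnot(length(v) == 3, all(is.finite(v)))
  if (!is.null(source_window)) {
    stopifnot(length(source_window) == 2, source_window[1] <= source_window[2])
  }
  structure(unname(as.numeric(v)),
            source_window = source_window, class = "gravity_vector")
}

#' @export
print.gravity_vector <- function(x, digits = 4, ...) {
  v <- signif(unclass(x), digits)
  cat(sprintf("<gravity> (%g, %g, %g) g  |g| = %g g\n",
              v[1], v[2], v[3], signif(gravity_magnitude(x), digits)))
  w <- attr(x, "source_window")
  if (!is.null(w)) cat(sprintf("  captured over [%g, %g] s\n", w[1], w[2]))
  invisible(x)
}

#' Magnitude of a gravity vector
#'
#' @param g a [gravity_vector()] or numeric length-3 vector.
#' @return \eqn{\sqrt{g_x^2 + g_y^2 + g_z^2}} in g-units.
#' @export
gravity_magnitude <- function(g) {
  sqrt(sum(unclass(g)[1:3]^2))
}

as_gravity3 <- function(g) {
  v <- if (inherits(g, "gravity_vector")) unclass(g)[1:3] else as.numeric(g)
  stopifnot(length(v) == 3, all(is.finite(v)))
  unname(v)
}

#' Decompose the rotation between two gravity vectors
#'
#' Factors the rotation that carries the before-fall gravity direction onto
#' the after-fall gravity direction into three elementary unit quaternions
#' and extracts the total rotation angle:
#'
#' * `Q1` tilts the before-gravity direction into the horizontal (i, j)
#'   plane, rotating by the elevation
#'   \eqn{\theta_1 = \arctan(g_z / \sqrt{g_x^2 + g_y^2})} about the
#'   horizontal axis \eqn{(\sin\alpha, \cos\alpha, 0)} with
#'   \eqn{\sin\alpha = -g_y/\rho}, \eqn{\cos\alpha = g_x/\rho}.
#' * `Q2` rotates about k by the azimuth difference
#'   \eqn{\theta_2 = \mathrm{atan2}(g'_y, g'_x) - \mathrm{atan2}(g_y, g_x)}.
#' * `Q3` tilts back out of the horizontal plane by
#'   \eqn{\theta_3 = -\arctan(g'_z / \sqrt{g'^2_x + g'^2_y})} about
#'   \eqn{(\sin\beta, \cos\beta, 0)}.
#'
#' The composition \eqn{Q = Q_3 \otimes Q_2 \otimes Q_1} satisfies
#' \eqn{\hat g_{after} = Q \otimes \hat g_{before} \otimes Q^*}; the total
#' angle is \eqn{\theta = 2\arctan(\sqrt{q_1^2+q_2^2+q_3^2}/q_0)}. During a
#' fall from upright to lying \eqn{|\theta| \approx 90^\circ}, which is the
#' detector's second feature.
#'
#' Both inputs are normalised to unit length first; only directions matter,
#' which removes sensitivity to the +/-0.3 g capture tolerance. The azimuth
#' difference \eqn{\theta_2} is the raw difference of the two two-argument
#' arctangents (range (-360, 360) degrees) and is deliberately not wrapped:
#' wrapping only flips the sign of \eqn{\theta} (never its magnitude), and
#' the unwrapped form is what produces the negative angles seen when the
#' azimuth crosses the +/-180 degree cut.
#'
#' If either vector is within `eps_h` of vertical (horizontal norm
#' \eqn{\sqrt{g_x^2+g_y^2} < \epsilon_h}), the corresponding axis angle
#' \eqn{\alpha} (or \eqn{\beta}) is undefined (0/0); the axis is then taken
#' as j, the azimuth as 0 and a degeneracy flag is set. The limit rotation is
#' well defined up to azimuth and the composed `Q` still maps the before
#' direction onto the after direction.
#'
#' @param g_before,g_after gravity vectors ([gravity_vector()] or numeric
#'   length 3) with non-zero magnitude.
#' @param eps_h degeneracy threshold on the horizontal norm of the normalised
#'   vectors.
#' @return An object of class `"gravity_decomposition"`: a list with unit
#'   quaternions `Q1`, `Q2`, `Q3`, `Q`, angles `theta1`, `theta2`, `theta3`,
#'   `theta` (degrees; `theta` signed in (-180, 180]), axis direction cosines
#'   `alpha_sin`, `alpha_cos`, `beta_sin`, `beta_cos`, and a logical
#'   `degenerate` flag per input.
#' @examples
#' d <- quat_decompose(c(1, 0, 0), c(0, 1, 0))
#' d$theta  # 90
#' @export
quat_decompose <- function(g_before, g_after, eps_h = 1e-8) {
  gb <- as_gravity3(g_before)
  ga <- as_gravity3(g_after)
  nb <- sqrt(sum(gb^2)); na <- sqrt(sum(ga^2))
  if (nb < .Machine$double.eps || na < .Machine$double.eps) {
    stop("gravity vectors must have non-zero magnitude")
  }
  gb <- gb / nb; ga <- ga / na
  rb <- sqrt(gb[1]^2 + gb[2]^2)
  ra <- sqrt(ga[1]^2 + ga[2]^2)

  deg_b <- rb < eps_h
  deg_a <- ra < eps_h

  # elevations via atan2(z, rho): rho >= 0, so equal to arctan(z/rho) except
  # in the degenerate limit where it correctly yields +/-90 degrees
  theta1 <- atan2(gb[3], rb)
  theta3 <- -atan2(ga[3], ra)
  if (deg_b) { alpha_sin <- 0; alpha_cos <- 1 } else {
    alpha_sin <- -gb[2] / rb; alpha_cos <- gb[1] / rb
  }
  if (deg_a) { beta_sin <- 0; beta_cos <- 1 } else {
    beta_sin <- -ga[2] / ra; beta_cos <- ga[1] / ra
  }
  az_b <- if (deg_b) 0 else atan2(gb[2], gb[1])
  az_a <- if (deg_a) 0 else atan2(ga[2], ga[1])
  theta2 <- az_a - az_b

  Q1 <- quaternion(cos(theta1 / 2),
                   sin(theta1 / 2) * alpha_sin,
                   sin(theta1 / 2) * alpha_cos, 0)
  Q2 <- quaternion(cos(theta2 / 2), 0, 0, sin(theta2 / 2))
  Q3 <- quaternion(cos(theta3 / 2),
                   sin(theta3 / 2) * beta_sin,
                   sin(theta3 / 2) * beta_cos, 0)
  Q <- quat_multiply(Q3, quat_multiply(Q2, Q1))

  structure(list(
    Q1 = Q1, Q2 = Q2, Q3 = Q3, Q = Q,
    theta1 = theta1 * 180 / pi,
    theta2 = theta2 * 180 / pi,
    theta3 = theta3 * 180 / pi,
    theta = quat_angle(Q),
    alpha_sin = alpha_sin, alpha_cos = alpha_cos,
    beta_sin = beta_sin, beta_cos = beta_cos,
    degenerate = c(before = deg_b, after = deg_a),
    g_before = gb, g_after = ga
  ), class = "gravity_decomposition")
}

#' @export
print.gravity_decomposition <- function(x, ...) {
  cat("Gravity rotation decomposition Q = Q3 (x) Q2 (x) Q1\n")
  cat(sprintf("  theta1 = %8.2f deg (tilt to horizontal)\n", x$theta1))
  cat(sprintf("  theta2 = %8.2f deg (azimuth about k)\n", x$theta2))
  cat(sprintf("  theta3 = %8.2f deg (tilt back)\n", x$theta3))
  cat(sprintf("  total rotation theta = %.2f deg\n", x$theta))
  if (any(x$degenerate)) {
    cat("  note: near-vertical input(s); azimuth taken as 0:",
        paste(names(x$degenerate)[x$degenerate], collapse = ", "), "\n")
  }
  invisible(x)
}
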