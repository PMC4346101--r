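test_that("Hamilton product follows the quaternion multiplication rules", {
  e <- quaternion(1, 0, 0, 0)
  i <- quaternion(0, 1, 0, 0)
  j <- quaternion(0, 0, 1, 0)
  k <- quaternion(0, 0, 0, 1)
  b <- quaternion(0.3, -1.2, 0.5, 2)
  expect_equal(unclass(quat_multiply(e, b)), unclass(b))
  expect_equal(unclass(quat_multiply(i, j)), unclass(k))
  expect_equal(unclass(quat_multiply(j, i)), -unclass(k))
  expect_equal(unclass(quat_multiply(i, i)), -unclass(e))
})

test_that("product agrees with the explicit 4x4 left-multiplication matrix", {
  # the matrix is written out element by element here, independently of
  # quat_matrix(), so both routes are cross-checked
  set.seed(11)
  for (rep in 1:1000) {
    a <- unclass(random_quat(unit = FALSE))
    b <- unclass(random_quat(unit = FALSE))
    M <- matrix(c(a[1], -a[2], -a[3], -a[4],
                  a[2],  a[1], -a[4],  a[3],
                  a[3],  a[4],  a[1], -a[2],
                  a[4], -a[3],  a[2],  a[1]), 4, 4, byrow = TRUE)
    direct <- unclass(quat_multiply(quaternion(a), quaternion(b)))
    expect_lt(max(abs(direct - as.numeric(M %*% b))), 1e-12)
    expect_equal(unclass(quat_matrix(quaternion(a))), unclass(M),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("Hamilton product is associative", {
  set.seed(12)
  for (rep in 1:200) {
    a <- random_quat(FALSE); b <- random_quat(FALSE); c <- random_quat(FALSE)
    lhs <- quat_multiply(quat_multiply(a, b), c)
    rhs <- quat_multiply(a, quat_multiply(b, c))
    expect_lt(max(abs(unclass(lhs) - unclass(rhs))), 1e-12)
  }
})

test_that("conjugation negates the vector part and Q (x) Q* = |Q|^2", {
  expect_equal(unclass(quat_conjugate(quaternion(1, 0, 0, 0))),
               unclass(quaternion(1, 0, 0, 0)))
  expect_equal(unclass(quat_conjugate(quaternion(0, 1, 0, 0))),
               unclass(quaternion(0, -1, 0, 0)))
  set.seed(13)
  for (rep in 1:50) {
    a <- random_quat(FALSE)
    p <- quat_multiply(a, quat_conjugate(a))
    expect_lt(max(abs(unclass(p) - c(quat_norm(a)^2, 0, 0, 0))), 1e-12)
  }
})

test_that("rotation angle extraction handles sign and the q0 = 0 limit", {
  expect_equal(quat_angle(quaternion(1, 0, 0, 0)), 0)
  expect_equal(quat_angle(quaternion(cos(pi / 4), sin(pi / 4), 0, 0)), 90)
  expect_equal(quat_angle(quaternion(0, 1, 0, 0)), 180)
  # signed q0 convention: negative scalar part gives a negative angle
  expect_lt(quat_angle(quaternion(-cos(pi / 3), sin(pi / 3), 0, 0)), 0)
  expect_equal(quat_angle(quat_axis_angle(c(1, 2, -1), 37)), 37)
})

test_that("vector rotation matches the rotation-matrix oracle", {
  ident <- quaternion(1, 0, 0, 0)
  v <- c(0.4, -1, 2)
  expect_equal(quat_rotate(ident, v), v)
  q90 <- quat_axis_angle(c(0, 0, 1), 90)
  expect_equal(quat_rotate(q90, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  set.seed(14)
  for (rep in 1:300) {
    q <- random_quat()
    v <- stats::rnorm(3) * 2
    expect_lt(max(abs(quat_rotate(q, v) -
                      as.numeric(oracle_quat_to_rotmat(q) %*% v))), 1e-12)
    expect_equal(sqrt(sum(quat_rotate(q, v)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("decomposition reproduces hand-evaluated elementary cases", {
  d0 <- quat_decompose(c(1, 0, 0), c(1, 0, 0))
  expect_equal(d0$theta1, 0)
  expect_equal(d0$theta2, 0)
  expect_equal(d0$theta3, 0)
  expect_equal(unclass(d0$Q), unclass(quaternion(1, 0, 0, 0)),
               tolerance = 1e-12)
  expect_equal(d0$theta, 0)

  d <- quat_decompose(c(1, 0, 0), c(0, 1, 0))
  expect_equal(d$theta1, 0)
  expect_equal(d$theta2, 90)
  expect_equal(d$theta3, 0)
  expect_equal(abs(d$theta), 90)
})

test_that("decomposition factors are unit quaternions with unit axis cosines", {
  set.seed(15)
  for (rep in 1:200) {
    d <- quat_decompose(random_unit3(), random_unit3())
    for (q in list(d$Q1, d$Q2, d$Q3, d$Q)) {
      expect_lt(abs(quat_norm(q) - 1), 1e-9)
    }
    expect_lt(abs(d$alpha_sin^2 + d$alpha_cos^2 - 1), 1e-9)
    expect_lt(abs(d$beta_sin^2 + d$beta_cos^2 - 1), 1e-9)
  }
})

test_that("composed rotation carries g_before onto g_after", {
  set.seed(16)
  for (rep in 1:1000) {
    gb <- random_unit3()
    ga <- random_unit3()
    # also exercise non-unit magnitudes within the capture tolerance
    d <- quat_decompose(gb * stats::runif(1, 0.7, 1.3),
                        ga * stats::runif(1, 0.7, 1.3))
    expect_lt(sqrt(sum((quat_rotate(d$Q, gb) - ga)^2)), 1e-9)
  }
})

test_that("composed rotation agrees with composing the three factor matrices", {
  set.seed(17)
  for (rep in 1:200) {
    gb <- random_unit3(); ga <- random_unit3()
    d <- quat_decompose(gb, ga)
    Rq <- oracle_quat_to_rotmat(d$Q)
    R3 <- oracle_quat_to_rotmat(d$Q3) %*% oracle_quat_to_rotmat(d$Q2) %*%
      oracle_quat_to_rotmat(d$Q1)
    expect_equal(Rq, R3, tolerance = 1e-9)
    expect_equal(as.numeric(R3 %*% gb), ga, tolerance = 1e-9)
  }
})

test_that("|theta| is invariant under a common azimuthal rotation", {
  set.seed(18)
  for (rep in 1:100) {
    gb <- random_unit3(); ga <- random_unit3()
    base <- abs(quat_decompose(gb, ga)$theta)
    Rz <- oracle_rotmat(c(0, 0, 1), stats::runif(1, 0, 360))
    rot <- abs(quat_decompose(as.numeric(Rz %*% gb),
                              as.numeric(Rz %*% ga))$theta)
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("identical input directions always decompose to zero rotation", {
  set.seed(19)
  for (rep in 1:100) {
    g <- random_unit3()
    expect_equal(quat_angle(quat_decompose(g, g)$Q), 0, tolerance = 1e-9)
  }
})

test_that("near-vertical gravity is flagged degenerate but still mapped", {
  d <- quat_decompose(c(0, 0, 1), c(1, 0, 0))
  expect_true(d$degenerate[["before"]])
  expect_false(d$degenerate[["after"]])
  expect_lt(sqrt(sum((quat_rotate(d$Q, c(0, 0, 1)) - c(1, 0, 0))^2)), 1e-9)
  expect_equal(abs(d$theta), 90, tolerance = 1e-9)

  d2 <- quat_decompose(c(1, 0, 0), c(0, 0, -1))
  expect_true(d2$degenerate[["after"]])
  expect_lt(sqrt(sum((quat_rotate(d2$Q, c(1, 0, 0)) - c(0, 0, -1))^2)), 1e-9)
})

test_that("zero-magnitude gravity input is rejected", {
  expect_error(quat_decompose(c(0, 0, 0), c(1, 0, 0)), "non-zero")
})

test_that("gravity vector magnitude follows the Euclidean norm", {
  g <- gravity_vector(0.6, 0.8, 0)
  expect_equal(gravity_magnitude(g), 1)
  expect_equal(gravity_magnitude(gravity_vector(1, 1, 1)), sqrt(3))
})
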