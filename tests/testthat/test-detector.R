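# builds a deterministic scripted trace: still x-down, free-fall dip,
# impact spike, ring-down, then lying with the gravity direction rotated by
# `angle_deg` toward +y; no noise, so every feature is exact
scripted_fall_trace <- function(angle_deg = 95, peak = 4, fs = 100) {
  t <- (seq_len(6 * fs) - 1) / fs
  m <- rep(1, length(t))
  m[t > 1.5 & t <= 1.8] <- 0.3
  imp <- t > 1.8 & t <= 1.85
  m[imp] <- 0.3 + (peak - 0.3) * sin(pi * (t[imp] - 1.8) / 0.05)
  a <- angle_deg * pi / 180
  u <- cbind(ifelse(t <= 1.85, 1, cos(a)), ifelse(t <= 1.85, 0, sin(a)), 0)
  accel_trace(t, m * u[, 1], m * u[, 2], m * u[, 3], sample_rate = fs)
}

test_that("configuration defaults and invariants are enforced", {
  cfg <- detector_config()
  expect_equal(cfg$a_threshold, 2)
  expect_equal(cfg$t_threshold, 2)
  expect_equal(cfg$gravity_band, c(0.7, 1.3))
  expect_equal(cfg$angle_band, c(60, 120))
  expect_error(detector_config(a_threshold = 1.2), "a_threshold")
  expect_error(detector_config(t_threshold = 0), "t_threshold")
  expect_error(detector_config(angle_band = c(120, 60)), "angle_band")
})

test_that("a scripted 95-degree fall yields exactly one alarm in band", {
  fit <- detect_falls(scripted_fall_trace(95))
  ev <- as.data.frame(fit)
  expect_equal(nrow(ev), 1)
  expect_true(ev$is_alarm)
  expect_equal(ev$reject_reason, "none")
  expect_equal(abs(ev$theta), 95, tolerance = 0.5)
  expect_gte(ev$peak_a, 2)
  expect_equal(ev$impact_time, 1.81, tolerance = 0.02)
})

test_that("synthetic forward fall (seed 42) raises exactly one alarm", {
  sim <- generate_motion(motion_spec("fall_forward", seed = 42))
  fit <- detect_falls(sim$trace)
  ev <- as.data.frame(fit)
  expect_equal(nrow(ev), 1)
  expect_true(ev$is_alarm)
  expect_gt(abs(ev$theta), 60)
  expect_lt(abs(ev$theta), 120)
})

test_that("jumping triggers impacts that are rejected by the angle feature", {
  sim <- generate_motion(motion_spec("jumping", seed = 7))
  fit <- detect_falls(sim$trace)
  ev <- as.data.frame(fit)
  expect_gt(nrow(ev), 0)
  expect_false(any(ev$is_alarm))
  expect_true(all(ev$reject_reason == "angle_out_of_band"))
  expect_true(all(abs(ev$theta) < 60))
})

test_that("resting never reaches the impact threshold, so no events", {
  sim <- generate_motion(motion_spec("resting", seed = 5))
  expect_lt(max(sum_acceleration(sim$trace)), 2)
  fit <- detect_falls(sim$trace)
  expect_equal(nrow(as.data.frame(fit)), 0)
})

test_that("the acceleration-only baseline alarms on every impact", {
  jump <- generate_motion(motion_spec("jumping", seed = 7))$trace
  fit <- detect_falls(jump, method = "acceleration")
  ev <- as.data.frame(fit)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$is_alarm))       # false positives by design
  expect_true(all(is.na(ev$theta)))   # angle feature not computed

  fall <- generate_motion(motion_spec("fall_forward", seed = 42))$trace
  expect_equal(sum(as.data.frame(detect_falls(fall, method = "acceleration"))$is_alarm), 1)

  walk <- generate_motion(motion_spec("walking", seed = 9))$trace
  expect_equal(nrow(as.data.frame(detect_falls(walk, method = "acceleration"))), 0)
})

test_that("scaling the impact below threshold suppresses all events", {
  tr <- scripted_fall_trace(95, peak = 4)
  s <- sum_acceleration(tr)
  scale <- ifelse(s >= 2, 1.9 / s, 1)  # push every peak under 2 g
  tr2 <- accel_trace(tr$t, tr$ax * scale, tr$ay * scale, tr$az * scale)
  expect_equal(nrow(as.data.frame(detect_falls(tr2))), 0)
})

test_that("an impact with no settling is rejected as no_settle", {
  fs <- 100
  t <- (seq_len(6 * fs) - 1) / fs
  # still, impact, then oscillation that never stays inside the band
  m <- rep(1, length(t))
  m[t > 1.5 & t <= 1.55] <- 4
  osc <- t > 1.55
  m[osc] <- 1 + 0.6 * sin(2 * pi * 5 * (t[osc] - 1.55))
  tr <- accel_trace(t, m, rep(0, length(t)), rep(0, length(t)))
  fit <- detect_falls(tr)
  ev <- as.data.frame(fit)
  expect_equal(nrow(ev), 1)
  expect_false(ev$is_alarm)
  expect_equal(ev$reject_reason, "no_settle")
  # brute-force check: indeed no 0.5 s window inside the band within 2 s
  s <- sum_acceleration(tr)
  imp <- which(s >= 2)[1]
  ok <- s >= 0.7 & s <= 1.3
  runs <- sapply(imp:(imp + 200), function(i) all(ok[i:(i + 49)]))
  expect_false(any(runs))
})

test_that("a trace that never starts still fails calibration loudly", {
  tr <- constant_trace(c(0, 0, 2), duration_s = 3)
  expect_error(detect_falls(tr), "calibration")
})

test_that("detection is deterministic and time-ordered", {
  sim <- generate_motion(motion_spec("jumping", seed = 31))
  f1 <- as.data.frame(detect_falls(sim$trace))
  f2 <- as.data.frame(detect_falls(sim$trace))
  expect_identical(f1, f2)
  expect_true(all(diff(f1$impact_time) > 0))
})

test_that("every alarm's |theta| lies inside the configured angle band", {
  set.seed(32)
  for (seed in sample.int(10000, 8)) {
    cls <- sample(motion_classes(), 1)
    sim <- generate_motion(motion_spec(cls, seed = seed))
    ev <- as.data.frame(detect_falls(sim$trace))
    if (any(ev$is_alarm)) {
      th <- abs(ev$theta[ev$is_alarm])
      expect_true(all(th >= 60 & th <= 120))
    }
  }
})

test_that("alarm decisions are invariant under a common k-axis rotation", {
  set.seed(33)
  for (cls in c("fall_forward", "fall_leftward", "jumping", "resting")) {
    sim <- generate_motion(motion_spec(cls, seed = 77))
    base <- as.data.frame(detect_falls(sim$trace))
    for (ang in c(30, 137, 260)) {
      Rz <- oracle_rotmat(c(0, 0, 1), ang)
      rot <- as.data.frame(detect_falls(rotate_trace(sim$trace, Rz)))
      expect_equal(nrow(rot), nrow(base))
      expect_equal(rot$is_alarm, base$is_alarm)
      if (nrow(base) > 0) {
        expect_equal(abs(rot$theta), abs(base$theta), tolerance = 1e-6)
      }
    }
  }
})

test_that("alarm messages substitute coordinates deterministically", {
  ev <- list(impact_time = 12.3, theta = 91.9)
  msg <- format_alarm_message(ev, 39.98, 116.34)
  expect_match(msg, "39.98,116.34", fixed = TRUE)
  expect_match(msg, "12.3", fixed = TRUE)
  expect_identical(msg, format_alarm_message(ev, 39.98, 116.34))
  expect_error(format_alarm_message(ev, 39.98, 181), "lon")
  expect_error(format_alarm_message(ev, -91, 0), "lat")
})
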