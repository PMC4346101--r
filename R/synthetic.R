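#' Motion classes known to the generator
#'
#' Four fall directions plus five activities of daily living (ADL). Falls
#' are the positive class for evaluation; ADLs the negative class.
#'
#' @return Character vector of the nine class names.
#' @export
motion_classes <- function() {
  c("fall_forward", "fall_backward", "fall_leftward", "fall_rightward",
    "walking", "jumping", "squatting", "sitting", "resting")
}

fall_classes <- function() motion_classes()[1:4]

# One table of waveform parameters per class. Ranges are sampled uniformly
# per trace. Falls: free-fall dip, half-sine impact spike, damped 15 Hz
# ring-down, then lying still. "tip_azimuth" is the direction gravity is
# swept toward in the device frame (90 = device +y); "roll" is the axial
# landing roll added to it. ADLs keep peaks below the 2 g impact threshold
# except jumping, whose landings are genuine 2.5-3.5 g spikes.
default_class_params <- function(motion_class) {
  base <- list(still_s = 1.5, mount_tilt_max_deg = 8)
  p <- switch(motion_class,
    fall_forward = list(duration_s = 6, angle_range = c(75, 105),
                        tip_azimuth_deg = 90, roll_range = c(0, 30),
                        dip_range = c(0.25, 0.35), dip_dur = c(0.2, 0.4),
                        peak_range = c(3, 6), impact_dur = c(0.03, 0.08),
                        ring_amp = c(0.4, 0.6)),
    fall_backward = list(duration_s = 6, angle_range = c(75, 105),
                         tip_azimuth_deg = -90, roll_range = c(0, 30),
                         dip_range = c(0.25, 0.35), dip_dur = c(0.2, 0.4),
                         peak_range = c(3, 6), impact_dur = c(0.03, 0.08),
                         ring_amp = c(0.4, 0.6)),
    fall_leftward = list(duration_s = 6, angle_range = c(75, 105),
                         tip_azimuth_deg = 180, roll_range = c(45, 85),
                         dip_range = c(0.25, 0.35), dip_dur = c(0.2, 0.4),
                         peak_range = c(3, 6), impact_dur = c(0.03, 0.08),
                         ring_amp = c(0.4, 0.6)),
    fall_rightward = list(duration_s = 6, angle_range = c(75, 105),
                          tip_azimuth_deg = 0, roll_range = c(45, 85),
                          dip_range = c(0.25, 0.35), dip_dur = c(0.2, 0.4),
                          peak_range = c(3, 6), impact_dur = c(0.03, 0.08),
                          ring_amp = c(0.4, 0.6)),
    walking = list(duration_s = 8, amp_range = c(0.35, 0.5),
                   freq_range = c(1.8, 2.2)),
    jumping = list(duration_s = 8, n_jumps = 3,
                   land_peak_range = c(2.5, 3.5),
                   residual_rot_range = c(2, 8)),
    squatting = list(duration_s = 6, dip_range = c(0.55, 0.75),
                     peak_range = c(1.3, 1.8), tilt_range = c(5, 14)),
    sitting = list(duration_s = 6, dip_range = c(0.6, 0.8),
                   peak_range = c(1.3, 1.9), tilt_range = c(10, 28)),
    resting = list(duration_s = 7, angle_range = c(92, 118),
                   azimuth_jitter_deg = 8, dip_range = c(0.5, 0.7),
                   peak_range = c(1.4, 1.8)),
    stop("unknown motion class: ", motion_class)
  )
  utils::modifyList(base, p)
}

#' Specify a synthetic motion trace
#'
#' @param motion_class one of [motion_classes()].
#' @param duration_s trace duration in seconds; `NULL` uses the class
#'   default.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @param noise_sigma_g standard deviation of the additive white Gaussian
#'   per-axis noise, in g (default 0.02, comfortably above the few-mg
#'   resolution of a consumer MEMS accelerometer).
#' @param sample_rate sampling rate in Hz (default 100).
#' @param device_orientation optional unit [quaternion()] applied to the
#'   whole trace (and to the ground-truth gravity directions), emulating an
#'   arbitrary device mounting.
#' @param class_params named list of overrides for the class waveform
#'   parameters.
#' @return An object of class `"motion_spec"`.
#' @export
motion_spec <- function(motion_class, duration_s = NULL, seed = 1,
                        noise_sigma_g = 0.02, sample_rate = 100,
                        device_orientation = NULL, class_params = list()) {
  motion_class <- match.arg(motion_class, motion_classes())
  params <- utils::modifyList(default_class_params(motion_class), class_params)
  if (!is.null(duration_s)) params$duration_s <- duration_s
  if (params$duration_s <= params$still_s + 1) {
    stop("duration_s must leave room for the pre-still phase and the motion")
  }
  if (!is.null(device_orientation)) {
    stopifnot(inherits(device_orientation, "quaternion"))
  }
  structure(list(motion_class = motion_class, seed = as.integer(seed),
                 noise_sigma_g = noise_sigma_g, sample_rate = sample_rate,
                 device_orientation = device_orientation, params = params),
            class = "motion_spec")
}

# --- small geometry helpers (internal) --------------------------------------

runif1 <- function(range) stats::runif(1, range[1], range[2])

# rotation matrix of a unit quaternion
quat_rotmat <- function(q) {
  q <- unclass(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# orthonormal frame (e_y, e_z) perpendicular to unit vector u, right-handed
# with u (u x e_y = e_z); e_y is the projection of the device j axis
perp_frame <- function(u) {
  ey <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
  if (sqrt(sum(ey^2)) < 1e-6) ey <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(u[2] * ey[3] - u[3] * ey[2],
          u[3] * ey[1] - u[1] * ey[3],
          u[1] * ey[2] - u[2] * ey[1])
  list(ey = ey, ez = ez)
}

# final gravity direction after tipping u0 by angle_deg toward device-frame
# azimuth psi_deg (90 = +e_y, 0 = -e_z, matching the tip-direction
# convention sin(psi) e_y - cos(psi) e_z)
tip_direction <- function(u0, angle_deg, psi_deg) {
  fr <- perp_frame(u0)
  a <- angle_deg * pi / 180
  p <- psi_deg * pi / 180
  dir <- sin(p) * fr$ey - cos(p) * fr$ez
  cos(a) * u0 + sin(a) * dir
}

# per-sample orientation path: rows are gravity directions obtained by
# rotating u0 toward u1 along the minimal geodesic with progress s in [0,1]
orientation_path <- function(u0, u1, s) {
  cang <- max(-1, min(1, sum(u0 * u1)))
  ang <- acos(cang)
  if (ang < 1e-12) return(matrix(rep(u0, each = length(s)), ncol = 3))
  w <- c(u0[2] * u1[3] - u0[3] * u1[2],
         u0[3] * u1[1] - u0[1] * u1[3],
         u0[1] * u1[2] - u0[2] * u1[1])
  w <- w / sqrt(sum(w^2))
  th <- ang * s
  wxu <- c(w[2] * u0[3] - w[3] * u0[2],
           w[3] * u0[1] - w[1] * u0[3],
           w[1] * u0[2] - w[2] * u0[1])
  wdu <- sum(w * u0)
  # Rodrigues formula, vectorised over the progress values
  outer(cos(th), u0) + outer(sin(th), wxu) + outer(1 - cos(th), wdu * w)
}

halfcos <- function(x) (1 - cos(pi * pmin(pmax(x, 0), 1))) / 2

# cosine-smoothed interpolation of magnitude knots (time, value)
magnitude_profile <- function(t, knots_t, knots_v) {
  out <- numeric(length(t))
  out[t <= knots_t[1]] <- knots_v[1]
  for (k in seq_len(length(knots_t) - 1)) {
    sel <- t > knots_t[k] & t <= knots_t[k + 1]
    if (any(sel)) {
      f <- halfcos((t[sel] - knots_t[k]) / (knots_t[k + 1] - knots_t[k]))
      out[sel] <- knots_v[k] + (knots_v[k + 1] - knots_v[k]) * f
    }
  }
  out[t > knots_t[length(knots_t)]] <- knots_v[length(knots_v)]
  out
}

# --- generation --------------------------------------------------------------

#' Generate a synthetic accelerometer trace with ground truth
#'
#' Builds a physically coherent trace for the requested motion class: a
#' scalar magnitude profile |a|(t) (impact spikes, free-fall dips, gait
#' oscillation) carried by a smoothly rotating gravity direction (the
#' orientation is interpolated along the geodesic between the initial and
#' final gravity directions, so intermediate samples are consistent), plus
#' additive white Gaussian noise per axis.
#'
#' Fall classes: still -> free-fall dip (|a| ~ 0.3 g) -> half-sine impact
#' spike (3-6 g, 30-80 ms) -> damped 15 Hz ring-down (~0.5 s) -> lying
#' still, with the lying direction at 90 +/- 15 degrees from the initial
#' gravity direction. The landing posture includes an axial roll (see the
#' class parameter table) so that the lying direction carries a substantial
#' device-y component: bodies pivot about their long axis as they collapse,
#' and landing postures confined to the device x-z plane are both
#' biomechanically atypical and numerically unstable for the tilt-azimuth
#' decomposition (see the package vignette).
#'
#' ADL classes: walking (1 +/- ~0.5 g at ~2 Hz, orientation constant),
#' jumping (flight dips near 0 g, landing spikes 2.5-3.5 g, posture
#' restored), squatting (sub-2 g dip/rise, transient lean < 15 degrees),
#' sitting (sub-2 g contact peak, persistent recline < 30 degrees), resting
#' (deliberate lying down: fall-like shape with peak only 1.4-1.8 g and a
#' 92-118 degree orientation change).
#'
#' @param spec a [motion_spec()].
#' @return A list of class `"motion_sim"` with elements `trace` (an
#'   [accel_trace()]) and `truth` (list: `motion_class`, `is_fall`,
#'   `g_before`, `g_after` (unit ground-truth gravity directions),
#'   `angle_deg` (the geodesic angle between them), `peak_a` (designed peak
#'   |a| before noise), `params` (the values drawn for this trace)).
#' @examples
#' sim <- generate_motion(motion_spec("fall_forward", seed = 42))
#' sim$truth$angle_deg
#' @export
generate_motion <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  set.seed(spec$seed)
  p <- spec$params
  fs <- spec$sample_rate
  n <- as.integer(round(p$duration_s * fs))
  t <- (seq_len(n) - 1) / fs

  # mounting: device x roughly along the trunk, with a small random tilt
  tilt <- stats::runif(1, 0, p$mount_tilt_max_deg)
  tilt_az <- stats::runif(1, 0, 360)
  u0 <- tip_direction(c(1, 0, 0), tilt, tilt_az)

  cls <- spec$motion_class
  drawn <- list(mount_tilt_deg = tilt)

  if (cls %in% fall_classes()) {
    A <- runif1(p$angle_range)
    roll <- sample(c(-1, 1), 1) * runif1(p$roll_range)
    psi <- p$tip_azimuth_deg + roll
    u1 <- tip_direction(u0, A, psi)
    dip <- runif1(p$dip_range)
    d_dip <- runif1(p$dip_dur)
    peak <- runif1(p$peak_range)
    d_imp <- runif1(p$impact_dur)
    ring_amp <- runif1(p$ring_amp)
    drawn <- c(drawn, list(angle_deg = A, tip_azimuth_deg = psi,
                           peak_a = peak))

    t0 <- p$still_s; t1 <- t0 + d_dip; t2 <- t1 + d_imp; t3 <- t2 + 0.5
    M <- numeric(n) + 1
    sel <- t > t0 & t <= t1
    M[sel] <- 1 + (dip - 1) * halfcos((t[sel] - t0) / d_dip)
    sel <- t > t1 & t <= t2
    M[sel] <- dip + (peak - dip) * sin(pi * (t[sel] - t1) / d_imp)
    sel <- t > t2 & t <= t3
    tau <- t[sel] - t2
    M[sel] <- 1 + ring_amp * exp(-tau / 0.12) * sin(2 * pi * 15 * tau)
    # orientation sweeps from upright to lying across the fall phase
    s_prog <- halfcos((t - t0) / (t2 - t0))
    U <- orientation_path(u0, u1, s_prog)
    peak_true <- peak
  } else if (cls == "walking") {
    amp <- runif1(p$amp_range)
    freq <- runif1(p$freq_range)
    drawn <- c(drawn, list(amp = amp, freq = freq))
    M <- numeric(n) + 1
    sel <- t > p$still_s
    M[sel] <- 1 + amp * sin(2 * pi * freq * (t[sel] - p$still_s)) *
      halfcos((t[sel] - p$still_s) / 0.5)  # ease in
    u1 <- u0
    U <- matrix(rep(u0, each = n), ncol = 3)
    peak_true <- 1 + amp
  } else if (cls == "jumping") {
    land_peaks <- stats::runif(p$n_jumps, p$land_peak_range[1],
                               p$land_peak_range[2])
    resid <- runif1(p$residual_rot_range)
    resid_az <- stats::runif(1, 0, 360)
    drawn <- c(drawn, list(land_peaks = land_peaks, residual_rot = resid))
    M <- numeric(n) + 1
    cyc <- 1.3
    for (j in seq_len(p$n_jumps)) {
      s0 <- p$still_s + (j - 1) * cyc
      kt <- s0 + c(0, 0.25, 0.32, 0.40, 0.62, 0.70, 0.73, 0.76, 0.90)
      kv <- c(1, 0.70, 1.60, 0.15, 0.15, land_peaks[j], 0.80, 1.15, 1)
      prof <- magnitude_profile(t, kt, kv)
      sel <- t > s0 & t <= s0 + 0.90
      M[sel] <- prof[sel]
    }
    u1 <- tip_direction(u0, resid, resid_az)
    s_prog <- halfcos((t - p$still_s) / (p$n_jumps * cyc))
    U <- orientation_path(u0, u1, s_prog)
    peak_true <- max(land_peaks)
  } else if (cls == "squatting") {
    dip <- runif1(p$dip_range)
    peak <- runif1(p$peak_range)
    tiltm <- runif1(p$tilt_range)
    drawn <- c(drawn, list(dip = dip, peak = peak, lean_deg = tiltm))
    t0 <- p$still_s
    kt <- t0 + c(0, 0.5, 1.0, 1.5, 1.9, 2.3)
    kv <- c(1, dip, 1, 1, peak, 1)
    M <- magnitude_profile(t, kt, kv)
    # transient forward lean, back upright at the end
    lean <- tip_direction(u0, tiltm, 90)
    bump <- halfcos((t - t0) / 1.2) * (1 - halfcos((t - t0 - 1.2) / 1.2))
    U <- orientation_path(u0, lean, bump)
    u1 <- u0
    peak_true <- peak
  } else if (cls == "sitting") {
    dip <- runif1(p$dip_range)
    peak <- runif1(p$peak_range)
    tiltm <- runif1(p$tilt_range)
    drawn <- c(drawn, list(dip = dip, peak = peak, recline_deg = tiltm))
    t0 <- p$still_s
    kt <- t0 + c(0, 0.4, 0.65, 1.0)
    kv <- c(1, dip, peak, 1)
    M <- magnitude_profile(t, kt, kv)
    u1 <- tip_direction(u0, tiltm, -90)  # recline backward, persists
    s_prog <- halfcos((t - t0) / 1.0)
    U <- orientation_path(u0, u1, s_prog)
    peak_true <- peak
  } else {  # resting: deliberate lying down
    A <- runif1(p$angle_range)
    side <- sample(c(-1, 1), 1)
    psi <- side * 90 + stats::runif(1, -p$azimuth_jitter_deg,
                                    p$azimuth_jitter_deg)
    dip <- runif1(p$dip_range)
    peak <- runif1(p$peak_range)
    drawn <- c(drawn, list(angle_deg = A, tip_azimuth_deg = psi,
                           peak_a = peak))
    u1 <- tip_direction(u0, A, psi)
    t0 <- p$still_s; d_tr <- 1.5
    kt <- t0 + d_tr * c(0, 0.4, 0.7, 1.0)
    kv <- c(1, dip, peak, 1)
    M <- magnitude_profile(t, kt, kv)
    s_prog <- halfcos((t - t0) / d_tr)
    U <- orientation_path(u0, u1, s_prog)
    peak_true <- peak
  }

  A3 <- U * M
  if (spec$noise_sigma_g > 0) {
    A3 <- A3 + matrix(stats::rnorm(3 * n, 0, spec$noise_sigma_g), ncol = 3)
  }
  if (!is.null(spec$device_orientation)) {
    R <- quat_rotmat(spec$device_orientation)
    A3 <- A3 %*% t(R)
    u0 <- as.numeric(R %*% u0)
    u1 <- as.numeric(R %*% u1)
  }

  is_fall <- cls %in% fall_classes()
  sa <- sqrt(rowSums(A3^2))
  if (is_fall || cls == "jumping") {
    stopifnot(max(sa) >= 2)
  } else {
    stopifnot(max(sa) < 2)
  }

  trace <- accel_trace(t, A3[, 1], A3[, 2], A3[, 3], sample_rate = fs)
  cosang <- max(-1, min(1, sum(u0 * u1)))
  truth <- list(motion_class = cls, is_fall = is_fall,
                g_before = gravity_vector(u0[1], u0[2], u0[3]),
                g_after = gravity_vector(u1[1], u1[2], u1[3]),
                angle_deg = acos(cosang) * 180 / pi,
                peak_a = peak_true, params = drawn)
  structure(list(trace = trace, truth = truth, spec = spec),
            class = "motion_sim")
}

#' @export
print.motion_sim <- function(x, ...) {
  cat(sprintf("<motion_sim> %s (seed %d): %d samples, true angle %.1f deg, design peak %.2f g\n",
              x$truth$motion_class, x$spec$seed, n_samples(x$trace),
              x$truth$angle_deg, x$truth$peak_a))
  invisible(x)
}

#' Generate a labelled cohort of synthetic traces
#'
#' Produces `n_per_class` traces for each motion class with per-trace seeds
#' derived deterministically from `seed`, mirroring a test protocol in which
#' each motion is repeated the same number of times. The default of 60
#' repetitions per class matches a protocol of 20 repetitions by each of
#' three volunteers.
#'
#' @param n_per_class traces per class (>= 1).
#' @param seed master seed for the cohort.
#' @param classes classes to include (default all nine).
#' @param ... passed on to [motion_spec()] (e.g. `noise_sigma_g`).
#' @return An object of class `"motion_cohort"`: list with `sims` (list of
#'   `motion_sim`) and `labels` (data frame: `id`, `motion_class`,
#'   `is_fall`, `seed`, `angle_deg`, `peak_a`).
#' @export
generate_cohort <- function(n_per_class = 60, seed = 42,
                            classes = motion_classes(), ...) {
  stopifnot(n_per_class >= 1)
  classes <- match.arg(classes, motion_classes(), several.ok = TRUE)
  n_total <- n_per_class * length(classes)
  set.seed(seed)
  trace_seeds <- sample.int(.Machine$integer.max, n_total)
  cls <- rep(classes, each = n_per_class)
  sims <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    sims[[k]] <- generate_motion(
      motion_spec(cls[k], seed = trace_seeds[k], ...))
  }
  labels <- data.frame(
    id = sprintf("%s_%03d", cls, sequence(rep(n_per_class, length(classes)))),
    motion_class = cls,
    is_fall = cls %in% fall_classes(),
    seed = trace_seeds,
    angle_deg = vapply(sims, function(s) s$truth$angle_deg, numeric(1)),
    peak_a = vapply(sims, function(s) s$truth$peak_a, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(sims = sims, labels = labels, seed = seed),
            class = "motion_cohort")
}

#' @export
print.motion_cohort <- function(x, ...) {
  cat(sprintf("<motion_cohort> %d traces (seed %d):\n",
              nrow(x$labels), x$seed))
  print(table(x$labels$motion_class))
  invisible(x)
}

#' Write a cohort to disk as CSV traces plus a label file
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing). Each trace is written
#'   as `<id>.csv` in the standard `t,ax,ay,az` dialect, alongside
#'   `labels.csv` with columns `filename`, `motion_class`, `true_angle`,
#'   `true_peak`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "motion_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fn <- paste0(cohort$labels$id, ".csv")
  for (k in seq_along(cohort$sims)) {
    write_accel_trace(cohort$sims[[k]]$trace, file.path(dir, fn[k]))
  }
  utils::write.csv(
    data.frame(filename = fn,
               motion_class = cohort$labels$motion_class,
               true_angle = cohort$labels$angle_deg,
               true_peak = cohort$labels$peak_a),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
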