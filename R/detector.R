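#' Detector configuration
#'
#' Bundles every threshold and filter parameter of the fall detector.
#' Defaults follow the operating point established for waist-worn use at a
#' 100 Hz sampling rate: an impact is a sum-acceleration peak of at least
#' 2 g; the wearer must come to rest within 2 s of the impact; "at rest"
#' means |a| within +/-0.3 g of 1 g; and a fall is declared when the
#' body-rotation angle magnitude lies within 90 +/- 30 degrees.
#'
#' @param a_threshold impact threshold on |a|, g-units (default 2).
#' @param t_threshold settling time limit after an impact, seconds
#'   (default 2).
#' @param gravity_band `(low, high)` band on |a| that counts as still,
#'   g-units (default `c(0.7, 1.3)`).
#' @param angle_band `(low, high)` band applied to the rotation-angle
#'   magnitude `|theta|`, degrees (default `c(60, 120)`).
#' @param still_window_s length of the still window used to capture gravity,
#'   seconds (default 0.5).
#' @param lowpass_cutoff_hz cutoff of the optional low-pass gravity filter,
#'   Hz (default 1).
#' @param sample_rate expected trace sampling rate, Hz (default 100).
#' @return An object of class `"detector_config"` (a named list).
#' @export
detector_config <- function(a_threshold = 2.0,
                            t_threshold = 2.0,
                            gravity_band = c(0.7, 1.3),
                            angle_band = c(60, 120),
                            still_window_s = 0.5,
                            lowpass_cutoff_hz = 1.0,
                            sample_rate = 100) {
  cfg <- list(a_threshold = as.numeric(a_threshold),
              t_threshold = as.numeric(t_threshold),
              gravity_band = as.numeric(gravity_band),
              angle_band = as.numeric(angle_band),
              still_window_s = as.numeric(still_window_s),
              lowpass_cutoff_hz = as.numeric(lowpass_cutoff_hz),
              sample_rate = as.numeric(sample_rate))
  if (length(cfg$gravity_band) != 2 || cfg$gravity_band[1] >= cfg$gravity_band[2]) {
    stop("gravity_band must be an increasing (low, high) pair")
  }
  if (cfg$a_threshold <= cfg$gravity_band[2]) {
    stop("a_threshold must exceed the upper gravity band limit")
  }
  if (cfg$t_threshold <= 0) stop("t_threshold must be positive")
  if (length(cfg$angle_band) != 2 ||
      cfg$angle_band[1] <= 0 || cfg$angle_band[1] >= cfg$angle_band[2] ||
      cfg$angle_band[2] > 180) {
    stop("angle_band must satisfy 0 < low < high <= 180")
  }
  if (cfg$still_window_s <= 0) stop("still_window_s must be positive")
  if (cfg$sample_rate <= 0) stop("sample_rate must be positive")
  structure(cfg, class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat("Fall detector configuration:\n")
  cat(sprintf("  impact threshold   : %.2f g\n", x$a_threshold))
  cat(sprintf("  settling limit     : %.2f s\n", x$t_threshold))
  cat(sprintf("  still band on |a|  : %.2f - %.2f g\n",
              x$gravity_band[1], x$gravity_band[2]))
  cat(sprintf("  alarm band on |th| : %.0f - %.0f deg\n",
              x$angle_band[1], x$angle_band[2]))
  cat(sprintf("  still window       : %.2f s, sample rate %g Hz\n",
              x$still_window_s, x$sample_rate))
  invisible(x)
}

#' Detect falls in an accelerometer trace
#'
#' Runs the online two-feature detection state machine
#' (CALIBRATE -> MONITOR -> IMPACT -> SETTLE -> ALARM or back to MONITOR):
#'
#' 1. *Calibrate*: the trace must open with a still period; the earliest
#'    still window (every |a| inside `gravity_band` for `still_window_s`)
#'    before any impact provides the upright reference gravity `g_before`.
#' 2. *Monitor*: wait for the first sample with |a| >= `a_threshold`.
#' 3. *Impact/settle*: record the running peak and search the next
#'    `t_threshold` seconds for a still window. If one appears, its mean
#'    vector is `g_after`; the rotation angle `theta` comes from
#'    [quat_decompose()] of `g_before` and `g_after`, and an alarm is raised
#'    iff `|theta|` lies inside `angle_band`. If the acceleration keeps
#'    fluctuating for the whole `t_threshold`, the event is rejected with
#'    reason `"no_settle"`.
#' 4. Monitoring resumes after the settle window (or after the search span
#'    when no still window appeared), so one impact's oscillation cannot be
#'    double counted. Events are non-overlapping and time ordered.
#'
#' `method = "acceleration"` runs the single-feature baseline: identical
#' impact bookkeeping, but every impact raises an alarm and no rotation
#' angle is computed (`theta` is `NA`). It exists as the comparison arm for
#' [run_benchmark()].
#'
#' @param trace an [accel_trace()].
#' @param config a [detector_config()].
#' @param method `"quaternion"` (the two-feature detector, default) or
#'   `"acceleration"` (impact-threshold-only baseline).
#' @param keep_trace keep the trace inside the returned object so that
#'   `plot()` can annotate it (default `TRUE`).
#' @return An object of class `"fall_detection"`: a list with `events` (a
#'   data frame with one row per impact event: `impact_time`, `peak_a`,
#'   `theta`, `is_alarm`, `reject_reason`, the captured `g_after` components
#'   and the settle window), `g_before`, `config`, `method`. Use
#'   `as.data.frame()` to extract the event table.
#' @examples
#' sim <- generate_motion(motion_spec("fall_forward", seed = 42))
#' fit <- detect_falls(sim$trace)
#' fit
#' as.data.frame(fit)
#' @export
detect_falls <- function(trace, config = detector_config(),
                         method = c("quaternion", "acceleration"),
                         keep_trace = TRUE) {
  stopifnot(inherits(trace, "accel_trace"), inherits(config, "detector_config"))
  method <- match.arg(method)
  fs <- trace$sample_rate
  n <- n_samples(trace)
  s <- sum_acceleration(trace)
  win <- max(1L, as.integer(round(config$still_window_s * fs)))
  span <- as.integer(round(config$t_threshold * fs))
  ok <- s >= config$gravity_band[1] & s <= config$gravity_band[2]

  first_impact <- which(s >= config$a_threshold)[1]
  calib_limit <- if (is.na(first_impact)) n - win + 1L else first_impact - win
  calib_start <- first_true_run(ok, win, from = 1L, last_start = calib_limit)
  if (is.na(calib_start)) {
    stop(sprintf(paste0(
      "calibration failed: the trace must begin with a still period of at ",
      "least %.2f s with |a| inside [%.2f, %.2f] g before any impact"),
      config$still_window_s, config$gravity_band[1], config$gravity_band[2]))
  }
  gi <- calib_start:(calib_start + win - 1L)
  g_before <- gravity_vector(mean(trace$ax[gi]), mean(trace$ay[gi]),
                             mean(trace$az[gi]),
                             source_window = c(trace$t[gi[1]], trace$t[gi[win]]))

  events <- list()
  i <- calib_start + win  # first MONITOR sample
  while (i <= n) {
    nxt <- which(s[i:n] >= config$a_threshold)[1]
    if (is.na(nxt)) break
    impact <- i + nxt - 1L
    # settle search: windows starting within t_threshold of the impact
    settle_start <- first_true_run(ok, win, from = impact,
                                   last_start = min(impact + span, n - win + 1L))
    if (!is.na(settle_start)) {
      peak <- max(s[impact:settle_start])
      si <- settle_start:(settle_start + win - 1L)
      g_after <- gravity_vector(mean(trace$ax[si]), mean(trace$ay[si]),
                                mean(trace$az[si]),
                                source_window = c(trace$t[si[1]], trace$t[si[win]]))
      if (method == "quaternion") {
        theta <- quat_decompose(g_before, g_after)$theta
        in_band <- abs(theta) >= config$angle_band[1] &
          abs(theta) <= config$angle_band[2]
        reject <- if (in_band) "none" else "angle_out_of_band"
        alarm <- in_band
      } else {
        theta <- NA_real_
        reject <- "none"
        alarm <- TRUE
      }
      events[[length(events) + 1L]] <- data.frame(
        impact_time = trace$t[impact], peak_a = peak, theta = theta,
        is_alarm = alarm, reject_reason = reject,
        ga_x = unclass(g_after)[1], ga_y = unclass(g_after)[2],
        ga_z = unclass(g_after)[3],
        settle_start = trace$t[si[1]], settle_end = trace$t[si[win]],
        stringsAsFactors = FALSE)
      i <- si[win] + 1L
    } else {
      search_end <- min(impact + span + win - 1L, n)
      peak <- max(s[impact:search_end])
      events[[length(events) + 1L]] <- data.frame(
        impact_time = trace$t[impact], peak_a = peak, theta = NA_real_,
        is_alarm = method == "acceleration",
        reject_reason = if (method == "acceleration") "none" else "no_settle",
        ga_x = NA_real_, ga_y = NA_real_, ga_z = NA_real_,
        settle_start = NA_real_, settle_end = NA_real_,
        stringsAsFactors = FALSE)
      i <- search_end + 1L
    }
  }

  events <- if (length(events) > 0) {
    do.call(rbind, events)
  } else {
    data.frame(impact_time = numeric(0), peak_a = numeric(0),
               theta = numeric(0), is_alarm = logical(0),
               reject_reason = character(0), ga_x = numeric(0),
               ga_y = numeric(0), ga_z = numeric(0),
               settle_start = numeric(0), settle_end = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(events = events, g_before = g_before, config = config,
                 method = method,
                 trace = if (keep_trace) trace else NULL),
            class = "fall_detection")
}

#' @export
print.fall_detection <- function(x, ...) {
  cat(sprintf("Fall detection (%s method): %d impact event(s), %d alarm(s)\n",
              x$method, nrow(x$events), sum(x$events$is_alarm)))
  if (nrow(x$events) > 0) {
    ev <- x$events
    for (k in seq_len(nrow(ev))) {
      cat(sprintf("  t = %6.2f s  peak %.2f g  theta %s  %s\n",
                  ev$impact_time[k], ev$peak_a[k],
                  if (is.na(ev$theta[k])) "  --  " else
                    sprintf("%6.1f", ev$theta[k]),
                  if (ev$is_alarm[k]) "ALARM" else
                    paste0("rejected (", ev$reject_reason[k], ")")))
    }
  }
  invisible(x)
}

#' @export
summary.fall_detection <- function(object, ...) {
  cat("Two-feature fall detection summary\n")
  print(object$config)
  cat("Reference gravity (g_before):\n  ")
  print(object$g_before)
  print(object)
  invisible(object)
}

#' @export
as.data.frame.fall_detection <- function(x, ...) x$events

#' @export
plot.fall_detection <- function(x, ...) {
  if (is.null(x$trace)) {
    stop("detection was run with keep_trace = FALSE; nothing to plot")
  }
  tr <- x$trace
  graphics::plot(tr$t, sum_acceleration(tr), type = "l",
                 xlab = "time [s]", ylab = "|a| [g]", ...)
  graphics::abline(h = x$config$a_threshold, lty = 2)
  graphics::abline(h = x$config$gravity_band, lty = 3, col = "grey50")
  ev <- x$events
  if (nrow(ev) > 0) {
    graphics::abline(v = ev$impact_time,
                     col = ifelse(ev$is_alarm, "red", "orange"))
    lab <- ifelse(ev$is_alarm,
                  sprintf("fall %.0f deg", ev$theta), ev$reject_reason)
    graphics::text(ev$impact_time, max(sum_acceleration(tr)), lab,
                   pos = 4, col = "red", cex = 0.8)
  }
  invisible(x)
}

#' Format a fall alarm message
#'
#' Builds the single-line alarm text a wearable would send to a caregiver,
#' embedding the impact time, the rotation angle and a web-map link with the
#' wearer's coordinates substituted into a URL template.
#'
#' @param event a one-row event (a row of the `events` data frame from
#'   [detect_falls()], or a list with `impact_time` and `theta`).
#' @param lat,lon wearer coordinates in degrees; `lat` in \[-90, 90\],
#'   `lon` in \[-180, 180\].
#' @param map_url_template URL template containing `{lat}` and `{lon}`
#'   placeholders.
#' @return A single deterministic string.
#' @examples
#' ev <- list(impact_time = 12.3, theta = 91.9)
#' format_alarm_message(ev, 39.98, 116.34)
#' @export
format_alarm_message <- function(event, lat, lon,
                                 map_url_template = "https://maps.example/?q={lat},{lon}") {
  if (!is.numeric(lat) || length(lat) != 1 || lat < -90 || lat > 90) {
    stop("lat must be a single value in [-90, 90]")
  }
  if (!is.numeric(lon) || length(lon) != 1 || lon < -180 || lon > 180) {
    stop("lon must be a single value in [-180, 180]")
  }
  url <- gsub("{lat}", format(lat, trim = TRUE),
              gsub("{lon}", format(lon, trim = TRUE),
                   map_url_template, fixed = TRUE), fixed = TRUE)
  theta_txt <- if (is.null(event$theta) || is.na(event$theta)) {
    "n/a"
  } else {
    sprintf("%.1f deg", event$theta)
  }
  sprintf("FALL ALARM at t=%.1f s (rotation %s). Location: %s",
          event$impact_time, theta_txt, url)
}
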