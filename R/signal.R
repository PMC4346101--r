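#' Sum acceleration
#'
#' The per-sample Euclidean norm
#' \eqn{|a| = \sqrt{a_x^2 + a_y^2 + a_z^2}} of the three axis accelerations.
#' At rest it equals 1 g regardless of how the device is oriented, which
#' makes it the natural impact feature for a wearable with no fixed mounting:
#' a fall's collision with the ground shows up as a peak of several g.
#'
#' @param trace an [accel_trace()].
#' @return Numeric vector of |a| in g-units, one value per sample.
#' @export
sum_acceleration <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}

#' Low-pass gravity estimate
#'
#' Separates the quasi-static gravity component from body-motion dynamics by
#' low-pass filtering each axis. Human posture changes are slow (well under
#' 1 Hz) while voluntary-movement dynamics sit at roughly 2 Hz and above, so
#' a 2nd-order Butterworth low-pass with a 1 Hz cutoff is used by default.
#' Filtering is forward-only (causal), as an online device would run it.
#'
#' The filter state is initialised by padding with the first sample held
#' constant, so a constant input is reproduced exactly from the first output
#' sample. The first `3 / (2 pi cutoff_hz)` seconds are nevertheless flagged
#' as warm-up (attribute `"warmup_s"`) and should be excluded from gravity
#' capture when the early signal is not known to be still.
#'
#' @param trace an [accel_trace()].
#' @param cutoff_hz cutoff frequency in Hz; must lie in
#'   `(0, sample_rate / 2)`.
#' @param order filter order (default 2).
#' @return A numeric matrix with columns `gx`, `gy`, `gz` (one row per
#'   sample) and attribute `warmup_s`.
#' @export
lowpass_gravity <- function(trace, cutoff_hz = 1, order = 2) {
  stopifnot(inherits(trace, "accel_trace"))
  fs <- trace$sample_rate
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1 ||
      cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff_hz must lie in (0, %g) for a %g Hz trace",
                 fs / 2, fs))
  }
  bf <- signal::butter(order, 2 * cutoff_hz / fs, type = "low")
  # hold-first-value padding settles the filter state so DC passes exactly
  n_pad <- ceiling(10 / cutoff_hz * fs)
  filt1 <- function(x) {
    y <- signal::filter(bf, c(rep(x[1], n_pad), x))
    as.numeric(y)[-seq_len(n_pad)]
  }
  out <- cbind(gx = filt1(trace$ax), gy = filt1(trace$ay),
               gz = filt1(trace$az))
  attr(out, "warmup_s") <- 3 / (2 * pi * cutoff_hz)
  out
}

# earliest run of `win` consecutive TRUE values in `ok`; returns start index
# or NA. `from` restricts starts to indices >= from, `last_start` to <= it.
first_true_run <- function(ok, win, from = 1L, last_start = length(ok)) {
  n <- length(ok)
  if (win < 1 || n < win) return(NA_integer_)
  cs <- cumsum(as.integer(ok))
  lo <- max(1L, from)
  hi <- min(n - win + 1L, last_start)
  if (hi < lo) return(NA_integer_)
  # number of TRUE in window starting at i: cs[i+win-1] - cs[i-1]
  starts <- seq.int(lo, hi)
  full <- cs[starts + win - 1L] - c(0, cs)[starts]
  hit <- which(full == win)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

#' Capture gravity from the earliest still window
#'
#' Scans the trace for the earliest contiguous window of length `window_s`
#' in which every sample's sum acceleration lies inside `band_g` (by default
#' 0.7-1.3 g, i.e. within +/-0.3 g of standing or lying still). The mean
#' axis vector over that window is returned as the gravity estimate; this is
#' how both the pre-fall reference `g_before` and the post-impact `g_after`
#' are obtained.
#'
#' @param trace an [accel_trace()].
#' @param window_s window length in seconds (> 0; default 0.5 s, long enough
#'   to average residual oscillation yet short against the 2 s settling
#'   limit).
#' @param band_g numeric length-2 `(low, high)` acceptance band on |a| in
#'   g-units.
#' @param from_time,to_time restrict the search to windows starting at or
#'   after `from_time` and ending at or before `to_time` (seconds).
#' @return A [gravity_vector()] with `source_window` set, or `NULL` if no
#'   qualifying window exists (absence is a value, not an error).
#' @export
capture_still_gravity <- function(trace, window_s = 0.5,
                                  band_g = c(0.7, 1.3),
                                  from_time = -Inf, to_time = Inf) {
  stopifnot(inherits(trace, "accel_trace"),
            length(band_g) == 2, band_g[1] < band_g[2])
  if (!is.numeric(window_s) || window_s <= 0) {
    stop("window_s must be positive")
  }
  fs <- trace$sample_rate
  win <- max(1L, as.integer(round(window_s * fs)))
  s <- sum_acceleration(trace)
  ok <- s >= band_g[1] & s <= band_g[2]
  from <- if (is.finite(from_time)) {
    which(trace$t >= from_time)[1]
  } else 1L
  if (is.na(from)) return(NULL)
  last_end <- if (is.finite(to_time)) {
    ends <- which(trace$t <= to_time)
    if (length(ends) == 0) return(NULL)
    ends[length(ends)]
  } else length(s)
  start <- first_true_run(ok, win, from = from,
                          last_start = last_end - win + 1L)
  if (is.na(start)) return(NULL)
  idx <- start:(start + win - 1L)
  gravity_vector(mean(trace$ax[idx]), mean(trace$ay[idx]),
                 mean(trace$az[idx]),
                 source_window = c(trace$t[idx[1]], trace$t[idx[win]]))
}
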