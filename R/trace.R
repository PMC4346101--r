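#' Construct a triaxial accelerometer trace
#'
#' A uniformly sampled, timestamped triaxial acceleration series in g-units.
#' All thresholds in this package are stated in g (multiples of standard
#' gravity), matching how wearable accelerometers report and how the
#' detection thresholds are specified.
#'
#' @param t sample times in seconds, strictly increasing and uniform at
#'   `sample_rate` (each step within 1e-6 s of `1/sample_rate`).
#' @param ax,ay,az per-sample accelerations along the device axes, in
#'   g-units.
#' @param sample_rate sampling rate in Hz (default 100, the usual rate for
#'   human-movement capture).
#' @return An object of class `"accel_trace"`: a list with elements `t`,
#'   `ax`, `ay`, `az`, `sample_rate`.
#' @seealso [read_accel_trace()], [sum_acceleration()], [detect_falls()]
#' @export
accel_trace <- function(t, ax, ay, az, sample_rate = 100) {
  t <- as.numeric(t); ax <- as.numeric(ax)
  ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(t)
  if (n < 1) stop("trace must contain at least one sample")
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("t, ax, ay, az must have equal length")
  }
  if (!all(is.finite(t)) || !all(is.finite(ax)) ||
      !all(is.finite(ay)) || !all(is.finite(az))) {
    stop("trace contains non-finite values")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  if (n > 1) {
    dt <- diff(t)
    bad <- which(abs(dt - 1 / sample_rate) >= 1e-6)
    if (length(bad) > 0) {
      stop(sprintf(
        "non-uniform or non-increasing timestamps at sample %d (t = %g -> %g; expected step %g s)",
        bad[1] + 1, t[bad[1]], t[bad[1] + 1], 1 / sample_rate))
    }
  }
  structure(list(t = t, ax = ax, ay = ay, az = az, sample_rate = sample_rate),
            class = "accel_trace")
}

#' Number of samples in a trace
#' @param trace an [accel_trace()].
#' @return Integer sample count.
#' @export
n_samples <- function(trace) length(trace$t)

#' @export
print.accel_trace <- function(x, ...) {
  s <- sum_acceleration(x)
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.2f s)\n",
              n_samples(x), x$sample_rate, x$t[length(x$t)] - x$t[1]))
  cat(sprintf("  |a| range: %.3f - %.3f g\n", min(s), max(s)))
  invisible(x)
}

#' @export
as.data.frame.accel_trace <- function(x, ...) {
  data.frame(t = x$t, ax = x$ax, ay = x$ay, az = x$az)
}

#' @export
plot.accel_trace <- function(x, which = c("norm", "axes"), ...) {
  which <- match.arg(which)
  if (which == "norm") {
    graphics::plot(x$t, sum_acceleration(x), type = "l",
                   xlab = "time [s]", ylab = "|a| [g]", ...)
  } else {
    graphics::matplot(x$t, cbind(x$ax, x$ay, x$az), type = "l", lty = 1,
                      xlab = "time [s]", ylab = "acceleration [g]", ...)
    graphics::legend("topright", legend = c("ax", "ay", "az"),
                     col = 1:3, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Read an accelerometer trace from CSV
#'
#' Expects the dialect written by [write_accel_trace()]: a header line
#' `t,ax,ay,az`, one row per sample, times in seconds, accelerations in
#' g-units. Timestamps must be strictly increasing and uniform; malformed
#' rows are rejected with their line number.
#'
#' @param path path to a CSV file.
#' @param sample_rate expected sampling rate in Hz; if `NULL` (default) it is
#'   inferred from the median timestamp step.
#' @return An [accel_trace()].
#' @export
read_accel_trace <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("trace file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) stop("trace file ", path, " contains no samples")
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("trace file %s: non-numeric value in column '%s' at line %d",
                   path, col, bad[1] + 1L))  # +1 for header line
    }
    df[[col]] <- v
  }
  if (nrow(df) > 1 && any(diff(df$t) <= 0)) {
    bad <- which(diff(df$t) <= 0)[1]
    stop(sprintf("trace file %s: timestamps not strictly increasing at line %d",
                 path, bad + 2L))
  }
  if (is.null(sample_rate)) {
    sample_rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$t)) else 100
  }
  tryCatch(
    accel_trace(df$t, df$ax, df$ay, df$az, sample_rate = sample_rate),
    error = function(e) stop("trace file ", path, ": ", conditionMessage(e))
  )
}

#' Write an accelerometer trace to CSV
#'
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @param digits significant digits used when formatting (default keeps the
#'   write/read round trip well below 1e-9).
#' @return `path`, invisibly.
#' @export
write_accel_trace <- function(trace, path, digits = 15) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- as.data.frame(trace)
  df[] <- lapply(df, function(v) formatC(v, digits = digits, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
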