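#' Per-class alarm/trial counts
#'
#' Bookkeeping container for an evaluation in which each trace (trial) of a
#' motion class either raised at least one alarm or did not. Fall classes
#' are the positive class; ADLs the negative class.
#'
#' @param motion_class character vector of class names.
#' @param alarms integer vector: trials of that class with >= 1 alarm.
#' @param trials integer vector: total trials of that class.
#' @param is_fall logical vector mapping each class to fall/ADL; by default
#'   inferred from the class name (`fall_*`).
#' @return An object of class `"confusion_counts"` (a data frame).
#' @examples
#' confusion_counts(c("fall_forward", "walking"), alarms = c(58, 0),
#'                  trials = c(60, 60))
#' @export
confusion_counts <- function(motion_class, alarms, trials,
                             is_fall = startsWith(motion_class, "fall")) {
  stopifnot(length(motion_class) == length(alarms),
            length(alarms) == length(trials),
            length(is_fall) == length(motion_class))
  alarms <- as.integer(alarms); trials <- as.integer(trials)
  if (any(alarms < 0) || any(trials < 0) || any(alarms > trials)) {
    stop("counts must satisfy 0 <= alarms <= trials for every class")
  }
  structure(data.frame(motion_class = as.character(motion_class),
                       alarms = alarms, trials = trials, is_fall = is_fall,
                       stringsAsFactors = FALSE),
            class = c("confusion_counts", "data.frame"))
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Sensitivity and specificity from per-class counts
#'
#' Aggregates per-class alarm counts into the 2x2 confusion totals and the
#' two headline rates: alarmed fall trials are true positives, silent fall
#' trials false negatives, alarmed ADL trials false positives and silent
#' ADL trials true negatives. Then
#' \deqn{\mathrm{sensitivity} = 100 \cdot TP / (TP + FN), \qquad
#'       \mathrm{specificity} = 100 \cdot TN / (TN + FP).}
#'
#' @param counts a [confusion_counts()] containing at least one fall class
#'   and one ADL class, each with at least one trial.
#' @return An object of class `"fall_metrics"`: list with `sensitivity` and
#'   `specificity` (exact percentages), `tp`, `fn`, `fp`, `tn`, and the
#'   per-class `counts`. The print method reports rates rounded half-up to
#'   one decimal alongside the exact fractions.
#' @examples
#' m <- fall_metrics(confusion_counts(
#'   c("fall_forward", "walking"), alarms = c(58, 1), trials = c(60, 60)))
#' m$sensitivity
#' @export
fall_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (!any(counts$is_fall) || !all(counts$trials[counts$is_fall] > 0)) {
    stop("need at least one fall class with a positive trial count")
  }
  if (!any(!counts$is_fall) || !all(counts$trials[!counts$is_fall] > 0)) {
    stop("need at least one ADL class with a positive trial count")
  }
  tp <- sum(counts$alarms[counts$is_fall])
  fn <- sum(counts$trials[counts$is_fall]) - tp
  fp <- sum(counts$alarms[!counts$is_fall])
  tn <- sum(counts$trials[!counts$is_fall]) - fp
  structure(list(sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 tp = tp, fn = fn, fp = fp, tn = tn,
                 counts = counts),
            class = "fall_metrics")
}

#' @export
print.fall_metrics <- function(x, ...) {
  cat(sprintf("Sensitivity: %.1f%%  (%d/%d fall trials alarmed; exact %.4f%%)\n",
              round_half_up(x$sensitivity), x$tp, x$tp + x$fn, x$sensitivity))
  cat(sprintf("Specificity: %.1f%%  (%d/%d ADL trials silent;  exact %.4f%%)\n",
              round_half_up(x$specificity), x$tn, x$tn + x$fp, x$specificity))
  cat("Per-class alarms/trials:\n")
  df <- x$counts
  for (k in seq_len(nrow(df))) {
    cat(sprintf("  %-15s %3d/%3d %s\n", df$motion_class[k], df$alarms[k],
                df$trials[k], if (df$is_fall[k]) "[fall]" else "[ADL]"))
  }
  invisible(x)
}

#' Benchmark both detectors on a synthetic cohort
#'
#' Runs the two-feature quaternion detector and the acceleration-only
#' baseline on every trace of a labelled cohort, counts a trial as alarmed
#' when at least one event with `is_alarm = TRUE` occurs, and computes
#' sensitivity/specificity for both detectors. Deterministic for a fixed
#' cohort.
#'
#' @param cohort a [generate_cohort()] result (non-empty).
#' @param config a [detector_config()].
#' @return An object of class `"fall_benchmark"`: list with
#'   `counts_quaternion`, `counts_baseline` ([confusion_counts()]),
#'   `metrics_quaternion`, `metrics_baseline` ([fall_metrics()]) and
#'   `per_trace` (data frame: `id`, `motion_class`, `is_fall`,
#'   `alarm_quaternion`, `alarm_baseline`, `n_events`, `theta` of the first
#'   alarmed or rejected event, `NA` when no event).
#' @export
run_benchmark <- function(cohort, config = detector_config()) {
  stopifnot(inherits(cohort, "motion_cohort"))
  if (length(cohort$sims) == 0) stop("cohort is empty")
  lab <- cohort$labels
  n <- nrow(lab)
  alarm_q <- logical(n); alarm_b <- logical(n)
  nev <- integer(n); theta <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    tr <- cohort$sims[[k]]$trace
    fit_q <- tryCatch(
      detect_falls(tr, config, method = "quaternion", keep_trace = FALSE),
      error = function(e) stop("trace ", lab$id[k], ": ",
                               conditionMessage(e), call. = FALSE))
    fit_b <- detect_falls(tr, config, method = "acceleration",
                          keep_trace = FALSE)
    ev <- fit_q$events
    alarm_q[k] <- any(ev$is_alarm)
    alarm_b[k] <- any(fit_b$events$is_alarm)
    nev[k] <- nrow(ev)
    if (nrow(ev) > 0) {
      pick <- if (any(ev$is_alarm)) which(ev$is_alarm)[1] else 1L
      theta[k] <- ev$theta[pick]
    }
  }
  per_trace <- data.frame(id = lab$id, motion_class = lab$motion_class,
                          is_fall = lab$is_fall, alarm_quaternion = alarm_q,
                          alarm_baseline = alarm_b, n_events = nev,
                          theta = theta, stringsAsFactors = FALSE)
  agg <- function(flag) {
    cls <- unique(lab$motion_class)
    confusion_counts(cls,
                     alarms = vapply(cls, function(cc)
                       sum(flag[lab$motion_class == cc]), numeric(1)),
                     trials = vapply(cls, function(cc)
                       sum(lab$motion_class == cc), numeric(1)))
  }
  cq <- agg(alarm_q); cb <- agg(alarm_b)
  structure(list(counts_quaternion = cq, counts_baseline = cb,
                 metrics_quaternion = fall_metrics(cq),
                 metrics_baseline = fall_metrics(cb),
                 per_trace = per_trace, config = config),
            class = "fall_benchmark")
}

#' @export
print.fall_benchmark <- function(x, ...) {
  cat("Benchmark on", nrow(x$per_trace), "synthetic traces\n\n")
  cat("Quaternion (two-feature) detector:\n")
  print(x$metrics_quaternion)
  cat("\nAcceleration-threshold baseline:\n")
  print(x$metrics_baseline)
  invisible(x)
}

#' Benchmark report as a Table-style data frame
#'
#' One row per motion class with alarm/trial counts for both detectors,
#' convenient for export.
#'
#' @param bench a [run_benchmark()] result.
#' @return A data frame with columns `motion_class`, `is_fall`,
#'   `alarms_quaternion`, `alarms_baseline`, `trials`.
#' @export
benchmark_table <- function(bench) {
  stopifnot(inherits(bench, "fall_benchmark"))
  q <- bench$counts_quaternion
  b <- bench$counts_baseline
  data.frame(motion_class = q$motion_class, is_fall = q$is_fall,
             alarms_quaternion = q$alarms,
             alarms_baseline = b$alarms[match(q$motion_class, b$motion_class)],
             trials = q$trials, stringsAsFactors = FALSE)
}
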