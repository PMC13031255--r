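#' Slider traces
#'
#' A `slider_trace` is a uniformly sampled, normalized comprehension time
#' series for one trial: values in `[0, 1]` at sampling rate `fs` (default
#' 250 Hz, the device readout rate), starting at time `t0`, with the trial's
#' speech-rate condition and identifiers attached.
#'
#' @param values numeric vector in `[0, 1]`.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @param condition speech-rate label (e.g. `1`, `2.5`), or `NA`.
#' @param participant_id,trial_id identifiers.
#' @param quality named list of quality metadata (e.g. filled gap count).
#' @return an object of class `slider_trace`.
#' @export
slider_trace <- function(values, fs = 250, t0 = 0, condition = NA,
                         participant_id = NA_character_,
                         trial_id = NA_character_, quality = list()) {
  if (!is.numeric(values) || length(values) == 0)
    stopf("'values' must be a non-empty numeric vector")
  if (any(!is.finite(values)) || any(values < -1e-9) || any(values > 1 + 1e-9))
    stopf("trace values must lie in [0, 1]")
  if (!is_scalar_number(fs) || fs <= 0) stopf("'fs' must be positive")
  structure(list(values = clip01(as.numeric(values)), fs = fs, t0 = t0,
                 condition = condition, participant_id = participant_id,
                 trial_id = trial_id, quality = quality),
            class = "slider_trace")
}

#' @export
print.slider_trace <- function(x, ...) {
  cat(sprintf("<slider_trace> %d samples @ %g Hz (%.2f s), condition %s\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              format(x$condition)))
  cat(sprintf("  median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.slider_trace <- function(x) length(x$values)

# Sample times of a trace, seconds.
trace_times <- function(trace) trace$t0 + (seq_along(trace$values) - 1) / trace$fs

#' Parse a raw slider device log
#'
#' Device logs are CSV files with a header and columns `device_time_ms`
#' (milliseconds on the device clock), `host_time_s` (seconds on the host
#' clock) and `value` (8-bit ADC reading, 0-255). Device timestamps must be
#' strictly increasing and values within the ADC range; violations raise a
#' format error naming the offending row.
#'
#' @param path path to a CSV log file.
#' @return a `data.frame` with the three typed columns.
#' @seealso [write_slider_log()], [to_trace()]
#' @export
parse_slider_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_slider_log(df, where = path)
}

validate_slider_log <- function(df, where = "slider log") {
  need <- c("device_time_ms", "host_time_s", "value")
  if (!all(need %in% names(df)))
    stopf("%s: missing column(s) %s", where,
          paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  if (nrow(df) == 0) stopf("%s: empty log", where)
  bad <- which(df$value < 0 | df$value > 255 | df$value != floor(df$value))
  if (length(bad))
    stopf("%s: value outside 0-255 at row %d", where, bad[1])
  nonmono <- which(diff(df$device_time_ms) <= 0)
  if (length(nonmono))
    stopf("%s: device_time_ms not strictly increasing at row %d",
          where, nonmono[1] + 1L)
  df$value <- as.integer(df$value)
  df
}

#' @param log a raw slider log `data.frame`.
#' @rdname parse_slider_log
#' @export
write_slider_log <- function(log, path) {
  validate_slider_log(log)
  utils::write.csv(log[c("device_time_ms", "host_time_s", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate device clock drift against the host clock
#'
#' The device (MCU) clock and the host clock diverge slowly; the drift is
#' estimated by comparing elapsed time on the two clocks with a least-squares
#' straight line `device_time = offset + rate_ratio * host_time`. A device
#' clock running fast by 400 ppm gives `rate_ratio = 1.0004`; the drift
#' fraction is `rate_ratio - 1`. The host clock is the reference ("golden")
#' clock because it is aligned with audio playback.
#'
#' @param log a raw slider log (see [parse_slider_log()]).
#' @return a list with `rate_ratio` (device seconds per host second), `offset`
#'   (device clock reading at host time 0, seconds), `drift_fraction`
#'   (`rate_ratio - 1`), and `max_residual` (largest absolute fit residual,
#'   seconds; nonzero under USB timing jitter).
#' @export
estimate_clock_drift <- function(log) {
  log <- validate_slider_log(log)
  if (nrow(log) < 2) stopf("need at least 2 log rows to estimate clock drift")
  x <- log$host_time_s
  y <- log$device_time_ms / 1000
  vx <- stats::var(x)
  if (vx == 0) stopf("host timestamps are constant; cannot estimate drift")
  slope <- stats::cov(x, y) / vx
  offset <- mean(y) - slope * mean(x)
  res <- y - (offset + slope * x)
  list(rate_ratio = slope, offset = offset, drift_fraction = slope - 1,
       max_residual = max(abs(res)))
}

#' Convert a raw log to a uniform normalized trace
#'
#' Maps device timestamps onto the host clock (undoing the fitted clock
#' drift), normalizes ADC values, and resamples onto a uniform `fs` grid by
#' zero-order hold: the slider reports a held physical position, so the last
#' reported value persists until the next report (linear interpolation is
#' available as an option). Normalization divides by 255 (the device maximum)
#' by default so a participant who never reaches the top is not inflated;
#' `normalize = "trial"` applies per-trial min-max scaling instead.
#'
#' Gaps longer than 5 sample periods are filled by the hold and counted in the
#' trace's `quality$n_gaps` metadata.
#'
#' @param log a raw slider log.
#' @param fs output sampling rate in Hz.
#' @param correct_drift map device timestamps to the host clock first.
#' @param normalize `"device"` (divide by 255) or `"trial"` (min-max).
#' @param interpolation `"hold"` (zero-order hold) or `"linear"`.
#' @param duration_s grid duration; defaults to the log's time span.
#' @param condition,participant_id,trial_id metadata attached to the trace.
#' @return a [slider_trace()].
#' @export
to_trace <- function(log, fs = 250, correct_drift = TRUE,
                     normalize = c("device", "trial"),
                     interpolation = c("hold", "linear"),
                     duration_s = NULL, condition = NA,
                     participant_id = NA_character_,
                     trial_id = NA_character_) {
  log <- validate_slider_log(log)
  normalize <- match.arg(normalize)
  interpolation <- match.arg(interpolation)
  if (correct_drift && nrow(log) >= 2) {
    fit <- estimate_clock_drift(log)
    times <- (log$device_time_ms / 1000 - fit$offset) / fit$rate_ratio
  } else {
    times <- log$device_time_ms / 1000
  }
  times <- times - times[1]
  v <- if (normalize == "device") log$value / 255 else {
    rng <- range(log$value)
    if (diff(rng) == 0) rep(0, nrow(log)) else (log$value - rng[1]) / diff(rng)
  }
  if (is.null(duration_s)) duration_s <- max(times)
  n <- expected_sample_count(duration_s, fs)
  if (n < 1) stopf("log too short for a single output sample")
  grid <- (seq_len(n) - 1) / fs
  vals <- if (length(times) == 1) rep(v, n) else
    stats::approx(times, v, xout = grid,
                  method = if (interpolation == "hold") "constant" else "linear",
                  f = 0, rule = 2)$y
  n_gaps <- sum(diff(times) > 5 / fs)
  slider_trace(vals, fs = fs, t0 = 0, condition = condition,
               participant_id = participant_id, trial_id = trial_id,
               quality = list(n_gaps = n_gaps,
                              drift_corrected = isTRUE(correct_drift),
                              normalize = normalize))
}

#' Expected sample count of a trial
#'
#' Number of readout samples for a trial of a given duration, with half-up
#' rounding: at 250 Hz, mean durations 29, 14.55, 10.93, 7.28 and 5.81 s give
#' 7250, 3638, 2733, 1820 and 1453 samples.
#'
#' @param duration_s trial duration in seconds, non-negative.
#' @param fs sampling rate in Hz.
#' @return integer sample count.
#' @export
expected_sample_count <- function(duration_s, fs = 250) {
  if (!is.numeric(duration_s) || any(duration_s < 0))
    stopf("'duration_s' must be non-negative")
  if (!is_scalar_number(fs) || fs <= 0) stopf("'fs' must be positive")
  as.integer(round_half_up(duration_s * fs))
}

#' Median slider score of a trial
#'
#' The median of the trace's time course, the single comprehension score used
#' per trial.
#'
#' @param trace a [slider_trace()].
#' @return the median, in `[0, 1]`.
#' @export
median_score <- function(trace) {
  if (!inherits(trace, "slider_trace")) stopf("'trace' must be a slider_trace")
  if (length(trace$values) == 0) stopf("empty trace")
  stats::median(trace$values)
}

#' Per-rate initial-movement cutoffs (seconds)
#'
#' Cut-off points for the initial movement away from the slider origin: 5, 4,
#' 2.5, 2 and 1.5 s for speech rates x1 to x5.
#' @export
initial_movement_cutoffs <- c(`1` = 5, `2` = 4, `3` = 2.5, `4` = 2, `5` = 1.5)

#' Crop the initial slider movement
#'
#' Removes the opening portion of a trace where the participant is still
#' moving away from the 0 origin, using per-rate cutoffs (default
#' [initial_movement_cutoffs]).
#'
#' @param trace a [slider_trace()].
#' @param rate speech-rate condition, used to select the cutoff.
#' @param cutoffs named vector mapping rate labels to cutoff seconds.
#' @return the cropped [slider_trace()]; errors if the trace is not longer
#'   than the cutoff.
#' @export
crop_initial_movement <- function(trace, rate,
                                  cutoffs = initial_movement_cutoffs) {
  if (!inherits(trace, "slider_trace")) stopf("'trace' must be a slider_trace")
  key <- as.character(rate)
  if (!key %in% names(cutoffs))
    stopf("no initial-movement cutoff defined for rate '%s'", key)
  cut <- cutoffs[[key]]
  n_cut <- as.integer(round_half_up(cut * trace$fs))
  if (n_cut >= length(trace$values))
    stopf("trace (%.2f s) is not longer than the %.2f s cutoff",
          length(trace$values) / trace$fs, cut)
  out <- trace
  out$values <- trace$values[(n_cut + 1L):length(trace$values)]
  out$t0 <- trace$t0 + n_cut / trace$fs
  out
}

#' First differences of a trace
#'
#' The change between consecutive slider values.
#'
#' @param trace a [slider_trace()].
#' @return numeric vector of length `length(trace) - 1`.
#' @export
differential <- function(trace) {
  if (!inherits(trace, "slider_trace")) stopf("'trace' must be a slider_trace")
  if (length(trace$values) < 2) stopf("need at least 2 samples")
  diff(trace$values)
}

#' Pentile medians of a trace
#'
#' Splits the trace into five contiguous time bins (pentiles) whose sizes
#' differ by at most one sample (remainder to the earliest bins) and returns
#' the median slider score per bin.
#'
#' @param trace a [slider_trace()].
#' @return numeric vector of five medians.
#' @export
pentile_trace_scores <- function(trace) {
  if (!inherits(trace, "slider_trace")) stopf("'trace' must be a slider_trace")
  idx <- pentile_index(length(trace$values))
  as.numeric(tapply(trace$values, idx, stats::median))
}

#' Movement-based attention check
#'
#' Flags participants whose overall slider movement is an outlier: the
#' movement statistic is each participant's mean, over trials, of the total
#' absolute trace displacement (sum of absolute first differences), and a
#' participant is flagged when their statistic lies beyond `threshold`
#' standard deviations from the group mean (default 3.5).
#'
#' @param records list of trial records (see [simulate_session()]); each must
#'   carry `participant_id` and a `trace`.
#' @param threshold flagging threshold in group standard deviations.
#' @return a `data.frame` with `participant_id`, `movement` and logical
#'   `flagged`.
#' @export
movement_outlier_check <- function(records, threshold = 3.5) {
  if (length(records) == 0) stopf("no records")
  pid <- vapply(records, function(r) r$participant_id, character(1))
  disp <- vapply(records, function(r) sum(abs(diff(r$trace$values))), numeric(1))
  per <- tapply(disp, pid, mean)
  if (length(per) < 2)
    stopf("need at least 2 participants for the movement outlier check")
  mu <- mean(per); sdv <- stats::sd(per)
  flagged <- if (sdv == 0) rep(FALSE, length(per)) else
    abs(per - mu) > threshold * sdv
  data.frame(participant_id = names(per), movement = as.numeric(per),
             flagged = as.logical(flagged), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a trace as CSV
#'
#' Writes columns `t` (seconds) and `value`.
#' @param trace a [slider_trace()].
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t = trace_times(trace), value = trace$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
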