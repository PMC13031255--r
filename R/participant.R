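#' Simulated participant profiles
#'
#' A participant profile collects the latent quantities that drive the
#' synthetic slider data: a sigmoidal comprehension-versus-speech-rate curve
#' (asymptote, slope and center), a gamma-shaped motor response-delay kernel,
#' motor noise, device clock drift, and the two covariate scores (digit span
#' and digit-in-noise). All downstream generators consume a profile, so the
#' ground truth behind every simulated trace is known and recoverable.
#'
#' The comprehension curve is
#' \deqn{c(x) = \mathrm{comp\_max} / (1 + \exp(\mathrm{comp\_slope}\,(x - \mathrm{comp\_center})))}
#' which declines monotonically in speech rate \eqn{x} for `comp_slope > 0`,
#' from `comp_max` at slow rates toward 0 at fast rates, with midpoint
#' `comp_max / 2` at `x = comp_center`.
#'
#' @param seed single non-negative integer; the profile is a deterministic
#'   function of it.
#' @param overrides named list of field values overriding the seeded draws.
#'   Unknown names or values violating a field invariant raise an error naming
#'   the field.
#' @return an object of class `participant_profile`: a named list with fields
#'   `participant_id`, `comp_max` (in (0, 1]), `comp_slope` (> 0),
#'   `comp_center` (speech-rate units), `delay_shape` and `delay_scale`
#'   (gamma kernel, seconds), `motor_noise_sd` (normalized slider units),
#'   `drift_ppm` (parts-per-million, at most 500 so drift stays below 0.05%),
#'   `digit_span` (integer 3-9), `digit_in_noise` (percent), `rng_seed`.
#' @examples
#' p <- make_participant(1)
#' latent_comprehension(p, rate = 1:5)
#' @export
make_participant <- function(seed, overrides = list()) {
  if (!is_scalar_number(seed) || seed < 0)
    stopf("'seed' must be a single non-negative integer")
  prof <- with_seed(seed, list(
    participant_id = sprintf("sub-%05d", as.integer(seed %% 100000)),
    comp_max       = stats::runif(1, 0.75, 1),
    comp_slope     = stats::runif(1, 1.5, 2.5),
    comp_center    = stats::runif(1, 2.5, 3.5),
    delay_shape    = stats::runif(1, 2, 4),
    delay_scale    = stats::runif(1, 0.3, 0.6),
    motor_noise_sd = 0.05,
    drift_ppm      = stats::runif(1, 0, 500),
    digit_span     = sample(3:9, 1),
    digit_in_noise = round(stats::runif(1, 50, 100), 1),
    rng_seed       = as.integer(seed %% 2147483647)
  ))
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stopf("'overrides' must be a named list")
    unknown <- setdiff(names(overrides), names(prof))
    if (length(unknown))
      stopf("unknown participant field(s): %s", paste(unknown, collapse = ", "))
    prof[names(overrides)] <- overrides
  }
  validate_participant(prof)
  structure(prof, class = "participant_profile")
}

validate_participant <- function(p) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stopf("invalid participant field '%s': %s", field, what)
  }
  chk(is_scalar_number(p$comp_max) && p$comp_max > 0 && p$comp_max <= 1,
      "comp_max", "must be in (0, 1]")
  chk(is_scalar_number(p$comp_slope) && p$comp_slope > 0,
      "comp_slope", "must be > 0")
  chk(is_scalar_number(p$comp_center), "comp_center", "must be a finite number")
  chk(is_scalar_number(p$delay_shape) && p$delay_shape > 0,
      "delay_shape", "must be > 0")
  chk(is_scalar_number(p$delay_scale) && p$delay_scale > 0,
      "delay_scale", "must be > 0")
  chk(is_scalar_number(p$motor_noise_sd) && p$motor_noise_sd >= 0,
      "motor_noise_sd", "must be >= 0")
  chk(is_scalar_number(p$drift_ppm) && p$drift_ppm >= 0 && p$drift_ppm <= 500,
      "drift_ppm", "must be in [0, 500] (drift below 0.05%)")
  chk(is_scalar_number(p$digit_span) && p$digit_span %in% 3:9,
      "digit_span", "must be an integer in 3..9")
  chk(is_scalar_number(p$digit_in_noise) && p$digit_in_noise >= 0 &&
        p$digit_in_noise <= 100,
      "digit_in_noise", "must be a percentage in [0, 100]")
  invisible(p)
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("<participant_profile> %s\n", x$participant_id))
  cat(sprintf("  comprehension: max %.3f, slope %.2f, center x%.2f\n",
              x$comp_max, x$comp_slope, x$comp_center))
  cat(sprintf("  delay kernel : gamma(shape %.2f, scale %.2f s), mode %.2f s\n",
              x$delay_shape, x$delay_scale,
              max(0, (x$delay_shape - 1) * x$delay_scale)))
  cat(sprintf("  motor noise %.3f, drift %.0f ppm, digit span %d, DIN %.1f%%\n",
              x$motor_noise_sd, x$drift_ppm, as.integer(x$digit_span),
              x$digit_in_noise))
  invisible(x)
}

#' Latent comprehension level at a speech rate
#'
#' Evaluates the participant's declining sigmoid
#' `comp_max / (1 + exp(comp_slope * (rate - comp_center)))`.
#'
#' @param profile a [make_participant()] profile.
#' @param rate positive speech-rate factor(s) (1 = original recording rate).
#' @return comprehension level(s) in `[0, 1]`, non-increasing in `rate`.
#' @export
latent_comprehension <- function(profile, rate) {
  if (!inherits(profile, "participant_profile"))
    stopf("'profile' must be a participant_profile")
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0))
    stopf("'rate' must be positive")
  profile$comp_max / (1 + exp(profile$comp_slope * (rate - profile$comp_center)))
}

#' Discrete motor response-delay kernel
#'
#' The participant's response delay is modeled as a gamma density (a unimodal,
#' strictly positive-lag kernel); this returns it sampled at `fs` and
#' normalized to unit mass, so convolving a target trajectory with the kernel
#' delays and smooths it without changing its level.
#'
#' @param profile a [make_participant()] profile.
#' @param fs sampling rate in Hz.
#' @param t_max kernel support in seconds; defaults to the 99.9% gamma
#'   quantile.
#' @return numeric vector of weights summing to one; element k acts at lag
#'   `(k-1)/fs` seconds.
#' @export
delay_kernel <- function(profile, fs, t_max = NULL) {
  if (!is_scalar_number(fs) || fs <= 0) stopf("'fs' must be positive")
  if (is.null(t_max))
    t_max <- stats::qgamma(0.999, shape = profile$delay_shape,
                           scale = profile$delay_scale)
  t <- seq(0, t_max, by = 1 / fs)
  w <- stats::dgamma(t, shape = profile$delay_shape, scale = profile$delay_scale)
  if (sum(w) <= 0) stopf("degenerate delay kernel")
  w / sum(w)
}
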