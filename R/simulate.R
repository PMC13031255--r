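# Synthetic-data generators: device logs, sessions, word events, summaries.
# Every generator is a deterministic function of its seed (or of the
# participant profile's rng_seed), so downstream stages can be tested against
# known ground truth without the physical device.

# Internal vocabulary used for synthetic segments and stories.
.compslide_vocab <- c(
  "the", "a", "an", "and", "but", "or", "so", "because", "while", "when",
  "morning", "evening", "night", "summer", "winter", "garden", "river",
  "mountain", "village", "city", "house", "kitchen", "window", "door",
  "road", "forest", "field", "market", "harbor", "island", "bridge",
  "teacher", "doctor", "farmer", "sailor", "painter", "writer", "child",
  "mother", "father", "sister", "brother", "friend", "neighbor", "stranger",
  "dog", "cat", "horse", "bird", "fox", "ant", "grasshopper", "wind", "sun",
  "mouse", "grape", "walked", "ran", "spoke", "listened", "watched",
  "waited", "carried", "found", "lost", "opened", "closed", "remembered",
  "forgot", "promised", "decided", "laughed", "cried", "whispered",
  "shouted", "cooked", "planted", "harvested", "sailed", "painted", "wrote",
  "slowly", "quickly", "quietly", "suddenly", "carefully", "finally",
  "early", "late", "often", "never", "always", "again", "together", "alone",
  "old", "young", "small", "large", "warm", "cold", "bright", "dark",
  "heavy", "light", "empty", "full", "happy", "tired", "hungry", "proud",
  "storm", "rain", "snow", "cloud", "letter", "story", "song", "secret",
  "journey", "dinner", "breakfast", "afternoon", "yesterday", "tomorrow")

# Mean words per minute at the original recording rate; inter-word interval
# at speech rate r is 60 / (.base_wpm * r) seconds.
.base_wpm <- 195.76

#' Session plans
#'
#' Builds the trial schedule for one of the three experiment designs:
#'
#' * `exp1` - 125 short audiobook segments, 25 at each of the five speech
#'   rates x1..x5, with per-rate mean durations 29, 14.55, 10.93, 7.28 and
#'   5.81 s, in shuffled order.
#' * `exp2` - continuous blocks of 7.5-s chunks; each block presents each of
#'   the five rates 16 times (10 minutes per block) in pseudo-random order
#'   with no immediate rate repeats.
#' * `exp3` - four stories presented at both x1 and x2.5 (eight trials),
#'   alternating low- and high-surprisal parts of about 30 words each; two
#'   stories start at x1 and two at x2.5.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param n_blocks number of blocks (exp2 only).
#' @param chunk_s chunk duration in seconds (exp2).
#' @param words_per_chunk words per surprisal part (exp3).
#' @param n_chunks surprisal parts per story (exp3, even).
#' @param seed seed for the trial ordering.
#' @return an object of class `session_plan`: list with `experiment`, a
#'   `trials` data.frame (`trial_id`, `speech_rate`, `duration_s`, `block`,
#'   `surprisal_schedule`), `chunk_s`, `words_per_chunk`.
#' @export
session_plan <- function(experiment = c("exp1", "exp2", "exp3"),
                         n_blocks = 2, chunk_s = 7.5, words_per_chunk = 30,
                         n_chunks = 10, seed = 1) {
  experiment <- match.arg(experiment)
  trials <- switch(experiment,
    exp1 = {
      durs <- c(`1` = 29, `2` = 14.55, `3` = 10.93, `4` = 7.28, `5` = 5.81)
      rate <- rep(1:5, each = 25)
      ord <- with_seed(seed, sample.int(length(rate)))
      data.frame(speech_rate = rate[ord],
                 duration_s = durs[as.character(rate[ord])],
                 block = 1L, surprisal_schedule = "none",
                 stringsAsFactors = FALSE)
    },
    exp2 = {
      one_block <- function() {
        # 16 chunks of each rate, no immediate repeats: draw sequentially,
        # always taking the majority rate when it must be interleaved,
        # otherwise sampling among allowed rates by remaining count
        repeat {
          left <- stats::setNames(rep(16L, 5), 1:5)
          out <- integer(80)
          ok <- TRUE
          for (j in seq_len(80)) {
            allowed <- names(left)[left > 0]
            if (j > 1) allowed <- setdiff(allowed, as.character(out[j - 1]))
            if (length(allowed) == 0) { ok <- FALSE; break }
            must <- allowed[left[allowed] > (80 - j + 1) / 2]
            pick <- if (length(must)) must[1] else
              sample(allowed, 1, prob = left[allowed])
            out[j] <- as.integer(pick)
            left[pick] <- left[pick] - 1L
          }
          if (ok) return(out)
        }
      }
      rate <- with_seed(seed, unlist(lapply(seq_len(n_blocks),
                                            function(b) one_block())))
      data.frame(speech_rate = rate, duration_s = chunk_s,
                 block = rep(seq_len(n_blocks), each = 80L),
                 surprisal_schedule = "none", stringsAsFactors = FALSE)
    },
    exp3 = {
      if (n_chunks %% 2 != 0) stopf("'n_chunks' must be even")
      # 4 stories x 2 speeds; two stories start at x1, two at x2.5, and the
      # second presentation of each story uses the other speed.
      first <- with_seed(seed, sample(rep(c(1, 2.5), 2)))
      rate <- c(first, ifelse(first == 1, 2.5, 1))
      n_words <- n_chunks * words_per_chunk
      data.frame(speech_rate = rate,
                 duration_s = n_words * 60 / (.base_wpm * rate),
                 block = rep(1:2, each = 4L),
                 surprisal_schedule = "alternating", stringsAsFactors = FALSE)
    })
  trials$trial_id <- sprintf("%s-t%03d", experiment, seq_len(nrow(trials)))
  plan <- structure(list(experiment = experiment, trials = trials,
                         chunk_s = chunk_s, words_per_chunk = words_per_chunk,
                         n_blocks = if (experiment == "exp2") n_blocks else
                           length(unique(trials$block))),
                    class = "session_plan")
  validate_session_plan(plan)
  plan
}

validate_session_plan <- function(plan) {
  tr <- plan$trials
  if (plan$experiment == "exp1") {
    tab <- table(tr$speech_rate)
    if (!all(tab == 25) || length(tab) != 5)
      stopf("exp1 plan must have 25 trials per each of 5 rates")
  }
  if (plan$experiment == "exp2") {
    per_block <- table(tr$block, tr$speech_rate)
    if (!all(per_block == 16))
      stopf("exp2 blocks must contain 16 chunks per each of 5 rates")
  }
  if (plan$experiment == "exp3") {
    if (!identical(tr$surprisal_schedule, rep("alternating", nrow(tr))))
      stopf("exp3 trials must alternate low/high surprisal chunks")
  }
  invisible(plan)
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %s: %d trials, rates {%s}\n", x$experiment,
              nrow(x$trials),
              paste(sort(unique(x$trials$speech_rate)), collapse = ", ")))
  invisible(x)
}

#' Simulate one slider trial
#'
#' Generates the raw device log of a single trial together with the latent
#' ground-truth trace. The latent target starts at the 0 origin, rises toward
#' the participant's [latent_comprehension()] level via convolution with the
#' gamma delay kernel, and is modulated downward by `surprisal_drop` during
#' high-surprisal word spans when `word_events` are supplied. The observed
#' signal adds motor noise, is clipped to `[0, 1]`, quantized to the 8-bit ADC
#' range 0-255, and logged with device timestamps scaled by
#' `1 + drift_ppm * 1e-6` (a pure linear clock-rate offset); optional USB
#' timing jitter perturbs host timestamps by i.i.d. uniform +/- 2 ms.
#'
#' @param profile a [make_participant()] profile.
#' @param rate speech-rate factor (> 0).
#' @param duration_s trial duration in seconds.
#' @param word_events optional word-event table from
#'   [simulate_surprisal_story()] (columns `onset_s`, `surprisal`,
#'   `chunk_type`).
#' @param fs device sampling rate in Hz (default 250).
#' @param surprisal_drop fractional reduction of the latent target during
#'   high-surprisal spans.
#' @param jitter add uniform +/- 2 ms USB jitter to host timestamps.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return list with `log` (data.frame `device_time_ms`, `host_time_s`,
#'   `value`), `latent` (ground-truth [slider_trace()]) and `level` (the
#'   asymptotic comprehension level).
#' @export
simulate_trial <- function(profile, rate, duration_s, word_events = NULL,
                           fs = 250, surprisal_drop = 0.3, jitter = FALSE,
                           seed = NULL) {
  if (!inherits(profile, "participant_profile"))
    stopf("'profile' must be a participant_profile")
  if (!is_scalar_number(duration_s) || duration_s <= 0)
    stopf("'duration_s' must be positive")
  if (!is_scalar_number(fs) || fs <= 0) stopf("'fs' must be positive")
  with_seed(seed, {
    n <- expected_sample_count(duration_s, fs)
    t <- (seq_len(n) - 1) / fs
    level <- latent_comprehension(profile, rate)
    target <- rep(level, n)
    if (!is.null(word_events) && nrow(word_events) > 0) {
      hi <- word_events$chunk_type == "high"
      if (any(hi)) {
        # hold each word's chunk type until the next word onset
        idx <- findInterval(t, word_events$onset_s)
        in_high <- idx > 0 & hi[pmax(idx, 1L)]
        target[in_high] <- target[in_high] * (1 - surprisal_drop)
      }
    }
    kernel <- delay_kernel(profile, fs)
    latent <- causal_conv(target, kernel)
    observed <- clip01(latent + stats::rnorm(n, 0, profile$motor_noise_sd))
    adc <- as.integer(round(observed * 255))
    host <- t
    if (jitter) host <- host + stats::runif(n, -0.002, 0.002)
    log <- data.frame(
      device_time_ms = t * 1000 * (1 + profile$drift_ppm * 1e-6),
      host_time_s = host, value = adc)
    list(log = log,
         latent = slider_trace(latent, fs = fs, condition = rate,
                               participant_id = profile$participant_id),
         level = level)
  })
}

#' Score-level trial generator
#'
#' Shortcut generator that emits per-trial median slider scores directly
#' (latent comprehension level plus Gaussian noise, clipped to `[0, 1]`),
#' bypassing trace synthesis. Used for cohort-scale studies of the rate
#' models, where only the per-trial median enters the analysis.
#'
#' @param profile a [make_participant()] profile.
#' @param rates vector of per-trial speech rates.
#' @param noise_sd score noise; defaults to the profile's `motor_noise_sd`.
#' @param seed optional seed.
#' @return data.frame with `speech_rate` and `score`.
#' @export
simulate_median_scores <- function(profile, rates = rep(1:5, each = 25),
                                   noise_sd = NULL, seed = NULL) {
  if (is.null(noise_sd)) noise_sd <- profile$motor_noise_sd
  with_seed(seed, {
    level <- latent_comprehension(profile, rates)
    data.frame(speech_rate = rates,
               score = clip01(level + stats::rnorm(length(rates), 0, noise_sd)))
  })
}

#' Simulate a full session
#'
#' Runs [simulate_trial()] for every trial of a [session_plan()] and attaches
#' generated metadata: segment words, post hoc scores (10-point rating
#' `round(10 * median latent)`; multiple-choice correctness with probability
#' `0.25 + 0.75 * latent`, mixing the 25% guessing floor with comprehension),
#' a written summary for a fraction of trials, and the participant
#' covariates. Deterministic given the profile's `rng_seed`.
#'
#' @param plan a [session_plan()].
#' @param profile a [make_participant()] profile.
#' @param fs sampling rate in Hz.
#' @param summary_fraction fraction of trials with a written summary.
#' @param recency_bias recency bias passed to [simulate_summary()].
#' @param surprisal_drop see [simulate_trial()].
#' @param keep_logs retain each trial's raw device log in the record.
#' @return list of `trial_record` objects; each has `participant_id`,
#'   `trial_id`, `speech_rate`, `duration_s`, `trace` (preprocessed
#'   [slider_trace()]), `latent`, `scale_10`, `mc_correct`, `segment_words`,
#'   `summary_words`, `summary_text`, `digit_span`, `digit_in_noise`, and
#'   optionally `log`.
#' @export
simulate_session <- function(plan, profile, fs = 250, summary_fraction = 0.6,
                             recency_bias = 2, surprisal_drop = 0.3,
                             keep_logs = FALSE) {
  validate_session_plan(plan)
  with_seed(profile$rng_seed, {
    tr <- plan$trials
    has_summary <- seq_len(nrow(tr)) %in%
      sample.int(nrow(tr), round(summary_fraction * nrow(tr)))
    lapply(seq_len(nrow(tr)), function(i) {
      rate <- tr$speech_rate[i]
      dur <- tr$duration_s[i]
      events <- NULL
      if (tr$surprisal_schedule[i] == "alternating") {
        n_story_words <- round(dur * .base_wpm * rate / 60)
        n_ch <- max(2L, 2L * (n_story_words %/% (2L * plan$words_per_chunk)))
        events <- simulate_surprisal_story(
          n_chunks = n_ch, words_per_chunk = plan$words_per_chunk, rate = rate)
      }
      sim <- simulate_trial(profile, rate, dur, word_events = events, fs = fs,
                            surprisal_drop = surprisal_drop)
      trace <- to_trace(sim$log, fs = fs, duration_s = dur, condition = rate,
                        participant_id = profile$participant_id,
                        trial_id = tr$trial_id[i])
      n_words <- max(5L, as.integer(round(dur * .base_wpm * rate / 60)))
      words <- sample(.compslide_vocab, n_words, replace = TRUE)
      summary_words <- if (has_summary[i])
        simulate_summary(words, comprehension = sim$level,
                         recency_bias = recency_bias) else NULL
      structure(list(
        participant_id = profile$participant_id, trial_id = tr$trial_id[i],
        speech_rate = rate, duration_s = dur, trace = trace,
        latent = sim$latent,
        scale_10 = as.integer(round(10 * stats::median(sim$latent$values))),
        mc_correct = stats::rbinom(1, 1, 0.25 + 0.75 * sim$level),
        segment_words = words, summary_words = summary_words,
        summary_text = if (is.null(summary_words)) NA_character_ else
          paste(summary_words, collapse = " "),
        digit_span = profile$digit_span,
        digit_in_noise = profile$digit_in_noise,
        log = if (keep_logs) sim$log else NULL), class = "trial_record")
    })
  })
}

#' Simulate a written summary with a recency bias
#'
#' Samples `ceiling(comprehension * length(segment_words))` word positions
#' without replacement, with inclusion weights increasing across segment
#' pentiles proportionally to `1 + recency_bias * pentile`; the sampled words
#' are returned in their original segment order. `recency_bias = 0` samples
#' uniformly; larger values over-represent the final fifths of the segment.
#'
#' @param segment_words non-empty character vector of segment words.
#' @param comprehension inclusion fraction in `[0, 1]`.
#' @param recency_bias non-negative recency weight.
#' @param seed optional seed.
#' @return character vector of summary words (empty when `comprehension` 0).
#' @export
simulate_summary <- function(segment_words, comprehension, recency_bias = 0,
                             seed = NULL) {
  if (length(segment_words) == 0) stopf("'segment_words' must be non-empty")
  if (!is_scalar_number(comprehension) || comprehension < 0 || comprehension > 1)
    stopf("'comprehension' must be in [0, 1]")
  if (!is_scalar_number(recency_bias) || recency_bias < 0)
    stopf("'recency_bias' must be >= 0")
  n <- length(segment_words)
  n_take <- ceiling(comprehension * n)
  if (n_take == 0) return(character(0))
  with_seed(seed, {
    w <- if (n >= 5) 1 + recency_bias * pentile_index(n) else rep(1, n)
    pos <- sort(sample.int(n, n_take, prob = w))
    segment_words[pos]
  })
}

#' Simulate a surprisal-alternating story
#'
#' Emits a word-event table for a story that alternates between low- and
#' high-surprisal parts (chunks), as produced upstream by forced alignment
#' plus a language model. Word onsets are spaced by a rate-scaled mean
#' inter-word interval (`60 / (195.76 * rate)` seconds, i.e. faster speech
#' compresses onsets proportionally) with multiplicative uniform 0.7-1.3
#' duration jitter per word, mimicking natural word-length variability (and
#' avoiding the strictly periodic impulse comb that would leave lagged
#' regression kernels unidentified at the comb's spectral nulls); per-word
#' surprisal is drawn from a Normal truncated at zero around the chunk's
#' mean. Under a fixed seed, onsets at rate r2 are exactly the onsets at
#' rate r1 compressed by r2/r1.
#'
#' @param n_chunks even number of alternating parts (low first).
#' @param words_per_chunk words per part (about 30).
#' @param mean_low,mean_high target mean surprisal of low/high parts
#'   (defaults 4.91 and 5.90).
#' @param rate speech-rate factor.
#' @param sd per-word surprisal standard deviation.
#' @param seed optional seed.
#' @return data.frame with `word`, `onset_s` (strictly increasing),
#'   `surprisal`, `chunk` (1-based index) and `chunk_type` (`"low"`/`"high"`).
#' @export
simulate_surprisal_story <- function(n_chunks, words_per_chunk = 30,
                                     mean_low = 4.91, mean_high = 5.90,
                                     rate = 1, sd = 0.5, seed = NULL) {
  if (!is_scalar_number(n_chunks) || n_chunks < 2 || n_chunks %% 2 != 0)
    stopf("'n_chunks' must be a positive even number")
  if (mean_high <= mean_low) stopf("'mean_high' must exceed 'mean_low'")
  if (!is_scalar_number(rate) || rate <= 0) stopf("'rate' must be positive")
  with_seed(seed, {
    n_words <- n_chunks * words_per_chunk
    chunk <- rep(seq_len(n_chunks), each = words_per_chunk)
    chunk_type <- c("low", "high")[(chunk - 1) %% 2 + 1]
    mu <- ifelse(chunk_type == "high", mean_high, mean_low)
    s <- stats::rnorm(n_words, mu, sd)
    while (any(s <= 0)) {  # truncate at zero by redrawing
      bad <- s <= 0
      s[bad] <- stats::rnorm(sum(bad), mu[bad], sd)
    }
    iwi <- 60 / (.base_wpm * rate)
    gaps <- iwi * stats::runif(n_words - 1, 0.7, 1.3)
    data.frame(word = sample(.compslide_vocab, n_words, replace = TRUE),
               onset_s = c(0, cumsum(gaps)),
               surprisal = s, chunk = chunk, chunk_type = chunk_type,
               stringsAsFactors = FALSE)
  })
}

#' Write session artifacts to disk
#'
#' Writes each trial's device log as CSV (`device_time_ms`, `host_time_s`,
#' `value`), the word events as CSV (`word`, `onset_s`, `surprisal`), and the
#' trial metadata as JSON.
#'
#' @param records output of [simulate_session()] (with `keep_logs = TRUE` for
#'   log export).
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_session <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  meta <- lapply(records, function(r) {
    if (!is.null(r$log)) {
      f <- file.path(dir, paste0(r$trial_id, "_log.csv"))
      write_slider_log(r$log, f)
      files <<- c(files, f)
    }
    r[c("participant_id", "trial_id", "speech_rate", "duration_s", "scale_10",
        "mc_correct", "summary_text", "digit_span", "digit_in_noise")]
  })
  mf <- file.path(dir, "trials.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, mf))
}
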