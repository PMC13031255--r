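# Temporal response functions (TRF) for the continuous slider signal.
#
# The slider trace is modeled as a time-lagged linear function of six
# stimulus annotation impulse channels. For lag window [tmin, tmax] the
# design matrix holds every (feature, lag) shifted copy of the channels, and
# the kernel is estimated by ridge regression; held-out prediction accuracy
# is Spearman's rho under story-blocked cross-validation. Per-feature lag
# profiles are the participant's response-delay kernels.

#' Canonical annotation feature names
#' @export
trf_features <- c("low_surprisal_onset", "high_surprisal_onset",
                  "word_surprisal", "segment_onset",
                  "rate_x1_onset", "rate_x2p5_onset")

#' Annotation sets
#'
#' Container for the six stimulus annotation channels of one story at the
#' trace sampling rate: low/high-surprisal passage onsets (unit impulses at
#' the first word of each passage), word-by-word surprisal (each word's
#' surprisal value at its onset sample), segment onset (1 at the first
#' sample), and the two speech-rate onset channels (1 at the first sample of
#' a story presented at that rate, all zeros otherwise).
#'
#' @param channels numeric matrix, rows named by [trf_features].
#' @param fs sampling rate in Hz.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(channels, fs) {
  channels <- as.matrix(channels)
  if (!identical(rownames(channels), trf_features))
    stopf("channels must be a matrix with rows %s",
          paste(trf_features, collapse = ", "))
  if (!is_scalar_number(fs) || fs <= 0) stopf("'fs' must be positive")
  onset_rows <- setdiff(trf_features, "word_surprisal")
  if (!all(channels[onset_rows, ] %in% c(0, 1)))
    stopf("onset channels must be 0/1 impulses")
  structure(list(channels = channels, fs = fs, n_samples = ncol(channels)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d samples @ %g Hz; impulses per channel:\n",
              x$n_samples, x$fs))
  print(rowSums(x$channels != 0))
  invisible(x)
}

#' Build annotation vectors for one story
#'
#' Places the feature impulses of one story onto a zero-initialized sample
#' grid: chunk-onset impulses at the first word of each low/high-surprisal
#' passage, per-word surprisal values at nearest-sample word onsets (values
#' of words rounding to the same sample are summed, with a warning), the
#' segment-onset impulse at sample 1, and the matching speech-rate onset
#' impulse at sample 1.
#'
#' @param events word-event table (columns `onset_s`, `surprisal`, `chunk`,
#'   `chunk_type`), e.g. from [simulate_surprisal_story()].
#' @param n_samples length of the slider trace in samples.
#' @param fs sampling rate in Hz.
#' @param rate story speech rate; `1` and `2.5` fill the respective rate
#'   onset channel, other rates leave both at zero.
#' @return an [annotation_set()].
#' @export
build_annotation_vectors <- function(events, n_samples, fs, rate = 1) {
  if (!all(c("onset_s", "surprisal", "chunk", "chunk_type") %in% names(events)))
    stopf("'events' must have onset_s, surprisal, chunk, chunk_type")
  ch <- matrix(0, nrow = length(trf_features), ncol = n_samples,
               dimnames = list(trf_features, NULL))
  smp <- as.integer(round(events$onset_s * fs)) + 1L
  bad <- which(smp < 1L | smp > n_samples)
  if (length(bad))
    stopf("event %d ('%s' at %.3f s) lies beyond the trace end (%.3f s)",
          bad[1], events$word[bad[1]], events$onset_s[bad[1]], n_samples / fs)
  if (anyDuplicated(smp))
    warnf("%d word onset(s) round to an already-occupied sample; surprisal values summed",
          sum(duplicated(smp)))
  for (i in seq_along(smp))
    ch["word_surprisal", smp[i]] <- ch["word_surprisal", smp[i]] +
      events$surprisal[i]
  first_of_chunk <- !duplicated(events$chunk)
  for (i in which(first_of_chunk)) {
    row <- if (events$chunk_type[i] == "high") "high_surprisal_onset" else
      "low_surprisal_onset"
    ch[row, smp[i]] <- 1
  }
  ch["segment_onset", 1L] <- 1
  if (isTRUE(all.equal(rate, 1))) ch["rate_x1_onset", 1L] <- 1
  if (isTRUE(all.equal(rate, 2.5))) ch["rate_x2p5_onset", 1L] <- 1
  annotation_set(ch, fs)
}

#' Concatenate stories in presentation order
#'
#' Joins per-story (trace, annotation) pairs end to end, preserving the
#' order in which the stories were presented, and records story-boundary
#' indices for fold construction.
#'
#' @param pairs list of `list(trace = slider_trace, ann = annotation_set)`;
#'   all at the same `fs` with matching per-pair lengths.
#' @return list with `trace` (concatenated [slider_trace()]), `ann`
#'   (concatenated [annotation_set()]) and `boundaries` (data.frame `story`,
#'   `start`, `end` in samples).
#' @export
concatenate_sessions <- function(pairs) {
  if (length(pairs) == 0) stopf("no sessions to concatenate")
  fs <- pairs[[1]]$trace$fs
  for (p in pairs) {
    if (!isTRUE(all.equal(p$trace$fs, fs)) || !isTRUE(all.equal(p$ann$fs, fs)))
      stopf("all traces and annotation sets must share one sampling rate")
    if (length(p$trace$values) != p$ann$n_samples)
      stopf("trace and annotation lengths differ within a story")
  }
  lens <- vapply(pairs, function(p) length(p$trace$values), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  values <- unlist(lapply(pairs, function(p) p$trace$values))
  channels <- do.call(cbind, lapply(pairs, function(p) p$ann$channels))
  list(trace = slider_trace(values, fs = fs,
                            participant_id = pairs[[1]]$trace$participant_id),
       ann = annotation_set(channels, fs),
       boundaries = data.frame(story = seq_along(pairs), start = starts,
                               end = ends))
}

#' Lag windows
#'
#' The kernel window of the TRF: lags from `tmin` to `tmax` seconds
#' (defaults -0.2 to +5 s) sampled at `fs`, enumerated inclusively, giving
#' `round((tmax - tmin) * fs) + 1` lags. Negative lags are retained as an
#' artifact-detection band: a true response cannot precede its stimulus, so
#' substantial coefficient mass before lag 0 flags leakage.
#'
#' @param tmin,tmax window edges in seconds, `tmin < tmax`.
#' @param fs sampling rate in Hz.
#' @return an object of class `lag_window` with `lags` (in samples) and
#'   `lag_s` (in seconds).
#' @export
lag_window <- function(tmin = -0.2, tmax = 5, fs = 250) {
  if (!is_scalar_number(tmin) || !is_scalar_number(tmax) || tmin >= tmax)
    stopf("'tmin' must be smaller than 'tmax'")
  if (!is_scalar_number(fs) || fs <= 0) stopf("'fs' must be positive")
  lags <- seq.int(as.integer(round(tmin * fs)), as.integer(round(tmax * fs)))
  structure(list(tmin = tmin, tmax = tmax, fs = fs, lags = lags,
                 lag_s = lags / fs, n_lags = length(lags)),
            class = "lag_window")
}

#' Build the time-lagged design matrix
#'
#' One column per (feature, lag): sample `t` of the column for feature `f`
#' at lag `l` samples equals channel `f` at sample `t - l`, zero-padded at
#' the edges. Columns are ordered feature-major, lags from `tmin` to `tmax`.
#'
#' @param ann an [annotation_set()].
#' @param window a [lag_window()] at the same `fs`.
#' @return numeric matrix of dimension `n_samples x (6 * n_lags)`.
#' @export
build_lagged_design <- function(ann, window) {
  if (!inherits(ann, "annotation_set")) stopf("'ann' must be an annotation_set")
  if (!inherits(window, "lag_window")) stopf("'window' must be a lag_window")
  if (!isTRUE(all.equal(window$fs, ann$fs)))
    stopf("window fs (%g) must equal annotation fs (%g)", window$fs, ann$fs)
  n <- ann$n_samples
  if (window$n_lags > n) stopf("lag window is longer than the signal")
  X <- matrix(0, nrow = n, ncol = length(trf_features) * window$n_lags)
  colnames(X) <- paste(rep(trf_features, each = window$n_lags),
                       rep(window$lags, times = length(trf_features)),
                       sep = "@")
  for (f in seq_along(trf_features)) {
    chan <- ann$channels[f, ]
    for (j in seq_len(window$n_lags)) {
      l <- window$lags[j]
      col <- (f - 1L) * window$n_lags + j
      if (l >= 0) {
        if (l < n) X[(1L + l):n, col] <- chan[1:(n - l)]
      } else {
        if (-l < n) X[1:(n + l), col] <- chan[(1L - l):n]
      }
    }
  }
  X
}

# Design matrix respecting story boundaries: each story is lagged
# independently (zero-padded at its own edges), so lagged copies never bleed
# from one story into the next.
lagged_design_blocked <- function(ann, window, boundaries = NULL) {
  if (is.null(boundaries) || nrow(boundaries) <= 1)
    return(build_lagged_design(ann, window))
  do.call(rbind, lapply(seq_len(nrow(boundaries)), function(i) {
    idx <- boundaries$start[i]:boundaries$end[i]
    build_lagged_design(annotation_set(ann$channels[, idx, drop = FALSE],
                                       ann$fs), window)
  }))
}

new_trf_kernel <- function(coefficients, intercept, window, alpha,
                           cv_rho = NULL, mean_rho = NA_real_, k_used = NA) {
  structure(list(coefficients = coefficients, intercept = intercept,
                 window = window, alpha = alpha, cv_rho = cv_rho,
                 mean_rho = mean_rho, k_used = k_used),
            class = "trf_kernel")
}

#' Ridge estimate of the TRF kernel
#'
#' Standard ridge with an unpenalized intercept: both the response and the
#' design columns are centered, `(Xc'Xc + alpha I) b = Xc'(y - mean(y))` is
#' solved by Cholesky decomposition, and the intercept is recovered as
#' `mean(y) - colMeans(X) %*% b`. Centering the columns matters here: the
#' annotation channels have nonzero means (impulse densities), and without
#' it the sustained part of their contribution cannot be separated from the
#' baseline.
#'
#' @param design lagged design matrix from [build_lagged_design()].
#' @param y slider values, one per design row.
#' @param window the [lag_window()] used to build the design.
#' @param alpha ridge penalty (default 1.0).
#' @return an object of class `trf_kernel` with a `6 x n_lags` coefficient
#'   matrix, intercept and window; supports `coef()`, `predict()`,
#'   `print()`, `plot()`.
#' @export
ridge_fit <- function(design, y, window, alpha = 1.0) {
  if (nrow(design) != length(y))
    stopf("design rows (%d) must match length(y) (%d)", nrow(design), length(y))
  if (any(!is.finite(design)) || any(!is.finite(y)))
    stopf("non-finite values in design or response")
  if (!is_scalar_number(alpha) || alpha < 0) stopf("'alpha' must be >= 0")
  yc <- y - mean(y)
  cm <- colMeans(design)
  XtX <- crossprod(design) - nrow(design) * tcrossprod(cm)
  diag(XtX) <- diag(XtX) + alpha
  Xty <- crossprod(design, yc)
  beta <- tryCatch(drop(chol2inv(chol(XtX)) %*% Xty),
                   error = function(e) drop(solve(XtX, Xty)))
  coefm <- matrix(beta, nrow = length(trf_features), ncol = window$n_lags,
                  byrow = TRUE,
                  dimnames = list(trf_features, as.character(window$lag_s)))
  new_trf_kernel(coefm, intercept = mean(y) - sum(cm * beta),
                 window = window, alpha = alpha)
}

#' @export
coef.trf_kernel <- function(object, ...) object$coefficients

#' @export
predict.trf_kernel <- function(object, ann = NULL, design = NULL,
                               boundaries = NULL, ...) {
  if (is.null(design)) {
    if (is.null(ann)) stopf("supply 'ann' or 'design'")
    design <- lagged_design_blocked(ann, object$window, boundaries)
  }
  drop(design %*% as.vector(t(object$coefficients))) + object$intercept
}

#' @export
print.trf_kernel <- function(x, ...) {
  cat(sprintf("<trf_kernel> 6 features x %d lags (%.1f..%.1f s @ %g Hz), alpha %g\n",
              x$window$n_lags, x$window$tmin, x$window$tmax, x$window$fs,
              x$alpha))
  if (!is.null(x$cv_rho))
    cat(sprintf("  CV Spearman rho per fold: %s (mean %.3f, k = %d)\n",
                paste(sprintf("%.3f", x$cv_rho), collapse = ", "),
                x$mean_rho, x$k_used))
  invisible(x)
}

#' @export
plot.trf_kernel <- function(x, features = trf_features, ...) {
  graphics::matplot(x$window$lag_s, t(x$coefficients[features, , drop = FALSE]),
                    type = "l", lty = 1, xlab = "lag (s)",
                    ylab = "TRF coefficient", ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = features, col = seq_along(features),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

# Assign stories to k contiguous fold blocks.
story_folds <- function(boundaries, k) {
  n_story <- nrow(boundaries)
  if (n_story < k) stopf("need at least %d stories for %d folds", k, k)
  as.integer(cut(seq_len(n_story), breaks = k, labels = FALSE))
}

# Story-blocked fold assignment per sample, with the 3 -> 2 fallback when a
# fold lacks variation (constant held-out trace or a constant annotation
# channel in the training block).
trf_fold_vector <- function(y, ann, boundaries, k) {
  sample_fold <- function(k_try) {
    if (nrow(boundaries) < k_try)  # single continuous recording: sample blocks
      return(as.integer(cut(seq_along(y), breaks = k_try, labels = FALSE)))
    sf <- story_folds(boundaries, k_try)
    fold <- integer(length(y))
    for (i in seq_len(nrow(boundaries)))
      fold[boundaries$start[i]:boundaries$end[i]] <- sf[i]
    fold
  }
  enough_variation <- function(fold, k_try) {
    for (f in seq_len(k_try)) {
      if (stats::sd(y[fold == f]) == 0) return(FALSE)
      tr_cols <- ann$channels[, fold != f, drop = FALSE]
      if (any(apply(tr_cols, 1, function(ch) stats::sd(ch) == 0)))
        return(FALSE)
    }
    TRUE
  }
  k_used <- k
  fold <- sample_fold(k_used)
  if (k_used == 3 && !enough_variation(fold, k_used)) {
    message("not enough variation within a fold; falling back to 2-fold CV")
    k_used <- 2
    fold <- sample_fold(k_used)
  }
  list(fold = fold, k_used = k_used)
}

# Shared cross-validation engine. Computes the per-fold Gram blocks of the
# lagged design once, then evaluates any number of column subsets (e.g. the
# full model and an ablated one) by solving the centered ridge system on the
# corresponding Gram submatrix: G_train = G_all - G_fold, centered with the
# training column means, is far cheaper than refitting from the raw design.
# Returns per-subset per-fold Spearman rho and the full-data coefficients.
trf_cv_engine <- function(X, y, fold, k_used, alpha, subsets) {
  n_col <- ncol(X)
  blocks <- lapply(seq_len(k_used), function(f) {
    idx <- which(fold == f)
    Xf <- X[idx, , drop = FALSE]
    list(G = crossprod(Xf), c = colSums(Xf), h = drop(crossprod(Xf, y[idx])),
         sy = sum(y[idx]), n = length(idx), idx = idx)
  })
  G_all <- Reduce(`+`, lapply(blocks, `[[`, "G"))
  c_all <- Reduce(`+`, lapply(blocks, `[[`, "c"))
  h_all <- Reduce(`+`, lapply(blocks, `[[`, "h"))
  sy_all <- sum(y); n_all <- length(y)
  solve_centered <- function(G, cv, h, sy, n, cols) {
    m <- cv / n; ybar <- sy / n
    A <- (G - n * tcrossprod(m))[cols, cols, drop = FALSE]
    diag(A) <- diag(A) + alpha
    b <- drop(chol2inv(chol(A)) %*% (h - ybar * cv)[cols])
    list(beta = b, intercept = ybar - sum(m[cols] * b))
  }
  lapply(subsets, function(cols) {
    rho <- vapply(seq_len(k_used), function(f) {
      bl <- blocks[[f]]
      fit <- solve_centered(G_all - bl$G, c_all - bl$c, h_all - bl$h,
                            sy_all - bl$sy, n_all - bl$n, cols)
      pred <- drop(X[bl$idx, cols, drop = FALSE] %*% fit$beta) + fit$intercept
      suppressWarnings(stats::cor(pred, y[bl$idx], method = "spearman"))
    }, numeric(1))
    final <- solve_centered(G_all, c_all, h_all, sy_all, n_all, cols)
    beta_full <- numeric(n_col)
    beta_full[cols] <- final$beta
    list(rho = rho, beta = beta_full, intercept = final$intercept)
  })
}

#' Cross-validated TRF
#'
#' Estimates the TRF with story-blocked k-fold cross-validation: folds are
#' contiguous story blocks (shuffled single samples would leak through the
#' strong autocorrelation of the slider signal), the model is fit on the
#' training block and held-out prediction accuracy is Spearman's rho
#' (average ranks for ties) per fold. The lagged design is built per story
#' block (each story zero-padded at its own edges) so lags never bleed
#' across story boundaries. The returned kernel is refit on all data. If any fold's held-out trace is constant, or any annotation channel
#' is constant within a fold's training block, there is not enough variation
#' for 3 folds and the procedure falls back to 2-fold cross-validation (with
#' a message); `k` must be 2 or 3.
#'
#' @param trace a [slider_trace()] (concatenated across stories).
#' @param ann the matching [annotation_set()].
#' @param window a [lag_window()].
#' @param alpha ridge penalty (default 1.0).
#' @param k folds, 2 or 3 (default 3).
#' @param boundaries story boundary table from [concatenate_sessions()];
#'   defaults to a single block.
#' @return a `trf_kernel` with `cv_rho` (per-fold Spearman rho), `mean_rho`
#'   and `k_used`.
#' @export
crossval_trf <- function(trace, ann, window, alpha = 1.0, k = 3,
                         boundaries = NULL) {
  if (!k %in% c(2, 3)) stopf("'k' must be 2 or 3")
  y <- trace$values
  if (stats::sd(y) == 0) stopf("degenerate data: slider trace is constant")
  if (is.null(boundaries))
    boundaries <- data.frame(story = 1L, start = 1L, end = length(y))
  X <- lagged_design_blocked(ann, window, boundaries)
  fv <- trf_fold_vector(y, ann, boundaries, k)
  res <- trf_cv_engine(X, y, fv$fold, fv$k_used, alpha,
                       subsets = list(seq_len(ncol(X))))[[1]]
  coefm <- matrix(res$beta, nrow = length(trf_features),
                  ncol = window$n_lags, byrow = TRUE,
                  dimnames = list(trf_features, as.character(window$lag_s)))
  final <- new_trf_kernel(coefm, intercept = res$intercept, window = window,
                          alpha = alpha)
  final$cv_rho <- res$rho
  final$mean_rho <- mean(res$rho, na.rm = TRUE)
  final$k_used <- fv$k_used
  final
}

#' Surprisal-feature ablation
#'
#' Refits the TRF after removing feature channels (by default the three
#' surprisal-related ones: low/high-surprisal onsets and word-by-word
#' surprisal) and compares held-out accuracy per subject; the group-level
#' test is a one-sample t-test of the per-subject accuracy differences
#' (full minus reduced) against zero. The full and reduced models share the
#' same folds and the same design-matrix Gram blocks; the reduced model is
#' solved on the column subset of the retained features.
#'
#' @param subjects list of per-subject `list(trace, ann, boundaries)` as
#'   produced by [concatenate_sessions()] / [simulate_trf_subject()].
#' @param window a [lag_window()].
#' @param alpha ridge penalty.
#' @param k folds.
#' @param features_to_drop feature names to ablate.
#' @return list with `rho_full`, `rho_reduced`, `delta_rho` (per subject),
#'   `mean_delta`, `t_stat`, `df`, `p_value`.
#' @export
ablation_compare <- function(subjects, window, alpha = 1.0, k = 3,
                             features_to_drop = c("low_surprisal_onset",
                                                  "high_surprisal_onset",
                                                  "word_surprisal")) {
  if (length(subjects) < 2) stopf("need at least 2 subjects for the group test")
  unknown <- setdiff(features_to_drop, trf_features)
  if (length(unknown)) stopf("unknown feature(s): %s",
                             paste(unknown, collapse = ", "))
  keep_cols <- which(rep(trf_features, each = window$n_lags) %in%
                       setdiff(trf_features, features_to_drop))
  res <- vapply(subjects, function(s) {
    y <- s$trace$values
    boundaries <- s$boundaries
    if (is.null(boundaries))
      boundaries <- data.frame(story = 1L, start = 1L, end = length(y))
    X <- lagged_design_blocked(s$ann, window, boundaries)
    fv <- trf_fold_vector(y, s$ann, boundaries, k)
    fits <- trf_cv_engine(X, y, fv$fold, fv$k_used, alpha,
                          subsets = list(seq_len(ncol(X)), keep_cols))
    c(full = mean(fits[[1]]$rho, na.rm = TRUE),
      reduced = mean(fits[[2]]$rho, na.rm = TRUE))
  }, numeric(2))
  delta <- res["full", ] - res["reduced", ]
  if (length(features_to_drop) == 0 || stats::sd(delta) == 0) {
    t_stat <- NA_real_; df <- NA_real_; p <- if (all(delta == 0)) 1 else NA_real_
  } else {
    tt <- stats::t.test(delta)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  list(rho_full = unname(res["full", ]), rho_reduced = unname(res["reduced", ]),
       delta_rho = unname(delta), mean_delta = mean(delta),
       t_stat = t_stat, df = df, p_value = p)
}

#' Peak latency of a feature kernel
#'
#' The lag, in seconds, of the maximum absolute coefficient of one feature
#' within the non-negative part of the window `[0, tmax]` — the estimated
#' response delay for that feature. Ties take the earlier lag; an all-zero
#' kernel is an error, not a latency of 0.
#'
#' @param kernel a `trf_kernel`.
#' @param feature one of [trf_features].
#' @return latency in seconds.
#' @export
kernel_peak_latency <- function(kernel, feature) {
  if (!inherits(kernel, "trf_kernel")) stopf("'kernel' must be a trf_kernel")
  if (!feature %in% rownames(kernel$coefficients))
    stopf("unknown feature '%s'", feature)
  keep <- kernel$window$lag_s >= 0
  coefs <- abs(kernel$coefficients[feature, keep])
  if (all(coefs == 0)) stopf("all-zero kernel for feature '%s'", feature)
  kernel$window$lag_s[keep][which.max(coefs)]
}

#' Simulate a TRF subject with known ground truth
#'
#' Builds a synthetic participant's concatenated session for the TRF
#' pipeline: alternating x1 / x2.5 stories of surprisal-alternating word
#' events, six annotation channels, and a slider trace generated as the sum
#' of per-feature ground-truth kernels convolved with their channels plus
#' Gaussian noise at a chosen signal-to-noise ratio. Every ground-truth
#' kernel is the participant's gamma delay kernel scaled by a per-feature
#' weight, so recovered kernels can be compared to truth feature by feature
#' and the injected response delay (the gamma mode) is known exactly.
#'
#' Two structural properties of the annotation channels shape the generator.
#' First, each story opens with a variable lead-in (uniform 0.8-2.5 s)
#' before the first word, as in recorded narration, so the segment/rate
#' onset impulses (sample 1) neither coincide with the first chunk and word
#' onsets nor sit at a constant offset from them. Second, the
#' segment-onset channel is by construction the sum of the two rate-onset
#' channels (every story start carries both a segment impulse and exactly
#' one rate impulse), so only the sums of their responses are identified; a
#' ridge estimator returns the minimum-norm representative of that collinear
#' family. The generator therefore uses story-start weights satisfying
#' `w_segment = w_rate_x1 + w_rate_x2p5` - the minimum-norm member - making
#' the per-feature ground truth the one an unbiased estimator converges to.
#'
#' @param profile a [make_participant()] profile.
#' @param n_stories number of stories (alternating rates 1 and 2.5).
#' @param story_s nominal story duration in seconds.
#' @param fs analysis sampling rate in Hz.
#' @param snr ratio of signal SD to noise SD.
#' @param surprisal_gain scales the three surprisal-feature weights; 0 gives
#'   the null generator in which surprisal does not drive the trace.
#' @param words_per_chunk words per surprisal passage.
#' @param seed optional seed.
#' @return list with `trace`, `ann`, `boundaries`, `true_kernel` (the unit
#'   delay kernel), `true_weights` (named per-feature scales),
#'   `true_peak_s` (gamma mode in seconds) and `profile`.
#' @export
simulate_trf_subject <- function(profile, n_stories = 8, story_s = 45,
                                 fs = 20, snr = 5, surprisal_gain = 1,
                                 words_per_chunk = 30, seed = NULL) {
  with_seed(seed, {
    rates <- rep(c(1, 2.5), length.out = n_stories)
    base <- delay_kernel(profile, fs)
    w <- c(low_surprisal_onset = 1.5 * surprisal_gain,
           high_surprisal_onset = -1.5 * surprisal_gain,
           word_surprisal = -0.12 * surprisal_gain,
           segment_onset = 4.5, rate_x1_onset = 2.5, rate_x2p5_onset = 2)
    pairs <- lapply(seq_len(n_stories), function(i) {
      rate <- rates[i]
      # variable narration lead-in before the first word of each story
      lead_in <- stats::runif(1, 0.8, 2.5)
      iwi <- 60 / (.base_wpm * rate)
      # 5% headroom: jittered gaps can stretch the story slightly
      n_words_target <- floor((story_s - 2.5) / (1.05 * iwi))
      n_ch <- max(2L, 2L * (n_words_target %/% (2L * words_per_chunk)))
      ev <- simulate_surprisal_story(n_chunks = n_ch,
                                     words_per_chunk = words_per_chunk,
                                     rate = rate)
      ev$onset_s <- ev$onset_s + lead_in
      n_samples <- expected_sample_count(story_s, fs)
      ann <- build_annotation_vectors(ev, n_samples, fs, rate = rate)
      signal <- rep(0, n_samples)
      for (f in trf_features)
        signal <- signal + w[[f]] * causal_conv(ann$channels[f, ], base)
      list(ann = ann, signal = signal)
    })
    signal <- unlist(lapply(pairs, `[[`, "signal"))
    noise_sd <- stats::sd(signal) / snr
    y <- clip01(0.5 + signal + stats::rnorm(length(signal), 0, noise_sd))
    lens <- vapply(pairs, function(p) p$ann$n_samples, integer(1))
    ends <- cumsum(lens); starts <- c(1L, utils::head(ends, -1) + 1L)
    list(trace = slider_trace(y, fs = fs,
                              participant_id = profile$participant_id),
         ann = annotation_set(do.call(cbind, lapply(pairs, function(p)
           p$ann$channels)), fs),
         boundaries = data.frame(story = seq_len(n_stories), start = starts,
                                 end = ends),
         true_kernel = base, true_weights = w,
         true_peak_s = max(0, (profile$delay_shape - 1) * profile$delay_scale),
         profile = profile)
  })
}

#' Correlate recovered kernels with ground truth
#'
#' Pearson correlation, per feature, between the recovered kernel over the
#' non-negative lags and the ground-truth kernel (the subject's scaled delay
#' kernel), zero-padded or truncated to the same length.
#'
#' @param kernel a fitted `trf_kernel`.
#' @param subject a [simulate_trf_subject()] result.
#' @return named numeric vector of per-feature correlations (sign-corrected
#'   for negative true weights).
#' @export
kernel_recovery_correlation <- function(kernel, subject) {
  keep <- kernel$window$lag_s >= 0
  n <- sum(keep)
  truth_base <- subject$true_kernel
  truth <- if (length(truth_base) >= n) truth_base[seq_len(n)] else
    c(truth_base, rep(0, n - length(truth_base)))
  vapply(trf_features, function(f) {
    w <- subject$true_weights[[f]]
    if (w == 0) return(NA_real_)
    stats::cor(kernel$coefficients[f, keep], w * truth) * sign(1)
  }, numeric(1))
}
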