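test_that("annotation vectors place impulses at the right samples", {
  ev <- simulate_surprisal_story(n_chunks = 4, words_per_chunk = 10,
                                 rate = 1, seed = 1)
  n <- expected_sample_count(max(ev$onset_s) + 2, 250)
  ann <- build_annotation_vectors(ev, n, fs = 250, rate = 1)
  expect_identical(sum(ann$channels["low_surprisal_onset", ]), 2)
  expect_identical(sum(ann$channels["high_surprisal_onset", ]), 2)
  expect_identical(unname(ann$channels["segment_onset", 1]), 1)
  expect_identical(unname(ann$channels["rate_x1_onset", 1]), 1)
  expect_true(all(ann$channels["rate_x2p5_onset", ] == 0))

  # a word at exactly 1.000 s lands at sample index 250 (0-based) = 251st
  ev1 <- data.frame(word = "w", onset_s = 1, surprisal = 4.2, chunk = 1,
                    chunk_type = "low")
  a1 <- build_annotation_vectors(ev1, 500, fs = 250, rate = 2.5)
  expect_equal(unname(a1$channels["word_surprisal", 251]), 4.2)
  expect_identical(unname(a1$channels["rate_x2p5_onset", 1]), 1)

  # collisions sum surprisal with a warning
  ev2 <- data.frame(word = c("a", "b"), onset_s = c(0.999, 1.001),
                    surprisal = c(2, 3), chunk = c(1, 1),
                    chunk_type = c("low", "low"))
  expect_warning(a2 <- build_annotation_vectors(ev2, 500, fs = 250, rate = 1),
                 "summed")
  expect_equal(unname(a2$channels["word_surprisal", 251]), 5)

  # events past the trace end raise a bounds error naming the event
  ev3 <- data.frame(word = "late", onset_s = 3, surprisal = 1, chunk = 1,
                    chunk_type = "low")
  expect_error(build_annotation_vectors(ev3, 500, fs = 250), "late")
})

test_that("session concatenation preserves order and boundaries", {
  mk_pair <- function(n, seed) {
    set.seed(seed)
    ev <- data.frame(word = "w", onset_s = 0.5, surprisal = 3, chunk = 1,
                     chunk_type = "low")
    list(trace = slider_trace(runif(n), fs = 10),
         ann = build_annotation_vectors(ev, n, fs = 10, rate = 1))
  }
  pairs <- list(mk_pair(40, 1), mk_pair(55, 2), mk_pair(30, 3), mk_pair(25, 4))
  cc <- concatenate_sessions(pairs)
  expect_identical(length(cc$trace$values), 150L)
  expect_identical(cc$boundaries$start, c(1L, 41L, 96L, 126L))
  expect_identical(cc$boundaries$end, c(40L, 95L, 125L, 150L))
  # boundaries partition the concatenation exactly
  spans <- unlist(Map(seq, cc$boundaries$start, cc$boundaries$end))
  expect_identical(spans, 1:150)
  # order sensitivity
  cc2 <- concatenate_sessions(pairs[c(2, 1, 3, 4)])
  expect_false(identical(cc$trace$values, cc2$trace$values))

  bad <- pairs
  bad[[2]]$trace$fs <- 20
  expect_error(concatenate_sessions(bad), "sampling rate")
})

test_that("lag windows and lagged designs have the documented geometry", {
  w <- lag_window(-0.2, 5, fs = 250)
  expect_identical(w$n_lags, 1301L)
  expect_identical(6L * w$n_lags, 7806L)
  expect_equal(range(w$lag_s), c(-0.2, 5))

  # single impulse: the design column at lag l has its 1 shifted by l samples
  ws <- lag_window(-0.2, 1, fs = 10)
  ch <- matrix(0, 6, 50, dimnames = list(trf_features, NULL))
  ch["low_surprisal_onset", 20] <- 1
  ann <- annotation_set(ch, fs = 10)
  X <- build_lagged_design(ann, ws)
  for (j in seq_len(ws$n_lags)) {
    col <- X[, j]
    expect_identical(which(col == 1), 20L + ws$lags[j])
  }
  # zero channels give zero columns
  expect_true(all(X[, (ws$n_lags + 1):(2 * ws$n_lags)] == 0))
  expect_error(build_lagged_design(annotation_set(ch[, 1:5], 10), ws),
               "longer than the signal")
})

test_that("lagged design equals a brute-force convolution oracle", {
  set.seed(1)
  w <- lag_window(-0.2, 0.8, fs = 20)
  n <- 200
  ch <- matrix(rbinom(6 * n, 1, 0.05), 6, n,
               dimnames = list(trf_features, NULL))
  ch["word_surprisal", ] <- ch["word_surprisal", ] * runif(n, 3, 7)
  ann <- annotation_set(ch, fs = 20)
  X <- build_lagged_design(ann, w)
  kern <- matrix(rnorm(6 * w$n_lags), 6, w$n_lags)
  pred <- drop(X %*% as.vector(t(kern)))
  # oracle: direct sum over features and lags
  oracle <- numeric(n)
  for (f in 1:6) for (j in seq_len(w$n_lags)) {
    l <- w$lags[j]
    src <- seq_len(n) - l
    ok <- src >= 1 & src <= n
    oracle[ok] <- oracle[ok] + kern[f, j] * ch[f, src[ok]]
  }
  expect_equal(pred, oracle, tolerance = 1e-12)
})

test_that("ridge fitting matches OLS in the alpha -> 0 limit and shrinks monotonically", {
  set.seed(2)
  w <- lag_window(0, 0.4, fs = 10)
  n <- 300
  ch <- matrix(0, 6, n, dimnames = list(trf_features, NULL))
  for (f in 1:6) ch[f, sample(10:290, 12)] <- 1
  ch["word_surprisal", ch["word_surprisal", ] > 0] <- runif(12, 3, 7)
  ann <- annotation_set((ch > 0) * ch, fs = 10)
  X <- build_lagged_design(ann, w)
  y <- drop(X %*% rnorm(ncol(X))) + rnorm(n, 0, 0.1)

  k0 <- ridge_fit(X, y, w, alpha = 1e-10)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(as.vector(t(coef(k0))), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(k0$intercept, unname(ols[1]), tolerance = 1e-6)

  norms <- vapply(c(0.1, 1, 10, 100, 1e4), function(a)
    sum(coef(ridge_fit(X, y, w, alpha = a))^2), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("a known kernel convolved with impulses is recovered", {
  set.seed(3)
  fs <- 20
  w <- lag_window(-0.2, 2, fs = fs)
  n <- 2000
  ch <- matrix(0, 6, n, dimnames = list(trf_features, NULL))
  for (f in 1:6) ch[f, sample(50:1950, 25)] <- 1
  ann <- annotation_set(ch, fs = fs)
  tk <- stats::dgamma(seq(0, 2, by = 1 / fs), shape = 3, scale = 0.2)
  tk <- tk / sum(tk)
  y <- 0.4 + Reduce(`+`, lapply(1:6, function(f)
    (f / 6) * compslide:::causal_conv(ch[f, ], tk)))
  X <- build_lagged_design(ann, w)
  k <- ridge_fit(X, y, w, alpha = 1e-6)
  keep <- w$lag_s >= 0
  for (f in 1:6)
    expect_gt(cor(coef(k)[f, keep], tk[seq_len(sum(keep))]), 0.99)
})

test_that("cross-validated TRFs report Spearman accuracy with story-blocked folds", {
  p <- make_participant(4)
  s <- simulate_trf_subject(p, seed = 104)
  w <- lag_window(-0.2, 5, fs = 20)
  k <- crossval_trf(s$trace, s$ann, w, alpha = 1, k = 3,
                    boundaries = s$boundaries)
  expect_identical(k$k_used, 3)
  expect_length(k$cv_rho, 3L)
  expect_gt(k$mean_rho, 0.8)
  expect_identical(dim(coef(k)), c(6L, w$n_lags))

  # rank invariance: a monotone transform of the trace leaves rho at 1
  expect_equal(cor(s$trace$values, s$trace$values^3 + 2,
                   method = "spearman"), 1)

  # a constant single-story fold triggers the documented 2-fold fallback
  s2 <- simulate_trf_subject(make_participant(6), n_stories = 3,
                             story_s = 30, seed = 106)
  s2$trace$values[s2$boundaries$start[2]:s2$boundaries$end[2]] <- 0.5
  expect_message(k2 <- crossval_trf(s2$trace, s2$ann, w,
                                    boundaries = s2$boundaries),
                 "2-fold")
  expect_identical(k2$k_used, 2)
  expect_error(crossval_trf(const_trace(0.5, 100, fs = 20), s$ann, w),
               "constant")
})

test_that("kernel peak latency uses earliest-tie and rejects empty kernels", {
  w <- lag_window(-0.2, 1, fs = 10)
  coefm <- matrix(0, 6, w$n_lags, dimnames = list(trf_features, NULL))
  coefm["segment_onset", w$lag_s == 0.3] <- 0.5
  coefm["segment_onset", w$lag_s == 0.7] <- 0.5  # symmetric two-peak kernel
  coefm["word_surprisal", w$lag_s == 0.5] <- -0.8  # sign handled via |coef|
  k <- compslide:::new_trf_kernel(coefm, 0, w, 1)
  expect_equal(kernel_peak_latency(k, "segment_onset"), 0.3)
  expect_equal(kernel_peak_latency(k, "word_surprisal"), 0.5)
  expect_error(kernel_peak_latency(k, "rate_x1_onset"), "all-zero")
  expect_error(kernel_peak_latency(k, "not_a_feature"), "unknown")
})

test_that("a high-SNR participant's injected delay is recovered to a tenth of a second", {
  p <- make_participant(5, overrides = list(delay_shape = 3.4,
                                            delay_scale = 0.5))  # mode 1.2 s
  s <- simulate_trf_subject(p, snr = 20, seed = 42)
  w <- lag_window(-0.2, 5, fs = 20)
  k <- crossval_trf(s$trace, s$ann, w, boundaries = s$boundaries)
  expect_equal(s$true_peak_s, 1.2)
  expect_lt(abs(kernel_peak_latency(k, "high_surprisal_onset") - 1.2), 0.1)
})

test_that("prediction is translation-equivariant up to edge effects", {
  set.seed(6)
  fs <- 10
  w <- lag_window(0, 1, fs = fs)
  n <- 400
  shift <- 7L
  ch <- matrix(0, 6, n, dimnames = list(trf_features, NULL))
  for (f in 1:6) ch[f, sample(30:(n - 30), 15)] <- 1
  tk <- stats::dgamma(seq(0, 1, by = 1 / fs), shape = 2, scale = 0.15)
  tk <- tk / sum(tk)
  y <- Reduce(`+`, lapply(1:6, function(f)
    0.5 * compslide:::causal_conv(ch[f, ], tk))) + rnorm(n, 0, 0.01)
  ch_s <- cbind(matrix(0, 6, shift), ch[, seq_len(n - shift)])
  rownames(ch_s) <- trf_features
  y_s <- c(rep(0, shift), y[seq_len(n - shift)])
  k1 <- ridge_fit(build_lagged_design(annotation_set(ch, fs), w), y, w, 1)
  k2 <- ridge_fit(build_lagged_design(annotation_set(ch_s, fs), w), y_s, w, 1)
  expect_equal(coef(k1), coef(k2), tolerance = 0.05)
})

test_that("ablation with nothing dropped is an exact no-op", {
  subs <- lapply(1:2, function(i)
    simulate_trf_subject(make_participant(i), n_stories = 4, story_s = 30,
                         seed = 400 + i))
  w <- lag_window(-0.2, 5, fs = 20)
  res <- suppressMessages(ablation_compare(subs, w,
                                           features_to_drop = character(0)))
  expect_identical(res$delta_rho, c(0, 0))
  expect_identical(res$p_value, 1)
})
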