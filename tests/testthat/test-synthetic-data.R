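test_that("participant profiles are deterministic and validated", {
  expect_identical(make_participant(1), make_participant(1))
  expect_false(identical(make_participant(1), make_participant(2)))
  expect_error(make_participant(1, overrides = list(comp_max = 1.5)),
               "comp_max")
  expect_error(make_participant(1, overrides = list(drift_ppm = 600)),
               "drift_ppm")
  expect_error(make_participant(1, overrides = list(nonsense = 1)), "unknown")
})

test_that("delay kernels integrate to one across seeds", {
  for (s in seq_len(100)) {
    p <- make_participant(s)
    expect_equal(sum(delay_kernel(p, fs = 50)), 1, tolerance = 1e-9)
  }
  # discrete kernel tracks the analytic gamma density mass
  p <- make_participant(3)
  dens <- stats::integrate(stats::dgamma, 0, Inf, shape = p$delay_shape,
                           scale = p$delay_scale)$value
  expect_equal(dens, 1, tolerance = 1e-6)
})

test_that("latent comprehension follows the declining sigmoid", {
  p <- make_participant(1, overrides = list(comp_max = 0.9, comp_slope = 2,
                                            comp_center = 3))
  expect_equal(latent_comprehension(p, 3), 0.45)          # midpoint = max / 2
  expect_equal(latent_comprehension(p, 4), 0.9 / (1 + exp(2)))
  expect_equal(latent_comprehension(p, 4), 0.1073, tolerance = 1e-3)
  expect_lt(latent_comprehension(p, 100), 1e-6)           # fast-rate asymptote
  expect_equal(latent_comprehension(p, 1e-6), 0.9, tolerance = 1e-2)
  rates <- seq(0.5, 6, by = 0.25)
  expect_true(all(diff(latent_comprehension(p, rates)) <= 0))
  expect_error(latent_comprehension(p, 0), "positive")
})

test_that("simulated trials have the device's sample count, quantization and drift", {
  p <- quiet_participant(1)
  sim <- simulate_trial(p, rate = 1, duration_s = 29, seed = 2)
  expect_identical(nrow(sim$log), 7250L)
  expect_true(all(sim$log$value %in% 0:255))
  expect_true(all(diff(sim$log$device_time_ms) > 0))

  # saturated participant: latent 1 after the initial ramp -> ADC 255
  psat <- quiet_participant(2, comp_max = 1, comp_center = 50,
                            delay_shape = 2, delay_scale = 0.1)
  sim2 <- simulate_trial(psat, rate = 1, duration_s = 10, seed = 3)
  post_ramp <- sim2$log$value[sim2$log$host_time_s > 2]
  expect_true(all(post_ramp == 255))

  # 400 ppm drift leads the host clock by 12 ms after 30 s
  pd <- quiet_participant(3, drift_ppm = 400)
  sim3 <- simulate_trial(pd, rate = 1, duration_s = 30, seed = 4)
  lead_ms <- max(sim3$log$device_time_ms) - max(sim3$log$host_time_s) * 1000
  expect_equal(lead_ms, max(sim3$log$host_time_s) * 1000 * 4e-4)
  expect_equal(lead_ms, 12, tolerance = 0.01)
})

test_that("session plans encode the three experiment designs", {
  p1 <- session_plan("exp1")
  expect_identical(nrow(p1$trials), 125L)
  expect_true(all(table(p1$trials$speech_rate) == 25))
  p2 <- session_plan("exp2", n_blocks = 2)
  expect_true(all(table(p2$trials$block, p2$trials$speech_rate) == 16))
  expect_true(all(table(p2$trials$speech_rate) == 32))
  expect_no_repeats(p2$trials$speech_rate, p2$trials$block)
  expect_equal(sum(p2$trials$duration_s[p2$trials$block == 1]) / 60, 10)
  p3 <- session_plan("exp3")
  expect_identical(sort(unique(p3$trials$speech_rate)), c(1, 2.5))
  expect_true(all(table(p3$trials$speech_rate) == 4))
})

test_that("simulated sessions carry trials, post hoc scores and summaries", {
  prof <- quiet_participant(5)
  recs <- simulate_session(session_plan("exp1"), prof, fs = 50)
  expect_length(recs, 125L)
  expect_true(all(vapply(recs, function(r) r$scale_10 %in% 0:10, logical(1))))
  expect_true(all(vapply(recs, function(r) r$mc_correct %in% 0:1, logical(1))))
  got <- vapply(recs, function(r) !is.na(r$summary_text), logical(1))
  expect_equal(sum(got), round(0.6 * 125))
  durs <- vapply(recs, function(r) length(r$trace$values) / r$trace$fs,
                 numeric(1))
  expect_equal(durs, vapply(recs, `[[`, numeric(1), "duration_s"),
               tolerance = 1 / 50)

  # degenerate comprehension: center 0 puts every rate on the floor
  p0 <- quiet_participant(6, comp_center = 0, comp_slope = 2.5)
  expect_lt(max(latent_comprehension(p0, 1:5)), 0.08)
})

test_that("recency-biased summaries over-represent late pentiles", {
  words <- sprintf("w%02d", 1:50)
  expect_identical(simulate_summary(words, comprehension = 0), character(0))

  # unbiased sampling: pentile counts consistent with uniform inclusion
  counts <- rep(0, 5)
  idx <- rep(1:5, each = 10)
  for (i in 1:1000) {
    s <- simulate_summary(words, comprehension = 0.3, recency_bias = 0,
                          seed = i)
    counts <- counts + tabulate(idx[match(s, words)], 5)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # strong bias: final pentile included far more often than the first
  counts5 <- rep(0, 5)
  for (i in 1:1000) {
    s <- simulate_summary(words, comprehension = 0.3, recency_bias = 5,
                          seed = 2000 + i)
    counts5 <- counts5 + tabulate(idx[match(s, words)], 5)
  }
  expect_gt(counts5[5], counts5[1])
})

test_that("surprisal stories alternate chunks with target means and rate-scaled onsets", {
  ev <- simulate_surprisal_story(n_chunks = 10, rate = 1, seed = 1)
  expect_identical(nrow(ev), 300L)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_identical(unique(ev$chunk_type[ev$chunk %% 2 == 1]), "low")
  expect_identical(unique(ev$chunk_type[ev$chunk %% 2 == 0]), "high")
  expect_equal(mean(ev$surprisal[ev$chunk_type == "low"]), 4.91,
               tolerance = 0.2)
  expect_equal(mean(ev$surprisal[ev$chunk_type == "high"]), 5.90,
               tolerance = 0.2)

  ev_fast <- simulate_surprisal_story(n_chunks = 10, rate = 2.5, seed = 1)
  expect_equal(ev_fast$onset_s * 2.5, ev$onset_s, tolerance = 1e-10)

  two <- simulate_surprisal_story(n_chunks = 2, rate = 1, seed = 5)
  expect_identical(nrow(two), 60L)
  expect_true(all(diff(two$onset_s) > 0))
  expect_error(simulate_surprisal_story(n_chunks = 3), "even")
  expect_error(simulate_surprisal_story(n_chunks = 4, mean_low = 6,
                                        mean_high = 5), "mean_high")
})

test_that("toy embeddings are deterministic unit vectors", {
  emb <- make_toy_embeddings(c("dog", "cat", "dog", "rain"), dim = 8, seed = 1)
  expect_identical(nrow(emb$vectors), 3L)  # duplicates collapse
  expect_equal(unname(sqrt(rowSums(emb$vectors^2))), rep(1, 3))
  expect_equal(cosine(emb$vectors["dog", ], emb$vectors["dog", ]), 1)

  f1 <- tempfile(fileext = ".txt"); f2 <- tempfile(fileext = ".txt")
  write_word2vec(emb, f1)
  write_word2vec(make_toy_embeddings(c("dog", "cat", "dog", "rain"),
                                     dim = 8, seed = 1), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_word2vec(f1)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-7)
  expect_error(make_toy_embeddings(character(0)), "at least one")
  expect_error(make_toy_embeddings("a", dim = 1), "at least 2")
})

test_that("generators are reproducible under a fixed seed", {
  p <- make_participant(7)
  a <- simulate_trial(p, 2, 5, fs = 50, seed = 11)
  b <- simulate_trial(p, 2, 5, fs = 50, seed = 11)
  expect_identical(a$log, b$log)
  expect_identical(simulate_surprisal_story(4, seed = 3),
                   simulate_surprisal_story(4, seed = 3))
  expect_identical(simulate_summary(letters, 0.5, 2, seed = 9),
                   simulate_summary(letters, 0.5, 2, seed = 9))
})
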