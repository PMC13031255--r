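# Shared fixtures, built in code.

# Hand-checkable 2-D embedding table: dog = (1, 0), cat = (0.8, 0.6),
# rain = (0, 1); all unit norm, cos(dog, cat) = 0.8, cos(cat, rain) = 0.6,
# cos(dog, rain) = 0.
toy_emb_2d <- function() {
  embedding_table(c("dog", "cat", "rain"),
                  rbind(c(1, 0), c(0.8, 0.6), c(0, 1)))
}

# A small deterministic participant with no noise or drift unless overridden.
quiet_participant <- function(seed = 1, ...) {
  make_participant(seed, overrides = utils::modifyList(
    list(motor_noise_sd = 0, drift_ppm = 0), list(...)))
}

# Constant-valued slider trace.
const_trace <- function(v, n = 100, fs = 250, ...) {
  slider_trace(rep(v, n), fs = fs, ...)
}

expect_no_repeats <- function(rates, blocks) {
  same_block <- diff(blocks) == 0
  expect_true(all(diff(rates)[same_block] != 0))
}
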