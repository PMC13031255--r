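# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the prior
#' RNG state, so seeded generators do not disturb the caller's random stream.
#' A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
      stopf("'seed' must be a single non-negative number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Derive a stream-specific child seed from a base seed, kept inside the 32-bit
# integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483587)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Half-up rounding of duration*fs style products. Products such as 5.81 * 250
# land at 1452.4999999999998 in binary floating point although the decimal
# arithmetic gives exactly 1452.5; values are snapped at 1e-6 before rounding
# so exact decimal halves round up.
round_half_up <- function(x) floor(round(x, 6) + 0.5)

# Pentile index (1..5) for each of n ordered elements; contiguous bins whose
# sizes differ by at most one, remainder assigned to the earliest bins.
pentile_index <- function(n) {
  if (n < 5) stopf("need at least 5 elements to form pentiles, got %d", n)
  base <- n %/% 5L
  sizes <- base + as.integer(seq_len(5L) <= n %% 5L)
  rep.int(1:5, sizes)
}

# Causal discrete convolution of a signal with a kernel (kernel[1] acts at lag
# 0); the signal is treated as zero before its first sample, so output length
# equals input length.
causal_conv <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(kernel)) {
    if (k > n) break
    idx <- k:n
    out[idx] <- out[idx] + kernel[k] * x[seq_len(n - k + 1L)]
  }
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
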