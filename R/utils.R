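# Internal helpers: deterministic seeding and small numeric utilities.
#
# All stochastic operations in the package draw from R's RNG inside
# `local_seed()`, which saves and restores the caller's RNG state, so no
# function leaks randomness into (or depends on) the global stream.

local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and an index, keeping values in
# [1, 2^31 - 2] so they remain valid 32-bit integer seeds. A fixed LCG-style
# mix keeps streams for different indices well separated.
child_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m)
  ((s * 48271 + as.double(index) * 8313487 + 1) %% (m - 1)) + 1
}

# 1/f ("pink") noise of length n via spectral shaping: white Gaussian
# spectrum scaled by f^(-1/2) in amplitude, inverse FFT, unit-variance
# normalized. Draws 2*n normals from the current RNG stream.
pink_noise <- function(n) {
  if (n == 1) return(rnorm(1))
  re <- rnorm(n)
  im <- rnorm(n)
  spec <- complex(real = re, imaginary = im)
  f <- c(1, seq_len(n - 1)) # DC treated as f = 1 to avoid division by zero
  f <- pmin(f, n - f + 1)   # mirror frequencies above Nyquist
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(x)
  (x - mean(x)) / s
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}

`%||%` <- rlang::`%||%`
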