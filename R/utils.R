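## internal helpers shared across modules

## run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

## Gaussian-kernel smoothed standard-normal random field via circular FFT
## convolution; lengthscale in cells (0 = white noise). Standardised to
## mean 0, sd 1.
smoothed_field <- function(nr, nc, lengthscale) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (lengthscale <= 0) return(z)
  if (2 * ceiling(3 * lengthscale) + 1 > min(nr, nc))
    stop(sprintf(
      "grid (%d x %d) too small for kernel length-scale %g (needs >= %d cells)",
      nr, nc, lengthscale, 2 * ceiling(3 * lengthscale) + 1))
  di <- pmin(seq_len(nr) - 1, nr - (seq_len(nr) - 1))
  dj <- pmin(seq_len(nc) - 1, nc - (seq_len(nc) - 1))
  k <- exp(-outer(di^2, dj^2, `+`) / (2 * lengthscale^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    length(z)
  (sm - mean(sm)) / stats::sd(as.vector(sm))
}
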