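# Seeded random draws without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Colored (1/f^beta) noise generator
#'
#' Generates a Gaussian noise series whose power spectrum falls off as
#' `1/f^beta` (`beta = 0` white, `beta = 1` pink), by shaping the Fourier
#' amplitudes of a white series and inverting the transform. The output is
#' renormalized exactly to mean 0 and sample SD `amplitude_sd`, so the
#' spectral exponent is the only irregularity knob.
#'
#' @param n_samples series length, >= 64.
#' @param beta spectral exponent >= 0.
#' @param amplitude_sd target sample SD, > 0.
#' @param seed integer seed; identical seeds give identical series. `NULL`
#'   draws from the ambient RNG stream.
#' @return numeric vector of length `n_samples`.
#' @examples
#' x <- colored_noise(4096, beta = 1, seed = 1)
#' sd(x)
#' @export
colored_noise <- function(n_samples, beta = 0, amplitude_sd = 1, seed = NULL) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 64L)
    abort(sprintf("n_samples = %d too small: need >= 64.", n_samples))
  if (beta < 0) abort("`beta` must be >= 0.")
  if (amplitude_sd <= 0) abort("`amplitude_sd` must be > 0.")
  w <- with_seed(seed, rnorm(n_samples))
  if (beta > 0) {
    half <- n_samples %/% 2L
    # two-sided FFT bin frequencies (index units; DC handled separately)
    f <- c(1, seq_len(half),
           if (n_samples %% 2L == 0L) seq(half - 1L, 1L) else seq(half, 1L))
    sp <- fft(w) * f^(-beta / 2)
    sp[1] <- 0
    w <- Re(fft(sp, inverse = TRUE)) / n_samples
  }
  w <- w - mean(w)
  w / sd(w) * amplitude_sd
}

# Variance-preserving convex mixture of white and 1/f noise; `w` is the
# white-noise proportion, the irregularity knob of the synthetic EEG.
mixed_noise <- function(n_samples, w, beta = 1, amplitude_sd = 1,
                        seed = NULL) {
  w <- min(max(w, 0), 1)
  x <- with_seed(seed, {
    white <- colored_noise(n_samples, beta = 0)
    pink <- colored_noise(n_samples, beta = beta)
    w * white + (1 - w) * pink
  })
  x <- x - mean(x)
  x / sd(x) * amplitude_sd
}
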