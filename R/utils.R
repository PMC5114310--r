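## Internal numeric helpers shared by the simulator and the epoching code.

#' Pink (1/f) noise
#'
#' Spectral-shaping generator: white Gaussian Fourier coefficients are
#' scaled by 1/sqrt(f) and transformed back, then standardized to the
#' requested standard deviation. DC is removed.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @return numeric vector of length `n`.
#' @keywords internal
pinkNoise <- function(n, sd = 1) {
  if (n < 2 || sd == 0) return(numeric(n))
  nfft <- n
  half <- floor(nfft / 2)
  f <- seq_len(half)
  amp <- 1 / sqrt(f)
  spec <- amp * complex(real = stats::rnorm(half),
                        imaginary = stats::rnorm(half)) / sqrt(2)
  full <- complex(real = numeric(nfft), imaginary = numeric(nfft))
  full[2:(half + 1)] <- spec
  if (nfft %% 2 == 0) {
    full[half + 1] <- complex(real = Re(spec[half]), imaginary = 0)
    if (half > 1) full[nfft:(nfft - half + 2)] <- Conj(spec[1:(half - 1)])
  } else {
    full[nfft:(nfft - half + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / nfft
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (sd / s)
}

## Time grid of an epoch: sample n (1-based) <-> t = -500 + 2*(n-1) ms.
epochTimes <- function() seq(-500, 1498, by = 2)

## 1-based sample indices of a half-open [from, to) ms interval of an epoch.
epochSampleIndex <- function(fromMs, toMs) {
  t <- epochTimes()
  which(t >= fromMs & t < toMs)
}

## Derive a substream seed below 2^31 from (seed, index).
substreamSeed <- function(seed, index) {
  (as.numeric(seed) * 1103L + index * 12347) %% 2147483629
}
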