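# Internal helpers shared across the simulation and processing stages.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

# Smooth spatial noise field: white Gaussian noise low-passed with an
# isotropic Gaussian kernel (via FFT), standardised to mean 0, sd 1.
smooth_noise <- function(nrow, ncol, sigma_px = 3) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  fr <- c(0:(nrow %/% 2), -((ceiling(nrow / 2) - 1):1)) / nrow
  fc <- c(0:(ncol %/% 2), -((ceiling(ncol / 2) - 1):1)) / ncol
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, `+`))
  s <- Re(fft(fft(z) * h, inverse = TRUE)) / (nrow * ncol)
  (s - mean(s)) / sd(s)
}

# Phase unwrapping along the first dimension of a matrix (or a vector):
# removes 2*pi jumps between successive samples.
unwrap_phase <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  d <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
  jumps <- round(d / (2 * pi))
  corr <- apply(jumps, 2, cumsum)
  if (is.null(dim(corr))) corr <- matrix(corr, ncol = ncol(x))
  x[-1, ] <- x[-1, , drop = FALSE] - 2 * pi * corr
  if (vec) drop(x) else x
}

# Magnitude of the analytic signal (Hilbert envelope) of a real trace.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Inverse FFT of a half-spectrum (bins 0..n/2) back to a real trace of
# length n. Inverse of rfft_bins().
irfft_real <- function(S, n) {
  full <- complex(length.out = n)
  nh <- length(S)
  full[1:nh] <- S
  full[(nh + 1):n] <- Conj(S[seq(nh - 1, 2)])
  Re(fft(full, inverse = TRUE)) / n
}

rfft_bins <- function(x) {
  n <- length(x)
  fft(x)[1:(n %/% 2 + 1)]
}

# Tukey (tapered cosine) window.
tukey_window <- function(n, alpha = 0.25) {
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
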