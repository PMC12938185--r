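# Zero-phase FIR filtering and Fourier resampling primitives.

# Windowed-sinc band-pass design (Hamming). Transition width defaults to 25% of
# the lower edge with a 1 Hz floor so the kernel stays shorter than a 10 s
# analysis segment even for the delta band; it is additionally clipped so the
# transition bands stay inside (0, Nyquist).
design_bandpass_fir <- function(low, high, fs, trans = NULL) {
  nyq <- fs / 2
  if (!(low > 0 && high > low && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  if (is.null(trans)) trans <- max(0.25 * low, 1)
  trans <- min(trans, low, nyq - high)
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  as.numeric(signal::fir1(ntaps - 1, c(low, high) / nyq, type = "pass",
                          window = signal::hamming(ntaps)))
}

# Causal FIR convolution via FFT (keeps the first length(x) samples,
# i.e. the same alignment as stats::filter(x, b, sides = 1)).
fft_fir <- function(b, x) {
  nf <- stats::nextn(length(x) + length(b) - 1L, 2)
  B <- stats::fft(c(b, rep(0, nf - length(b))))
  X <- stats::fft(c(x, rep(0, nf - length(x))))
  y <- Re(stats::fft(B * X, inverse = TRUE)) / nf
  y[seq_along(x)]
}

# Forward-backward (zero-phase) FIR filtering of one vector with odd
# reflection padding of one kernel length at each end.
zero_phase_filter_vec <- function(b, x) {
  n <- length(x)
  L <- length(b)
  if (n < 3 * L)
    stop(sprintf("recording too short for zero-phase filtering: %d samples < 3 x %d filter taps", n, L))
  pad <- L
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- fft_fir(b, xp)
  y <- rev(fft_fir(b, rev(y)))
  # forward+backward each delay by (L-1)/2 in opposite directions: net zero phase
  y[(pad + 1L):(pad + n)]
}

# Apply zero-phase band-pass to every row of a channel x sample matrix.
zero_phase_filter_mat <- function(b, x) {
  t(apply(x, 1L, function(row) zero_phase_filter_vec(b, row)))
}

# Fourier-domain resampling of a vector to exactly n_out samples
# (band-limited interpolation; inputs here are already low-passed).
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- rep(0 + 0i, n_out)
  nmin <- min(n, n_out)
  h <- nmin %/% 2                  # Nyquist-side positive bins: 1..h+1
  g <- (nmin - 1L) %/% 2           # negative-frequency bins copied
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  if (g >= 1L) Y[(n_out - g + 1L):n_out] <- X[(n - g + 1L):n]
  if (nmin %% 2L == 0L) {
    if (n_out < n) {
      Y[h + 1L] <- X[h + 1L] + X[n - h + 1L]  # fold the split Nyquist energy
    } else {
      Y[h + 1L] <- X[h + 1L] / 2
      Y[n_out - h + 1L] <- X[h + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
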