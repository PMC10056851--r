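#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing chain: polyphase resampling to
#' `target_rate`, nearest-neighbour resizing to `block_len` samples,
#' tapering with a symmetric Hamming window, and (for the noise-only
#' derivation) a zero-phase 4th-order Butterworth highpass at
#' `highpass_fc` applied at the original rate.
#'
#' @param target_rate output sampling rate in Hz (default 6400).
#' @param block_len block length N in samples (default 64000, i.e. 10 s
#'   at 6400 Hz).
#' @param window taper family; only `"hamming"` is implemented.
#' @param highpass_order Butterworth order for the noise derivation.
#' @param highpass_fc highpass cut-off in Hz.
#' @return a `preprocess_config` object.
#' @export
preprocess_config <- function(target_rate = 6400, block_len = 64000,
                              window = "hamming", highpass_order = 4,
                              highpass_fc = 2000) {
  stopifnot(target_rate > 0, block_len > 0, highpass_order >= 1, highpass_fc > 0)
  window <- match.arg(window, "hamming")
  structure(list(target_rate = target_rate, block_len = block_len,
                 window = window, highpass_order = highpass_order,
                 highpass_fc = highpass_fc),
            class = "preprocess_config")
}

# Kaiser window of length n, shape beta (I0 via base besselI)
kaiser_window <- function(n, beta) {
  m <- n - 1
  k <- 0:m
  besselI(beta * sqrt(pmax(0, 1 - ((2 * k - m) / m)^2)), 0) / besselI(beta, 0)
}

# Kaiser-windowed-sinc lowpass FIR; cutoff in normalized frequency
# (cycles/sample), odd length, unit DC gain.  beta = 8 gives ~81 dB
# stopband, comfortably past the 60 dB anti-aliasing requirement.
design_lowpass_fir <- function(cutoff, half_width, beta = 8) {
  n <- 2L * half_width + 1L
  k <- -half_width:half_width
  h <- 2 * cutoff * sinc(2 * cutoff * k) * kaiser_window(n, beta)
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Polyphase rational resampling
#'
#' Resample to `target_rate` through zero-stuffing by the rational
#' up-factor, a Kaiser-windowed-sinc anti-aliasing lowpass, and
#' decimation, evaluated only on the output grid (polyphase).  Output
#' length is `round(length(x) * target_rate / rate)`.
#'
#' @param x an [audio_segment()].
#' @param target_rate requested rate in Hz.
#' @return the resampled [audio_segment()].
#' @export
resample_audio <- function(x, target_rate) {
  stopifnot(inherits(x, "scat_audio"))
  if (target_rate <= 0) stop("target_rate must be > 0")
  if (target_rate == x$rate) return(x)
  fr <- ratio_pq(target_rate, x$rate)
  p <- fr[1]; q <- fr[2]
  n_in <- length(x$samples)
  n_out <- round(n_in * target_rate / x$rate)
  # operate on the up-sampled grid of rate p * x$rate
  cutoff <- 0.5 / max(p, q)                  # of the upsampled rate
  half <- 10L * max(p, q)
  h <- design_lowpass_fir(cutoff, half) * p  # restore DC gain after zero-stuffing
  up <- numeric(n_in * p)
  up[seq(1L, by = p, length.out = n_in)] <- x$samples
  # y[m] = sum_k h[k] * up[(m-1)*q + 1 + (k - half - 1)] evaluated per tap,
  # vectorized over output samples (classic polyphase evaluation)
  y <- numeric(n_out)
  base <- (seq_len(n_out) - 1L) * q + 1L
  nup <- length(up)
  for (k in seq_along(h)) {
    idx <- base + (k - half - 1L)
    ok <- idx >= 1L & idx <= nup
    if (any(ok)) y[ok] <- y[ok] + h[k] * up[idx[ok]]
  }
  replace_samples(x, y, rate = target_rate)
}

ratio_pq <- function(target, source) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  # rationalize with a denominator cap; rates are integer-valued in practice
  r <- round(c(target, source))
  d <- g(r[1], r[2])
  c(r[1] / d, r[2] / d)
}

#' Nearest-neighbour resize
#'
#' Maps a signal of length L onto exactly `N` samples with the inclusive
#' endpoint index map `i_src = round(i_out * (L-1)/(N-1))` (0-based).
#' The rate metadata is preserved: the result is treated as an N-sample
#' block at the current rate (time compression, spectral content read as
#' unmodified).
#'
#' @param x an [audio_segment()].
#' @param N output length in samples.
#' @return the resized [audio_segment()].
#' @export
resize_nn <- function(x, N) {
  stopifnot(inherits(x, "scat_audio"))
  if (N <= 0) stop("N must be > 0")
  L <- length(x$samples)
  if (L == N) return(x)
  idx <- if (N == 1L) 1L else round((seq_len(N) - 1) * (L - 1) / (N - 1)) + 1L
  replace_samples(x, x$samples[idx])
}

#' Apply the N-sample symmetric Hamming taper
#'
#' Pointwise multiplication by `0.54 - 0.46 * cos(2*pi*n/(N-1))`,
#' `n = 0..N-1` (canonical coefficients).
#'
#' @param x an [audio_segment()] whose length equals the configured block
#'   length.
#' @param N expected block length (defaults to the signal length).
#' @return the tapered [audio_segment()].
#' @export
apply_window <- function(x, N = length(x$samples)) {
  stopifnot(inherits(x, "scat_audio"))
  if (length(x$samples) != N)
    stop("length mismatch: signal has ", length(x$samples), " samples, window ", N)
  replace_samples(x, x$samples * hamming_taper(N))
}

hamming_taper <- function(N) {
  if (N == 1L) return(1)
  n <- 0:(N - 1)
  0.54 - 0.46 * cos(2 * pi * n / (N - 1))
}

# ---- Butterworth highpass (bilinear transform) -------------------------

# analog lowpass prototype poles -> highpass at warped wc -> bilinear.
# returns list(b, a) of the digital filter, fs-normalized.
butter_highpass <- function(order, fc, fs) {
  if (fc >= fs / 2) stop("highpass cut-off must be below Nyquist")
  wc <- 2 * fs * tan(pi * fc / fs)          # pre-warped analog frequency
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP poles
  p_hp <- wc / p_lp                          # lowpass -> highpass
  z_hp <- rep(0+0i, order)                   # order zeros at s = 0
  # bilinear transform s = 2*fs*(1-z^-1)/(1+z^-1)
  fs2 <- 2 * fs
  pz <- (fs2 + p_hp) / (fs2 - p_hp)
  zz <- (fs2 + z_hp) / (fs2 - z_hp)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(zz))
  # unity gain at Nyquist (z = -1) for a highpass
  gain <- sum(b * (-1)^(0:order)) / sum(a * (-1)^(0:order))
  list(b = b / gain, a = a)
}

poly_from_roots <- function(r) {
  p <- 1+0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# zero-phase IIR filtering: odd-reflection padding, forward pass,
# time-reverse, second pass, reverse and trim (squared magnitude response)
filtfilt_iir <- function(b, a, x) {
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= nfact) stop("signal too short for zero-phase filtering")
  pre <- 2 * x[1] - x[(nfact + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - nfact)]
  xx <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, xx)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  y[(nfact + 1L):(nfact + length(x))]
}

#' Derive a noise-only recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth highpass applied
#' at the recording's original rate; the effective magnitude response is
#' the squared single-pass response, so stopband tones are attenuated
#' twice as strongly (in dB) as the one-pass design.  The result is
#' labelled `"noise"`.
#'
#' @param x an [audio_segment()] at the original (pre-resampling) rate.
#' @param cfg a [preprocess_config()].
#' @return the filtered [audio_segment()], labelled `"noise"`.
#' @export
derive_noise_only <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "scat_audio"))
  ba <- butter_highpass(cfg$highpass_order, cfg$highpass_fc, x$rate)
  audio_segment(filtfilt_iir(ba$b, ba$a, x$samples) + 0, x$rate, "noise")
}

#' Run the full preprocessing chain
#'
#' Composition resample -> resize -> window, in that order.  A 5-min
#' 64-kHz recording becomes a 64,000-sample Hamming-tapered block at
#' 6400 Hz; an input already at `target_rate` and `block_len` is only
#' windowed.
#'
#' @param x an [audio_segment()].
#' @param cfg a [preprocess_config()].
#' @return the preprocessed [audio_segment()] of exactly
#'   `cfg$block_len` samples.
#' @export
preprocess_segment <- function(x, cfg = preprocess_config()) {
  y <- resample_audio(x, cfg$target_rate)
  y <- resize_nn(y, cfg$block_len)
  apply_window(y, cfg$block_len)
}
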