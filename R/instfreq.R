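#' Instantaneous-frequency feature configuration
#'
#' Short-time spectral-moment features: per STFT frame, the first moment
#' of `|STFT|^2` over the one-sided frequency grid.  The reference
#' comparison uses a 256-sample rectangular window moving with
#' step-size 1; larger hops subsample the same trajectory (used by the
#' pipeline for tractable sequence lengths).
#'
#' @param window_len rectangular window length in samples (>= 2).
#' @param hop frame step in samples (>= 1).
#' @return an `instfreq_config` object.
#' @export
instfreq_config <- function(window_len = 256, hop = 1) {
  stopifnot(window_len >= 2, hop >= 1)
  structure(list(window_len = as.integer(window_len), hop = as.integer(hop)),
            class = "instfreq_config")
}

#' Instantaneous frequency by first spectral moment
#'
#' `f_i(n) = sum_k f_k |STFT(n,k)|^2 / sum_k |STFT(n,k)|^2` over the
#' one-sided DFT bins `f_k = k * rate / window_len`.  An all-zero frame
#' yields 0 by convention.
#'
#' @param x an [audio_segment()] with at least `window_len` samples.
#' @param cfg an [instfreq_config()].
#' @return list with `freq_hz` (one value per frame) and `time_s`
#'   (frame centres in seconds).
#' @export
instantaneous_frequency <- function(x, cfg = instfreq_config()) {
  stopifnot(inherits(x, "scat_audio"), inherits(cfg, "instfreq_config"))
  v <- x$samples
  W <- cfg$window_len
  if (length(v) < W) stop("signal shorter than the analysis window")
  starts <- seq(1L, length(v) - W + 1L, by = cfg$hop)
  frames <- matrix(v[outer(0:(W - 1L), starts, "+")], nrow = W)
  spec <- Mod(stats::mvfft(frames))^2
  K <- W %/% 2L + 1L
  spec <- spec[1:K, , drop = FALSE]
  fk <- (0:(K - 1L)) * x$rate / W
  den <- colSums(spec)
  num <- colSums(spec * fk)
  fi <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  list(freq_hz = fi, time_s = (starts - 1L + W / 2) / x$rate)
}
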