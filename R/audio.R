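#' Labelled mono waveform
#'
#' The universal currency between all pipeline stages: a numeric sample
#' vector (dimensionless amplitude), its sampling rate in Hz and an
#' optional class label from `c("blue_whale", "fin_whale", "noise")`.
#'
#' @param samples numeric vector of finite sample values.
#' @param rate sampling frequency in Hz (positive scalar).
#' @param label optional class tag; `NULL` for unlabelled audio.
#' @return an object of class `scat_audio`.
#' @export
#' @examples
#' x <- audio_segment(sin(2 * pi * 45 * seq(0, 1, by = 1 / 6400)), 6400)
#' duration_seconds(x)
audio_segment <- function(samples, rate, label = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop("'samples' contains non-finite values")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a positive scalar (Hz)")
  if (!is.null(label)) label <- as.character(label)
  structure(list(samples = as.double(samples), rate = as.double(rate),
                 label = label),
            class = "scat_audio")
}

#' @rdname audio_segment
#' @param x a `scat_audio` object.
#' @export
duration_seconds <- function(x) {
  stopifnot(inherits(x, "scat_audio"))
  length(x$samples) / x$rate
}

#' @export
print.scat_audio <- function(x, ...) {
  cat(sprintf("<scat_audio> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$rate, duration_seconds(x),
              if (is.null(x$label)) "" else paste0(" label=", x$label)))
  invisible(x)
}

# internal: keep metadata, swap samples
replace_samples <- function(x, samples, rate = x$rate, label = x$label) {
  audio_segment(samples, rate, label)
}
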