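#' Read a RIFF WAV file
#'
#' Supports PCM integer (8/16/24/32 bit) and IEEE float (32/64 bit)
#' encodings.  Multichannel files are reduced to their first channel with
#' a warning.  Integer samples are scaled to `[-1, 1]` by the convention
#' `value / 2^(bits - 1)`.
#'
#' @param path path to an existing WAV file.
#' @return a [audio_segment()] (unlabelled).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("corrupt WAV header (no RIFF tag): ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("corrupt WAV header (no WAVE tag): ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels     = readBin(raw_fmt[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate         = readBin(raw_fmt[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("corrupt WAV file (missing fmt chunk): ", path)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("zero-length audio in WAV file: ", path)

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  if (fmt$audio_format == 1L) {          # integer PCM
    if (fmt$bits == 8L) {
      v <- (as.integer(data_raw[seq_len(n_total)]) - 128L) / 128
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v) / 8388608
    } else {
      v <- readBin(data_raw, "integer", n_total, bytes, signed = TRUE,
                   endian = "little") / 2^(fmt$bits - 1L)
    }
  } else if (fmt$audio_format == 3L) {   # IEEE float
    v <- readBin(data_raw, "double", n_total, bytes, endian = "little")
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, "): ", path)
  }
  if (fmt$channels > 1L) {
    warning("multichannel WAV; taking first of ", fmt$channels, " channels")
    v <- v[seq(1L, length(v), by = fmt$channels)]
  }
  if (length(v) == 0L) stop("zero-length audio in WAV file: ", path)
  audio_segment(v, fmt$rate)
}

#' Write a RIFF WAV file
#'
#' @param x a [audio_segment()].
#' @param path output file path.
#' @param format `"pcm16"` (16-bit integer, values clipped to `[-1, 1]`)
#'   or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(x, "scat_audio"))
  format <- match.arg(format)
  n <- length(x$samples)
  if (format == "pcm16") {
    bits <- 16L; tag <- 1L
    pcm <- as.integer(pmin(32767, pmax(-32768, round(x$samples * 32768))))
    data_size <- 2L * n
  } else {
    bits <- 32L; tag <- 3L
    data_size <- 4L * n
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  rate <- as.integer(round(x$rate))
  block <- as.integer(bits / 8L)
  writeBin(16L, con, 4L, endian = "little")                # fmt chunk size
  writeBin(tag, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                 # mono
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * block), con, 4L, endian = "little")
  writeBin(block, con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (format == "pcm16") {
    writeBin(pcm, con, 2L, endian = "little")
  } else {
    writeBin(as.double(x$samples), con, 4L, endian = "little")
  }
  invisible(path)
}
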