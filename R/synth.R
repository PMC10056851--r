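#' Specification of one synthetic whale call
#'
#' Parameter container for the synthetic call generator.  The frequency
#' extent must respect the species band: blue-whale components live in
#' 20--100 Hz, fin-whale components in 5--100 Hz.
#'
#' @param species `"blue"` or `"fin"`.
#' @param call_type one of `"tonal_B"` (constant-frequency B-call),
#'   `"downsweep_D"` (linear FM D-call, `f_start > f_end`),
#'   `"pulse_20Hz"` (~1 s downsweep near 20 Hz) or `"pulse_train"`
#'   (repeated 20-Hz pulses at a fixed inter-pulse interval).
#' @param f_start,f_end start/end frequency in Hz.
#' @param duration_s call duration in seconds (for `pulse_train`, the
#'   span of the whole train).
#' @param amplitude linear peak amplitude (>= 0).
#' @param ipi_s inter-pulse interval for `pulse_train`, seconds.
#' @return a `call_spec` object.
#' @export
call_spec <- function(species = c("blue", "fin"),
                      call_type = c("tonal_B", "downsweep_D", "pulse_20Hz", "pulse_train"),
                      f_start, f_end = f_start, duration_s, amplitude = 1,
                      ipi_s = 3) {
  species <- match.arg(species)
  call_type <- match.arg(call_type)
  band <- if (species == "blue") c(20, 100) else c(5, 100)
  fr <- range(f_start, f_end)
  if (fr[1] < band[1] || fr[2] > band[2])
    stop(sprintf("%s-whale call must stay inside %g-%g Hz (got %g-%g)",
                 species, band[1], band[2], fr[1], fr[2]))
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (call_type == "downsweep_D" && f_start <= f_end)
    stop("downsweep_D requires f_start > f_end")
  structure(list(species = species, call_type = call_type,
                 f_start = f_start, f_end = f_end, duration_s = duration_s,
                 amplitude = amplitude, ipi_s = ipi_s),
            class = "call_spec")
}

#' Specification of the synthetic ocean-noise background
#'
#' Gaussian noise with a `1/f^alpha` power spectrum plus optional
#' shipping-like tonal interferers.
#'
#' @param spectral_slope exponent `alpha >= 0` of the power-law decay.
#' @param level linear RMS of the noise (>= 0).
#' @param tonal_interference optional two-column matrix / data.frame of
#'   `(frequency_hz, amplitude)` rows.
#' @return a `noise_spec` object.
#' @export
noise_spec <- function(spectral_slope = 1, level = 1, tonal_interference = NULL) {
  if (spectral_slope < 0) stop("spectral_slope must be >= 0")
  if (level < 0) stop("level must be >= 0")
  if (!is.null(tonal_interference)) {
    tonal_interference <- as.matrix(tonal_interference)
    stopifnot(ncol(tonal_interference) == 2L)
  }
  structure(list(spectral_slope = spectral_slope, level = level,
                 tonal_interference = tonal_interference),
            class = "noise_spec")
}

# raised-cosine onset/offset envelope covering `frac` of each end
taper_envelope <- function(n, frac = 0.1) {
  m <- max(1L, floor(n * frac))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  env <- rep(1, n)
  env[seq_len(m)] <- ramp
  env[n + 1L - seq_len(m)] <- rev(ramp)
  env
}

# one smooth FM pulse: linear chirp f0 -> f1 with random start phase
chirp_samples <- function(f0, f1, duration_s, rate, phase) {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  ph <- 2 * pi * (f0 * t + (f1 - f0) / (2 * duration_s) * t^2) + phase
  sin(ph) * taper_envelope(length(t))
}

#' Synthesize one whale call
#'
#' Deterministic given `seed` (the only random element is the start
#' phase).  All call types are amplitude-tapered by a raised-cosine
#' onset/offset envelope.
#'
#' @param spec a [call_spec()].
#' @param rate sampling rate in Hz; must be at least twice the highest
#'   call frequency.
#' @param seed integer seed.
#' @return a labelled [audio_segment()] (`blue_whale` or `fin_whale`).
#' @export
#' @examples
#' d <- synth_call(call_spec("blue", "downsweep_D", 100, 40, 3), 6400, 1)
synth_call <- function(spec, rate, seed = 1L) {
  stopifnot(inherits(spec, "call_spec"))
  if (rate < 2 * max(spec$f_start, spec$f_end))
    stop("sampling rate violates Nyquist for this call")
  phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  v <- switch(spec$call_type,
    tonal_B = chirp_samples(spec$f_start, spec$f_start, spec$duration_s, rate, phase),
    downsweep_D = chirp_samples(spec$f_start, spec$f_end, spec$duration_s, rate, phase),
    pulse_20Hz = chirp_samples(spec$f_start, spec$f_end,
                               min(spec$duration_s, 1), rate, phase),
    pulse_train = {
      pulse <- chirp_samples(spec$f_start, spec$f_end, 1, rate, phase)
      n <- max(1L, round(spec$duration_s * rate))
      ipi <- max(length(pulse), round(spec$ipi_s * rate))
      out <- numeric(n)
      at <- 1L
      while (at <= n) {
        idx <- at:min(n, at + length(pulse) - 1L)
        out[idx] <- out[idx] + pulse[seq_along(idx)]
        at <- at + ipi
      }
      out
    })
  label <- if (spec$species == "blue") "blue_whale" else "fin_whale"
  audio_segment(spec$amplitude * v + 0, rate, label)
}

#' Synthesize colored ocean background noise
#'
#' White Gaussian noise shaped in the frequency domain to a `1/f^alpha`
#' power spectrum, rescaled to the requested RMS `level`, plus optional
#' tonal interferers.  Deterministic given `seed`.
#'
#' @param duration_s length in seconds (> 0).
#' @param rate sampling rate in Hz.
#' @param spec a [noise_spec()].
#' @param seed integer seed.
#' @return an [audio_segment()] labelled `"noise"`.
#' @export
synth_noise <- function(duration_s, rate, spec = noise_spec(), seed = 1L) {
  stopifnot(inherits(spec, "noise_spec"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  n <- round(duration_s * rate)
  if (spec$level == 0 && is.null(spec$tonal_interference))
    return(audio_segment(numeric(n) + 0, rate, "noise"))
  w <- with_seed(seed, stats::rnorm(n))
  if (spec$spectral_slope > 0) {
    wh <- stats::fft(w)
    k <- c(1, seq_len(n - 1))               # DC bin reuses the first gain
    f <- pmin(k, n - k) / n                 # two-sided frequency magnitude
    gain <- f^(-spec$spectral_slope / 2)
    gain[1] <- gain[2]
    w <- Re(stats::fft(wh * gain, inverse = TRUE)) / n
  }
  if (spec$level > 0) {
    w <- w * spec$level / sqrt(mean(w^2))
  } else {
    w <- numeric(n)
  }
  if (!is.null(spec$tonal_interference)) {
    t <- seq_len(n) / rate
    for (i in seq_len(nrow(spec$tonal_interference)))
      w <- w + spec$tonal_interference[i, 2] *
        sin(2 * pi * spec$tonal_interference[i, 1] * t)
  }
  audio_segment(w, rate, "noise")
}

#' Embed a call in noise at a prescribed SNR
#'
#' The call is scaled so that `10*log10(P_call / P_noise) = snr_db`,
#' where both powers are measured over the call's support (its non-zero
#' extent), then added to the noise centred in time.  `snr_db = -Inf`
#' returns the noise unchanged.
#'
#' @param call,noise [audio_segment()]s at equal rates; `noise` at least
#'   as long as `call`.
#' @param snr_db target signal-to-noise ratio in dB (may be `-Inf`).
#' @return an [audio_segment()] carrying the call's label (or `"noise"`
#'   when `snr_db = -Inf`).
#' @export
mix_at_snr <- function(call, noise, snr_db) {
  stopifnot(inherits(call, "scat_audio"), inherits(noise, "scat_audio"))
  if (call$rate != noise$rate) stop("rate mismatch between call and noise")
  if (length(call$samples) > length(noise$samples))
    stop("noise must be at least as long as the call")
  if (identical(snr_db, -Inf))
    return(audio_segment(noise$samples, noise$rate, "noise"))
  support <- which(call$samples != 0)
  if (length(support) == 0L)
    return(audio_segment(noise$samples, noise$rate, call$label))
  offset <- (length(noise$samples) - length(call$samples)) %/% 2L
  idx <- offset + support
  p_call <- mean(call$samples[support]^2)
  p_noise <- mean(noise$samples[idx]^2)
  g <- sqrt(10^(snr_db / 10) * p_noise / p_call)
  out <- noise$samples
  out[offset + seq_along(call$samples)] <-
    out[offset + seq_along(call$samples)] + g * call$samples
  audio_segment(out, noise$rate, call$label)
}

# class-conditional call parameter distributions; literature-style
# defaults (D-calls: 1-4 s downsweeps inside 20-100 Hz; B-calls: long
# 40-50 Hz tonals; fin: ~1 s pulses near 20 Hz, trains at a fixed IPI)
sample_call_spec <- function(class, duration_s) {
  if (class == "blue_whale") {
    if (stats::runif(1) < 0.5) {
      call_spec("blue", "tonal_B", f_start = stats::runif(1, 40, 50),
                duration_s = stats::runif(1, min(4, 0.5 * duration_s),
                                          min(8, duration_s)))
    } else {
      f0 <- stats::runif(1, 60, 90)
      call_spec("blue", "downsweep_D", f_start = f0,
                f_end = stats::runif(1, 25, 40),
                duration_s = stats::runif(1, min(1, 0.5 * duration_s),
                                          min(4, duration_s)))
    }
  } else if (class == "fin_whale") {
    f0 <- stats::runif(1, 23, 28)
    f1 <- stats::runif(1, 15, 18)
    if (stats::runif(1) < 0.5) {
      call_spec("fin", "pulse_20Hz", f_start = f0, f_end = f1,
                duration_s = min(1, duration_s))
    } else {
      call_spec("fin", "pulse_train", f_start = f0, f_end = f1,
                duration_s = duration_s, ipi_s = stats::runif(1, 2.5, 4))
    }
  } else stop("unknown class: ", class)
}

# one clip's worth of calling activity: baleen whale calls are
# repetitive, so a labelled recording carries a series of calls of one
# type (repeated at short gaps until the clip ends), not an isolated
# vocalization; fin pulse trains already span the clip by construction
call_track <- function(class, duration_s, rate, seed) {
  ss <- derive_seeds(seed, 3L)
  cs <- with_seed(ss[1], sample_call_spec(class, duration_s))
  call <- synth_call(cs, rate, ss[2])
  if (cs$call_type == "pulse_train")
    return(call)
  n <- round(duration_s * rate)
  out <- numeric(n)
  tm <- with_seed(ss[3], list(gaps = stats::runif(16, 0.5, 2),
                              onset = stats::runif(1, 0, 0.5)))
  gaps <- tm$gaps
  at <- 1L + round(tm$onset * rate)
  k <- 0L
  while (at <= n && k < 16L) {
    k <- k + 1L
    idx <- at:min(n, at + length(call$samples) - 1L)
    out[idx] <- out[idx] + call$samples[seq_along(idx)]
    at <- at + length(call$samples) + round(gaps[k] * rate)
  }
  audio_segment(out, rate, call$label)
}

#' Generate a labelled synthetic hydrophone dataset
#'
#' Fixed-length clips per class, with calls drawn from class-appropriate
#' parameter distributions, embedded in `1/f^alpha` noise at SNRs uniform
#' in `snr_range_db`.  Class `"noise"` produces clips with no injected
#' call.  Bit-reproducible given `seed`.
#'
#' @param n_per_class named integer vector, e.g.
#'   `c(blue_whale = 217, fin_whale = 715)` (names from
#'   `blue_whale`, `fin_whale`, `noise`).
#' @param snr_range_db length-2 numeric interval of mixing SNRs in dB.
#' @param rate sampling rate in Hz (64000 exercises the full
#'   preprocessing chain; 6400 is the fast option for tests).
#' @param seed master seed; every clip derives its own child seed.
#' @param duration_s clip length in seconds (default 10).
#' @return list of labelled [audio_segment()]s, classes in the order of
#'   `n_per_class`.
#' @export
make_dataset <- function(n_per_class, snr_range_db = c(0, 10), rate = 6400,
                         seed = 1L, duration_s = 10) {
  if (length(n_per_class) == 0L) stop("empty class mapping")
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class))))
    stop("n_per_class must be named")
  if (any(n_per_class < 1)) stop("class counts must be >= 1")
  total <- sum(n_per_class)
  seeds <- derive_seeds(seed, 3L * total)
  out <- vector("list", total)
  i <- 0L
  for (class in names(n_per_class)) {
    for (k in seq_len(n_per_class[[class]])) {
      i <- i + 1L
      s_noise <- seeds[3L * i - 2L]; s_call <- seeds[3L * i - 1L]; s_mix <- seeds[3L * i]
      nspec <- with_seed(s_mix, noise_spec(spectral_slope = stats::runif(1, 0.5, 1.5)))
      bg <- synth_noise(duration_s, rate, nspec, s_noise)
      if (class == "noise") {
        out[[i]] <- bg
      } else {
        call <- call_track(class, duration_s, rate, s_call)
        snr <- with_seed(s_mix, stats::runif(1, snr_range_db[1], snr_range_db[2]))
        out[[i]] <- mix_at_snr(call, bg, snr)
      }
    }
  }
  out
}

#' Build a protocol dataset of call recordings plus derived noise
#'
#' Mirrors the evaluation protocol's class construction: the noise-only
#' class is obtained from the call recordings themselves by zero-phase
#' Butterworth highpass filtering (see [derive_noise_only()]), so a
#' "<species> + Noise" dataset contains each noisy call clip together
#' with its noise-only counterpart.  With two call species and
#' `derived_noise = FALSE`, the plain two-species dataset is returned.
#'
#' @param n_per_class named counts as in [make_dataset()]; entries named
#'   `"noise"` are realized as highpass-derived counterparts of extra
#'   call clips of the first call class.
#' @param snr_range_db,rate,seed,duration_s as in [make_dataset()].
#' @param highpass_fc highpass cut-off in Hz for the noise derivation.
#' @return list of labelled [audio_segment()]s.
#' @export
make_protocol_dataset <- function(n_per_class, snr_range_db = c(0, 10),
                                  rate = 6400, seed = 1L, duration_s = 10,
                                  highpass_fc = 2000) {
  classes <- names(n_per_class)
  n_noise <- if ("noise" %in% classes) n_per_class[["noise"]] else 0L
  call_classes <- setdiff(classes, "noise")
  if (length(call_classes) == 0L) stop("need at least one call class")
  counts <- n_per_class[call_classes]
  # extra call clips that become the noise-only class after filtering
  if (n_noise > 0) counts[[call_classes[1]]] <- counts[[call_classes[1]]] + n_noise
  ds <- make_dataset(counts, snr_range_db, rate, seed, duration_s)
  if (n_noise > 0) {
    cfg <- preprocess_config(target_rate = rate, highpass_fc = highpass_fc)
    first_n <- n_per_class[[call_classes[1]]]
    donors <- ds[first_n + seq_len(n_noise)]
    noise <- lapply(donors, derive_noise_only, cfg = cfg)
    ds <- c(ds[seq_len(first_n)],
            if (length(call_classes) > 1)
              ds[counts[[call_classes[1]]] + seq_len(sum(unlist(counts[-1])))],
            noise)
  }
  ds
}

#' Class labels of a dataset
#' @param dataset list of [audio_segment()]s.
#' @return character vector of labels.
#' @export
dataset_labels <- function(dataset)
  vapply(dataset, function(x) if (is.null(x$label)) NA_character_ else x$label, "")
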