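test_that("WAV round trip preserves rate, length and amplitude", {
  x <- audio_segment(sin(2 * pi * 45 * seq(0, 1, by = 1 / 6400)), 6400)
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, p16, "pcm16")
  y <- read_wav(p16)
  expect_equal(y$rate, 6400)
  expect_equal(length(y$samples), length(x$samples))
  expect_lt(max(abs(y$samples - x$samples)), 1 / 32768 + 1e-12)

  pf <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, pf, "float32")
  z <- read_wav(pf)
  expect_lt(max(abs(z$samples - x$samples)), 1e-7)

  # constant-zero round trip is exact
  z0 <- audio_segment(numeric(100) + 0, 8000)
  p0 <- withr::local_tempfile(fileext = ".wav")
  write_wav(z0, p0)
  expect_identical(read_wav(p0)$samples, z0$samples)
})

test_that("16-bit PCM scaling follows value / 32768", {
  n <- 256
  sq <- audio_segment(rep(c(1, -1), n / 2), 8000)   # full-scale square wave
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(sq, p, "pcm16")
  y <- read_wav(p)
  # oracle: positive rail quantizes to 32767/32768, negative to -32767/32768
  expect_equal(max(y$samples), 32767 / 32768)
  expect_lte(abs(max(abs(y$samples)) - 1), 1 / 32768)
})

test_that("read_wav rejects broken inputs", {
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "not found")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:16), bad)
  expect_error(read_wav(bad), "corrupt")
})

test_that("annotation parsing reproduces the dataset's class counts", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_count_fixture_csv(p, 217, 715, extra_multi = 5)
  ann <- parse_annotations(p, single_label_only = TRUE)
  expect_equal(nrow(ann), 932)
  expect_equal(as.integer(table(ann$class_label)[c("blue_whale", "fin_whale")]),
               c(217L, 715L))
  all_rows <- parse_annotations(p)
  expect_equal(nrow(all_rows), 937)

  # clip_id determinism and uniqueness
  ann2 <- parse_annotations(p, single_label_only = TRUE)
  expect_identical(ann$clip_id, ann2$clip_id)
  expect_equal(anyDuplicated(ann$clip_id), 0L)
})

test_that("annotation schema errors are explicit", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1, b = 2), p, row.names = FALSE)
  expect_error(parse_annotations(p), "required column")
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(start_s = "oops", end_s = 2, label = "x",
                              source_file = "f.wav"), p2, row.names = FALSE)
  expect_error(parse_annotations(p2), "row 1")
})

test_that("downsweep chirp follows its frequency law (zero-crossing oracle)", {
  x <- synth_call(call_spec("blue", "downsweep_D", 100, 40, 3), 6400, 1)
  v <- x$samples
  zc <- which(diff(sign(v)) != 0)             # zero-crossing sample indices
  freq <- 6400 / (2 * diff(zc))               # one crossing per half period
  mid <- freq[zc[-length(zc)] > 0.1 * 6400 & zc[-length(zc)] < 2.9 * 6400]
  expect_lt(mean(head(mid, 20)), 105); expect_gt(mean(head(mid, 20)), 90)
  expect_lt(mean(tail(mid, 20)), 46); expect_gt(mean(tail(mid, 20)), 36)
  fit <- stats::lm(mid ~ seq_along(mid))
  expect_lt(coef(fit)[2], 0)                  # monotone decreasing trend
})

test_that("tonal B-call peaks at its nominal frequency (FFT oracle)", {
  x <- synth_call(call_spec("blue", "tonal_B", 45, duration_s = 5), 6400, 2)
  sp <- Mod(stats::fft(x$samples))[1:16000]
  peak_hz <- (which.max(sp) - 1) * 6400 / length(x$samples)
  expect_lt(abs(peak_hz - 45), 6400 / length(x$samples) + 1e-9)

  z <- synth_call(call_spec("blue", "tonal_B", 45, duration_s = 2,
                            amplitude = 0), 6400, 2)
  expect_true(all(z$samples == 0))
  expect_error(call_spec("blue", "downsweep_D", 40, 100, 2), "f_start > f_end")
  expect_error(call_spec("blue", "tonal_B", 10, duration_s = 2), "20-100")
  expect_error(synth_call(call_spec("fin", "tonal_B", 90, duration_s = 1), 100),
               "Nyquist")
})

test_that("synthetic calls keep >= 90% energy inside the species band", {
  specs <- list(call_spec("blue", "tonal_B", 45, duration_s = 5),
                call_spec("blue", "downsweep_D", 90, 30, 3),
                call_spec("fin", "pulse_20Hz", 25, 17, 1),
                call_spec("fin", "pulse_train", 26, 16, 10, ipi_s = 3))
  for (cs in specs) {
    x <- synth_call(cs, 6400, 7)
    n <- length(x$samples)
    sp <- Mod(stats::fft(x$samples))^2
    f <- (seq_len(n) - 1) * 6400 / n
    band <- if (cs$species == "blue") c(20, 100) else c(5, 100)
    sel <- (f >= band[1] & f <= band[2]) | (f >= 6400 - band[2])
    expect_gt(sum(sp[sel]) / sum(sp), 0.9)
  }
})

test_that("colored noise has the requested level and spectral slope", {
  w <- synth_noise(10, 6400, noise_spec(spectral_slope = 0, level = 1), 1)
  expect_lt(abs(stats::var(w$samples) - 1), 0.05)
  expect_true(all(synth_noise(1, 6400, noise_spec(level = 0), 1)$samples == 0))

  pink <- synth_noise(20, 6400, noise_spec(spectral_slope = 1), 5)
  sp <- stats::spec.pgram(stats::ts(pink$samples, frequency = 6400),
                          spans = 31, taper = 0, plot = FALSE)
  sel <- sp$freq > 10 & sp$freq < 2000
  slope <- unname(coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.3)

  tonal <- synth_noise(5, 6400, noise_spec(level = 0.01,
                                           tonal_interference = cbind(300, 2)), 1)
  spec <- Mod(stats::fft(tonal$samples))
  peak_hz <- (which.max(spec[1:16000]) - 1) * 6400 / length(tonal$samples)
  expect_lt(abs(peak_hz - 300), 1)
})

test_that("mix_at_snr realizes the requested power ratio", {
  rate <- 6400
  call <- synth_call(call_spec("blue", "tonal_B", 45, duration_s = 4), rate, 1)
  noise <- synth_noise(10, rate, noise_spec(spectral_slope = 1), 2)
  for (snr in c(0, 10)) {
    mixed <- mix_at_snr(call, noise, snr)
    sup <- which(call$samples != 0)
    off <- (length(noise$samples) - length(call$samples)) %/% 2
    embedded <- mixed$samples[off + sup] - noise$samples[off + sup]
    meas <- 10 * log10(mean(embedded^2) / mean(noise$samples[off + sup]^2))
    expect_lt(abs(meas - snr), 0.01)
    expect_equal(mixed$label, "blue_whale")
  }
  pass <- mix_at_snr(call, noise, -Inf)
  expect_identical(pass$samples, noise$samples)
  expect_equal(pass$label, "noise")
  bad <- synth_noise(10, 3200, noise_spec(), 1)
  expect_error(mix_at_snr(call, bad, 0), "rate mismatch")
})

test_that("make_dataset honors counts, labels and determinism", {
  ds <- make_dataset(c(blue_whale = 3, fin_whale = 4, noise = 2),
                     rate = 6400, seed = 11)
  expect_length(ds, 9)
  expect_equal(as.integer(table(dataset_labels(ds))[c("blue_whale", "fin_whale", "noise")]),
               c(3L, 4L, 2L))
  expect_true(all(vapply(ds, function(x) length(x$samples), 0) == 64000))

  ds2 <- make_dataset(c(blue_whale = 3, fin_whale = 4, noise = 2),
                      rate = 6400, seed = 11)
  expect_identical(ds[[1]]$samples, ds2[[1]]$samples)   # bit-reproducible
  expect_identical(ds[[9]]$samples, ds2[[9]]$samples)
  ds3 <- make_dataset(c(blue_whale = 3, fin_whale = 4, noise = 2),
                      rate = 6400, seed = 12)
  expect_false(identical(ds[[1]]$samples, ds3[[1]]$samples))
  expect_error(make_dataset(c()), "empty")
})

test_that("protocol dataset derives its noise class by highpass filtering", {
  ds <- make_protocol_dataset(c(blue_whale = 2, noise = 2), rate = 6400, seed = 3)
  labs <- dataset_labels(ds)
  expect_equal(as.integer(table(labs)[c("blue_whale", "noise")]), c(2L, 2L))
  nz <- ds[[which(labs == "noise")[1]]]
  sp <- Mod(stats::fft(nz$samples))^2
  f <- (seq_along(sp) - 1) * 6400 / length(sp)
  low <- sum(sp[f < 1000]) / sum(sp)
  expect_lt(low, 1e-6)                        # essentially no low-band energy
})
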