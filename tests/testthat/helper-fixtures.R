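# shared fixtures: everything is generated in code at test time

# small scattering configuration used by the oracle / property tests
small_scat_cfg <- function(...)
  scattering_config(Q1 = 2, Q2 = 1, invariance_scale_s = 0.25,
                    signal_len = 1024, rate = 1000, ...)

# write an annotation CSV emulating the reference dataset's class counts:
# 932 single-label rows (217 blue, 715 fin) plus `extra_multi`
# multi-label rows
write_count_fixture_csv <- function(path, n_blue = 217, n_fin = 715,
                                    extra_multi = 0) {
  n <- n_blue + n_fin + extra_multi
  lab <- c(rep("blue_whale", n_blue), rep("fin_whale", n_fin),
           rep("blue_whale;fin_whale", extra_multi))
  df <- data.frame(start_s = seq_len(n), end_s = seq_len(n) + 10,
                   label = lab,
                   source_file = sprintf("rec_%04d.wav", seq_len(n)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a pure tone segment
tone_segment <- function(freq, duration_s, rate, amp = 1) {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  audio_segment(amp * sin(2 * pi * freq * t), rate)
}

# brute-force order-1 scattering oracle: time-domain circular
# convolution (via an explicit circulant matrix), modulus, full-rate
# lowpass, then plain decimation.  Independent of the package's sparse
# frequency-domain path.
brute_force_order1 <- function(x, fb) {
  npad <- fb$npad
  xp <- c(x, numeric(npad - length(x)))
  shift_idx <- (outer(seq_len(npad), seq_len(npad), "-") %% npad) + 1L
  phit <- Re(stats::fft(scatcall:::gauss_hat(npad, fb$sigma_phi),
                        inverse = TRUE)) / npad
  Cphi <- matrix(phit[shift_idx], npad, npad)
  out <- matrix(0, nrow(fb$psi1), fb$n_windows)
  for (i in seq_len(nrow(fb$psi1))) {
    psih <- scatcall:::morlet_hat(npad, fb$psi1$xi[i], fb$psi1$sigma[i],
                                  norm = fb$norm1)
    psit <- stats::fft(psih, inverse = TRUE) / npad
    Cpsi <- matrix(psit[shift_idx], npad, npad)
    u <- Mod(Cpsi %*% xp)
    s <- Cphi %*% u
    out[i, ] <- s[seq(1, npad, by = 2^fb$j_pool)]
  }
  out
}

# scalar logistic, for hand-traced LSTM arithmetic
sig <- function(x) 1 / (1 + exp(-x))
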