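# fold an FFT by k: spectrum periodization == time-domain decimation
fold_fft <- function(X, k) {
  if (k == 1) return(X)
  n <- length(X)
  rowSums(matrix(X, n / k, k)) / k
}

ifft <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# ---- sparse frequency-domain filtering ---------------------------------
# Filters are Gaussians: only bins within `slice_mult` sigmas carry
# non-negligible weight (truncation ~ exp(-slice_mult^2/2)).  A filter is
# therefore applied as (bins, values) pairs on the absolute `npad`-bin
# frequency grid, and folding to a shorter grid becomes index arithmetic.
SLICE_MULT <- 12

# support slice of an analytic Morlet on an n-point grid whose bins are
# absolute frequencies k/npad (n = npad/2^j); returns 0-based bins + values
psi_slice <- function(n, npad, xi, sigma, norm = 1) {
  lo <- max(0L, floor((xi - SLICE_MULT * sigma) * npad))
  hi <- min(n - 1L, ceiling((xi + SLICE_MULT * sigma) * npad))
  k <- lo:hi
  f <- k / npad
  v <- exp(-(f - xi)^2 / (2 * sigma^2))
  kappa <- exp(-xi^2 / (2 * sigma^2))
  if (kappa > 1e-14) {
    # admissibility correction: subtract kappa * baseband Gaussian
    # (two-sided, so include the wrapped negative-frequency end)
    v <- v - kappa * exp(-f^2 / (2 * sigma^2))
    hi0 <- min(n - 1L, ceiling(SLICE_MULT * sigma * npad))
    k0 <- 0:hi0
    lo1 <- max(hi0 + 1L, n - hi0 - 1L)
    k1 <- if (lo1 <= n - 1L) lo1:(n - 1L) else integer(0)
    fneg <- (n - k1) / npad
    extra_k <- c(k0, k1)
    extra_v <- c(exp(-((k0 / npad) - xi)^2 / (2 * sigma^2)) -
                   kappa * exp(-(k0 / npad)^2 / (2 * sigma^2)),
                 exp(-(-fneg - xi)^2 / (2 * sigma^2)) -
                   kappa * exp(-fneg^2 / (2 * sigma^2)))
    keep <- !(extra_k %in% k)
    k <- c(k, extra_k[keep]); v <- c(v, extra_v[keep])
  }
  list(k = k, v = v / norm)
}

# support slice of the real even Gaussian lowpass on an n-point grid with
# absolute bin frequencies k/npad
phi_slice <- function(n, npad, sigma) {
  hw <- min(n %/% 2L, ceiling(SLICE_MULT * sigma * npad))
  kpos <- 0:hw
  kneg <- if (hw >= 1L) (n - hw):(n - 1L) else integer(0)
  k <- c(kpos, kneg)
  f <- c(kpos, -(n - kneg)) / npad
  list(k = k, v = exp(-f^2 / (2 * sigma^2)))
}

# multiply spectrum values at absolute bins `k` (0-based, grid length
# n_in) and fold to grid length n_out; returns the complex spectrum.
# Duplicate target bins can only come from different fold periods, so
# accumulation is done period by period (each period is duplicate-free).
sparse_apply_fold <- function(spec_vals, k, n_out, fold) {
  out <- complex(n_out)
  period <- k %/% n_out
  idx <- k - period * n_out + 1L
  for (m in unique(period)) {
    sel <- period == m
    out[idx[sel]] <- out[idx[sel]] + spec_vals[sel]
  }
  out / fold
}

#' Wavelet scattering transform
#'
#' Computes the three-layer scattering representation of a signal:
#' order 0 `z * phi`, order 1 `|z * psi_lambda| * phi`, and order 2
#' `||z * psi_lambda| * psi_mu| * phi` for the admissible pairs, all by
#' frequency-domain (circular) convolution on the padded grid, with
#' alias-guarded intermediate subsampling and critical output
#' subsampling to `fb$n_windows` time windows.
#'
#' @param x an [audio_segment()] of exactly `cfg$signal_len` samples, or
#'   a plain numeric vector of that length.
#' @param fb a [build_filter_banks()] result.
#' @return a `scattering_features` object: `order0` (1 x T), `order1`
#'   (paths x T), `order2` (pairs x T) matrices of raw (non-negative for
#'   orders 1-2) coefficients, plus `path_table` and `T`.
#' @export
scattering_transform <- function(x, fb) {
  stopifnot(inherits(fb, "filter_banks"))
  v <- if (inherits(x, "scat_audio")) x$samples else as.double(x)
  cfg <- fb$cfg
  if (length(v) != cfg$signal_len)
    stop("signal length ", length(v), " does not match configured N = ", cfg$signal_len)
  npad <- fb$npad; jp <- fb$j_pool; T <- fb$n_windows
  zh <- stats::fft(c(v, numeric(npad - length(v))))

  gs0 <- phi_slice(npad, npad, fb$sigma_phi)
  order0 <- matrix(Re(ifft(sparse_apply_fold(zh[gs0$k + 1L] * gs0$v,
                                             gs0$k, T, 2^jp))), nrow = 1)

  # lowpass + fold to the T output windows, from an envelope spectrum on
  # a grid of length n at intermediate resolution j
  pool_phi <- function(uh, j) {
    gs <- phi_slice(length(uh), npad, fb$sigma_phi)
    Re(ifft(sparse_apply_fold(uh[gs$k + 1L] * gs$v, gs$k, T, 2^(jp - j))))
  }

  n1 <- nrow(fb$psi1)
  order1 <- matrix(0, n1, T)
  u1_hat <- vector("list", n1)   # fft of decimated envelopes, for order 2
  j1s <- fb$psi1$j
  has_pairs <- tabulate(fb$pairs$i1, n1) > 0L
  for (i in seq_len(n1)) {
    j1 <- j1s[i]
    sl <- psi_slice(npad, npad, fb$psi1$xi[i], fb$psi1$sigma[i], fb$norm1)
    Yf <- sparse_apply_fold(zh[sl$k + 1L] * sl$v, sl$k, npad / 2^j1, 2^j1)
    u1 <- Mod(ifft(Yf))
    uh <- stats::fft(u1)
    if (has_pairs[i]) u1_hat[[i]] <- uh
    order1[i, ] <- pool_phi(uh, j1)
  }

  np <- nrow(fb$pairs)
  order2 <- matrix(0, np, T)
  if (np > 0) for (p in seq_len(np)) {
    i <- fb$pairs$i1[p]; m <- fb$pairs$i2[p]
    j1 <- j1s[i]
    j2 <- max(j1, min(fb$psi2$j[m], jp))
    uh <- u1_hat[[i]]
    sl <- psi_slice(length(uh), npad, fb$psi2$xi[m], fb$psi2$sigma[m], fb$norm2)
    Wf <- sparse_apply_fold(uh[sl$k + 1L] * sl$v, sl$k,
                            npad / 2^j2, 2^(j2 - j1))
    u2 <- Mod(ifft(Wf))
    order2[p, ] <- pool_phi(stats::fft(u2), j2)
  }

  structure(list(order0 = order0, order1 = order1, order2 = order2,
                 path_table = fb$path_table, T = T, cfg = cfg,
                 logged = FALSE),
            class = "scattering_features")
}

#' @export
print.scattering_features <- function(x, ...) {
  cat(sprintf("<scattering_features> %d paths x %d windows (orders 0/1/2: 1/%d/%d)%s\n",
              nrow(x$path_table), x$T, nrow(x$order1), nrow(x$order2),
              if (x$logged) ", log-scattering" else ""))
  invisible(x)
}

#' Log-scattering postprocessing
#'
#' Replaces the coefficients by `log(c + eps_abs)` where
#' `eps_abs = eps * max(c)` over the signal's coefficients (floor
#' `.Machine$double.xmin` for an all-zero signal).  Orders 1 and 2 are
#' always logged; the order-0 row is logged too by default.
#'
#' @param S a [scattering_transform()] result with raw coefficients.
#' @param eps relative regularizer (default 1e-12 of the per-signal
#'   maximum).
#' @param include_order0 also log the order-0 path (default TRUE).
#' @return the transformed `scattering_features`.
#' @export
log_scattering <- function(S, eps = 1e-12, include_order0 = TRUE) {
  stopifnot(inherits(S, "scattering_features"))
  if (S$logged) stop("coefficients are already log-scattering")
  if (min(S$order1, S$order2) < 0)
    stop("negative raw scattering coefficient: upstream bug")
  mx <- max(abs(S$order0), S$order1, if (length(S$order2)) S$order2 else 0)
  eps_abs <- max(eps * mx, .Machine$double.xmin)
  S$order1 <- log(S$order1 + eps_abs)
  if (length(S$order2)) S$order2 <- log(S$order2 + eps_abs)
  if (include_order0) S$order0 <- log(abs(S$order0) + eps_abs)
  S$logged <- TRUE
  S
}

# imaginary part of the analytic signal (Hilbert transform) computed on
# the same padded grid as the scattering transform
hilbert_imag <- function(v, npad = next_pow2(length(v))) {
  zh <- stats::fft(c(v, numeric(npad - length(v))))
  h <- numeric(npad)
  h[2:(npad / 2)] <- -1           # -i * sign convention folded into gains
  h[(npad / 2 + 2):npad] <- 1
  Re(ifft(zh * h * 1i))[seq_along(v)]
}

#' Scattering feature planes for classification
#'
#' Stacks the (optionally log-) scattering coefficients of the signal
#' and of its Hilbert pair (the analytic signal's real and imaginary
#' parts) into a `paths' x T` matrix: with the reference configuration,
#' 2 x 246 = 492 feature planes over 8 windows.  `analytic_pair = FALSE`
#' keeps the single real-signal block; `drop_order0 = TRUE` removes the
#' order-0 plane(s) (path 1).
#'
#' @param x [audio_segment()] or numeric vector of configured length.
#' @param fb a [build_filter_banks()] result.
#' @param analytic_pair stack the Hilbert-pair planes (default TRUE).
#' @param log apply [log_scattering()] (default TRUE).
#' @param drop_order0 exclude the order-0 path planes (default FALSE,
#'   keeping the full printed plane count).
#' @return numeric matrix `paths' x T`.
#' @export
wst_features <- function(x, fb, analytic_pair = TRUE, log = TRUE,
                         drop_order0 = FALSE) {
  v <- if (inherits(x, "scat_audio")) x$samples else as.double(x)
  one <- function(sig) {
    S <- scattering_transform(sig, fb)
    if (log) S <- log_scattering(S)
    m <- rbind(S$order0, S$order1, S$order2)
    if (drop_order0) m[-1, , drop = FALSE] else m
  }
  out <- one(v)
  if (analytic_pair)
    out <- rbind(out, one(hilbert_imag(v, fb$npad)))
  out
}

#' Assemble a classifier-facing feature set
#'
#' Stacks per-signal feature matrices (from [wst_features()]) into the
#' three-dimensional array `paths' x T x M`, or the fully flattened
#' `(paths' * T) x M` matrix for classifiers that read one long 1D
#' sequence per signal.
#'
#' @param S_list list of `paths' x T` matrices with identical shapes.
#' @param layout `"sequence"` (array, T kept as the temporal axis) or
#'   `"flat"` (matrix of flattened columns).
#' @return array or matrix with `M = length(S_list)` along the last axis.
#' @export
assemble_feature_set <- function(S_list, layout = c("sequence", "flat")) {
  layout <- match.arg(layout)
  stopifnot(length(S_list) >= 1L)
  d <- dim(S_list[[1]])
  for (s in S_list) if (!identical(dim(s), d))
    stop("inhomogeneous feature shapes in S_list")
  arr <- array(unlist(S_list, use.names = FALSE), dim = c(d[1], d[2], length(S_list)))
  if (layout == "sequence") arr
  else matrix(arr, nrow = d[1] * d[2], ncol = length(S_list))
}

#' Order-1 scattergram
#'
#' The modulus representation `|z * psi_lambda|` of the first filter
#' bank, averaged only to the scattergram's own time resolution (stride
#' `2^j_sg`, default 8x finer than the scattering output), rows ordered
#' by descending centre frequency -- the wavelet analogue of a
#' mel-spectrogram.
#'
#' @param x [audio_segment()] or numeric vector of configured length.
#' @param fb a [build_filter_banks()] result.
#' @param j_sg log2 of the time stride in padded samples (default
#'   `fb$j_pool - 3`, floored at 0).
#' @return matrix `n_filters x (npad / 2^j_sg)`.
#' @export
scattergram <- function(x, fb, j_sg = max(0L, fb$j_pool - 3L)) {
  v <- if (inherits(x, "scat_audio")) x$samples else as.double(x)
  cfg <- fb$cfg
  if (length(v) != cfg$signal_len)
    stop("signal length ", length(v), " does not match configured N = ", cfg$signal_len)
  npad <- fb$npad
  zh <- stats::fft(c(v, numeric(npad - length(v))))
  ncol_out <- npad / 2^j_sg
  out <- matrix(0, nrow(fb$psi1), ncol_out)
  # smoothing lowpass for decimation to the scattergram stride 2^j_sg
  sg_sigma <- 1 / (16 * 2^j_sg)
  for (i in seq_len(nrow(fb$psi1))) {
    j1 <- min(fb$psi1$j[i], j_sg)
    sl <- psi_slice(npad, npad, fb$psi1$xi[i], fb$psi1$sigma[i], fb$norm1)
    Yf <- sparse_apply_fold(zh[sl$k + 1L] * sl$v, sl$k, npad / 2^j1, 2^j1)
    u1 <- Mod(ifft(Yf))
    if (j1 < j_sg) {
      gs <- phi_slice(length(u1), npad, sg_sigma)
      uh <- stats::fft(u1)
      u1 <- Re(ifft(sparse_apply_fold(uh[gs$k + 1L] * gs$v, gs$k,
                                      ncol_out, 2^(j_sg - j1))))
    }
    out[i, ] <- u1
  }
  out
}

# ---- feature store -----------------------------------------------------

#' Write / read scattering features as plain text
#'
#' Columnar file: one row per path (`order`, `lambda_hz`, `mu_hz`, then
#' the T window values at full double precision) plus a JSON sidecar
#' (`<path>.json`) carrying the full configuration; reload is bit-exact.
#'
#' @param S a `scattering_features` object.
#' @param path output file path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_features <- function(S, path) {
  stopifnot(inherits(S, "scattering_features"))
  m <- rbind(S$order0, S$order1, S$order2)
  df <- cbind(S$path_table,
              as.data.frame(matrix(sprintf("%.17g", m), nrow(m), ncol(m))))
  names(df)[-(1:3)] <- paste0("w", seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(unclass(S$cfg), list(T = S$T, logged = S$logged))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wcols <- grep("^w[0-9]+$", names(df))
  m <- unname(as.matrix(df[, wcols]))
  o <- df$order
  cfg <- do.call(scattering_config,
                 meta[intersect(names(meta), names(formals(scattering_config)))])
  structure(list(order0 = m[o == 0L, , drop = FALSE],
                 order1 = m[o == 1L, , drop = FALSE],
                 order2 = m[o == 2L, , drop = FALSE],
                 path_table = df[, c("order", "lambda_hz", "mu_hz")],
                 T = meta$T, cfg = cfg, logged = meta$logged),
            class = "scattering_features")
}
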