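#' Random train/test split
#'
#' Uniform random partition (the default, matching per-trial random
#' reconfiguration) or stratified-by-class splitting.  Deterministic
#' given `seed`.
#'
#' @param labels vector of class labels (its length defines the dataset
#'   size).
#' @param train_frac fraction in (0, 1) assigned to training.
#' @param seed integer seed.
#' @param stratified preserve class proportions across the two folds.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_frac = 0.5, seed = 1L, stratified = FALSE) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < 2L)) stop("need at least 2 items per class")
  if (stratified) {
    tr <- integer(0)
    with_seed(seed, for (cl in names(tab)) {
      idx <- which(labels == cl)
      tr <- c(tr, sample(idx, round(length(idx) * train_frac)))
    })
    tr <- sort(tr)
  } else {
    tr <- with_seed(seed, sort(sample.int(n, round(n * train_frac))))
  }
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Standardize features on training statistics
#'
#' Per-dimension zero-mean/unit-variance transform fitted on the
#' training rows only and applied to both folds; (near-)constant
#' dimensions get a unit divisor so they map to zeros.
#'
#' @param train,test numeric matrices, examples in rows.
#' @return list with transformed `train`, `test`, and the fitted
#'   `center`/`scale` vectors.
#' @export
standardize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (!all(is.finite(train))) stop("non-finite features")
  ctr <- colMeans(train)
  sc <- apply(train, 2, stats::sd)
  sc[!is.finite(sc) | sc < 1e-12] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, sc, "/")
  te <- if (is.null(test)) NULL else
    sweep(sweep(as.matrix(test), 2, ctr), 2, sc, "/")
  list(train = tr, test = te, center = ctr, scale = sc)
}

#' Confusion matrix and classification metrics
#'
#' Tallies the 2x2 confusion table (rows = true class, columns =
#' predicted class; the positive class is the first level) and derives
#' `accuracy = (TP+TN)/total`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, reported as percentages (full precision
#' retained; round only for display).
#'
#' @param truth,predicted equal-length label vectors over the same 2
#'   classes.
#' @param positive the positive class (default: first factor level of
#'   `truth`).
#' @return a `confusion_metrics` object: `counts` (2x2 integer matrix),
#'   `tp`, `fn`, `fp`, `tn`, `accuracy_pct`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
confusion_and_metrics <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted)) stop("label length mismatch")
  truth <- factor(truth)
  lv <- levels(truth)
  if (length(lv) != 2L) stop("exactly 2 classes required")
  predicted <- factor(predicted, levels = lv)
  if (anyNA(predicted)) stop("predicted labels outside the truth classes")
  if (!is.null(positive)) {
    if (!positive %in% lv) stop("unknown positive class: ", positive)
    lv <- c(positive, setdiff(lv, positive))
    truth <- factor(truth, levels = lv)
    predicted <- factor(predicted, levels = lv)
  }
  counts <- table(true = truth, predicted = predicted)
  tp <- counts[1, 1]; fn <- counts[1, 2]; fp <- counts[2, 1]; tn <- counts[2, 2]
  structure(list(counts = unclass(counts), class_names = lv,
                 tp = tp, fn = fn, fp = fp, tn = tn,
                 accuracy_pct = 100 * (tp + tn) / sum(counts),
                 sensitivity_pct = 100 * tp / (tp + fn),
                 specificity_pct = 100 * tn / (tn + fp)),
            class = "confusion_metrics")
}

#' Metrics from raw confusion counts
#'
#' Convenience for recomputing reference confusion tables from their
#' printed cells.
#'
#' @param tp,fn,fp,tn confusion cell counts.
#' @return list with `accuracy_pct`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
metrics_from_counts <- function(tp, fn, fp, tn) {
  list(accuracy_pct = 100 * (tp + tn) / (tp + fn + fp + tn),
       sensitivity_pct = 100 * tp / (tp + fn),
       specificity_pct = 100 * tn / (tn + fp))
}

#' @export
print.confusion_metrics <- function(x, digits = 2, ...) {
  cat("confusion matrix (rows = true class):\n")
  print(x$counts)
  cat(sprintf("accuracy %.*f%%  sensitivity %.*f%%  specificity %.*f%%\n",
              digits, x$accuracy_pct, digits, x$sensitivity_pct,
              digits, x$specificity_pct))
  invisible(x)
}

#' Transposed (comparison-style) confusion printer
#'
#' Prints the table with rows = predicted class, the layout used by the
#' comparison tables.
#'
#' @param x a `confusion_metrics` object.
#' @export
print_transposed <- function(x) {
  stopifnot(inherits(x, "confusion_metrics"))
  cat("confusion matrix (rows = predicted class):\n")
  print(t(x$counts))
  invisible(x)
}

#' Run the repeated random-split evaluation protocol
#'
#' For each trial: split, fit the fold standardization, train the
#' pipeline's classifier, predict the held-out fold and tally metrics.
#' Features are extracted once per dataset (they do not depend on the
#' split); per-trial seeds derive from the master seed.
#'
#' @param dataset list of labelled [audio_segment()]s, or a
#'   pre-extracted feature object from [extract_features()].
#' @param pipeline one of `"wst+lstm"`, `"wst+svm"`, `"stft_if+lstm"`,
#'   `"scattergram+cnn"`.
#' @param n_trials number of random splits (protocol default 100).
#' @param seed master seed.
#' @param train_frac training fraction (default 0.5).
#' @param stratified stratified splitting (default FALSE).
#' @param ... configuration overrides passed to [extract_features()] /
#'   the pipeline trainer (e.g. `scat_cfg`, `lstm_cfg`, `svm_cfg`,
#'   `cnn_cfg`, `if_cfg`).
#' @return a `protocol_result`: per-trial results, mean and sd accuracy.
#' @export
run_protocol <- function(dataset, pipeline, n_trials = 100, seed = 1L,
                         train_frac = 0.5, stratified = FALSE, ...) {
  feats <- if (inherits(dataset, "scat_features")) dataset
           else extract_features(dataset, pipeline, ...)
  labels <- feats$labels
  seeds <- derive_seeds(seed, n_trials)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sp <- split_dataset(labels, train_frac, seeds[k], stratified)
    pred <- pipeline_fit_predict(feats, sp, seeds[k], ...)
    cm <- confusion_and_metrics(labels[sp$test], pred)
    trials[[k]] <- list(split_seed = seeds[k], confusion = cm,
                        accuracy_pct = cm$accuracy_pct,
                        sensitivity_pct = cm$sensitivity_pct,
                        specificity_pct = cm$specificity_pct)
  }
  acc <- vapply(trials, `[[`, 0, "accuracy_pct")
  structure(list(pipeline = feats$pipeline, n_trials = n_trials,
                 trials = trials, accuracies_pct = acc,
                 mean_accuracy_pct = mean(acc),
                 sd_accuracy_pct = stats::sd(acc), seed = seed),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s: mean accuracy %.2f%% (sd %.2f) over %d trials\n",
              x$pipeline, x$mean_accuracy_pct,
              ifelse(is.na(x$sd_accuracy_pct), 0, x$sd_accuracy_pct), x$n_trials))
  invisible(x)
}

#' Invariance-scale sweep
#'
#' Re-runs the protocol with rebuilt filter banks at each requested
#' invariance scale.
#'
#' @param dataset list of labelled [audio_segment()]s.
#' @param scales_s numeric vector of invariance scales in seconds.
#' @param pipeline a WST pipeline tag (default `"wst+lstm"`).
#' @param n_trials,seed protocol arguments.
#' @param scat_cfg base [scattering_config()] whose scale is swept.
#' @param ... further arguments for [run_protocol()].
#' @return data.frame with `scale_s`, `mean_accuracy_pct`, `n_paths`,
#'   `n_windows`, plus the per-scale results as an attribute.
#' @export
invariance_sweep <- function(dataset, scales_s, pipeline = "wst+lstm",
                             n_trials = 10, seed = 1L,
                             scat_cfg = NULL, ...) {
  first <- dataset[[1]]
  if (is.null(scat_cfg))
    scat_cfg <- scattering_config(signal_len = length(first$samples),
                                  rate = first$rate,
                                  invariance_scale_s = scales_s[1])
  res <- vector("list", length(scales_s))
  out <- data.frame(scale_s = scales_s, mean_accuracy_pct = NA_real_,
                    n_paths = NA_integer_, n_windows = NA_integer_)
  for (i in seq_along(scales_s)) {
    cfg_i <- scattering_config(Q1 = scat_cfg$Q1, Q2 = scat_cfg$Q2,
                               invariance_scale_s = scales_s[i],
                               signal_len = scat_cfg$signal_len,
                               rate = scat_cfg$rate,
                               pair_factor = scat_cfg$pair_factor,
                               alpha = scat_cfg$alpha)
    fbi <- build_filter_banks(cfg_i)
    r <- run_protocol(dataset, pipeline, n_trials = n_trials, seed = seed,
                      scat_cfg = cfg_i, ...)
    res[[i]] <- r
    out$mean_accuracy_pct[i] <- r$mean_accuracy_pct
    out$n_paths[i] <- fbi$n_paths
    out$n_windows[i] <- fbi$n_windows
  }
  attr(out, "results") <- res
  out
}

#' Spectrogram diagnostic view
#'
#' Magnitude spectrogram with a 1600-sample Hann window (250 ms at
#' 6400 Hz) and 75% overlap, the layout used for visual inspection of
#' the recordings; optionally rendered to PNG.
#'
#' @param x an [audio_segment()] with at least `window_len` samples.
#' @param window_len Hann window length in samples.
#' @param overlap fractional overlap in [0, 1).
#' @param png optional output PNG path.
#' @return list with `magnitude` (freq bins x frames), `freq_hz`,
#'   `time_s`.
#' @export
spectrogram_view <- function(x, window_len = 1600, overlap = 0.75, png = NULL) {
  stopifnot(inherits(x, "scat_audio"))
  v <- x$samples
  if (length(v) < window_len) stop("signal shorter than the spectrogram window")
  hop <- round(window_len * (1 - overlap))
  starts <- seq(1L, length(v) - window_len + 1L, by = hop)
  n <- 0:(window_len - 1)
  hann <- 0.5 - 0.5 * cos(2 * pi * n / (window_len - 1))
  frames <- matrix(v[outer(0:(window_len - 1L), starts, "+")], nrow = window_len) * hann
  K <- window_len %/% 2L + 1L
  mag <- Mod(stats::mvfft(frames))[1:K, , drop = FALSE]
  freq <- (0:(K - 1L)) * x$rate / window_len
  time <- (starts - 1L + window_len / 2) / x$rate
  if (!is.null(png)) {
    grDevices::png(png, width = 900, height = 500)
    graphics::image(time, freq, t(log10(mag + 1e-12)),
                    xlab = "time (s)", ylab = "frequency (Hz)",
                    main = if (is.null(x$label)) "" else x$label)
    grDevices::dev.off()
  }
  list(magnitude = mag, freq_hz = freq, time_s = time)
}
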