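PIPELINES <- c("wst+lstm", "wst+svm", "stft_if+lstm", "scattergram+cnn")

#' Extract classifier-facing features for a pipeline
#'
#' Clips that are not already at the configured rate/length are first
#' passed through [preprocess_segment()].  Feature extraction does not
#' depend on the train/test split, so the protocol extracts once per
#' dataset.
#'
#' @param dataset list of labelled [audio_segment()]s.
#' @param pipeline one of `"wst+lstm"`, `"wst+svm"`, `"stft_if+lstm"`,
#'   `"scattergram+cnn"`.
#' @param scat_cfg [scattering_config()] for the WST pipelines (default:
#'   reference parameters at the dataset's rate/length).
#' @param if_cfg [instfreq_config()] for the instantaneous-frequency
#'   pipeline; the pipeline default uses hop 500 to keep the LSTM
#'   sequence length tractable (the unit definition is hop 1).
#' @param flatten_sequence feed the LSTM one long 1D sequence (the
#'   flattened reading) instead of T steps of feature vectors.
#' @param drop_order0 exclude the order-0 planes from WST features.
#' @param ... ignored (protocol plumbing).
#' @return a `scat_features` object.
#' @export
extract_features <- function(dataset, pipeline, scat_cfg = NULL,
                             if_cfg = NULL, flatten_sequence = FALSE,
                             drop_order0 = FALSE, ...) {
  pipeline <- match.arg(pipeline, PIPELINES)
  labels <- factor(dataset_labels(dataset))
  first <- dataset[[1]]
  if (is.null(scat_cfg)) {
    if (first$rate == 6400 || length(first$samples) / first$rate >= 10) {
      scat_cfg <- scattering_config()       # reference configuration
    } else {
      scat_cfg <- scattering_config(signal_len = length(first$samples),
                                    rate = first$rate,
                                    invariance_scale_s =
                                      min(6, length(first$samples) / first$rate / 2))
    }
  }
  prep <- function(x) {
    if (x$rate == scat_cfg$rate && length(x$samples) == scat_cfg$signal_len) x
    else preprocess_segment(x, preprocess_config(target_rate = scat_cfg$rate,
                                                 block_len = scat_cfg$signal_len))
  }
  dataset <- lapply(dataset, prep)

  if (pipeline %in% c("wst+lstm", "wst+svm")) {
    fb <- build_filter_banks(scat_cfg)
    mats <- lapply(dataset, wst_features, fb = fb, drop_order0 = drop_order0)
    data <- if (pipeline == "wst+svm") {
      assemble_feature_set(mats, "flat")            # (paths' * T) x M
    } else if (flatten_sequence) {
      fl <- assemble_feature_set(mats, "flat")
      array(fl, c(1L, nrow(fl), ncol(fl)))          # one long scalar sequence
    } else {
      assemble_feature_set(mats, "sequence")        # paths' x T x M
    }
  } else if (pipeline == "stft_if+lstm") {
    if (is.null(if_cfg)) if_cfg <- instfreq_config(hop = 500)
    seqs <- lapply(dataset, function(x) instantaneous_frequency(x, if_cfg)$freq_hz)
    L <- length(seqs[[1]])
    data <- array(unlist(seqs), c(1L, L, length(seqs)))
  } else {                                          # scattergram+cnn
    fb <- build_filter_banks(scat_cfg)
    sgs <- lapply(dataset, scattergram, fb = fb)
    d <- dim(sgs[[1]])
    data <- array(unlist(sgs), c(d[1], d[2], length(sgs)))
  }
  structure(list(pipeline = pipeline, labels = labels, data = data),
            class = "scat_features")
}

# standardize an array D x T x M (or matrix D x M) on the training fold
standardize_fold <- function(data, sp) {
  d <- dim(data)
  flat <- if (length(d) == 3L) t(matrix(data, d[1] * d[2], d[3])) else t(data)
  st <- standardize_features(flat[sp$train, , drop = FALSE],
                             flat[sp$test, , drop = FALSE])
  list(train = st$train, test = st$test, dim = d)
}

reshape_seq <- function(flat, d) {
  # flat: M x (D*T) rows back to D x T x M
  array(t(flat), c(d[1], d[2], nrow(flat)))
}

# one protocol trial: standardize on the fold, train, predict the test fold
pipeline_fit_predict <- function(feats, sp, seed,
                                 lstm_cfg = NULL, svm_cfg = NULL,
                                 cnn_cfg = NULL, ...) {
  sf <- standardize_fold(feats$data, sp)
  tr_lab <- feats$labels[sp$train]
  if (feats$pipeline == "wst+svm") {
    cfg <- if (is.null(svm_cfg)) svm_config() else svm_cfg
    model <- train_svm(sf$train, tr_lab, cfg)
    return(predict(model, sf$test)$labels)
  }
  if (feats$pipeline == "scattergram+cnn") {
    cfg <- if (is.null(cnn_cfg)) cnn_config() else cnn_cfg
    cfg$seed <- seed
    model <- train_cnn(reshape_seq(sf$train, sf$dim), tr_lab, cfg)
    return(predict(model, reshape_seq(sf$test, sf$dim))$labels)
  }
  cfg <- if (!is.null(lstm_cfg)) lstm_cfg
         else if (feats$pipeline == "stft_if+lstm")
           lstm_config(hidden_units = 100, learning_rate = 0.01, epochs = 10)
         else lstm_config()
  cfg$seed <- seed
  model <- train_lstm(reshape_seq(sf$train, sf$dim), tr_lab, cfg)
  predict(model, reshape_seq(sf$test, sf$dim))$labels
}
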