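#' LSTM training configuration
#'
#' Defaults follow the reference protocol for scattering-sequence
#' classification: 512 hidden units in a single LSTM layer, Adam with
#' learning rate 1e-4, minibatch 128, a single epoch.  The comparison
#' protocol for instantaneous-frequency sequences uses
#' `lstm_config(hidden_units = 100, learning_rate = 0.01, epochs = 10)`.
#'
#' @param hidden_units LSTM state size.
#' @param learning_rate Adam step size.
#' @param minibatch minibatch size (a smaller final batch is kept).
#' @param epochs full passes over the training set.
#' @param seed integer seed fixing initialization and shuffling.
#' @param sigmoid `"standard"` for the logistic `1/(1+exp(-x))`;
#'   `"shifted"` reproduces the printed variant `1/(1+exp(1-x))`
#'   (available for comparison, not recommended).
#' @param readout `"sum"` applies the class readout to every hidden
#'   state and sums the per-step losses (`L = sum_t L_t`); `"final"`
#'   reads out the last hidden state only.
#' @param init `"glorot_orthogonal"` uses Glorot-uniform input weights
#'   and orthogonal recurrent weights (the reference toolbox's
#'   defaults); `"uniform"` uses plain `U(-1/sqrt(H), 1/sqrt(H))`.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer
#'   (library defaults, pinned).
#' @return an `lstm_config` object.
#' @export
lstm_config <- function(hidden_units = 512, learning_rate = 1e-4,
                        minibatch = 128, epochs = 1, seed = 1L,
                        sigmoid = c("standard", "shifted"),
                        readout = c("sum", "final"),
                        init = c("glorot_orthogonal", "uniform"),
                        beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(hidden_units >= 1, learning_rate > 0, minibatch >= 1, epochs >= 0)
  structure(list(hidden_units = hidden_units, learning_rate = learning_rate,
                 minibatch = minibatch, epochs = epochs, seed = seed,
                 sigmoid = match.arg(sigmoid), readout = match.arg(readout),
                 init = match.arg(init),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "lstm_config")
}

sigmoid_fn <- function(x, kind = "standard") {
  if (kind == "standard") 1 / (1 + exp(-x)) else 1 / (1 + exp(1 - x))
}

# weights: Wx (4H x D), Wh (4H x H), b (4H) with gate blocks stacked in
# the order input, forget, output, candidate; forget bias 1; readout
# Wout (C x H) zero initialized (see vignette: makes the single-epoch
# Adam regime act as a trained linear probe), bout zero.
lstm_init <- function(D, H, C, seed, init = "glorot_orthogonal") {
  with_seed(seed, {
    if (init == "glorot_orthogonal") {
      s <- sqrt(6 / (D + 4 * H))
      Wx <- matrix(stats::runif(4 * H * D, -s, s), 4 * H, D)
      Wh <- do.call(rbind, lapply(1:4, function(k)
        qr.Q(qr(matrix(stats::rnorm(H * H), H, H)))))
    } else {
      s <- 1 / sqrt(H)
      Wx <- matrix(stats::runif(4 * H * D, -s, s), 4 * H, D)
      Wh <- matrix(stats::runif(4 * H * H, -s, s), 4 * H, H)
    }
    list(Wx = Wx, Wh = Wh,
         b = c(rep(0, H), rep(1, H), rep(0, 2 * H)),
         Wout = matrix(0, C, H), bout = rep(0, C))
  })
}

#' LSTM forward pass
#'
#' Runs the gate recursions over one sequence (or a batch) and maps the
#' final hidden state through the linear readout and softmax.  Gate
#' activations, candidate, cell and hidden states are returned per step
#' so that the recursions (input/forget/output gates, cell update
#' `c_t = f_t*c_{t-1} + i_t*d_t`, output `h_t = o_t*tanh(c_t)`) can be
#' inspected and asserted directly.
#'
#' @param x_seq numeric `D x T` matrix (one sequence) or `D x T x B`
#'   array (a batch).
#' @param weights list with `Wx`, `Wh`, `b`, `Wout`, `bout` (see
#'   [train_lstm()]; `b` stacks the input/forget/output/candidate gate
#'   biases).
#' @param sigmoid activation variant, see [lstm_config()].
#' @return list with per-step `i`, `f`, `o`, `d`, `c`, `h` (lists of
#'   `H x B` matrices), the final hidden state, `scores` (softmax class
#'   probabilities, `C x B`) and `logits`.
#' @export
lstm_forward <- function(x_seq, weights, sigmoid = "standard") {
  if (is.matrix(x_seq)) dim(x_seq) <- c(nrow(x_seq), ncol(x_seq), 1L)
  D <- dim(x_seq)[1]; T <- dim(x_seq)[2]; B <- dim(x_seq)[3]
  H <- ncol(weights$Wh)
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  gi <- gf <- go <- gd <- cs <- hs <- vector("list", T)
  idx <- function(k) ((k - 1) * H + 1):(k * H)
  for (t in seq_len(T)) {
    xt <- matrix(x_seq[, t, ], D, B)
    A <- weights$Wx %*% xt + weights$Wh %*% h + weights$b
    i_t <- sigmoid_fn(A[idx(1), , drop = FALSE], sigmoid)
    f_t <- sigmoid_fn(A[idx(2), , drop = FALSE], sigmoid)
    o_t <- sigmoid_fn(A[idx(3), , drop = FALSE], sigmoid)
    d_t <- tanh(A[idx(4), , drop = FALSE])
    cc <- f_t * cc + i_t * d_t
    h <- o_t * tanh(cc)
    gi[[t]] <- i_t; gf[[t]] <- f_t; go[[t]] <- o_t; gd[[t]] <- d_t
    cs[[t]] <- cc; hs[[t]] <- h
  }
  logits <- weights$Wout %*% h + weights$bout
  scores <- softmax_cols(logits)
  list(i = gi, f = gf, o = go, d = gd, c = cs, h = hs,
       final_h = h, logits = logits, scores = scores)
}

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2, apply(z, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# cross-entropy loss (mean over batch) and analytic BPTT gradients;
# Y is the C x B one-hot matrix.  readout "sum" applies the readout to
# every step and sums the per-step losses (L = sum_t L_t); "final" reads
# the last hidden state only.
lstm_loss_grad <- function(weights, x_seq, Y, sigmoid = "standard",
                           readout = "final") {
  if (is.matrix(x_seq)) dim(x_seq) <- c(nrow(x_seq), ncol(x_seq), 1L)
  fwd <- lstm_forward(x_seq, weights, sigmoid)
  D <- dim(x_seq)[1]; T <- dim(x_seq)[2]; B <- dim(x_seq)[3]
  H <- ncol(weights$Wh)

  step_dlogits <- vector("list", T)
  if (readout == "final") {
    loss <- -mean(colSums(Y * log(pmax(fwd$scores, 1e-300))))
    step_dlogits[[T]] <- (fwd$scores - Y) / B
  } else {
    loss <- 0
    for (t in seq_len(T)) {
      sc <- softmax_cols(weights$Wout %*% fwd$h[[t]] + weights$bout)
      loss <- loss - mean(colSums(Y * log(pmax(sc, 1e-300))))
      step_dlogits[[t]] <- (sc - Y) / B
    }
  }

  g <- list(Wx = matrix(0, 4 * H, D), Wh = matrix(0, 4 * H, H),
            b = numeric(4 * H),
            Wout = matrix(0, nrow(weights$Wout), H),
            bout = numeric(nrow(weights$Wout)))
  dh <- matrix(0, H, B)
  dc <- matrix(0, H, B)
  for (t in rev(seq_len(T))) {
    if (!is.null(step_dlogits[[t]])) {
      g$Wout <- g$Wout + step_dlogits[[t]] %*% t(fwd$h[[t]])
      g$bout <- g$bout + rowSums(step_dlogits[[t]])
      dh <- dh + t(weights$Wout) %*% step_dlogits[[t]]
    }
    i_t <- fwd$i[[t]]; f_t <- fwd$f[[t]]; o_t <- fwd$o[[t]]; d_t <- fwd$d[[t]]
    c_t <- fwd$c[[t]]
    c_prev <- if (t > 1) fwd$c[[t - 1]] else matrix(0, H, B)
    h_prev <- if (t > 1) fwd$h[[t - 1]] else matrix(0, H, B)
    tc <- tanh(c_t)
    do_ <- dh * tc
    dc <- dc + dh * o_t * (1 - tc^2)
    di <- dc * d_t
    df <- dc * c_prev
    dd <- dc * i_t
    # pre-activation gradients (logistic/tanh derivative; the shifted
    # sigmoid variant has the same derivative shape s(1-s))
    dAi <- di * i_t * (1 - i_t)
    dAf <- df * f_t * (1 - f_t)
    dAo <- do_ * o_t * (1 - o_t)
    dAd <- dd * (1 - d_t^2)
    dA <- rbind(dAi, dAf, dAo, dAd)
    xt <- matrix(x_seq[, t, ], D, B)
    g$Wx <- g$Wx + dA %*% t(xt)
    g$Wh <- g$Wh + dA %*% t(h_prev)
    g$b <- g$b + rowSums(dA)
    dh <- t(weights$Wh) %*% dA
    dc <- dc * f_t
  }
  list(loss = loss, grad = g, scores = fwd$scores)
}

adam_new <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(weights = weights, state = state)
}

#' Train the LSTM classifier
#'
#' Backpropagation through time with Adam updates, deterministic given
#' `cfg$seed` (initialization and shuffle streams are derived from it).
#' `epochs = 0` returns the initialized, untrained model.
#'
#' @param features `D x T x M` array (per-step feature vectors over T
#'   time steps) as produced by
#'   `assemble_feature_set(..., layout = "sequence")`.
#' @param labels factor (or coercible) of length M with >= 2 levels
#'   present.
#' @param cfg an [lstm_config()].
#' @return a `scat_lstm` model (weights, config, class levels, per-batch
#'   loss log).
#' @export
train_lstm <- function(features, labels, cfg = lstm_config()) {
  stopifnot(inherits(cfg, "lstm_config"))
  if (is.matrix(features)) dim(features) <- c(nrow(features), ncol(features), 1L)
  if (!all(is.finite(features))) stop("non-finite features")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes present")
  M <- dim(features)[3]
  stopifnot(M == length(labels))
  D <- dim(features)[1]; C <- nlevels(labels)
  seeds <- derive_seeds(cfg$seed, 1L + cfg$epochs)
  w <- lstm_init(D, cfg$hidden_units, C, seeds[1], cfg$init)
  st <- adam_new(w)
  Y_all <- stats::model.matrix(~ labels - 1)  # M x C one-hot
  loss_log <- numeric(0)
  if (cfg$epochs > 0) for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(seeds[1L + ep], sample.int(M))
    for (start in seq(1L, M, by = cfg$minibatch)) {
      bi <- ord[start:min(M, start + cfg$minibatch - 1L)]
      lg <- lstm_loss_grad(w, features[, , bi, drop = FALSE],
                           t(Y_all[bi, , drop = FALSE]), cfg$sigmoid,
                           cfg$readout)
      upd <- adam_step(w, lg$grad, st, cfg$learning_rate,
                       cfg$beta1, cfg$beta2, cfg$adam_eps)
      w <- upd$weights; st <- upd$state
      loss_log <- c(loss_log, lg$loss)
    }
  }
  structure(list(weights = w, cfg = cfg, levels = levels(labels),
                 loss_log = loss_log), class = "scat_lstm")
}

#' Predict classes with a trained LSTM
#'
#' @param object a `scat_lstm` model.
#' @param features `D x T x M` array in the training layout.
#' @param ... unused.
#' @return list with `labels` (factor) and `scores` (`M x C`, rows sum
#'   to 1; ties resolve to the earlier class level).
#' @export
predict.scat_lstm <- function(object, features, ...) {
  if (is.matrix(features)) dim(features) <- c(nrow(features), ncol(features), 1L)
  if (dim(features)[1] != ncol(object$weights$Wx))
    stop("feature layout does not match the trained model")
  fwd <- lstm_forward(features, object$weights, object$cfg$sigmoid)
  sc <- if (identical(object$cfg$readout, "final")) t(fwd$scores) else {
    acc <- 0
    for (t in seq_along(fwd$h))
      acc <- acc + softmax_cols(object$weights$Wout %*% fwd$h[[t]] +
                                  object$weights$bout)
    t(acc / length(fwd$h))
  }
  colnames(sc) <- object$levels
  lab <- factor(object$levels[max.col(sc, ties.method = "first")],
                levels = object$levels)
  list(labels = lab, scores = sc)
}
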