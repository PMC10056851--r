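#' Scattergram CNN configuration
#'
#' Three convolution blocks (1D convolution of kernel length 3 along
#' time, batch normalization, ReLU, max pooling of size 2 and stride 2
#' along time) with 8, 16 and 32 filters, a fully connected layer with
#' one neuron per class and a softmax, trained by stochastic gradient
#' descent.
#'
#' @param filters filter counts for the three blocks (strictly
#'   increasing as printed).
#' @param kernel 1D kernel length.
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum (standard default, pinned).
#' @param minibatch minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @return a `cnn_config` object.
#' @export
cnn_config <- function(filters = c(8, 16, 32), kernel = 3,
                       learning_rate = 1e-4, momentum = 0.9,
                       minibatch = 128, epochs = 1, seed = 1L) {
  stopifnot(length(filters) == 3, all(diff(filters) > 0), kernel >= 1,
            learning_rate > 0, epochs >= 0)
  structure(list(filters = filters, kernel = kernel,
                 learning_rate = learning_rate, momentum = momentum,
                 minibatch = minibatch, epochs = epochs, seed = seed),
            class = "cnn_config")
}

# same-padded 1D convolution along the time axis; x is C_in x L x B,
# W is C_out x C_in x K, returns C_out x L x B
conv1d_forward <- function(x, W, bias) {
  d <- dim(x); Cin <- d[1]; L <- d[2]; B <- d[3]
  K <- dim(W)[3]; Cout <- dim(W)[1]
  pad <- (K - 1L) %/% 2L
  xp <- array(0, c(Cin, L + K - 1L, B))
  xp[, pad + seq_len(L), ] <- x
  y <- matrix(0, Cout, L * B)
  for (k in seq_len(K)) {
    xs <- matrix(xp[, (k):(k + L - 1L), , drop = FALSE], Cin, L * B)
    y <- y + matrix(W[, , k], Cout, Cin) %*% xs
  }
  array(y + bias, c(Cout, L, B))
}

conv1d_backward <- function(x, W, dy) {
  d <- dim(x); Cin <- d[1]; L <- d[2]; B <- d[3]
  K <- dim(W)[3]; Cout <- dim(W)[1]
  pad <- (K - 1L) %/% 2L
  xp <- array(0, c(Cin, L + K - 1L, B))
  xp[, pad + seq_len(L), ] <- x
  dyf <- matrix(dy, Cout, L * B)
  dW <- array(0, dim(W)); dxp <- array(0, dim(xp))
  for (k in seq_len(K)) {
    xs <- matrix(xp[, (k):(k + L - 1L), , drop = FALSE], Cin, L * B)
    dW[, , k] <- dyf %*% t(xs)
    dxs <- t(matrix(W[, , k], Cout, Cin)) %*% dyf
    dxp[, (k):(k + L - 1L), ] <- dxp[, (k):(k + L - 1L), ] + array(dxs, c(Cin, L, B))
  }
  list(dW = dW, db = rowSums(dyf),
       dx = dxp[, pad + seq_len(L), , drop = FALSE])
}

bn_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  mu <- rowMeans(xm)
  va <- rowMeans((xm - mu)^2)
  xh <- (xm - mu) / sqrt(va + eps)
  list(y = array(gamma * xh + beta, d), xh = xh, mu = mu, va = va, eps = eps)
}

bn_backward <- function(cache, gamma, dy) {
  d <- dim(dy); n <- prod(d[-1])
  dym <- matrix(dy, d[1])
  dgamma <- rowSums(dym * cache$xh)
  dbeta <- rowSums(dym)
  dxh <- gamma * dym
  iv <- 1 / sqrt(cache$va + cache$eps)
  dx <- iv * (dxh - rowMeans(dxh) - cache$xh * rowMeans(dxh * cache$xh))
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

pool2_forward <- function(x) {
  d <- dim(x); L2 <- d[2] %/% 2L
  a <- x[, 2 * seq_len(L2) - 1L, , drop = FALSE]
  b <- x[, 2 * seq_len(L2), , drop = FALSE]
  list(y = pmax(a, b), take_first = a >= b, L2 = L2)
}

pool2_backward <- function(cache, x_dim, dy) {
  dx <- array(0, x_dim)
  L2 <- cache$L2
  dx[, 2 * seq_len(L2) - 1L, ] <- dy * cache$take_first
  dx[, 2 * seq_len(L2), ] <- dy * !cache$take_first
  dx
}

cnn_init <- function(Cin, L, filters, K, C, seed) {
  with_seed(seed, {
    p <- list()
    chans <- c(Cin, filters)
    for (bkt in 1:3) {
      fanin <- chans[bkt] * K
      p[[paste0("W", bkt)]] <- array(stats::rnorm(filters[bkt] * chans[bkt] * K,
                                                  sd = sqrt(2 / fanin)),
                                     c(filters[bkt], chans[bkt], K))
      p[[paste0("cb", bkt)]] <- rep(0, filters[bkt])
      p[[paste0("g", bkt)]] <- rep(1, filters[bkt])
      p[[paste0("be", bkt)]] <- rep(0, filters[bkt])
      L <- L %/% 2L
    }
    p$Wfc <- matrix(0, C, filters[3] * L)
    p$bfc <- rep(0, C)
    p
  })
}

cnn_forward_backward <- function(p, x, Y = NULL) {
  caches <- list(); a <- x
  for (bkt in 1:3) {
    W <- p[[paste0("W", bkt)]]
    z <- conv1d_forward(a, W, p[[paste0("cb", bkt)]])
    bn <- bn_forward(z, p[[paste0("g", bkt)]], p[[paste0("be", bkt)]])
    r <- pmax(bn$y, 0)
    pl <- pool2_forward(r)
    caches[[bkt]] <- list(a = a, z = z, bn = bn, r = r, pl = pl)
    a <- pl$y
  }
  d <- dim(a); B <- d[3]
  flat <- matrix(a, d[1] * d[2], B)
  logits <- p$Wfc %*% flat + p$bfc
  scores <- softmax_cols(logits)
  if (is.null(Y)) return(list(scores = scores))
  loss <- -mean(colSums(Y * log(pmax(scores, 1e-300))))

  g <- list()
  dlog <- (scores - Y) / B
  g$Wfc <- dlog %*% t(flat); g$bfc <- rowSums(dlog)
  da <- array(t(p$Wfc) %*% dlog, d)
  for (bkt in 3:1) {
    ch <- caches[[bkt]]
    dr <- pool2_backward(ch$pl, dim(ch$r), da)
    dbn_y <- dr * (ch$bn$y > 0)
    bb <- bn_backward(ch$bn, p[[paste0("g", bkt)]], dbn_y)
    cv <- conv1d_backward(ch$a, p[[paste0("W", bkt)]], bb$dx)
    g[[paste0("g", bkt)]] <- bb$dgamma
    g[[paste0("be", bkt)]] <- bb$dbeta
    g[[paste0("W", bkt)]] <- cv$dW
    g[[paste0("cb", bkt)]] <- cv$db
    da <- cv$dx
  }
  list(loss = loss, grad = g, scores = scores)
}

#' Train the scattergram CNN
#'
#' Deterministic given `cfg$seed`.  Scattergram inputs must share one
#' fixed size; each of the three blocks halves the time axis (floor
#' division), so after three pools the time axis shrinks by 8x.
#'
#' @param scattergrams list of `n_paths x L` matrices (see
#'   [scattergram()]), or a `C_in x L x M` array.
#' @param labels factor of length M.
#' @param cfg a [cnn_config()].
#' @return a `scat_cnn` model.
#' @export
train_cnn <- function(scattergrams, labels, cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (is.list(scattergrams)) {
    d <- dim(scattergrams[[1]])
    for (s in scattergrams) if (!identical(dim(s), d))
      stop("variable-size scattergram inputs")
    x <- array(unlist(scattergrams), c(d[1], d[2], length(scattergrams)))
  } else x <- scattergrams
  labels <- factor(labels)
  M <- dim(x)[3]
  stopifnot(M == length(labels), nlevels(labels) >= 2)
  C <- nlevels(labels)
  seeds <- derive_seeds(cfg$seed, 1L + cfg$epochs)
  p <- cnn_init(dim(x)[1], dim(x)[2], cfg$filters, cfg$kernel, C, seeds[1])
  vel <- lapply(p, function(w) w * 0)
  Y_all <- stats::model.matrix(~ labels - 1)
  loss_log <- numeric(0)
  if (cfg$epochs > 0) for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(seeds[1L + ep], sample.int(M))
    for (start in seq(1L, M, by = cfg$minibatch)) {
      bi <- ord[start:min(M, start + cfg$minibatch - 1L)]
      fb <- cnn_forward_backward(p, x[, , bi, drop = FALSE],
                                 t(Y_all[bi, , drop = FALSE]))
      for (nm in names(fb$grad)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * fb$grad[[nm]]
        p[[nm]] <- p[[nm]] + vel[[nm]]
      }
      loss_log <- c(loss_log, fb$loss)
    }
  }
  structure(list(params = p, cfg = cfg, levels = levels(labels),
                 input_dim = dim(x)[1:2], loss_log = loss_log),
            class = "scat_cnn")
}

#' Predict with the scattergram CNN
#'
#' @param object a `scat_cnn` model.
#' @param scattergrams list of matrices or `C_in x L x M` array matching
#'   the training size.
#' @param ... unused.
#' @return list with `labels` and `scores` (`M x C`).
#' @export
predict.scat_cnn <- function(object, scattergrams, ...) {
  if (is.list(scattergrams)) {
    d <- dim(scattergrams[[1]])
    x <- array(unlist(scattergrams), c(d[1], d[2], length(scattergrams)))
  } else x <- scattergrams
  if (!identical(dim(x)[1:2], object$input_dim))
    stop("scattergram size does not match the trained network")
  sc <- t(cnn_forward_backward(object$params, x)$scores)
  colnames(sc) <- object$levels
  lab <- factor(object$levels[max.col(sc, ties.method = "first")],
                levels = object$levels)
  list(labels = lab, scores = sc)
}
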