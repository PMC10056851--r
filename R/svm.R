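#' Least-squares SVM configuration
#'
#' Radial-basis-function least-squares SVM with the reference
#' hyperparameters `C = 10`, `gamma = 0.05`
#' (`K(u, v) = exp(-gamma * ||u - v||^2)`).
#'
#' @param C regularization parameter (> 0).
#' @param gamma RBF kernel scale (> 0).
#' @return an `svm_config` object.
#' @export
svm_config <- function(C = 10, gamma = 0.05) {
  stopifnot(C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma, kernel = "rbf", variant = "least_squares"),
            class = "svm_config")
}

rbf_kernel <- function(A, B, gamma) {
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b, rows are examples
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Train a least-squares SVM (binary)
#'
#' Solves the LS-SVM linear system
#' `[[0, 1'], [1, K + I/C]] [b; alpha] = [0; y]` with `y` in `{-1, +1}`
#' (first factor level mapped to +1).  The decision value is
#' `f(x) = sum_i alpha_i K(x_i, x) + b`; its sign gives the class, with
#' the boundary value 0 resolving to the positive (+1, first-level)
#' class.  The deterministic direct solve makes the decision function
#' invariant to permutations of the training examples.
#'
#' @param features `M x D` numeric matrix (standardize first, see
#'   [standardize_features()]).
#' @param labels factor with exactly 2 levels present.
#' @param cfg an [svm_config()].
#' @return a `scat_lssvm` model.
#' @export
train_svm <- function(features, labels, cfg = svm_config()) {
  stopifnot(inherits(cfg, "svm_config"))
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("least-squares SVM is binary; got ", nlevels(labels), " classes")
  y <- ifelse(labels == levels(labels)[1], 1, -1)
  M <- nrow(features)
  K <- rbf_kernel(features, features, cfg$gamma)
  A <- rbind(c(0, rep(1, M)), cbind(1, K + diag(M) / cfg$C))
  sol <- solve(A, c(0, y))
  structure(list(b = unname(sol[1]), alpha = unname(sol[-1]), X = features,
                 cfg = cfg, levels = levels(labels)), class = "scat_lssvm")
}

#' Predict with a least-squares SVM
#'
#' @param object a `scat_lssvm` model.
#' @param features `M x D` matrix in the training feature space.
#' @param ... unused.
#' @return list with `labels`, `decision` (raw decision values).
#' @export
predict.scat_lssvm <- function(object, features, ...) {
  features <- as.matrix(features)
  K <- rbf_kernel(features, object$X, object$cfg$gamma)
  f <- drop(K %*% object$alpha) + object$b
  lab <- factor(ifelse(f >= 0, object$levels[1], object$levels[2]),
                levels = object$levels)
  list(labels = lab, decision = f)
}
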