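#' Linear one-vs-rest maximum-margin baseline classifier
#'
#' Reference classifier for the perceptron: one linear soft-margin
#' (L2-regularized hinge loss) binary machine per class, combined
#' one-vs-rest by taking the class with the largest decision score. No
#' SVM library is assumed: each binary machine is trained by
#' deterministic full-batch projected subgradient descent on
#' `lambda/2 |w|^2 + mean(hinge)` with the classic `1/(lambda t)` step,
#' which is entirely adequate at cohort scale. A dual-class subject is a
#' positive example for both of its classes.
#'
#' @param x Numeric matrix or data frame of training rows.
#' @param class_sets List (one element per row) of class-index vectors.
#' @param k Number of classes.
#' @param lambda Regularization strength (default `1 / nrow(x)`, i.e.
#'   C = 1).
#' @param n_iter Subgradient iterations per binary machine (default 2000).
#' @return Object of class `ovr_svm_fit` with `weights` (k x f) and
#'   `bias` (k).
#' @export
ovr_svm_train <- function(x, class_sets, k, lambda = NULL, n_iter = 2000L) {
  X <- as.matrix(x)
  S <- nrow(X)
  if (length(class_sets) != S) abort("one class set per training row is required.")
  lambda <- lambda %||% (1 / S)
  W <- matrix(0, k, ncol(X))
  b <- numeric(k)
  for (cls in seq_len(k)) {
    y <- ifelse(vapply(class_sets, function(s) cls %in% s, logical(1)), 1, -1)
    w <- numeric(ncol(X))
    w0 <- 0
    for (t in seq_len(n_iter)) {
      margins <- y * (X %*% w + w0)
      viol <- as.vector(margins) < 1
      gw <- lambda * w - colSums(X[viol, , drop = FALSE] * y[viol]) / S
      g0 <- -sum(y[viol]) / S
      eta <- 1 / (lambda * t)
      w <- w - eta * gw
      w0 <- w0 - eta * g0
    }
    W[cls, ] <- w
    b[cls] <- w0
  }
  structure(list(weights = W, bias = b, k = k, lambda = lambda), class = "ovr_svm_fit")
}

#' Decision scores of the one-vs-rest linear baseline
#'
#' @param object An `ovr_svm_fit`.
#' @param newdata Feature rows.
#' @param ... Unused.
#' @return Matrix of decision scores, one row per case, one column per
#'   class (argmax gives the predicted class).
#' @export
predict.ovr_svm_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  t(object$weights %*% t(X) + object$bias)
}
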