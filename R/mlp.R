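#' Four-layer perceptron architecture
#'
#' The classifier has layer sizes (f, h, k, k): f selected connectivity
#' features in, h hidden sigmoid neurons, k sigmoid neurons (one per
#' diagnostic class), and a parameter-free softmax output layer turning
#' the k activations into class probabilities.
#'
#' @param f Input features.
#' @param h Hidden neurons.
#' @param k Classes.
#' @return Object of class `mlp_architecture`.
#' @examples
#' mlp_architecture(18, 7, 5)
#' @export
mlp_architecture <- function(f, h, k) {
  f <- as.integer(f); h <- as.integer(h); k <- as.integer(k)
  if (anyNA(c(f, h, k)) || f < 1 || h < 1 || k < 1) {
    abort("`f`, `h`, `k` must be positive integers.")
  }
  structure(list(f = f, h = h, k = k), class = "mlp_architecture")
}

#' @export
print.mlp_architecture <- function(x, ...) {
  cat(sprintf(
    "<mlp_architecture> layers (%d, %d, %d, %d), %d parameters\n",
    x$f, x$h, x$k, x$k, parameter_count(x)
  ))
  invisible(x)
}

#' Number of free parameters of the perceptron
#'
#' `w = h (f + k + 1) + k`: h x f hidden weights, h hidden thresholds,
#' k x h third-layer weights, k third-layer thresholds. The softmax layer
#' contributes none.
#'
#' @param arch An [mlp_architecture()].
#' @return Integer parameter count.
#' @examples
#' parameter_count(mlp_architecture(18, 7, 5))  # 173
#' @export
parameter_count <- function(arch) {
  stopifnot(inherits(arch, "mlp_architecture"))
  arch$h * (arch$f + arch$k + 1L) + arch$k
}

#' Parameter-parsimony constraint check
#'
#' Each training case pins the parameters with only k - 1 independent
#' nonlinear equations (the k outputs sum to 1), so S cases supply
#' (k - 1) S constraints. Overfitting is avoided by demanding
#' `h (f + k + 1) <= (k - 1) S - k`; at k = 5 and S = 45 (leave-one-out
#' on 46 subjects) the bound is 175, met by the (18, 7, 5, 5) network
#' with lhs 7 * (18 + 6) = 168.
#'
#' @param arch An [mlp_architecture()].
#' @param S Training-set size.
#' @return One-row tibble with `lhs`, `bound`, `pass`.
#' @examples
#' parsimony_check(mlp_architecture(18, 7, 5), S = 45)
#' @export
parsimony_check <- function(arch, S) {
  stopifnot(inherits(arch, "mlp_architecture"))
  S <- as.integer(S)
  if (is.na(S) || S < 1) abort("`S` must be a positive integer.")
  lhs <- arch$h * (arch$f + arch$k + 1L)
  bound <- (arch$k - 1L) * S - arch$k
  tibble::tibble(lhs = lhs, bound = bound, pass = lhs <= bound)
}

unpack_params <- function(params, arch) {
  w <- parameter_count(arch)
  if (length(params) != w) {
    abort(sprintf("parameter vector has length %d, expected %d.", length(params), w))
  }
  f <- arch$f; h <- arch$h; k <- arch$k
  i <- 0L
  W1 <- matrix(params[i + seq_len(h * f)], h, f); i <- i + h * f
  b1 <- params[i + seq_len(h)]; i <- i + h
  W2 <- matrix(params[i + seq_len(k * h)], k, h); i <- i + k * h
  b2 <- params[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

pack_params <- function(W1, b1, W2, b2) c(as.vector(W1), b1, as.vector(W2), b2)

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass on a batch: X is f x S. Returns activations for backprop.
forward_batch <- function(params, arch, X) {
  pp <- unpack_params(params, arch)
  A1 <- sigmoid(pp$W1 %*% X - pp$b1)        # h x S
  A2 <- sigmoid(pp$W2 %*% A1 - pp$b2)       # k x S
  E <- exp(A2)                              # softmax over the k sigmoid activations
  P <- sweep(E, 2, colSums(E), "/")
  list(A1 = A1, A2 = A2, P = P, pp = pp)
}

#' Forward pass of the perceptron on one feature vector
#'
#' Hidden and third layers apply `sigmoid(weights . x - threshold)`; the
#' output layer applies the (parameter-free) softmax to the k third-layer
#' activations.
#'
#' @param params Flat parameter vector of length [parameter_count()].
#' @param arch An [mlp_architecture()].
#' @param u Feature vector of length `arch$f`.
#' @return Probability vector of length `arch$k` summing to 1.
#' @examples
#' a <- mlp_architecture(3, 2, 5)
#' mlp_forward(rep(0, parameter_count(a)), a, c(1, 2, 3))  # all 0.2
#' @export
mlp_forward <- function(params, arch, u) {
  if (length(u) != arch$f) {
    abort(sprintf("input has length %d, expected f = %d.", length(u), arch$f))
  }
  as.vector(forward_batch(params, arch, matrix(u, ncol = 1))$P)
}

#' Encode diagnostic classes as training targets
#'
#' One-hot for an unambiguous subject; an ambiguously diagnosed subject
#' with two candidate classes gets 1/2 at each. Targets always sum to 1.
#'
#' @param classes Integer class indices (1 or 2 of them) in `1..k`.
#' @param k Number of classes.
#' @return Numeric target vector of length `k`.
#' @examples
#' encode_targets(3, 5)
#' encode_targets(c(1, 4), 5)
#' @export
encode_targets <- function(classes, k) {
  classes <- unique(as.integer(classes))
  if (length(classes) < 1 || length(classes) > 2) {
    abort("a subject must carry 1 or 2 classes.")
  }
  if (anyNA(classes) || any(classes < 1 | classes > k)) {
    abort("class indices must lie in 1..k.")
  }
  v <- numeric(k)
  v[classes] <- 1 / length(classes)
  v
}

# Mean cross-entropy -(1/S) sum_n sum_j v_j(n) log p_n(j). V, P are k x S.
cross_entropy <- function(P, V) -mean(colSums(V * log(P)))

# Analytic gradient of the mean cross-entropy wrt the flat parameters.
# X: f x S, V: k x S.
mlp_gradient <- function(params, arch, X, V) {
  S <- ncol(X)
  fw <- forward_batch(params, arch, X)
  # d loss / d A2 = (P - V) through the softmax (targets sum to 1),
  # then through the layer-3 sigmoid
  D2 <- (fw$P - V) * fw$A2 * (1 - fw$A2) / S       # k x S
  gW2 <- D2 %*% t(fw$A1)
  gb2 <- -rowSums(D2)
  D1 <- (t(fw$pp$W2) %*% D2) * fw$A1 * (1 - fw$A1) # h x S
  gW1 <- D1 %*% t(X)
  gb1 <- -rowSums(D1)
  list(grad = pack_params(gW1, gb1, gW2, gb2), loss = cross_entropy(fw$P, V))
}

#' Train the perceptron by full-batch gradient descent on cross-entropy
#'
#' Minimizes the mean cross-entropy between targets and softmax outputs by
#' plain full-batch gradient descent with a constant learning rate.
#' Parameters are initialized uniformly on \[-0.5, 0.5\] from the given
#' seed; training stops after `n_epochs` or when the loss improves by
#' less than `tol`. The parsimony constraint is checked against the
#' training-set size and a warning (not an error) is raised when it fails.
#'
#' @param x Numeric matrix or data frame of training inputs, one row per
#'   case, `arch$f` columns.
#' @param targets Numeric matrix of targets, one row per case, `arch$k`
#'   columns, rows summing to 1 (see [encode_targets()]).
#' @param arch An [mlp_architecture()].
#' @param learning_rate Constant step size (default 0.1).
#' @param n_epochs Maximum full-batch epochs (default 5000).
#' @param tol Early-stopping threshold on the loss decrease (default 1e-9).
#' @param seed Seed for the parameter initialization.
#' @return Object of class `mlp_fit`: list with `params`, `arch`,
#'   `loss_trace`, `epochs`, `converged`, and the hyperparameters.
#' @export
mlp_train <- function(x, targets, arch, learning_rate = 0.1, n_epochs = 5000L,
                      tol = 1e-9, seed = 1L) {
  X <- t(as.matrix(x))
  V <- t(as.matrix(targets))
  if (nrow(X) != arch$f) abort(sprintf("inputs have %d columns, expected f = %d.", nrow(X), arch$f))
  if (nrow(V) != arch$k) abort(sprintf("targets have %d columns, expected k = %d.", nrow(V), arch$k))
  if (ncol(X) != ncol(V)) abort("inputs and targets disagree on the number of cases.")
  if (any(abs(colSums(V) - 1) > 1e-8)) abort("each target row must sum to 1.")
  pc <- parsimony_check(arch, ncol(X))
  if (!pc$pass) {
    warn(sprintf(
      "parsimony constraint violated: h(f + k + 1) = %d > %d = (k - 1)S - k.",
      pc$lhs, pc$bound
    ))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  params <- runif(parameter_count(arch), -0.5, 0.5)
  loss_trace <- numeric(n_epochs)
  prev <- Inf
  converged <- FALSE
  epochs <- 0L
  for (e in seq_len(n_epochs)) {
    g <- mlp_gradient(params, arch, X, V)
    if (!is.finite(g$loss)) {
      abort(sprintf("training diverged: non-finite loss at epoch %d.", e))
    }
    params <- params - learning_rate * g$grad
    loss_trace[e] <- g$loss
    epochs <- e
    if (abs(prev - g$loss) < tol) {
      converged <- TRUE
      break
    }
    prev <- g$loss
  }
  structure(
    list(
      params = params, arch = arch, loss_trace = loss_trace[seq_len(epochs)],
      epochs = epochs, converged = converged,
      learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
      tol = tol, seed = as.integer(seed)
    ),
    class = "mlp_fit"
  )
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf(
    "<mlp_fit> layers (%d, %d, %d, %d), %d parameters; %d epochs, final loss %.6f%s\n",
    x$arch$f, x$arch$h, x$arch$k, x$arch$k, parameter_count(x$arch),
    x$epochs, x$loss_trace[x$epochs], if (x$converged) " (converged)" else ""
  ))
  invisible(x)
}

#' Predict class probabilities from a fitted perceptron
#'
#' @param object An `mlp_fit`.
#' @param newdata Matrix or data frame of feature rows (`arch$f` columns).
#' @param ... Unused.
#' @return Tibble of class probabilities, one row per case, columns
#'   `p1..pk`.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  X <- t(as.matrix(newdata))
  P <- t(forward_batch(object$params, object$arch, X)$P)
  colnames(P) <- paste0("p", seq_len(object$arch$k))
  tibble::as_tibble(P)
}

#' @export
tidy.mlp_fit <- function(x, ...) {
  pp <- unpack_params(x$params, x$arch)
  dplyr::bind_rows(
    tibble::tibble(
      layer = "hidden", type = "weight",
      to = rep(seq_len(x$arch$h), x$arch$f), from = rep(seq_len(x$arch$f), each = x$arch$h),
      value = as.vector(pp$W1)
    ),
    tibble::tibble(layer = "hidden", type = "threshold", to = seq_len(x$arch$h), from = NA_integer_, value = pp$b1),
    tibble::tibble(
      layer = "class", type = "weight",
      to = rep(seq_len(x$arch$k), x$arch$h), from = rep(seq_len(x$arch$h), each = x$arch$k),
      value = as.vector(pp$W2)
    ),
    tibble::tibble(layer = "class", type = "threshold", to = seq_len(x$arch$k), from = NA_integer_, value = pp$b2)
  )
}

#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(
    f = x$arch$f, h = x$arch$h, k = x$arch$k,
    n_params = parameter_count(x$arch),
    epochs = x$epochs, converged = x$converged,
    final_loss = x$loss_trace[x$epochs]
  )
}

#' @export
autoplot.mlp_fit <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_len(object$epochs), loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}
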