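# loss computed through the exported forward pass only (independent of
# the gradient code under test)
loss_via_forward <- function(params, arch, X, V) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    p <- mlp_forward(params, arch, X[i, ])
    tot <- tot - sum(V[i, ] * log(p))
  }
  tot / nrow(X)
}

test_that("parameter calculus and parsimony constraint match the printed arithmetic", {
  expect_identical(parameter_count(mlp_architecture(18, 7, 5)), 173L)
  expect_identical(parameter_count(mlp_architecture(1, 1, 1)), 4L)
  # strictly increasing in h at fixed (f, k)
  counts <- vapply(1:10, function(h) parameter_count(mlp_architecture(18, h, 5)), integer(1))
  expect_true(all(diff(counts) > 0))

  pc <- parsimony_check(mlp_architecture(18, 7, 5), S = 45)
  expect_identical(pc$lhs, 168L)
  expect_identical(pc$bound, 175L)
  expect_true(pc$pass)
  pc2 <- parsimony_check(mlp_architecture(100, 7, 5), S = 45)
  expect_identical(pc2$lhs, 742L)
  expect_false(pc2$pass)
  expect_error(mlp_architecture(0, 1, 1), "positive")
})

test_that("forward pass: symmetry at zero parameters, normalization, pencil-and-paper toy", {
  a5 <- mlp_architecture(3, 4, 5)
  p0 <- rep(0, parameter_count(a5))
  expect_equal(mlp_forward(p0, a5, c(1, -2, 0.5)), rep(0.2, 5))
  set.seed(31)
  for (i in 1:10) {
    params <- runif(parameter_count(a5), -1, 1)
    pr <- mlp_forward(params, a5, rnorm(3))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0 & pr < 1))
  }
  # 2-2-2-2 network worked by hand: sigmoid(Wx - b) twice, then softmax
  arch <- mlp_architecture(2, 2, 2)
  W1 <- matrix(c(1, -1, 0.5, 0.25), 2, 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(0.3, 0.7, -0.4, 0.2), 2, 2)
  b2 <- c(0, 0.5)
  u <- c(0.6, -1.2)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(c(
    1 * 0.6 + 0.5 * (-1.2) - 0.1,
    -1 * 0.6 + 0.25 * (-1.2) - (-0.2)
  ))
  a3 <- sig(c(
    0.3 * h[1] + (-0.4) * h[2] - 0,
    0.7 * h[1] + 0.2 * h[2] - 0.5
  ))
  manual <- exp(a3) / sum(exp(a3))
  got <- mlp_forward(c(as.vector(W1), b1, as.vector(W2), b2), arch, u)
  expect_equal(got, manual, tolerance = 1e-12)
  expect_error(mlp_forward(p0, a5, c(1, 2)), "length")
})

test_that("target encoding: one-hot, half/half for ambiguous, always sums to 1", {
  expect_identical(encode_targets(3, 5), c(0, 0, 1, 0, 0))
  expect_identical(encode_targets(c(1, 4), 5), c(0.5, 0, 0, 0.5, 0))
  for (i in 1:10) {
    cls <- sample(1:5, sample(1:2, 1))
    expect_equal(sum(encode_targets(cls, 5)), 1)
  }
  expect_error(encode_targets(integer(0), 5), "1 or 2")
  expect_error(encode_targets(c(1, 2, 3), 5), "1 or 2")
  expect_error(encode_targets(6, 5), "1..k")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(32)
  arch <- mlp_architecture(4, 3, 3)
  w <- parameter_count(arch)
  X <- matrix(rnorm(6 * 4), 6, 4)
  V <- t(vapply(1:6, function(i) encode_targets(sample(1:3, sample(1:2, 1)), 3), numeric(3)))
  eps <- 1e-6
  for (point in 1:50) {
    params <- runif(w, -1, 1)
    g <- epifocal:::mlp_gradient(params, arch, t(X), t(V))
    idx <- sample(w, 5)  # spot-check 5 coordinates per point
    for (j in idx) {
      up <- params; up[j] <- up[j] + eps
      dn <- params; dn[j] <- dn[j] - eps
      num <- (loss_via_forward(up, arch, X, V) - loss_via_forward(dn, arch, X, V)) / (2 * eps)
      # denominator floored where central-difference cancellation noise
      # (~ .Machine eps / 2 eps ~ 5e-11 absolute) limits the oracle
      denom <- max(abs(num) + abs(g$grad[j]), 1e-5)
      expect_lt(abs(num - g$grad[j]) / denom, 1e-5)
    }
    expect_equal(g$loss, loss_via_forward(params, arch, X, V), tolerance = 1e-10)
  }
})

test_that("training descends, reproduces bit-for-bit, and solves a separable toy", {
  set.seed(33)
  x <- matrix(c(rnorm(10, -2, 0.3), rnorm(10, 2, 0.3)), ncol = 1)
  targets <- rbind(
    matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE)
  )
  arch <- mlp_architecture(1, 2, 2)
  fit <- mlp_train(x, targets, arch, learning_rate = 0.5, n_epochs = 3000, seed = 5)
  expect_length(fit$params, parameter_count(arch))
  # descent property at a sane learning rate
  expect_true(all(diff(fit$loss_trace) <= 1e-12))
  # separable toy is classified perfectly
  pred <- as.matrix(predict(fit, x))
  expect_identical(apply(pred, 1, which.max), c(rep(1L, 10), rep(2L, 10)))
  # bit-reproducibility for a fixed seed
  fit2 <- mlp_train(x, targets, arch, learning_rate = 0.5, n_epochs = 3000, seed = 5)
  expect_identical(fit$params, fit2$params)
  # a different seed gives a different start
  fit3 <- mlp_train(x, targets, arch, learning_rate = 0.5, n_epochs = 5, seed = 6)
  expect_false(identical(fit$params[1], fit3$params[1]))
  # parsimony violation warns but trains
  expect_warning(
    mlp_train(x, targets, mlp_architecture(1, 50, 2), n_epochs = 2, seed = 1),
    "parsimony"
  )
})

test_that("label permutation symmetry of the loss", {
  set.seed(34)
  arch <- mlp_architecture(3, 2, 4)
  params <- runif(parameter_count(arch), -1, 1)
  X <- matrix(rnorm(5 * 3), 5, 3)
  V <- t(vapply(1:5, function(i) encode_targets(sample(1:4, 1), 4), numeric(4)))
  perm <- c(3, 1, 4, 2)
  pp <- epifocal:::unpack_params(params, arch)
  params_perm <- epifocal:::pack_params(pp$W1, pp$b1, pp$W2[perm, ], pp$b2[perm])
  expect_equal(
    loss_via_forward(params, arch, X, V),
    loss_via_forward(params_perm, arch, X, V[, perm]),
    tolerance = 1e-12
  )
})

test_that("a lone ambiguous case is driven to half/half output mass", {
  arch <- mlp_architecture(1, 2, 2)
  fit <- suppressWarnings(mlp_train(  # S = 1 cannot satisfy parsimony
    matrix(0.7), matrix(c(0.5, 0.5), 1), arch,
    learning_rate = 0.5, n_epochs = 4000, seed = 7
  ))
  p <- as.numeric(predict(fit, matrix(0.7)))
  expect_equal(p, c(0.5, 0.5), tolerance = 0.05)
})

test_that("tidy and glance expose the parameter partition and fit summary", {
  set.seed(35)
  arch <- mlp_architecture(2, 3, 2)
  fit <- suppressWarnings(mlp_train(matrix(rnorm(8), 4, 2),
    t(vapply(1:4, function(i) encode_targets(sample(1:2, 1), 2), numeric(2))),
    arch,
    n_epochs = 50, seed = 1
  ))
  td <- tidy(fit)
  expect_identical(nrow(td), parameter_count(arch))
  expect_identical(sum(td$type == "threshold"), arch$h + arch$k)
  gl <- glance(fit)
  expect_identical(gl$n_params, parameter_count(arch))
  expect_true(gl$final_loss >= 0)
})
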