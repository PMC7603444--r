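#' Equal-frequency (quantile) discretization of a time series
#'
#' Transforms a continuous series into a categorical one with `n_bins`
#' near-equal-frequency categories. Binning is rank-based: a point's rank
#' (ties resolved by original index order) determines its bin, so the
#' discretization — and every mutual-information value downstream — is
#' exactly invariant under any strictly increasing transform of the series.
#' When `length(series)` is not divisible by `n_bins`, the first
#' `n %% n_bins` bins receive one extra point.
#'
#' @param series Numeric vector, finite values, length at least `n_bins`.
#' @param n_bins Number of equal-frequency bins (default 5, i.e. bin edges
#'   at the 0, 20, 40, 60, 80, 100% quantiles).
#'
#' @return An object of class `discretized_series`: a list with
#'   `labels` (integer bin index per time point), `midpoints` (per-bin
#'   median of member values), `bin_edges` (the `n_bins + 1` quantiles),
#'   and `n_bins`.
#'
#' @examples
#' d <- quantile_discretize(sin(1:295))
#' table(d$labels)
#' @export
quantile_discretize <- function(series, n_bins = 5L) {
  if (!is.numeric(series) || length(series) == 0) {
    abort("`series` must be a non-empty numeric vector.")
  }
  if (anyNA(series) || any(!is.finite(series))) {
    abort("`series` must not contain missing or non-finite values.")
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) abort("`n_bins` must be a positive integer.")
  n <- length(series)
  if (n < n_bins) {
    abort(sprintf("`series` has %d points but %d bins were requested.", n, n_bins))
  }
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  r <- rank(series, ties.method = "first")
  labels <- rep.int(seq_len(n_bins), sizes)[r]
  midpoints <- as.numeric(tapply(series, factor(labels, levels = seq_len(n_bins)), median))
  structure(
    list(
      labels = as.integer(labels),
      midpoints = midpoints,
      bin_edges = unname(quantile(series, probs = seq(0, 1, length.out = n_bins + 1L), type = 7)),
      n_bins = n_bins
    ),
    class = "discretized_series"
  )
}

#' Joint histogram of two discrete label vectors
#'
#' Tabulates two equally long label vectors into a contingency table of
#' counts with marginal and joint relative frequencies.
#'
#' @param x_labels,y_labels Integer label vectors of equal length.
#' @return A list with `counts` (matrix), `p` and `q` (marginal relative
#'   frequencies of rows and columns) and `r` (joint relative frequencies).
#' @export
joint_histogram <- function(x_labels, y_labels) {
  if (length(x_labels) != length(y_labels)) {
    abort("`x_labels` and `y_labels` must have the same length.")
  }
  if (length(x_labels) == 0) abort("label vectors must be non-empty.")
  counts <- unclass(table(x_labels, y_labels))
  n <- length(x_labels)
  r <- counts / n
  list(counts = counts, p = rowSums(r), q = colSums(r), r = r)
}

#' Plug-in (empirical) entropy of a label vector, in nats
#'
#' `H = -sum p_k log(p_k)` over the observed categories, with natural
#' logarithm. Empty categories contribute zero (`0 log 0 := 0`).
#'
#' @param labels Non-empty vector of category labels.
#' @return Entropy in nats, between 0 and `log(number of categories)`.
#' @examples
#' entropy(rep(1:5, each = 59))  # log(5)
#' @export
entropy <- function(labels) {
  if (length(labels) == 0) abort("`labels` must be non-empty.")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Plug-in mutual information between two label vectors, in nats
#'
#' `MI(X, Y) = H(X) + H(Y) - H(X, Y)` from the empirical joint histogram.
#' Symmetric, non-negative, and zero when the empirical joint distribution
#' factorizes.
#'
#' @param x_labels,y_labels Label vectors of equal length.
#' @return Mutual information in nats.
#' @examples
#' mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0
#' mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2))  # log(2)
#' @export
mutual_information <- function(x_labels, y_labels) {
  if (length(x_labels) != length(y_labels)) {
    abort("`x_labels` and `y_labels` must have the same length.")
  }
  h <- joint_histogram(x_labels, y_labels)
  r <- h$r[h$r > 0]
  hxy <- -sum(r * log(r))
  px <- h$p[h$p > 0]
  qy <- h$q[h$q > 0]
  mi <- -sum(px * log(px)) - sum(qy * log(qy)) - hxy
  max(mi, 0)
}

#' Closed-form Gaussian mutual information from a correlation
#'
#' For a bivariate Gaussian pair with correlation `rho`,
#' `MI = -0.5 log(1 - rho^2)` nats. Used as an analytic reference for the
#' discretized estimator; not valid off the Gaussian case.
#'
#' @param correlation Correlation in (-1, 1); vectorized.
#' @return Mutual information in nats.
#' @examples
#' gaussian_mi_closed_form(0.9)
#' @export
gaussian_mi_closed_form <- function(correlation) {
  if (!is.numeric(correlation) || any(!is.finite(correlation))) {
    abort("`correlation` must be finite numeric.")
  }
  if (any(abs(correlation) >= 1)) {
    abort("`correlation` must lie strictly inside (-1, 1).")
  }
  -0.5 * log(1 - correlation^2)
}
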