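#' Coerce a per-subject time-series table to a parcels-by-time matrix
#'
#' Accepts either a data frame whose first column holds parcel identifiers
#' (remaining columns numeric time points, the on-disk layout) or a numeric
#' matrix with parcel identifiers as row names.
#'
#' @param ts Data frame or matrix of parcel time series.
#' @return Numeric matrix with unique parcel identifiers as row names.
#' @export
as_time_series_matrix <- function(ts) {
  if (is.data.frame(ts)) {
    ids <- as.character(ts[[1]])
    m <- as.matrix(ts[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else if (is.matrix(ts)) {
    m <- ts
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  } else {
    abort("`ts` must be a data frame or a numeric matrix.")
  }
  if (anyDuplicated(rownames(m))) {
    dup <- rownames(m)[duplicated(rownames(m))][1]
    abort(sprintf("duplicated parcel identifier: '%s'.", dup))
  }
  if (anyNA(m) || any(!is.finite(m))) abort("time series contain missing or non-finite values.")
  m
}

#' Pairwise mutual-information matrix over parcels
#'
#' Discretizes every parcel time series into `n_bins` equal-frequency bins
#' and computes the plug-in mutual information (nats) for every parcel pair.
#' The diagonal holds each parcel's own entropy `H(Y_i)` — flagged in the
#' `"diagonal"` attribute — and is excluded from region-level aggregation.
#'
#' @param ts Parcel time series (see [as_time_series_matrix()]).
#' @param n_bins Equal-frequency bins per series (default 5).
#' @return A symmetric numeric matrix of class `parcel_mi` with parcel
#'   identifiers as dimnames and attributes `n_bins` and
#'   `diagonal = "entropy"`.
#' @examples
#' ts <- matrix(rnorm(3 * 60), nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
#' pairwise_mi_matrix(ts)
#' @export
pairwise_mi_matrix <- function(ts, n_bins = 5L) {
  m <- as_time_series_matrix(ts)
  n_bins <- as.integer(n_bins)
  np <- nrow(m)
  n <- ncol(m)
  labels <- matrix(0L, np, n)
  for (i in seq_len(np)) labels[i, ] <- quantile_discretize(m[i, ], n_bins)$labels
  # one-hot indicators: joint counts for a pair are a 5x295 x 295x5 product
  ind <- lapply(seq_len(np), function(i) {
    b <- matrix(0, n_bins, n)
    b[cbind(labels[i, ], seq_len(n))] <- 1
    b
  })
  hh <- vapply(seq_len(np), function(i) entropy(labels[i, ]), numeric(1))
  mi <- matrix(0, np, np, dimnames = list(rownames(m), rownames(m)))
  diag(mi) <- hh
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      bi <- ind[[i]]
      for (j in seq.int(i + 1L, np)) {
        r <- tcrossprod(bi, ind[[j]]) / n
        r <- r[r > 0]
        v <- hh[i] + hh[j] + sum(r * log(r))
        mi[i, j] <- mi[j, i] <- max(v, 0)
      }
    }
  }
  structure(mi, n_bins = n_bins, diagonal = "entropy", class = c("parcel_mi", "matrix", "array"))
}

#' @export
print.parcel_mi <- function(x, ...) {
  cat(sprintf(
    "<parcel_mi> %d x %d mutual-information matrix (nats), %d bins, diagonal = %s\n",
    nrow(x), ncol(x), attr(x, "n_bins"), attr(x, "diagonal")
  ))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  invisible(x)
}

#' Tidy a mutual-information matrix into a long tibble
#'
#' @param x A `parcel_mi` or `region_mi` matrix.
#' @param upper_only Keep only pairs `a <= b` (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with columns `a`, `b`, `mi`.
#' @export
tidy.parcel_mi <- function(x, upper_only = TRUE, ...) {
  ids <- rownames(x)
  out <- tibble::tibble(
    a = rep(ids, times = length(ids)),
    b = rep(ids, each = length(ids)),
    mi = as.vector(unclass(x))
  )
  if (upper_only) {
    ia <- match(out$a, ids)
    ib <- match(out$b, ids)
    out <- out[ia <= ib, ]
  }
  out
}
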