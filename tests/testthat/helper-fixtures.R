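# Independent oracles and small fixture builders shared across the suite.

# Plug-in MI as the direct double sum  sum_km r_km log(r_km / (p_k q_m)),
# written against base::table only — independent of the package's
# H(X) + H(Y) - H(X,Y) route.
oracle_mi_double_sum <- function(x, y) {
  r <- unclass(table(x, y)) / length(x)
  p <- rowSums(r)
  q <- colSums(r)
  s <- 0
  for (k in seq_along(p)) {
    for (m in seq_along(q)) {
      if (r[k, m] > 0) s <- s + r[k, m] * log(r[k, m] / (p[k] * q[m]))
    }
  }
  unname(s)
}

# Rank binning by explicit sorting, independent of the package's
# rep/rank construction.
oracle_rank_bins <- function(series, n_bins) {
  n <- length(series)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ord <- order(series)  # stable: ties keep original index order
  lab <- integer(n)
  lab[ord] <- rep(seq_len(n_bins), times = sizes)
  lab
}

# Quantile of an explicit list by sort-and-interpolate at fractional
# index 1 + (n - 1) q.
oracle_quantile <- function(values, q) {
  v <- sort(values)
  idx <- 1 + (length(v) - 1) * q
  lo <- floor(idx)
  hi <- ceiling(idx)
  v[lo] + (idx - lo) * (v[hi] - v[lo])
}

# A tiny deterministic multi-subject fixture: feature table + membership
# with `k` classes of `per_class` subjects where feature `Fj` separates
# class j from all others by a large gap, everything else pure noise.
separable_cohort <- function(k = 3, per_class = 4, n_noise = 3, gap = 10, seed = 42) {
  set.seed(seed)
  n <- k * per_class
  classes <- sprintf("C%d", rep(seq_len(k), each = per_class))
  tab <- tibble::tibble(subject_id = sprintf("s%02d", seq_len(n)))
  for (j in seq_len(k)) {
    tab[[sprintf("R%03d_R%03d", j, j + k)]] <-
      ifelse(classes == sprintf("C%d", j), gap, 0) + rnorm(n, sd = 0.1)
  }
  for (j in seq_len(n_noise)) {
    tab[[sprintf("R%03d_R%03d", 2 * k + j, 3 * k + j)]] <- rnorm(n)
  }
  membership <- tibble::tibble(subject_id = tab$subject_id, classes = as.list(classes))
  list(table = tab, membership = membership, classes = classes)
}

# Small synthetic cohort used where the full default (45 subjects,
# T = 295) would be too slow; geometry and model identical, scale reduced.
small_cohort <- function(seed = 1, subjects_per_class = 3, n_timepoints = 120, ...) {
  generate_cohort(cohort_config(
    subjects_per_class = subjects_per_class,
    n_timepoints = n_timepoints, seed = seed, ...
  ))
}
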