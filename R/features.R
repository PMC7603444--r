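#' German-tank interval estimate of a uniform support
#'
#' Approximates the support of a feature's within-class distribution by a
#' uniform interval: takes the observed min m and max M of the s values
#' and extends the interval outward by `e = (M - m) / (s - 1)` on each
#' side (minimum-variance-unbiased endpoint correction for a uniform
#' sample).
#'
#' @param values Numeric vector of at least 2 values.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' german_tank_interval(1:5)  # c(0, 6)
#' @export
german_tank_interval <- function(values) {
  s <- length(values)
  if (s < 2) abort("German-tank interval needs at least 2 values.")
  if (anyNA(values)) abort("`values` must not contain NA.")
  m <- min(values)
  M <- max(values)
  e <- (M - m) / (s - 1)
  c(lower = m - e, upper = M + e)
}

#' Separability of two intervals
#'
#' With `I = J` intersect `J2`, the separability is
#' `min(|J - I| / |J|, |J2 - I| / |J2|)`: 1 when the intervals are
#' disjoint, 0 when one contains the other, in between the smaller of the
#' two uncovered-length fractions. Degenerate (zero-length) intervals get
#' the limit convention: 1 if the two sets are disjoint, else 0.
#'
#' @param j,j2 Intervals as length-2 numeric vectors `(lower, upper)`.
#' @return Separability in `[0, 1]`.
#' @examples
#' separability(c(0, 2), c(1, 3))  # 0.5
#' @export
separability <- function(j, j2) {
  if (length(j) != 2 || length(j2) != 2 || j[1] > j[2] || j2[1] > j2[2]) {
    abort("intervals must be numeric `(lower, upper)` with lower <= upper.")
  }
  len1 <- j[2] - j[1]
  len2 <- j2[2] - j2[1]
  ilen <- max(0, min(j[2], j2[2]) - max(j[1], j2[1]))
  if (len1 == 0 || len2 == 0) {
    disjoint <- j[1] > j2[2] || j2[1] > j[2]
    return(if (disjoint) 1 else 0)
  }
  unname(min((len1 - ilen) / len1, (len2 - ilen) / len2))
}

#' Discriminating power of a feature between two classes
#'
#' The separability of the two classes' German-tank interval estimates:
#' close to 1 when the within-class value ranges are nearly disjoint, 0
#' when one range swallows the other. Symmetric in the two classes and
#' invariant under a common increasing affine rescaling of the feature.
#'
#' @param values_p,values_q Feature values of the two classes (length >= 2
#'   each; a dual-class subject contributes to both lists).
#' @return Power in `[0, 1]`.
#' @examples
#' discriminating_power(c(0, 1), c(10, 11))  # 1
#' @export
discriminating_power <- function(values_p, values_q) {
  separability(german_tank_interval(values_p), german_tank_interval(values_q))
}

#' Enumerate region-pair features
#'
#' @param region_ids Character vector of region identifiers (in matrix
#'   order).
#' @param mode `"all"` (m <= n), `"inter"` (m < n) or `"intra"` (m = n).
#' @return Tibble with columns `region_a`, `region_b`, `feature` (the
#'   column name `<a>_<b>`).
#' @examples
#' nrow(feature_pairs(sprintf("R%03d", 1:148)))  # 11026
#' @export
feature_pairs <- function(region_ids, mode = c("all", "inter", "intra")) {
  mode <- match.arg(mode)
  ids <- as.character(region_ids)
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  out <- tibble::tibble(
    region_a = ids[idx[, "row"]],
    region_b = ids[idx[, "col"]]
  )
  out <- dplyr::arrange(out, match(region_a, ids), match(region_b, ids))
  if (mode == "inter") out <- out[out$region_a != out$region_b, ]
  if (mode == "intra") out <- out[out$region_a == out$region_b, ]
  out$feature <- paste0(out$region_a, "_", out$region_b)
  out
}

#' Assemble the per-subject feature table from region-level MI matrices
#'
#' One row per subject, one column per region-pair connectivity
#' coefficient `MIreg(m, n)` (inter mode m < n, intra mode m = n, all
#' mode m <= n).
#'
#' @param region_mats Named list (by subject identifier) of `region_mi`
#'   matrices sharing the same region set.
#' @param mode Feature pool, as in [feature_pairs()].
#' @return Tibble `subject_id` + feature columns, carrying the feature
#'   metadata in attribute `"features"`.
#' @export
feature_table <- function(region_mats, mode = c("all", "inter", "intra")) {
  mode <- match.arg(mode)
  if (is.null(names(region_mats)) || anyDuplicated(names(region_mats))) {
    abort("`region_mats` must be a list uniquely named by subject.")
  }
  ids <- rownames(region_mats[[1]])
  fp <- feature_pairs(ids, mode)
  rows <- purrr::map(region_mats, function(m) {
    if (!identical(rownames(m), ids)) abort("all region matrices must share one region set.")
    unclass(m)[cbind(fp$region_a, fp$region_b)]
  })
  tab <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(tab) <- fp$feature
  out <- dplyr::bind_cols(tibble::tibble(subject_id = names(region_mats)), tab)
  attr(out, "features") <- fp
  out
}

feature_metadata <- function(table) {
  fp <- attr(table, "features")
  cols <- setdiff(names(table), "subject_id")
  if (!is.null(fp) && all(cols %in% fp$feature)) {
    return(fp[match(cols, fp$feature), ])
  }
  # fall back to parsing `<a>_<b>` column names
  parts <- strsplit(cols, "_", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) abort(sprintf("cannot parse feature name '%s'.", cols[bad][1]))
  out <- tibble::tibble(
    region_a = vapply(parts, `[[`, "", 1),
    region_b = vapply(parts, `[[`, "", 2),
    feature = cols
  )
  dplyr::arrange(out, .data$region_a, .data$region_b)
}
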