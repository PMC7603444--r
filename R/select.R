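#' Validate class membership of a cohort
#'
#' Each subject belongs to 1 or 2 of the k diagnostic classes (a few
#' subjects are ambiguously diagnosed and belong to 2 classes
#' simultaneously); every class must have at least 2 members, counting
#' dual-class subjects in both of their classes.
#'
#' @param membership Data frame with columns `subject_id` and `classes`
#'   (either a list-column of character vectors or a character column with
#'   classes separated by `";"`).
#' @return Tibble of class `class_membership` with a list-column
#'   `classes`.
#' @export
class_membership <- function(membership) {
  if (!is.data.frame(membership) || !all(c("subject_id", "classes") %in% names(membership))) {
    abort("`membership` needs columns subject_id and classes.")
  }
  cl <- membership$classes
  if (!is.list(cl)) cl <- strsplit(as.character(cl), ";", fixed = TRUE)
  cl <- lapply(cl, function(x) unique(as.character(x)))
  sizes <- lengths(cl)
  if (any(sizes < 1 | sizes > 2)) {
    abort("every subject must carry 1 or 2 classes.")
  }
  out <- tibble::tibble(subject_id = as.character(membership$subject_id), classes = cl)
  if (anyDuplicated(out$subject_id)) abort("duplicated subject_id in membership.")
  counts <- table(unlist(out$classes))
  if (any(counts < 2)) {
    abort(sprintf("class '%s' has fewer than 2 members.", names(counts)[counts < 2][1]))
  }
  class(out) <- c("class_membership", class(out))
  out
}

class_ids <- function(membership) sort(unique(unlist(membership$classes)))

#' Enumerate the basic two-class discrimination tasks
#'
#' k classes yield `choose(k, 2)` unordered pairs "discriminate CL(p) vs
#' CL(q)" (10 tasks for the 5-lobe diagnosis problem).
#'
#' @param classes Character vector of class identifiers.
#' @return Tibble with columns `class_p`, `class_q` (p before q in the
#'   sorted class order).
#' @export
class_tasks <- function(classes) {
  classes <- sort(unique(as.character(classes)))
  if (length(classes) < 2) abort("need at least 2 classes.")
  pq <- combn(classes, 2)
  tibble::tibble(class_p = pq[1, ], class_q = pq[2, ])
}

# Per-task discriminating power of every feature column, vectorized over
# columns via per-class min/max.
task_powers <- function(values, in_p, in_q) {
  sp <- sum(in_p)
  sq <- sum(in_q)
  mp <- apply(values[in_p, , drop = FALSE], 2, min)
  Mp <- apply(values[in_p, , drop = FALSE], 2, max)
  mq <- apply(values[in_q, , drop = FALSE], 2, min)
  Mq <- apply(values[in_q, , drop = FALSE], 2, max)
  ep <- (Mp - mp) / (sp - 1)
  eq <- (Mq - mq) / (sq - 1)
  lo_p <- mp - ep; up_p <- Mp + ep
  lo_q <- mq - eq; up_q <- Mq + eq
  len_p <- up_p - lo_p
  len_q <- up_q - lo_q
  ilen <- pmax(0, pmin(up_p, up_q) - pmax(lo_p, lo_q))
  pow <- pmin((len_p - ilen) / len_p, (len_q - ilen) / len_q)
  deg <- len_p == 0 | len_q == 0
  if (any(deg)) {
    disjoint <- lo_p > up_q | lo_q > up_p
    pow[deg] <- ifelse(disjoint[deg], 1, 0)
  }
  pow
}

#' Select the most discriminating connectivity features
#'
#' For every unordered class pair (p, q), ranks all candidate region-pair
#' features by their discriminating power (interval separability of the
#' two classes' German-tank intervals) and keeps the top `per_task`
#' (default 2; 5 classes then give 10 tasks and 20 selections). The pooled
#' selections are deduplicated (a feature picked by several tasks counts
#' once) and, if more than `max_features` distinct features survive, the
#' roster is trimmed to `max_features` by descending maximum power —
#' enforcing the MLP parameter-parsimony budget. All ties break
#' lexicographically by region pair for determinism. Dual-class subjects
#' contribute their value to both classes' lists.
#'
#' `select_intra_features()` is the same procedure restricted to the
#' diagonal (intra-region) coefficients `MIreg(m, m)`.
#'
#' @param table Feature table ([feature_table()]): `subject_id` +
#'   numeric feature columns.
#' @param membership [class_membership()] covering every subject.
#' @param per_task Features kept per discrimination task (default 2).
#' @param max_features Size of the final input roster (default 18).
#' @return Object of class `selected_features`: list with `selections`
#'   (one row per task x rank: task, feature, power), `candidates` (the
#'   deduplicated features with their maximum power), and `selected`
#'   (the trimmed roster, at most `max_features` rows).
#' @export
select_features <- function(table, membership, per_task = 2L, max_features = 18L) {
  membership <- class_membership(membership)
  fmeta <- feature_metadata(table)
  miss <- setdiff(table$subject_id, membership$subject_id)
  if (length(miss)) abort(sprintf("subject '%s' has no class label.", miss[1]))
  values <- as.matrix(table[fmeta$feature])
  if (anyNA(values)) abort("feature table contains missing values.")
  subj_classes <- membership$classes[match(table$subject_id, membership$subject_id)]
  tasks <- class_tasks(class_ids(membership))
  # fmeta rows are in (m, n) lexicographic order: row index is the tie-break
  f_idx <- seq_len(nrow(fmeta))

  sel <- purrr::pmap(tasks, function(class_p, class_q) {
    in_p <- vapply(subj_classes, function(cl) class_p %in% cl, logical(1))
    in_q <- vapply(subj_classes, function(cl) class_q %in% cl, logical(1))
    if (sum(in_p) < 2 || sum(in_q) < 2) {
      abort(sprintf("task %s vs %s has a class with fewer than 2 subjects.", class_p, class_q))
    }
    pow <- task_powers(values, in_p, in_q)
    ord <- order(-pow, f_idx)
    keep <- ord[seq_len(min(per_task, length(ord)))]
    tibble::tibble(
      class_p = class_p, class_q = class_q,
      region_a = fmeta$region_a[keep], region_b = fmeta$region_b[keep],
      feature = fmeta$feature[keep], power = unname(pow[keep]),
      rank_in_task = seq_along(keep)
    )
  })
  selections <- dplyr::bind_rows(sel)

  candidates <- selections |>
    dplyr::group_by(.data$feature, .data$region_a, .data$region_b) |>
    dplyr::summarise(
      power = max(.data$power), n_tasks = dplyr::n(), .groups = "drop"
    )
  candidates <- candidates[order(-candidates$power, match(candidates$feature, fmeta$feature)), ]
  selected <- head(candidates, max_features)
  structure(
    list(selections = selections, candidates = candidates, selected = selected),
    class = "selected_features"
  )
}

#' @rdname select_features
#' @export
select_intra_features <- function(table, membership, per_task = 2L, max_features = 18L) {
  fmeta <- feature_metadata(table)
  intra <- fmeta$feature[fmeta$region_a == fmeta$region_b]
  if (length(intra) == 0) abort("the table contains no intra-region feature.")
  sub <- table[c("subject_id", intra)]
  attr(sub, "features") <- fmeta[fmeta$feature %in% intra, ]
  select_features(sub, membership, per_task, max_features)
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf(
    "<selected_features> %d selections over %d tasks -> %d candidate features -> %d kept\n",
    nrow(x$selections), dplyr::n_distinct(x$selections[c("class_p", "class_q")]),
    nrow(x$candidates), nrow(x$selected)
  ))
  print(x$selected, ...)
  invisible(x)
}

#' @export
tidy.selected_features <- function(x, ...) x$selections

#' @export
glance.selected_features <- function(x, ...) {
  tibble::tibble(
    n_tasks = dplyr::n_distinct(x$selections[c("class_p", "class_q")]),
    n_selections = nrow(x$selections),
    n_candidates = nrow(x$candidates),
    n_selected = nrow(x$selected),
    min_power = min(x$selected$power),
    max_power = max(x$selected$power)
  )
}
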