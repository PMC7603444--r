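#' Read and write the pipeline's plain-text formats
#'
#' All intermediates are diffable text at this scale: time series and
#' parcellation as TSV, feature tables as CSV, square MI matrices as TSV
#' with identifier headers and a `# key=value` metadata line, reports as
#' JSON. Writers and readers round-trip exactly on valid files; readers
#' raise validation errors naming the offending identifier or column.
#'
#' @param ts,parc,membership,m,table,report Object to write.
#' @param path File path.
#' @return Readers return the validated object; writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_time_series <- function(ts, path) {
  m <- as_time_series_matrix(ts)
  df <- tibble::as_tibble(m, .name_repair = ~ paste0("t", seq_len(ncol(m))))
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(parcel_id = rownames(m)), df), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_time_series <- function(path) {
  # base parser (strtod) so the shortest-round-trip representation the
  # writer emits reads back bit-exactly
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "parcel_id") abort(sprintf("'%s': first column must be parcel_id.", path))
  num <- vapply(df[-1], is.numeric, logical(1))
  if (!all(num)) {
    abort(sprintf("'%s': non-numeric time-point column '%s'.", path, names(df[-1])[!num][1]))
  }
  df$parcel_id <- as.character(df$parcel_id)
  m <- as_time_series_matrix(df)
  colnames(m) <- NULL  # time indices are positional
  m
}

#' @rdname pipeline_io
#' @export
write_parcellation <- function(parc, path) {
  readr::write_tsv(tibble::as_tibble(parcellation(parc)), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_parcellation <- function(path) {
  parcellation(readr::read_tsv(path, show_col_types = FALSE, col_types = "ccc"))
}

#' @rdname pipeline_io
#' @export
write_membership <- function(membership, path) {
  membership <- class_membership(membership)
  readr::write_tsv(tibble::tibble(
    subject_id = membership$subject_id,
    classes = vapply(membership$classes, paste, "", collapse = ";")
  ), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_membership <- function(path) {
  class_membership(readr::read_tsv(path, show_col_types = FALSE, col_types = "cc"))
}

#' @rdname pipeline_io
#' @param symmetry_tol Maximum tolerated |m - t(m)| when reading a matrix
#'   (default 1e-8).
#' @export
write_mi_matrix <- function(m, path) {
  meta <- character(0)
  if (inherits(m, "region_mi")) {
    meta <- sprintf("# quantile=%s level=%s", format(attr(m, "quantile_level")), attr(m, "level"))
  } else if (inherits(m, "parcel_mi")) {
    meta <- sprintf("# n_bins=%d diagonal=%s", attr(m, "n_bins"), attr(m, "diagonal"))
  }
  df <- tibble::as_tibble(unclass(m), .name_repair = "minimal")
  body <- dplyr::bind_cols(tibble::tibble(id = rownames(m)), df)
  lines <- c(
    meta,
    paste(c("id", rownames(m)), collapse = "\t"),
    vapply(seq_len(nrow(body)), function(i) {
      paste(c(body$id[i], sprintf("%.17g", as.numeric(body[i, -1]))), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_mi_matrix <- function(path, symmetry_tol = 1e-8) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(
    text = paste(grep("^#", lines, value = TRUE, invert = TRUE), collapse = "\n"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  ids <- as.character(df$id)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), ids)) abort(sprintf("'%s': row and column identifiers disagree.", path))
  rownames(m) <- ids
  asym <- max(abs(m - t(m)))
  if (asym > symmetry_tol) {
    abort(sprintf("'%s': matrix asymmetric beyond tolerance (max |m - t(m)| = %g).", path, asym))
  }
  meta <- list()
  if (length(meta_lines)) {
    kv <- strsplit(strsplit(sub("^#\\s*", "", meta_lines[1]), "\\s+")[[1]], "=")
    meta <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  }
  if (!is.null(meta$quantile)) {
    m <- structure(m,
      quantile_level = as.numeric(meta$quantile), level = meta$level %||% "region",
      class = c("region_mi", "matrix", "array")
    )
  } else if (!is.null(meta$n_bins)) {
    m <- structure(m,
      n_bins = as.integer(meta$n_bins), diagonal = meta$diagonal %||% "entropy",
      class = c("parcel_mi", "matrix", "array")
    )
  }
  m
}

#' @rdname pipeline_io
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "subject_id") abort(sprintf("'%s': first column must be subject_id.", path))
  if (anyDuplicated(df$subject_id)) abort(sprintf("'%s': duplicated subject_id.", path))
  df$subject_id <- as.character(df$subject_id)
  attr(df, "features") <- feature_metadata(df)
  df
}

#' @rdname pipeline_io
#' @export
write_loo_report <- function(report, path) {
  stopifnot(inherits(report, "loo_report"))
  out <- list(
    overall_accuracy = report$overall,
    se = report$se,
    per_class = report$per_class,
    folds = tidy(report),
    n_folds = report$n_folds,
    n_skipped = report$n_skipped,
    config = report$config
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param cohort A `synthetic_cohort` to write to `dir` (time-series TSV
#'   per subject, parcellation TSV, labels TSV, ground-truth JSON).
#' @param dir Output directory, created if absent.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$time_series)) {
    write_time_series(cohort$time_series[[id]], file.path(dir, paste0(id, "_timeseries.tsv")))
  }
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  write_membership(cohort$membership, file.path(dir, "labels.tsv"))
  jsonlite::write_json(cohort$planted, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
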