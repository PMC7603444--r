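#' Pipeline configuration
#'
#' Bundles the defaults of the whole workflow: 5 equal-frequency bins for
#' discretization, the 75% aggregation quantile, top-2 features per
#' discrimination task trimmed to an 18-feature roster, a hidden layer of
#' 7 neurons, and the leave-one-out protocol. One master seed drives all
#' randomness through derived child seeds.
#'
#' @param n_bins Discretization bins (default 5).
#' @param quantile_level Region aggregation quantile (default 0.75).
#' @param per_task,max_features Feature selection settings (defaults 2, 18).
#' @param hidden Hidden-layer size h (default 7).
#' @param classifier `"mlp"` or `"svm"`.
#' @param select_once Fix the feature roster on the full cohort before
#'   leave-one-out (default `FALSE`: re-select per fold).
#' @param intra Use the intra-region (diagonal) feature pool (default
#'   `FALSE`: inter-region).
#' @param learning_rate,n_epochs,tol,standardize Training settings, see
#'   [mlp_train()] and [leave_one_out()].
#' @param seed Master seed.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(n_bins = 5L, quantile_level = 0.75, per_task = 2L,
                            max_features = 18L, hidden = 7L,
                            classifier = c("mlp", "svm"), select_once = FALSE,
                            intra = FALSE, learning_rate = 0.1,
                            n_epochs = 5000L, tol = 1e-9, standardize = TRUE,
                            seed = 1L) {
  classifier <- match.arg(classifier)
  structure(
    list(
      n_bins = as.integer(n_bins), quantile_level = quantile_level,
      per_task = as.integer(per_task), max_features = as.integer(max_features),
      hidden = as.integer(hidden), classifier = classifier,
      select_once = isTRUE(select_once), intra = isTRUE(intra),
      learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
      tol = tol, standardize = isTRUE(standardize), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Compute every subject's region-level connectivity features
#'
#' Stage 2 + 3 of the workflow: parcel-level MI matrix per subject, then
#' quantile aggregation to the region scale, then the per-subject feature
#' table over all region pairs.
#'
#' @param time_series Named list (by subject) of parcel time-series
#'   matrices, or a `synthetic_cohort`.
#' @param parc The [parcellation()] (taken from the cohort when omitted).
#' @param n_bins,quantile_level See [pipeline_config()].
#' @param mode Feature pool handed to [feature_table()].
#' @return Feature table tibble (`subject_id` + region-pair columns).
#' @export
cohort_features <- function(time_series, parc = NULL, n_bins = 5L,
                            quantile_level = 0.75, mode = "all") {
  if (inherits(time_series, "synthetic_cohort")) {
    parc <- parc %||% time_series$parcellation
    time_series <- time_series$time_series
  }
  if (is.null(parc)) abort("a parcellation is required.")
  region_mats <- purrr::map(time_series, function(ts) {
    region_mi_matrix(pairwise_mi_matrix(ts, n_bins), parc, quantile_level)
  })
  feature_table(region_mats, mode = mode)
}

#' Run the full localization pipeline
#'
#' Executes the workflow end to end: per-subject parcel MI matrices,
#' region-level aggregation, feature tables, interval-separability
#' feature selection, and the leave-one-out evaluation of the chosen
#' classifier. The parsimony constraint for the configured
#' (max_features, hidden, k) at S = n - 1 is checked up front and logged;
#' a violation is a hard warning, not an error. When `out_dir` is given,
#' every intermediate (region matrices, feature table, selected features,
#' report JSON) is written as diffable text sufficient to resume any
#' later stage.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements
#'   `time_series`, `parcellation`, `membership`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for intermediates.
#' @return The [leave_one_out()] report, with the feature table and the
#'   full-cohort selection attached as attributes `"features"` and
#'   `"selection"`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  membership <- class_membership(cohort$membership)
  parc <- parcellation(cohort$parcellation)
  series <- cohort$time_series
  miss <- setdiff(membership$subject_id, names(series))
  if (length(miss)) abort(sprintf("no time series for subject '%s'.", miss[1]))
  k <- length(class_ids(membership))
  pc <- parsimony_check(
    mlp_architecture(config$max_features, config$hidden, k),
    S = length(series) - 1L
  )
  message(sprintf(
    "parsimony check: h(f + k + 1) = %d %s %d = (k - 1)S - k [%s]",
    pc$lhs, if (pc$pass) "<=" else ">", pc$bound, if (pc$pass) "pass" else "VIOLATED"
  ))
  if (!pc$pass) warn("parsimony constraint violated; training proceeds but is prone to overfitting.")

  mode <- if (config$intra) "intra" else "all"
  feats <- cohort_features(series, parc,
    n_bins = config$n_bins,
    quantile_level = config$quantile_level, mode = mode
  )
  selector <- if (config$intra) select_intra_features else select_features
  selection <- selector(feats, membership, config$per_task, config$max_features)
  report <- leave_one_out(feats, membership,
    classifier = config$classifier,
    select_once = config$select_once, per_task = config$per_task,
    max_features = config$max_features, intra = config$intra,
    hidden = config$hidden, learning_rate = config$learning_rate,
    n_epochs = config$n_epochs, tol = config$tol,
    standardize = config$standardize, seed = config$seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(feats, file.path(out_dir, "features.csv"))
    readr::write_csv(selection$selections, file.path(out_dir, "selected_features.csv"))
    readr::write_csv(selection$selected, file.path(out_dir, "feature_roster.csv"))
    write_loo_report(report, file.path(out_dir, "loo_report.json"))
  }
  attr(report, "features") <- feats
  attr(report, "selection") <- selection
  report
}

#' Heatmap of an MI connectivity matrix
#'
#' @param object A `parcel_mi` or `region_mi` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_mi <- function(object, ...) {
  df <- tidy.parcel_mi(object, upper_only = FALSE)
  ids <- rownames(object)
  df$a <- factor(df$a, levels = ids)
  df$b <- factor(df$b, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI (nats)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' @rdname autoplot.region_mi
#' @export
autoplot.parcel_mi <- autoplot.region_mi
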