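#' Score one prediction against the (possibly ambiguous) diagnosis
#'
#' A prediction is correct (1) when the most probable class is among the
#' subject's true classes — an ambiguously diagnosed subject is scored
#' correct for either of its two classes. Argmax ties break toward the
#' lowest class index.
#'
#' @param pred Probability (or decision-score) vector of length k.
#' @param true_classes Non-empty integer vector of true class indices.
#' @return 0 or 1.
#' @examples
#' score_prediction(c(0.6, 0.1, 0.1, 0.1, 0.1), 1)  # 1
#' score_prediction(c(0.6, 0.1, 0.1, 0.1, 0.1), 2)  # 0
#' @export
score_prediction <- function(pred, true_classes) {
  if (length(true_classes) == 0) abort("`true_classes` must be non-empty.")
  as.integer(which.max(pred) %in% as.integer(true_classes))
}

standardize_fold <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[sg == 0] <- 1
  list(
    train = sweep(sweep(train, 2, mu), 2, sg, "/"),
    test = sweep(sweep(test, 2, mu), 2, sg, "/")
  )
}

#' Leave-one-out evaluation of the connectivity classifier
#'
#' The canonical harness for a moderate cohort: each subject is held out
#' in turn, the classifier is trained on the remaining S = n - 1
#' subjects, and the held-out subject is scored 0/1 by
#' [score_prediction()]. The overall accuracy is the plain mean of the
#' fold scores (x 100); per-class accuracies tally each fold under every
#' class in its subject's true set, so a dual-class subject enters both
#' classes' denominators. By default feature selection is re-run inside
#' every fold on the training subjects only (no selection leakage);
#' `select_once = TRUE` reproduces the select-then-validate protocol in
#' which the roster is fixed on the full cohort first.
#'
#' @param table Feature table ([feature_table()]) for the full cohort,
#'   holding the candidate feature pool.
#' @param membership [class_membership()] for the cohort.
#' @param classifier `"mlp"` or `"svm"` (linear one-vs-rest baseline).
#' @param select_once Select features on the full cohort once instead of
#'   per fold (default `FALSE`).
#' @param per_task,max_features Passed to [select_features()].
#' @param intra Restrict the pool to intra-region coefficients (default
#'   `FALSE`).
#' @param hidden Hidden-layer size h of the perceptron (default 7).
#' @param learning_rate,n_epochs,tol Training hyperparameters, see
#'   [mlp_train()].
#' @param standardize Standardize features to zero mean / unit variance
#'   on each training fold (applied to the held-out subject with the
#'   training fold's statistics; default `TRUE`).
#' @param seed Base seed; each fold trains from a derived child seed.
#' @return Object of class `loo_report`: list with `folds` (per-fold
#'   tibble), `overall` (percent), `se` (binomial standard error over
#'   folds, in percent), `per_class` (tibble of per-class percentages),
#'   `n_folds`, `n_skipped`, and `config` (fingerprint of the settings).
#' @export
leave_one_out <- function(table, membership, classifier = c("mlp", "svm"),
                          select_once = FALSE, per_task = 2L, max_features = 18L,
                          intra = FALSE, hidden = 7L, learning_rate = 0.1,
                          n_epochs = 5000L, tol = 1e-9, standardize = TRUE,
                          seed = 1L) {
  classifier <- match.arg(classifier)
  membership <- class_membership(membership)
  table <- table[match(membership$subject_id, table$subject_id), ]
  if (anyNA(table$subject_id)) abort("feature table and membership disagree on subjects.")
  classes <- class_ids(membership)
  k <- length(classes)
  n <- nrow(table)
  if (n < k + 1) abort("cohort must have at least k + 1 subjects.")
  class_idx <- lapply(membership$classes, function(cl) match(cl, classes))
  selector <- if (intra) select_intra_features else select_features

  full_sel <- if (select_once) selector(table, membership, per_task, max_features) else NULL

  fold_rows <- vector("list", n)
  for (i in seq_len(n)) {
    train_tab <- table[-i, ]
    train_mem <- membership[-i, ]
    counts <- vapply(classes, function(cl) {
      sum(vapply(train_mem$classes, function(s) cl %in% s, logical(1)))
    }, numeric(1))
    if (any(counts < 2)) {
      warn(sprintf("fold %d skipped: a class was emptied below 2 members.", i))
      fold_rows[[i]] <- tibble::tibble(
        subject_id = table$subject_id[i],
        true = list(membership$classes[[i]]),
        predicted = NA_character_, score = NA_integer_, skipped = TRUE
      )
      next
    }
    sel <- full_sel %||% selector(train_tab, train_mem, per_task, max_features)
    feats <- sel$selected$feature
    x_train <- as.matrix(train_tab[feats])
    x_test <- as.matrix(table[i, feats, drop = FALSE])
    if (standardize) {
      st <- standardize_fold(x_train, x_test)
      x_train <- st$train
      x_test <- st$test
    }
    truth <- class_idx[[i]]
    if (classifier == "mlp") {
      arch <- mlp_architecture(length(feats), hidden, k)
      targets <- t(vapply(class_idx[-i], encode_targets, numeric(k), k = k))
      fit <- mlp_train(x_train, targets, arch,
        learning_rate = learning_rate, n_epochs = n_epochs,
        tol = tol, seed = child_seed(seed, i)
      )
      p <- as.numeric(predict(fit, x_test)[1, ])
    } else {
      fit <- ovr_svm_train(x_train, class_idx[-i], k)
      p <- as.numeric(predict(fit, x_test)[1, ])
    }
    fold_rows[[i]] <- tibble::tibble(
      subject_id = table$subject_id[i],
      true = list(membership$classes[[i]]),
      predicted = classes[which.max(p)],
      score = score_prediction(p, truth), skipped = FALSE
    )
  }
  folds <- dplyr::bind_rows(fold_rows)
  scored <- folds[!folds$skipped, ]
  overall <- 100 * mean(scored$score)
  se <- 100 * sqrt(mean(scored$score) * (1 - mean(scored$score)) / nrow(scored))
  per_class <- purrr::map_dfr(classes, function(cl) {
    rows <- scored[vapply(scored$true, function(tr) cl %in% tr, logical(1)), ]
    tibble::tibble(class = cl, n = nrow(rows), accuracy = 100 * mean(rows$score))
  })
  structure(
    list(
      folds = folds, overall = overall, se = se, per_class = per_class,
      n_folds = n, n_skipped = sum(folds$skipped),
      config = list(
        classifier = classifier, select_once = select_once,
        per_task = per_task, max_features = max_features, intra = intra,
        hidden = hidden, learning_rate = learning_rate, n_epochs = n_epochs,
        tol = tol, standardize = standardize, seed = seed
      )
    ),
    class = "loo_report"
  )
}

#' Leave-one-out run of the linear one-vs-rest baseline
#'
#' Same folds, feature selection, standardization and scoring as
#' [leave_one_out()], with the perceptron swapped for the linear
#' maximum-margin baseline, so the two reports compare side by side.
#'
#' @inheritParams leave_one_out
#' @param ... Passed on to [leave_one_out()].
#' @return A `loo_report`.
#' @export
svm_baseline <- function(table, membership, ...) {
  leave_one_out(table, membership, classifier = "svm", ...)
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf(
    "<loo_report> %s, %d folds (%d skipped): overall %.1f%% +/- %.1f%%\n",
    x$config$classifier, x$n_folds, x$n_skipped, x$overall, x$se
  ))
  print(x$per_class, ...)
  invisible(x)
}

#' @export
tidy.loo_report <- function(x, ...) {
  out <- x$folds
  out$true <- vapply(out$true, paste, "", collapse = ";")
  out
}

#' @export
glance.loo_report <- function(x, ...) {
  tibble::tibble(
    classifier = x$config$classifier,
    overall_accuracy = x$overall, se = x$se,
    n_folds = x$n_folds, n_skipped = x$n_skipped
  )
}

#' @export
autoplot.loo_report <- function(object, ...) {
  ggplot2::ggplot(object$per_class, ggplot2::aes(x = .data$class, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall, linetype = "dashed") +
    ggplot2::labs(
      x = "diagnostic class", y = "leave-one-out accuracy (%)",
      subtitle = sprintf("overall %.1f%% (dashed)", object$overall)
    ) +
    ggplot2::theme_minimal()
}
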