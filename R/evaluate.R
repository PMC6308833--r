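new_mboss_eval <- function(strategy, per_subject, confusion, fits) {
  total <- sum(confusion)
  structure(
    list(strategy = strategy, per_subject = per_subject,
         confusion = confusion,
         accuracy = sum(diag(confusion)) / total,
         mean_accuracy = mean(per_subject$accuracy),
         median_accuracy = median(per_subject$accuracy),
         fits = fits),
    class = "mboss_eval"
  )
}

#' Personalized (within-subject) evaluation
#'
#' Builds and scores a model per subject: each subject's instances are split
#' into stratified folds and every test fold is predicted by a classifier
#' fitted -- including the (w, l) parameter search -- on the remaining folds.
#' Reports per-subject accuracies, the pooled confusion matrix and the median
#' accuracy across subjects. Subjects with a single class are skipped with a
#' warning.
#'
#' @param data A labeled dataset tibble with subject identifiers.
#' @param config A [fit_config()]; `folds` caps the per-subject outer folds
#'   (reduced when classes are small).
#' @return An object of class `mboss_eval`.
#' @export
evaluate_personalized <- function(data, config = fit_config()) {
  data <- validate_dataset(data, min_classes = 2L)
  subjects <- sort(unique(data$subject))
  class_order <- sort(unique(data$label))
  truth <- character(0)
  pred <- character(0)
  rows <- list()
  fits <- list()
  for (si in seq_along(subjects)) {
    d_s <- dplyr::filter(data, .data$subject == subjects[si])
    d_s <- dplyr::arrange(d_s, .data$label, .data$instance_id)
    if (length(unique(d_s$label)) < 2L) {
      warn(sprintf("subject %s has a single class; skipped.", subjects[si]))
      next
    }
    seed_s <- derive_seed(config$seed, si)
    fold <- make_folds(d_s$label, config$folds, seed_s)
    t_s <- character(0)
    p_s <- character(0)
    for (f in sort(unique(fold[fold > 0L]))) {
      cfg_f <- config
      cfg_f$seed <- derive_seed(seed_s, f)
      clf <- mboss_fit(d_s[fold != f, ], cfg_f)
      pr <- predict(clf, d_s[fold == f, ])
      t_s <- c(t_s, d_s$label[fold == f])
      p_s <- c(p_s, pr$pred)
      fits[[length(fits) + 1L]] <-
        tibble(subject = subjects[si], fold = f,
               w = clf$chosen$w, l = clf$chosen$l, score = clf$chosen$score)
    }
    rows[[length(rows) + 1L]] <-
      tibble(subject = subjects[si], n = length(t_s),
             accuracy = mean(t_s == p_s))
    truth <- c(truth, t_s)
    pred <- c(pred, p_s)
  }
  if (length(rows) == 0L) abort("no subject with at least 2 classes.")
  new_mboss_eval("personalized", dplyr::bind_rows(rows),
                 confusion_matrix(truth, pred, class_order),
                 dplyr::bind_rows(fits))
}

#' Generalized (leave-one-subject-out) evaluation
#'
#' One fold per subject: a classifier is fitted -- including parameter
#' selection -- on all other subjects' data and scored on the held-out
#' subject. Reports per-subject accuracies, the pooled confusion matrix and
#' the mean and median accuracy.
#'
#' @param data A labeled dataset tibble with >= 2 subjects.
#' @param config A [fit_config()].
#' @return An object of class `mboss_eval`.
#' @export
evaluate_generalized <- function(data, config = fit_config()) {
  data <- validate_dataset(data, min_classes = 2L)
  subjects <- sort(unique(data$subject))
  if (length(subjects) < 2L) abort("need at least 2 subjects for LOSO.")
  class_order <- sort(unique(data$label))
  truth <- character(0)
  pred <- character(0)
  rows <- list()
  fits <- list()
  for (si in seq_along(subjects)) {
    test <- dplyr::filter(data, .data$subject == subjects[si])
    train <- dplyr::filter(data, .data$subject != subjects[si])
    cfg_s <- config
    cfg_s$seed <- derive_seed(config$seed, si)
    clf <- mboss_fit(train, cfg_s)
    pr <- predict(clf, test)
    rows[[si]] <- tibble(subject = subjects[si], n = nrow(test),
                         accuracy = mean(pr$pred == test$label))
    fits[[si]] <- tibble(subject = subjects[si], fold = si,
                         w = clf$chosen$w, l = clf$chosen$l,
                         score = clf$chosen$score)
    truth <- c(truth, test$label)
    pred <- c(pred, pr$pred)
  }
  new_mboss_eval("loso", dplyr::bind_rows(rows),
                 confusion_matrix(truth, pred, class_order),
                 dplyr::bind_rows(fits))
}

#' @export
print.mboss_eval <- function(x, ...) {
  cat(sprintf("<mboss_eval> strategy: %s\n", x$strategy))
  cat(sprintf("  pooled accuracy: %.4f | mean: %.4f | median: %.4f (%d subjects)\n",
              x$accuracy, x$mean_accuracy, x$median_accuracy,
              nrow(x$per_subject)))
  cat("  confusion matrix (truth x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.mboss_eval <- function(x, ...) {
  x$per_subject
}

#' @export
glance.mboss_eval <- function(x, ...) {
  tibble(strategy = x$strategy, accuracy = x$accuracy,
         mean_accuracy = x$mean_accuracy, median_accuracy = x$median_accuracy,
         n_subjects = nrow(x$per_subject), n_instances = sum(x$confusion))
}

#' Plot an evaluation report
#'
#' Either the per-subject accuracy profile or the pooled confusion matrix as
#' a heat map.
#'
#' @param object An `mboss_eval` report.
#' @param type `"accuracy"` (per-subject bars) or `"confusion"` (heat map).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mboss_eval <- function(object, type = c("accuracy", "confusion"),
                                ...) {
  type <- match.arg(type)
  if (type == "accuracy") {
    ggplot2::ggplot(object$per_subject,
                    ggplot2::aes(x = .data$subject, y = .data$accuracy)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_hline(yintercept = object$accuracy, linetype = 2) +
      ggplot2::labs(title = paste0("Per-subject accuracy (", object$strategy, ")"),
                    x = "subject", y = "accuracy") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    df <- as.data.frame(as.table(object$confusion))
    names(df) <- c("truth", "predicted", "n")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$n)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
      ggplot2::scale_y_discrete(limits = rev) +
      ggplot2::labs(title = paste0("Confusion matrix (", object$strategy, ")")) +
      ggplot2::theme_minimal()
  }
}
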