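#' Fitting configuration for the grid search
#'
#' Collects the grid-search and cross-validation settings used by
#' [mboss_fit()]: alphabet size (default 4), the even word-length grid
#' {4, 6, ..., 16} derived from a maximum word length of 16, the number of
#' cross-validation folds (10) and the fold-assignment seed. Candidate window
#' sizes come from [window_grid()] unless `window_sizes` overrides them.
#'
#' @param alphabet_size Alphabet size `c`.
#' @param max_word_length Longest word length; the transform is computed once
#'   at this length and shorter grid values are derived by word truncation.
#' @param word_length_grid Even word lengths to search, all
#'   `<= max_word_length`.
#' @param folds Cross-validation folds (>= 2); reduced with a warning when a
#'   class has fewer instances.
#' @param seed Integer seed for stratified fold assignment.
#' @param window_sizes Optional explicit window-size candidates (overrides
#'   [window_grid()]).
#' @param drop_first_coeff,normalize Passed to [sfa_params()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(alphabet_size = 4L, max_word_length = 16L,
                       word_length_grid = c(4L, 6L, 8L, 10L, 12L, 14L, 16L),
                       folds = 10L, seed = 1L, window_sizes = NULL,
                       drop_first_coeff = TRUE, normalize = "window") {
  word_length_grid <- sort(unique(as.integer(word_length_grid)))
  if (any(word_length_grid %% 2L != 0L) ||
      any(word_length_grid > max_word_length)) {
    abort("`word_length_grid` values must be even and <= max_word_length.")
  }
  if (folds < 2L) abort("`folds` must be >= 2.")
  structure(
    list(alphabet_size = as.integer(alphabet_size),
         max_word_length = as.integer(max_word_length),
         word_length_grid = word_length_grid,
         folds = as.integer(folds), seed = as.integer(seed),
         window_sizes = if (!is.null(window_sizes)) as.integer(window_sizes),
         drop_first_coeff = isTRUE(drop_first_coeff),
         normalize = normalize,
         tie_rule = "max score; ties -> smaller l, then smaller w"),
    class = "fit_config"
  )
}

#' Candidate window sizes for the grid search
#'
#' An arithmetic progression from 10 up to the instance length `n` with step
#' `max(1, round(sqrt(n - 10)))`, giving about `sqrt(n)` candidates.
#' Optionally filters out windows too short to supply the coefficients of the
#' longest word searched.
#'
#' @param n Instance length in samples.
#' @param l_max Optional longest word length; candidates below
#'   `l_max + 2 * drop_first_coeff` are dropped.
#' @param drop_first_coeff Whether X0 is dropped (affects the minimum viable
#'   window).
#' @return Integer vector of window sizes.
#' @examples
#' window_grid(128) # 10, 21, 32, ..., 120
#' @export
window_grid <- function(n, l_max = NULL, drop_first_coeff = TRUE) {
  n <- as.integer(check_scalar_number(n, "n"))
  if (n < 10L) {
    warn("instance length below 10; using a single window candidate.")
    ws <- n
  } else {
    step <- max(1L, as.integer(round(sqrt(n - 10))))
    ws <- unique(as.integer(seq.int(10L, n, by = step)))
  }
  if (!is.null(l_max)) {
    ws <- ws[ws >= l_max + 2L * drop_first_coeff & ws <= n]
    if (length(ws) == 0L) {
      abort("no window candidate can host the requested word length.")
    }
  }
  ws
}

# Stratified fold assignment. Returns an integer fold id per instance; 0
# marks instances never used as test (single-instance classes).
make_folds <- function(labels, folds, seed) {
  counts <- table(labels)
  usable <- counts[counts >= 2L]
  k_eff <- min(folds, if (length(usable)) min(usable) else 2L)
  if (k_eff < folds) {
    warn(sprintf("reducing folds from %d to %d (smallest class size).",
                 folds, k_eff))
  }
  if (any(counts < 2L)) {
    warn("classes with a single instance are kept in training folds only.")
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in sort(names(counts))) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) {
        fold[idx] <- 0L
      } else {
        fold[idx] <- rep_len(seq_len(k_eff), length(idx))[sample.int(length(idx))]
      }
    }
  })
  fold
}

# Total correct CV predictions for one (w, l) given a precomputed count
# matrix and fold assignment.
cv_score_counts <- function(counts, labels, fold, class_order) {
  score <- 0L
  for (f in sort(unique(fold[fold > 0L]))) {
    tr <- which(fold != f)
    te <- which(fold == f)
    fit <- vs_fit(counts[, tr, drop = FALSE], labels[tr], class_order)
    sc <- vs_score(counts[, te, drop = FALSE], fit)
    pred <- class_order[max.col(sc, ties.method = "first")]
    score <- score + sum(pred == labels[te])
  }
  score
}

#' Cross-validated score of one (w, l) candidate
#'
#' Transforms the training set once at the given window size and word length
#' (MCB fitted on the full training set, as in the grid-search structure),
#' assigns seeded stratified folds, fits tf-idf models on each train split
#' and counts correct predictions on the held-out fold. The summed correct
#' count over folds is the grid-search score.
#'
#' @param data A labeled dataset tibble.
#' @param w Window size.
#' @param l Word length.
#' @param config A [fit_config()].
#' @return Integer: total correct predictions over all folds.
#' @export
cross_validate <- function(data, w, l, config = fit_config()) {
  data <- validate_dataset(data, min_classes = 2L)
  params <- sfa_params(w, l, config$alphabet_size,
                       config$drop_first_coeff, config$normalize)
  tr <- transform_all(data$segment, params)
  counts <- kept_to_counts(lapply(tr$words, kept_words))
  class_order <- sort(unique(data$label))
  fold <- make_folds(data$label, config$folds, config$seed)
  cv_score_counts(counts, data$label, fold, class_order)
}

#' Fit an MBOSS classifier by grid search with cross-validation
#'
#' Searches window size and word length jointly: for each candidate window
#' size the whole training set is transformed once at the maximum word
#' length, the shorter word lengths of the grid are derived by word
#' truncation, and each (w, l) pair is scored by stratified k-fold
#' cross-validation of the tf-idf vector-space classifier. The best pair
#' (ties resolved toward the smaller word length, then the smaller window) is
#' refit on the entire training set.
#'
#' @param data A labeled dataset tibble with >= 2 classes.
#' @param config A [fit_config()].
#' @return An object of class `mboss_classifier`: per-class tf-idf models,
#'   fitted per-axis MCB tables, the chosen [sfa_params()], the class order
#'   and the full cross-validation grid (`cv_results`).
#' @examples
#' \donttest{
#' cfg <- generator_config(subjects = 2, instances_per_class = 3, seed = 7)
#' d <- generate_dataset(cfg)
#' clf <- mboss_fit(d, fit_config(window_sizes = 32, word_length_grid = c(4, 8),
#'                                folds = 3, seed = 1))
#' }
#' @export
mboss_fit <- function(data, config = fit_config()) {
  data <- validate_dataset(data, min_classes = 2L)
  # canonical instance order: fold assignment independent of row shuffling
  data <- dplyr::arrange(data, .data$label, .data$subject, .data$instance_id)
  labels <- data$label
  class_order <- sort(unique(labels))
  n <- nrow(data$segment[[1L]])
  wcand <- config$window_sizes %||%
    window_grid(n, l_max = config$max_word_length,
                drop_first_coeff = config$drop_first_coeff)
  wcand <- wcand[wcand >= config$max_word_length +
                   2L * config$drop_first_coeff & wcand <= n]
  if (length(wcand) == 0L) abort("no viable window-size candidate.")
  fold <- make_folds(labels, config$folds, config$seed)
  grid <- tidyr::expand_grid(w = wcand, l = config$word_length_grid)
  scores <- integer(nrow(grid))
  for (w in wcand) {
    params_max <- sfa_params(w, config$max_word_length, config$alphabet_size,
                             config$drop_first_coeff, config$normalize)
    tr <- transform_all(data$segment, params_max)
    for (l in config$word_length_grid) {
      counts <- kept_to_counts(lapply(tr$words, kept_words, l = l))
      scores[grid$w == w & grid$l == l] <-
        cv_score_counts(counts, labels, fold, class_order)
    }
  }
  grid$score <- scores
  best <- dplyr::arrange(grid, dplyr::desc(.data$score), .data$l, .data$w)[1L, ]
  # final refit on the entire training set at the chosen (w, l)
  params <- sfa_params(best$w, best$l, config$alphabet_size,
                       config$drop_first_coeff, config$normalize)
  tr <- transform_all(data$segment, params)
  fit <- vs_fit(kept_to_counts(lapply(tr$words, kept_words)),
                labels, class_order)
  structure(
    list(class_models = vs_fit_to_models(fit), class_order = class_order,
         params = params, mcbs = tr$mcbs,
         chosen = list(w = best$w, l = best$l, score = best$score),
         cv_results = grid, n_train = nrow(data)),
    class = "mboss_classifier"
  )
}

#' @export
print.mboss_classifier <- function(x, ...) {
  cat(sprintf(
    "<mboss_classifier> %d classes, %d training instances\n  chosen w = %d, l = %d, c = %d (CV score %d)\n",
    length(x$class_order), x$n_train, x$chosen$w, x$chosen$l,
    x$params$alphabet_size, x$chosen$score))
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' Predict activity labels for new instances
#'
#' Transforms each instance with the classifier's fitted parameters and MCB
#' tables and scores it against every class tf-idf vector by cosine
#' similarity; the label of the maximizing class is assigned (ties and
#' all-zero score rows go to the first class in class order and are flagged).
#'
#' @param object A fitted [mboss_fit()] classifier.
#' @param newdata A dataset tibble of instances.
#' @param ... Unused.
#' @return A tibble with one row per instance: `pred`, `flagged` and per-class
#'   `score_*` columns.
#' @export
predict.mboss_classifier <- function(object, newdata, ...) {
  newdata <- validate_dataset(newdata)
  hists <- lapply(newdata$segment, mboss_transform,
                  params = object$params, mcbs = object$mcbs)
  fit <- models_to_vs_fit(object$class_models, object$class_order)
  scores <- vs_score(hists_to_counts(hists, vocab = fit$vocab), fit)
  score_table(scores, object$class_order)
}

#' Confusion matrix
#'
#' Entry (i, j) counts instances of true class i predicted as class j; rows
#' sum to the per-class instance counts and `sum(diag(.)) / sum(.)` is the
#' accuracy.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param class_order Label ordering for rows/columns; defaults to the sorted
#'   union of both vectors.
#' @return An integer matrix with dimnames `truth` x `predicted`.
#' @export
confusion_matrix <- function(truth, predicted,
                             class_order = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (!all(c(truth, predicted) %in% class_order)) {
    abort("labels outside `class_order`.")
  }
  m <- table(factor(truth, levels = class_order),
             factor(predicted, levels = class_order))
  out <- matrix(as.integer(m), nrow = length(class_order),
                dimnames = list(truth = class_order, predicted = class_order))
  out
}

#' @export
tidy.mboss_classifier <- function(x, ...) {
  as_tibble(x$cv_results)
}

#' @export
glance.mboss_classifier <- function(x, ...) {
  tibble(window_size = x$chosen$w, word_length = x$chosen$l,
         alphabet_size = x$params$alphabet_size, cv_score = x$chosen$score,
         n_classes = length(x$class_order), n_train = x$n_train)
}
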