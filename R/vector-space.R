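# Vector-space classification: per-class tf-idf weight vectors compared to
# query tf vectors by cosine similarity. Natural logarithms throughout.

tf_weight <- function(counts) {
  ifelse(counts > 0, 1 + log(counts), 0)
}

#' Term frequency of a word in one histogram
#'
#' `tf(p, T) = 1 + log(B_T(p))` when the word's count is positive, else 0
#' (natural log).
#'
#' @param hist A [numerosity_reduce()] histogram (named counts).
#' @param word The word to look up.
#' @return A single non-negative number.
#' @examples
#' term_frequency(numerosity_reduce(c("aa", "ab", "ab")), "aa") # 1
#' @export
term_frequency <- function(hist, word) {
  count <- unname(unclass(hist)[word])
  if (is.na(count)) 0 else tf_weight(count)
}

#' Class-level term frequency
#'
#' `tf(p, C) = 1 + log(sum of the word's counts over the class's training
#' histograms)` when that sum is positive, else 0.
#'
#' @param class_hists List of word histograms belonging to one class.
#' @param word The word to look up.
#' @return A single non-negative number.
#' @export
class_term_frequency <- function(class_hists, word) {
  total <- sum(vapply(class_hists,
                      function(h) {
                        x <- unclass(h)[word]
                        if (is.na(x)) 0L else as.integer(x)
                      }, integer(1)))
  tf_weight(total)
}

#' Inverse document frequency of a word over classes
#'
#' `idf(p) = log(|CLASSES| / number of classes containing p)`; a word present
#' in every class is weighted 0, a word confined to one class gets the
#' maximal weight `log(|CLASSES|)`.
#'
#' @param word The word to look up.
#' @param class_hists_by_class Named list (one element per class) of lists of
#'   word histograms.
#' @return A single non-negative number; errors for a word in no class (which
#'   cannot happen for training-vocabulary words).
#' @export
inverse_document_frequency <- function(word, class_hists_by_class) {
  present <- vapply(class_hists_by_class, function(hists) {
    any(vapply(hists, function(h) {
      x <- unclass(h)[word]
      !is.na(x) && x > 0
    }, logical(1)))
  }, logical(1))
  n_with <- sum(present)
  if (n_with == 0L) abort("word occurs in no class; idf is undefined.")
  log(length(class_hists_by_class) / n_with)
}

# --- sparse fitting core ------------------------------------------------------

# Stack histograms into a sparse vocabulary x instance count matrix.
hists_to_counts <- function(hists, vocab = NULL) {
  all_names <- lapply(hists, names)
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(all_names, use.names = FALSE)))
  }
  i <- match(unlist(all_names, use.names = FALSE), vocab)
  j <- rep.int(seq_along(hists), lengths(hists))
  x <- as.integer(unlist(lapply(hists, unclass), use.names = FALSE))
  keep <- !is.na(i)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(length(vocab), length(hists)),
                       dimnames = list(vocab, NULL))
}

# Per-class tf-idf weight matrix from a count matrix and labels.
# Returns list(weights = V x K dgCMatrix, norms, class_order, vocab).
vs_fit <- function(counts, labels, class_order) {
  k <- length(class_order)
  y <- Matrix::sparseMatrix(i = seq_along(labels),
                            j = match(labels, class_order), x = 1,
                            dims = c(length(labels), k))
  s <- counts %*% y # summed counts per class
  if (!methods::is(s, "CsparseMatrix")) s <- methods::as(s, "CsparseMatrix")
  df <- tabulate(s@i + 1L, nbins = nrow(s)) # classes containing each word
  idf <- log(k / df)
  idf[df == 0] <- 0
  w <- s
  w@x <- (1 + log(s@x)) * idf[s@i + 1L] # tf(p, C) * idf(p)
  dimnames(w) <- list(rownames(counts), class_order)
  list(weights = w, norms = sqrt(Matrix::colSums(w^2)),
       class_order = class_order, vocab = rownames(counts))
}

# Cosine similarity of query histograms (columns of a count matrix) against
# each class model. Query weighting is tf only, with the query norm over the
# query's own words. Returns an n_query x K matrix.
vs_score <- function(counts, fit) {
  q <- counts
  if (length(q@x)) q@x <- 1 + log(q@x)
  qnorm <- sqrt(Matrix::colSums(q^2))
  num <- as.matrix(Matrix::crossprod(q, fit$weights))
  den <- outer(qnorm, fit$norms)
  out <- num / den
  out[den == 0] <- 0
  colnames(out) <- fit$class_order
  out
}

vs_fit_to_models <- function(fit) {
  w <- fit$weights
  lapply(seq_along(fit$class_order), function(j) {
    col <- w[, j]
    nz <- which(col != 0)
    list(label = fit$class_order[j],
         tfidf = stats::setNames(as.numeric(col[nz]), fit$vocab[nz]),
         norm = fit$norms[[j]])
  })
}

models_to_vs_fit <- function(class_models, class_order) {
  vocab <- sort(unique(unlist(lapply(class_models, function(m) names(m$tfidf)),
                              use.names = FALSE)))
  k <- length(class_models)
  w <- Matrix::sparseMatrix(
    i = unlist(lapply(class_models, function(m) match(names(m$tfidf), vocab))),
    j = rep.int(seq_len(k), vapply(class_models, function(m) length(m$tfidf),
                                   integer(1))),
    x = unlist(lapply(class_models, function(m) unname(m$tfidf))),
    dims = c(length(vocab), k), dimnames = list(vocab, class_order))
  list(weights = w,
       norms = vapply(class_models, function(m) m$norm, numeric(1)),
       class_order = class_order, vocab = vocab)
}

#' Build per-class tf-idf models from labeled histograms
#'
#' For every word in the training vocabulary, the weight in class C is the
#' class-level term frequency times the inverse document frequency. Each
#' class's weight vector and its Euclidean norm form a compact
#' representation of all training instances of that class.
#'
#' @param hists List of word histograms.
#' @param labels Character vector of class labels, one per histogram; at
#'   least 2 distinct classes, each non-empty.
#' @return An object of class `mboss_vs`: per-class models (`label`, sparse
#'   `tfidf` named vector, `norm`) and the lexicographic `class_order`.
#' @export
build_class_models <- function(hists, labels) {
  labels <- as.character(labels)
  if (length(hists) != length(labels)) {
    abort("`hists` and `labels` must have equal length.")
  }
  class_order <- sort(unique(labels))
  if (length(class_order) < 2L) abort("need at least 2 classes.")
  fit <- vs_fit(hists_to_counts(hists), labels, class_order)
  structure(list(class_models = vs_fit_to_models(fit),
                 class_order = class_order),
            class = "mboss_vs")
}

#' Cosine similarity between a query tf vector and one class model
#'
#' The dot product over the query's words divided by the product of the query
#' tf-vector norm (over the query's own words) and the model norm (over the
#' model's full vocabulary). Always in `[0, 1]`; a zero query or zero model
#' yields 0.
#'
#' @param query_tf Named numeric vector of query tf weights (from
#'   [term_frequency()] applied to a histogram).
#' @param model One class model from [build_class_models()] (a list with
#'   `tfidf` and `norm`).
#' @return A single number in `[0, 1]`.
#' @export
cosine_similarity <- function(query_tf, model) {
  qn <- sqrt(sum(query_tf^2))
  if (qn == 0 || model$norm == 0) return(0)
  shared <- intersect(names(query_tf), names(model$tfidf))
  sum(query_tf[shared] * model$tfidf[shared]) / (qn * model$norm)
}

# tf vector of a histogram (named).
hist_tf <- function(hist) {
  stats::setNames(tf_weight(as.numeric(hist)), names(hist))
}

#' Classify word histograms against fitted class models
#'
#' Scores each histogram against every class by cosine similarity and
#' assigns the label of the maximizing class; exact ties (including the
#' all-zero case of an empty or out-of-vocabulary histogram) go to the first
#' class in `class_order`, and such degenerate rows are flagged.
#'
#' @param object An `mboss_vs` model set from [build_class_models()].
#' @param hists A list of word histograms (or a single histogram).
#' @param ... Unused.
#' @return A tibble with `pred` (label), `flagged` (all-zero score row) and
#'   one `score_<class>` column per class.
#' @export
predict.mboss_vs <- function(object, hists, ...) {
  if (inherits(hists, "word_histogram")) hists <- list(hists)
  fit <- models_to_vs_fit(object$class_models, object$class_order)
  scores <- vs_score(hists_to_counts(hists, vocab = fit$vocab), fit)
  score_table(scores, object$class_order)
}

score_table <- function(scores, class_order) {
  idx <- max.col(scores, ties.method = "first")
  flagged <- rowSums(scores != 0) == 0L
  out <- tibble(pred = class_order[idx], flagged = flagged)
  sc <- as_tibble(as.data.frame(scores))
  names(sc) <- paste0("score_", class_order)
  dplyr::bind_cols(out, sc)
}
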