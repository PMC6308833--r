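#' SFA word sequence of one axis
#'
#' Transforms every sliding window of a univariate series into its SFA word:
#' windows are normalized according to the parameters (per-window
#' z-normalization by default), approximated by their truncated Fourier
#' coefficients and quantized through a fitted MCB table. Each word carries a
#' leading axis-identifier prefix (e.g. axis 2's word `"ab"` is stored as
#' `"2ab"`) so histograms of different axes never collide when fused.
#'
#' @param series Numeric vector of length `>= window_size`.
#' @param params An [sfa_params()].
#' @param mcb A [fit_mcb()] table fitted on coefficients of the same
#'   normalization.
#' @param axis_id Integer axis identifier (1-based).
#' @return An object of class `word_sequence`: ordered words (one per window
#'   position), the axis id and the prefix width.
#' @export
boss_word_sequence <- function(series, params, mcb, axis_id = 1L) {
  stopifnot(inherits(params, "sfa_params"), inherits(mcb, "mcb_table"))
  if (!is.numeric(series) || length(series) < params$window_size) {
    abort("`series` must be numeric with length >= window_size.")
  }
  if (mcb$word_length != params$word_length) {
    abort("MCB column count does not match the word length.")
  }
  coeffs <- sliding_norm_coeffs(series, params)
  prefix <- axis_prefix(axis_id)
  new_word_sequence(paste0(prefix, discretize(coeffs, mcb)),
                    as.integer(axis_id), nchar(prefix))
}

new_word_sequence <- function(words, axis_id, prefix_nchar) {
  structure(list(words = words, axis_id = axis_id,
                 prefix_nchar = prefix_nchar),
            class = "word_sequence")
}

#' @export
print.word_sequence <- function(x, ...) {
  cat(sprintf("<word_sequence> axis %d, %d windows: %s ...\n", x$axis_id,
              length(x$words), paste(head(x$words, 5L), collapse = " ")))
  invisible(x)
}

#' Numerosity-reduced word histogram
#'
#' Counts a window's word only when it differs from the immediately
#' preceding window's word, suppressing the runs of identical words that
#' stable signal regions produce; the first word is always counted.
#'
#' @param seq A [boss_word_sequence()] (or a plain character vector of
#'   words).
#' @return A `word_histogram`: a named integer vector of positive counts,
#'   sorted by word.
#' @examples
#' numerosity_reduce(c("aa", "aa", "ab", "ab", "aa")) # aa: 2, ab: 1
#' @export
numerosity_reduce <- function(seq) {
  words <- if (inherits(seq, "word_sequence")) seq$words else as.character(seq)
  new_word_histogram(count_first_of_runs(words))
}

# Keep the first word of each run, then tabulate.
count_first_of_runs <- function(words) {
  k <- length(words)
  if (k == 0L) return(stats::setNames(integer(0), character(0)))
  count_tabulate(words[c(TRUE, words[-1L] != words[-k])])
}

new_word_histogram <- function(counts) {
  structure(counts, class = "word_histogram")
}

#' @export
print.word_histogram <- function(x, ...) {
  cat(sprintf("<word_histogram> %d distinct words, total count %d\n",
              length(x), sum(x)))
  if (length(x)) print(utils::head(unclass(x), 10L))
  invisible(x)
}

#' @export
tidy.word_histogram <- function(x, ...) {
  tibble(word = names(x), count = as.integer(x))
}

#' Multivariate BOSS transform of one instance
#'
#' Builds the fused word histogram of a multivariate instance: each axis is
#' transformed to its axis-prefixed SFA word sequence, numerosity reduction
#' is applied per axis (the last-word comparison resets at every axis
#' boundary), and the per-axis histograms are merged. Axis prefixes make the
#' merge a disjoint union, so the fused total equals the sum of per-axis
#' totals.
#'
#' @param instance An `n x v` numeric segment matrix (or one row of a
#'   dataset tibble's `segment` column).
#' @param params An [sfa_params()].
#' @param mcbs A list of one [fit_mcb()] table per axis.
#' @return A `word_histogram` over axis-prefixed words.
#' @export
mboss_transform <- function(instance, params, mcbs) {
  if (!is.matrix(instance) || !is.numeric(instance)) {
    abort("`instance` must be a numeric matrix (rows = time, columns = axes).")
  }
  v <- ncol(instance)
  if (!is.list(mcbs) || length(mcbs) < v) {
    abort("`mcbs` must provide one MCB table per axis.")
  }
  kept <- unlist(lapply(seq_len(v), function(i) {
    seq_i <- boss_word_sequence(instance[, i], params, mcbs[[i]], i)
    k <- length(seq_i$words)
    seq_i$words[c(TRUE, seq_i$words[-1L] != seq_i$words[-k])]
  }), use.names = FALSE)
  new_word_histogram(count_tabulate(kept))
}

count_tabulate <- function(words) {
  if (length(words) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  r <- rle(sort(words, method = "radix"))
  stats::setNames(r$lengths, r$values)
}

#' Truncate the words of a sequence to a shorter word length
#'
#' Keeps each word's axis prefix and its first `l_new` symbols. Because MCB
#' columns are per-coefficient, words at a shorter length are exactly the
#' prefixes of words computed at a longer length, so model fitting computes
#' the longest word once and derives the shorter grids by truncation.
#' Numerosity reduction is not applied here; it is reapplied downstream on
#' the truncated sequence.
#'
#' @param seq A [boss_word_sequence()].
#' @param l_new New word length (even, at most the stored symbol length).
#' @return A `word_sequence` with truncated words.
#' @export
truncate_words <- function(seq, l_new) {
  stopifnot(inherits(seq, "word_sequence"))
  l_new <- as.integer(check_scalar_number(l_new, "l_new"))
  if (l_new %% 2L != 0L) abort("`l_new` must be even.")
  cur <- nchar(seq$words[1L]) - seq$prefix_nchar
  if (length(seq$words) && l_new > cur) {
    abort("`l_new` exceeds the stored word length.")
  }
  new_word_sequence(substr(seq$words, 1L, seq$prefix_nchar + l_new),
                    seq$axis_id, seq$prefix_nchar)
}

# --- internal dataset-level transform machinery ------------------------------

# Transform all instances at the given params: fits one MCB per axis on the
# normalized coefficients of every sliding window of every instance, then
# emits per-instance, per-axis prefixed word vectors.
# Returns list(mcbs = <list of mcb_table>, words = <list per instance of
# list per axis of character vectors>).
transform_all <- function(segments, params) {
  v <- ncol(segments[[1L]])
  mcbs <- vector("list", v)
  words <- rep(list(vector("list", v)), length(segments))
  for (i in seq_len(v)) {
    coeffs <- lapply(segments, function(m) sliding_norm_coeffs(m[, i], params))
    mcbs[[i]] <- fit_mcb(do.call(rbind, coeffs), params$alphabet_size)
    prefix <- axis_prefix(i)
    for (k in seq_along(segments)) {
      words[[k]][[i]] <- paste0(prefix, discretize(coeffs[[k]], mcbs[[i]]))
    }
  }
  list(mcbs = mcbs, words = words)
}

# Numerosity-kept (run-first) words of one instance, fused over axes,
# optionally truncating symbols to length l first (prefix widths per axis).
kept_words <- function(axis_words, l = NULL) {
  unlist(lapply(seq_along(axis_words), function(i) {
    wds <- axis_words[[i]]
    if (!is.null(l)) {
      wds <- substr(wds, 1L, nchar(axis_prefix(i)) + l)
    }
    k <- length(wds)
    wds[c(TRUE, wds[-1L] != wds[-k])]
  }), use.names = FALSE)
}

# Fused numerosity-reduced histogram from per-axis word vectors.
fuse_histogram <- function(axis_words, l = NULL) {
  new_word_histogram(count_tabulate(kept_words(axis_words, l)))
}

# Sparse vocabulary x instance count matrix straight from numerosity-kept
# word occurrences (duplicate triplets sum to counts).
kept_to_counts <- function(kept_list) {
  occ <- unlist(kept_list, use.names = FALSE)
  vocab <- sort(unique(occ), method = "radix")
  Matrix::sparseMatrix(
    i = match(occ, vocab),
    j = rep.int(seq_along(kept_list), lengths(kept_list)),
    x = 1L,
    dims = c(length(vocab), length(kept_list)),
    dimnames = list(vocab, NULL))
}

#' Transform every instance of a dataset into word histograms
#'
#' Fits one MCB table per axis on the full dataset and returns the fused
#' MBOSS histogram of every instance, the standard feature extraction step
#' ahead of vector-space model building.
#'
#' @param data A dataset tibble (see [generate_dataset()]).
#' @param params An [sfa_params()].
#' @return A list with `histograms` (one `word_histogram` per instance),
#'   `mcbs` (per-axis tables) and `params`.
#' @export
mboss_transform_dataset <- function(data, params) {
  data <- validate_dataset(data)
  tr <- transform_all(data$segment, params)
  list(histograms = lapply(tr$words, fuse_histogram),
       mcbs = tr$mcbs, params = params)
}
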