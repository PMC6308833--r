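# Readers/writers: long-format CSV datasets, JSON models/MCB/histograms,
# sparse histogram export and memory-footprint accounting.

#' Read a long-format sensor CSV into a segmented dataset
#'
#' Expects the header `subject,label,t,<axis1>,<axis2>,...`. Rows are grouped
#' into one recording per (subject, label) pair, ordered by `t`, and
#' segmented with the requested mode: `"sliding"` fixed windows with overlap
#' or `"peak"` magnitude-peak-centered windows. Malformed rows (non-numeric
#' axis values) are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param mode Segmentation mode.
#' @param seg_len Window length in samples (sliding mode).
#' @param overlap_frac Overlap fraction in `[0, 1)` (sliding mode).
#' @param sampling_rate Sampling rate in Hz (required metadata; used by peak
#'   mode).
#' @param threshold,seg_seconds Peak-mode parameters, see [peak_segments()].
#' @return A dataset tibble.
#' @export
read_dataset <- function(path, mode = c("sliding", "peak"), seg_len = 128L,
                         overlap_frac = 0, sampling_rate = 50,
                         threshold = 1.5, seg_seconds = 3) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_character(), label = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  needed <- c("subject", "label", "t")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("CSV is missing required header column(s): ",
                 paste(missing, collapse = ", ")))
  }
  axes <- setdiff(names(df), needed)
  if (length(axes) == 0L) abort("CSV has no axis columns.")
  for (col in c("t", axes)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value(s) in column '%s' at line(s): %s",
                    col, paste(bad + 1L, collapse = ", ")))
    }
    if (anyNA(vals)) {
      abort(sprintf("missing value(s) in column '%s' at line(s): %s", col,
                    paste(which(is.na(vals)) + 1L, collapse = ", ")))
    }
    df[[col]] <- vals
  }
  groups <- dplyr::group_split(dplyr::group_by(df, .data$subject, .data$label))
  out <- purrr::map_dfr(groups, function(g) {
    g <- dplyr::arrange(g, .data$t)
    rec <- raw_recording(as.matrix(g[, axes, drop = FALSE]), sampling_rate,
                         label = g$label[1L], subject = g$subject[1L])
    if (mode == "sliding") {
      sliding_segments(rec, seg_len, overlap_frac)
    } else {
      peak_segments(rec, threshold, seg_seconds)
    }
  })
  if (nrow(out) > 0) out$instance_id <- seq_len(nrow(out))
  out
}

#' Write a dataset to long-format CSV
#'
#' Inverse of [read_dataset()] for pre-segmented data: each instance's rows
#' are written consecutively with a within-instance 0-based sample index
#' `t`; the `label` column carries `label#instance_id` so the round trip
#' resegments instances exactly.
#'
#' @param data A dataset tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  data <- validate_dataset(data)
  long <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    seg <- data$segment[[i]]
    out <- tibble(subject = data$subject[i],
                  label = paste0(data$label[i], "#", data$instance_id[i]),
                  t = seq_len(nrow(seg)) - 1L)
    dplyr::bind_cols(out, as_tibble(as.data.frame(seg)))
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' Re-read a pre-segmented dataset written by [write_dataset()]
#'
#' @param path CSV path produced by [write_dataset()].
#' @return A dataset tibble.
#' @export
read_segmented_dataset <- function(path) {
  seg_len <- NULL
  df <- readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_character(), label = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  axes <- setdiff(names(df), c("subject", "label", "t"))
  parts <- strsplit(df$label, "#", fixed = TRUE)
  df$instance_id <- as.integer(vapply(parts, `[`, "", 2L))
  df$label <- vapply(parts, `[`, "", 1L)
  groups <- dplyr::group_split(dplyr::group_by(df, .data$instance_id))
  purrr::map_dfr(groups, function(g) {
    g <- dplyr::arrange(g, .data$t)
    new_dataset_row(as.matrix(g[, axes, drop = FALSE]), g$label[1L],
                    g$subject[1L], g$instance_id[1L])
  })
}

# --- MCB / model / histogram JSON -------------------------------------------

mcb_to_list <- function(mcb) {
  bp <- mcb$breakpoints
  cols <- lapply(seq_len(ncol(bp)), function(j) {
    v <- bp[, j]
    out <- as.list(v)
    out[v == -Inf] <- "-inf"
    out[v == Inf] <- "inf"
    out
  })
  list(alphabet_size = mcb$alphabet_size, word_length = mcb$word_length,
       breakpoints = cols)
}

mcb_from_list <- function(x) {
  bp <- vapply(x$breakpoints, function(col) {
    vapply(col, function(v) {
      if (identical(v, "-inf")) -Inf
      else if (identical(v, "inf")) Inf
      else as.numeric(v)
    }, numeric(1))
  }, numeric(x$alphabet_size + 1L))
  structure(list(breakpoints = bp, alphabet = letters[seq_len(x$alphabet_size)],
                 alphabet_size = as.integer(x$alphabet_size),
                 word_length = as.integer(x$word_length)),
            class = "mcb_table")
}

#' Serialize an MCB table to JSON
#'
#' Column-major breakpoint lists with `"-inf"`/`"inf"` sentinels.
#'
#' @param mcb A [fit_mcb()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mcb <- function(mcb, path) {
  stopifnot(inherits(mcb, "mcb_table"))
  jsonlite::write_json(mcb_to_list(mcb), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mcb
#' @export
read_mcb <- function(path) {
  mcb_from_list(jsonlite::read_json(path))
}

#' Serialize a fitted classifier to a single JSON model file
#'
#' Stores the SFA parameters, per-axis MCB tables, class order, the chosen
#' grid point and the per-class sparse tf-idf maps. Counts round-trip
#' exactly; weights round-trip to full double precision.
#'
#' @param clf A fitted [mboss_fit()] classifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(clf, path) {
  stopifnot(inherits(clf, "mboss_classifier"))
  models <- lapply(clf$class_models, function(m) {
    ord <- order(names(m$tfidf))
    list(label = m$label,
         tfidf = as.list(m$tfidf[ord]),
         norm = m$norm)
  })
  names(models) <- clf$class_order
  obj <- list(
    params = unclass(clf$params),
    class_order = as.list(clf$class_order),
    chosen = clf$chosen,
    n_train = clf$n_train,
    mcbs = lapply(clf$mcbs, mcb_to_list),
    class_models = models
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  p <- obj$params
  params <- sfa_params(p$window_size, p$word_length, p$alphabet_size,
                       isTRUE(p$drop_first_coeff), p$normalize)
  class_order <- unlist(obj$class_order)
  models <- lapply(obj$class_models, function(m) {
    list(label = m$label,
         tfidf = unlist(m$tfidf) %||% stats::setNames(numeric(0), character(0)),
         norm = as.numeric(m$norm))
  })
  names(models) <- NULL
  structure(
    list(class_models = models, class_order = class_order, params = params,
         mcbs = lapply(obj$mcbs, mcb_from_list),
         chosen = list(w = obj$chosen$w, l = obj$chosen$l,
                       score = obj$chosen$score),
         cv_results = NULL, n_train = obj$n_train),
    class = "mboss_classifier"
  )
}

#' Serialize word histograms to JSON
#'
#' A JSON array of `{word: count}` objects, one per instance.
#'
#' @param hists List of word histograms.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histograms <- function(hists, path) {
  jsonlite::write_json(lapply(hists, function(h) as.list(unclass(h))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sparse triplet export of a histogram collection
#'
#' The instances-by-vocabulary count matrix in triplet form, for feeding
#' external classifiers.
#'
#' @param hists List of word histograms.
#' @return A tibble with `instance`, `word`, `count`.
#' @export
histogram_triplets <- function(hists) {
  tibble(
    instance = rep.int(seq_along(hists), lengths(hists)),
    word = unlist(lapply(hists, names), use.names = FALSE),
    count = as.integer(unlist(lapply(hists, unclass), use.names = FALSE))
  )
}

#' Memory footprint of raw vs. symbolic representation
#'
#' The raw footprint counts 8 bytes (a double) per sample: `instances x n x
#' v x 8`. The symbolic footprint is the serialized size of all fused word
#' histograms: the UTF-8 bytes of each distinct word plus a 4-byte count.
#' The reduction is `100 * (1 - symbolic / raw)`.
#'
#' @param data A dataset tibble (may be empty).
#' @param clf A fitted [mboss_fit()] classifier (or any list with `params`
#'   and `mcbs`) defining the transform.
#' @return A tibble with `raw_bytes`, `symbolic_bytes`, `reduction_percent`.
#' @export
memory_report <- function(data, clf) {
  if (nrow(data) == 0L) {
    return(tibble(raw_bytes = 0, symbolic_bytes = 0, reduction_percent = 0))
  }
  data <- validate_dataset(data)
  raw_bytes <- nrow(data) * nrow(data$segment[[1L]]) *
    ncol(data$segment[[1L]]) * 8
  hists <- lapply(data$segment, mboss_transform,
                  params = clf$params, mcbs = clf$mcbs)
  symbolic_bytes <- sum(vapply(hists, function(h) {
    sum(nchar(names(h), type = "bytes")) + 4 * length(h)
  }, numeric(1)))
  tibble(raw_bytes = raw_bytes, symbolic_bytes = symbolic_bytes,
         reduction_percent = 100 * (1 - symbolic_bytes / raw_bytes))
}

#' Write an evaluation report to JSON and CSV
#'
#' The JSON carries the strategy, pooled/mean/median accuracies, per-subject
#' accuracies and chosen parameters; the confusion matrix goes to a sibling
#' CSV.
#'
#' @param eval An `mboss_eval` report.
#' @param path Output JSON path; the confusion matrix is written next to it
#'   with suffix `_confusion.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(eval, path) {
  stopifnot(inherits(eval, "mboss_eval"))
  obj <- list(strategy = eval$strategy, accuracy = eval$accuracy,
              mean_accuracy = eval$mean_accuracy,
              median_accuracy = eval$median_accuracy,
              per_subject = eval$per_subject, fits = eval$fits)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  cm <- as.data.frame(as.table(eval$confusion))
  cm_path <- sub("\\.json$", "_confusion.csv", path)
  readr::write_csv(tidyr::pivot_wider(cm, names_from = "predicted",
                                      values_from = "Freq"), cm_path)
  invisible(path)
}
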