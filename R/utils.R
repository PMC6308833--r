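# Internal helpers shared across modules.

# Flat-window guard used by z-normalization and coefficient scaling.
.eps_flat <- 1e-8

#' Validate an instance dataset tibble
#'
#' Datasets are ordinary tibbles with one row per segmented instance:
#' `subject` (character), `label` (character), `instance_id` (integer) and
#' `segment` (list column of n x v numeric matrices, one column per sensor
#' axis). All functions that consume a dataset call this check.
#'
#' @param data A data frame with columns `subject`, `label`, `instance_id`,
#'   `segment`.
#' @param min_classes Minimum number of distinct labels required.
#' @return The input, invisibly, as a tibble.
#' @keywords internal
validate_dataset <- function(data, min_classes = 1L) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of instances.")
  }
  needed <- c("subject", "label", "instance_id", "segment")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0) {
    abort("dataset has no instances.")
  }
  if (!is.list(data$segment) || !all(vapply(data$segment, is.matrix, logical(1)))) {
    abort("`segment` must be a list column of numeric matrices.")
  }
  v <- vapply(data$segment, ncol, integer(1))
  if (length(unique(v)) != 1L) {
    abort("all instances must have the same number of axes.")
  }
  n <- vapply(data$segment, nrow, integer(1))
  if (length(unique(n)) != 1L) {
    abort("all instances must have the same segment length.")
  }
  if (any(vapply(data$segment, anyNA, logical(1)))) {
    abort("instances must not contain missing values.")
  }
  if (length(unique(data$label)) < min_classes) {
    abort(paste0("dataset must contain at least ", min_classes, " classes."))
  }
  invisible(as_tibble(data))
}

# Deterministic sub-seed derivation: one root seed drives independent,
# stable streams (adding subjects/instances never perturbs earlier ones).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  for (k in idx) {
    s <- (s * 48271 + as.double(k)) %% 2147483647
  }
  as.integer(s)
}

# Axis identifier prefix for SFA words: single digit up to axis 9, a
# delimited decimal prefix beyond ("10|").
axis_prefix <- function(axis_id) {
  axis_id <- as.integer(axis_id)
  ifelse(axis_id <= 9L, as.character(axis_id), paste0(axis_id, "|"))
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  x
}
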