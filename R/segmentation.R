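#' Construct a raw multivariate recording
#'
#' A recording is one continuous multivariate stream from a single subject
#' performing a single activity: a samples matrix (one row per time step, one
#' column per sensor axis), its sampling rate, and the class/subject
#' identifiers its segments will inherit.
#'
#' @param samples Numeric matrix, rows = time steps, columns = axes.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param label Class identifier (character).
#' @param subject Subject identifier (character).
#' @return An object of class `raw_recording`.
#' @examples
#' rec <- raw_recording(cbind(x = sin(1:100), y = cos(1:100), z = 1), 50)
#' @export
raw_recording <- function(samples, sampling_rate, label = NA_character_,
                          subject = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (rows = time, columns = axes).")
  }
  if (ncol(samples) < 1L) abort("a recording needs at least one axis.")
  check_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) abort("`sampling_rate` must be > 0.")
  if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("axis", seq_len(ncol(samples)))
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         label = as.character(label), subject = as.character(subject)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples x %d axes @ %g Hz (subject %s, label %s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate, x$subject, x$label))
  invisible(x)
}

new_dataset_row <- function(segment, label, subject, instance_id) {
  tibble(subject = subject, label = label,
         instance_id = as.integer(instance_id), segment = list(segment))
}

#' Segment a recording with a fixed-size sliding window
#'
#' Cuts a recording into fixed-length instances with a configurable overlap
#' fraction. Windows start every `round(seg_len * (1 - overlap_frac))`
#' samples; a trailing partial window is discarded, never padded. Each
#' instance inherits the recording's label and subject.
#'
#' @param recording A [raw_recording()].
#' @param seg_len Window length in samples (>= 2).
#' @param overlap_frac Overlap fraction in `[0, 1)`; 0.5 halves the stride.
#' @return A tibble of instances (`subject`, `label`, `instance_id`,
#'   `segment`); zero rows when the recording is shorter than one window.
#' @examples
#' rec <- raw_recording(matrix(rnorm(256 * 3), ncol = 3), 50, "walking", "s1")
#' sliding_segments(rec, 128, 0.5) # 3 instances: starts 0, 64, 128
#' @export
sliding_segments <- function(recording, seg_len, overlap_frac = 0) {
  stopifnot(inherits(recording, "raw_recording"))
  seg_len <- as.integer(check_scalar_number(seg_len, "seg_len"))
  if (seg_len < 2L) abort("`seg_len` must be at least 2 samples.")
  check_scalar_number(overlap_frac, "overlap_frac")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must lie in [0, 1).")
  }
  n <- nrow(recording$samples)
  empty <- tibble(subject = character(), label = character(),
                  instance_id = integer(), segment = list())
  if (n < seg_len) return(empty)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap_frac))))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  purrr::map_dfr(seq_along(starts), function(i) {
    s <- starts[i]
    new_dataset_row(recording$samples[s:(s + seg_len - 1L), , drop = FALSE],
                    recording$label, recording$subject, i)
  })
}

#' Per-sample Euclidean magnitude of a tri-axial signal
#'
#' `mag(t) = sqrt(ax(t)^2 + ay(t)^2 + az(t)^2)`. Used by the magnitude-peak
#' segmentation of fall-style recordings and available as a univariate
#' reduction of tri-axial instances.
#'
#' @param x A numeric matrix with exactly 3 columns, a `raw_recording`, or an
#'   instance segment matrix.
#' @return Numeric vector of non-negative magnitudes, one per time step.
#' @examples
#' magnitude(matrix(c(3, 4, 0), nrow = 1)) # 5
#' @export
magnitude <- function(x) {
  if (inherits(x, "raw_recording")) x <- x$samples
  if (!is.matrix(x)) abort("`x` must be a matrix (or raw_recording).")
  if (ncol(x) != 3L) abort("magnitude is defined for exactly 3 axes.")
  sqrt(rowSums(x^2))
}

#' Segment a recording around magnitude peaks
#'
#' Emits one fixed-duration instance centered on every valid threshold
#' crossing of the signal magnitude: a peak at index t is valid iff
#' `mag(t) > threshold` and `mag(t - 1) < threshold`. Windows that would
#' extend past the recording bounds are skipped. With accelerometer data in
#' g units the conventional threshold is 1.5 (1.5 g).
#'
#' @param recording A tri-axial [raw_recording()].
#' @param threshold Magnitude threshold (> 0), in signal units.
#' @param seg_seconds Window duration in seconds; the window length is
#'   `round(seg_seconds * sampling_rate)` samples, with `floor((len - 1) / 2)`
#'   samples before the peak.
#' @return A tibble of instances, possibly empty.
#' @export
peak_segments <- function(recording, threshold = 1.5, seg_seconds = 3) {
  stopifnot(inherits(recording, "raw_recording"))
  check_scalar_number(threshold, "threshold")
  if (threshold <= 0) abort("`threshold` must be > 0.")
  mag <- magnitude(recording)
  n <- length(mag)
  len <- as.integer(round(seg_seconds * recording$sampling_rate))
  before <- (len - 1L) %/% 2L
  peaks <- which(mag[-1] > threshold & mag[-n] < threshold) + 1L
  out <- tibble(subject = character(), label = character(),
                instance_id = integer(), segment = list())
  k <- 0L
  for (t in peaks) {
    s <- t - before
    e <- s + len - 1L
    if (s < 1L || e > n) next
    k <- k + 1L
    out <- dplyr::bind_rows(out, new_dataset_row(
      recording$samples[s:e, , drop = FALSE],
      recording$label, recording$subject, k))
  }
  out
}

#' z-normalize a window
#'
#' Centers and scales a window to mean 0 and population (1/n) standard
#' deviation 1, the normalization that gives SFA words amplitude and offset
#' invariance. Flat windows (sd below `eps`) map to all zeros rather than
#' dividing by ~0.
#'
#' @param window Numeric vector, length >= 2.
#' @param eps Flat-window guard on the population sd.
#' @return Numeric vector of the same length.
#' @examples
#' znormalize_window(c(1, 2, 3))
#' znormalize_window(c(5, 5, 5, 5)) # flat -> zeros
#' @export
znormalize_window <- function(window, eps = .eps_flat) {
  if (!is.numeric(window) || length(window) < 2L) {
    abort("`window` must be a numeric vector of length >= 2.")
  }
  m <- mean(window)
  s <- sqrt(mean((window - m)^2))
  if (s < eps) {
    rep(0, length(window))
  } else {
    (window - m) / s
  }
}

# Population sd of every length-w sliding window, via cumulative sums.
sliding_pop_sd <- function(x, w) {
  n <- length(x)
  c1 <- cumsum(x)
  c2 <- cumsum(x^2)
  s1 <- c1[w:n] - c(0, c1)[seq_len(n - w + 1L)]
  s2 <- c2[w:n] - c(0, c2)[seq_len(n - w + 1L)]
  sqrt(pmax(s2 / w - (s1 / w)^2, 0))
}
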