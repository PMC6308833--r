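# Hand-crafted time/frequency baseline features: 12 per axis, 36 per
# tri-axial instance, the conventional comparison point for symbolic models.

time_feature_names <- c("mean", "median", "min", "max", "variance", "std",
                        "zcr", "rms")
freq_feature_names <- c("dc", "sum_first5_coef", "spectral_energy",
                        "spectral_entropy")

#' Time-domain features of one axis window
#'
#' Mean, median, min, max, variance, standard deviation, zero crossing rate
#' and root mean square, in that order. Variance and sd are
#' population-normalized (1/n); the zero crossing rate is the number of
#' strict sign changes between consecutive samples divided by `n - 1`.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector of length 8.
#' @examples
#' time_features(c(1, -1, 1, -1))["zcr"] # 1
#' @export
time_features <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort("`x` must be a numeric vector of length >= 2.")
  }
  n <- length(x)
  v <- mean((x - mean(x))^2)
  zc <- sum(x[-1] * x[-n] < 0) / (n - 1)
  stats::setNames(
    c(mean(x), median(x), min(x), max(x), v, sqrt(v), zc,
      sqrt(mean(x^2))),
    time_feature_names
  )
}

#' Frequency-domain features of one axis window
#'
#' Four spectral statistics of the 1/n-normalized DFT, using the one-sided
#' spectrum (coefficients 1..floor(n/2)): the DC component `|X0|` (the
#' absolute mean), the sum of the magnitudes of the first five non-DC
#' coefficients, the spectral energy (mean squared magnitude over the
#' one-sided bins) and the spectral entropy of the normalized power spectrum
#' in nats (0 for an all-zero spectrum; a single dominant bin also gives 0,
#' white noise approaches `log` of the bin count).
#'
#' @param x Numeric vector, length >= 8; raw (unnormalized) windows are
#'   expected so the DC component is informative.
#' @return Named numeric vector of length 4.
#' @export
frequency_features <- function(x) {
  if (!is.numeric(x) || length(x) < 8L) {
    abort("`x` must be a numeric vector of length >= 8.")
  }
  n <- length(x)
  spec <- fft(x) / n
  m <- n %/% 2L
  mag <- Mod(spec[2:(m + 1L)]) # one-sided, non-DC
  pw <- mag^2
  total <- sum(pw)
  entropy <- if (total <= 0) {
    0
  } else {
    p <- pw / total
    p <- p[p > 0]
    -sum(p * log(p))
  }
  stats::setNames(
    c(Mod(spec[1L]), sum(mag[seq_len(min(5L, m))]), mean(pw), entropy),
    freq_feature_names
  )
}

#' Hand-crafted feature vector of a tri-axial instance
#'
#' Concatenates the 8 time-domain and 4 frequency-domain features per axis,
#' axis-major (x, then y, then z), yielding 36 named values.
#'
#' @param instance An `n x 3` numeric segment matrix.
#' @return Named numeric vector of length 36.
#' @export
feature_vector <- function(instance) {
  if (!is.matrix(instance) || ncol(instance) != 3L) {
    abort("`instance` must be a matrix with exactly 3 axes.")
  }
  axes <- colnames(instance) %||% c("x", "y", "z")
  out <- unlist(lapply(seq_len(3L), function(i) {
    f <- c(time_features(instance[, i]), frequency_features(instance[, i]))
    stats::setNames(f, paste0(axes[i], "_", names(f)))
  }))
  out
}

#' Feature matrix of a dataset
#'
#' Applies [feature_vector()] to every instance, returning a tibble ready for
#' any external classifier (one row per instance, the 36 features plus
#' subject/label identifiers).
#'
#' @param data A tri-axial dataset tibble.
#' @return A tibble with `subject`, `label`, `instance_id` and 36 feature
#'   columns.
#' @export
feature_matrix <- function(data) {
  data <- validate_dataset(data)
  feats <- do.call(rbind, lapply(data$segment, feature_vector))
  dplyr::bind_cols(
    dplyr::select(data, "subject", "label", "instance_id"),
    as_tibble(as.data.frame(feats))
  )
}
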