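#' SFA parameter set
#'
#' The tunable triple of the symbolic Fourier approximation: window size `w`
#' (samples), word length `l` (symbols) and alphabet size `c`, plus two
#' behavioural flags. With `drop_first_coeff = TRUE` (the default) the DC
#' coefficient X0 is discarded and coefficients X1..X(l/2) are kept, making
#' words invariant to vertical offsets; `normalize = "window"` z-normalizes
#' each sliding window before transformation (amplitude invariance),
#' `"series"` normalizes the whole series once, `"none"` leaves values raw.
#'
#' @param window_size Window size `w` in samples; must be at least
#'   `word_length + 2 * drop_first_coeff` so `l/2` coefficients exist.
#' @param word_length Word length `l`, an even integer in `[4, 16]`.
#' @param alphabet_size Alphabet size `c` in `[2, 26]`; 4 is the
#'   conventional default.
#' @param drop_first_coeff Drop X0 for offset invariance (default `TRUE`).
#' @param normalize One of `"window"`, `"series"`, `"none"`.
#' @return An object of class `sfa_params`.
#' @examples
#' sfa_params(window_size = 30, word_length = 8)
#' @export
sfa_params <- function(window_size, word_length, alphabet_size = 4L,
                       drop_first_coeff = TRUE,
                       normalize = c("window", "series", "none")) {
  normalize <- match.arg(normalize)
  w <- as.integer(check_scalar_number(window_size, "window_size"))
  l <- as.integer(check_scalar_number(word_length, "word_length"))
  cc <- as.integer(check_scalar_number(alphabet_size, "alphabet_size"))
  if (l < 4L || l > 16L || l %% 2L != 0L) {
    abort("`word_length` must be an even integer in [4, 16].")
  }
  if (cc < 2L || cc > 26L) abort("`alphabet_size` must lie in [2, 26].")
  if (w < l + 2L * drop_first_coeff) {
    abort("`window_size` is too small for the requested word length.")
  }
  # the word space must fit a 64-bit count
  count_possible_words(l, cc)
  structure(
    list(window_size = w, word_length = l, alphabet_size = cc,
         drop_first_coeff = isTRUE(drop_first_coeff), normalize = normalize),
    class = "sfa_params"
  )
}

#' @export
print.sfa_params <- function(x, ...) {
  cat(sprintf("<sfa_params> w = %d, l = %d, c = %d, drop X0: %s, normalize: %s\n",
              x$window_size, x$word_length, x$alphabet_size,
              x$drop_first_coeff, x$normalize))
  invisible(x)
}

# Index range of kept Fourier coefficients (0-based frequencies).
kept_coeff_range <- function(word_length, drop_first_coeff) {
  if (drop_first_coeff) seq.int(1L, word_length / 2L)
  else seq.int(0L, word_length / 2L - 1L)
}

# Interleave an (S x m) complex coefficient matrix into (S x 2m) reals
# (real0, imag0, real1, imag1, ...).
interleave_reim <- function(z) {
  s <- nrow(z)
  out <- matrix(0, s, 2L * ncol(z))
  out[, seq.int(1L, by = 2L, length.out = ncol(z))] <- Re(z)
  out[, seq.int(2L, by = 2L, length.out = ncol(z))] <- Im(z)
  out
}

#' Truncated Fourier coefficients of a single window
#'
#' Computes the first `l/2` Fourier coefficients of a window under the
#' normalized transform `X_u = (1/n) * sum_x T(x) exp(-2*pi*i*u*x/n)` (so X0
#' equals the window mean) and returns their interleaved real/imaginary
#' parts, `(Re X, Im X)` per coefficient. With `drop_first_coeff` the kept
#' coefficients are X1..X(l/2) instead of X0..X(l/2 - 1).
#'
#' @param window Numeric vector (the window itself; no normalization is
#'   applied here).
#' @param params An [sfa_params()] (only `word_length` and `drop_first_coeff`
#'   are used), or `NULL` if `word_length` is given directly.
#' @param word_length,drop_first_coeff Overrides used when `params` is NULL.
#' @return Numeric vector of length `word_length`.
#' @examples
#' dft_coefficients(c(1, 2, 3, 4), word_length = 4, drop_first_coeff = FALSE)
#' # (2.5, 0, -0.5, 0.5)
#' @export
dft_coefficients <- function(window, params = NULL,
                             word_length = params$word_length,
                             drop_first_coeff = params$drop_first_coeff) {
  l <- as.integer(word_length)
  drop <- isTRUE(drop_first_coeff)
  if (!is.numeric(window)) abort("`window` must be numeric.")
  if (length(window) < l + 2L * drop) {
    abort("window is too short for the requested number of coefficients.")
  }
  u <- kept_coeff_range(l, drop)
  z <- fft(window)[u + 1L] / length(window)
  drop(interleave_reim(matrix(z, nrow = 1L)))
}

# Recursive sliding (momentary) Fourier transform. Returns the complex
# (n - w + 1) x length(u_set) matrix of 1/w-normalized coefficients of every
# length-w window. Each coefficient obeys the one-step update
#   X_u(s + 1) = exp(2*pi*i*u/w) * (X_u(s) + (T(s + w) - T(s)) / w),
# applied in closed form (cumulative sum) within chunks; the chunk-leading
# window is recomputed directly every `chunk` windows to bound drift.
mft_core <- function(x, w, u_set, chunk = 256L) {
  n <- length(x)
  n_win <- n - w + 1L
  out <- matrix(0i, n_win, length(u_set))
  tw <- exp(2i * pi * u_set / w)
  s <- 1L
  while (s <= n_win) {
    len <- min(chunk, n_win - s + 1L)
    x0 <- fft(x[s:(s + w - 1L)])[u_set + 1L] / w
    out[s, ] <- x0
    if (len > 1L) {
      m <- 0:(len - 2L)
      d <- (x[(s + w):(s + w + len - 2L)] - x[s:(s + len - 2L)]) / w
      for (k in seq_along(u_set)) {
        cum <- cumsum(d * tw[k]^(-m))
        out[s + 1L:(len - 1L), k] <- tw[k]^(m + 1) * (x0[k] + cum)
      }
    }
    s <- s + len
  }
  out
}

#' Sliding-window Fourier coefficients of a series
#'
#' Computes the truncated, 1/w-normalized Fourier coefficients of every
#' length-`w` sliding window of a series (n - w + 1 windows) using a
#' recursive momentary-transform update, equivalent to a direct per-window
#' DFT to well below 1e-8.
#'
#' @param series Numeric vector of length `n >= w`.
#' @param params An [sfa_params()].
#' @return Numeric matrix with `n - w + 1` rows and `word_length` columns of
#'   interleaved real/imaginary coefficient parts; no normalization of the
#'   windows is applied here.
#' @examples
#' p <- sfa_params(30, 8)
#' nrow(mft_sliding_coefficients(rnorm(256), p)) # 227
#' @export
mft_sliding_coefficients <- function(series, params) {
  stopifnot(inherits(params, "sfa_params"))
  w <- params$window_size
  if (!is.numeric(series) || length(series) < w) {
    abort("`series` must be numeric with length >= window_size.")
  }
  u <- kept_coeff_range(params$word_length, params$drop_first_coeff)
  interleave_reim(mft_core(as.numeric(series), w, u))
}

# Sliding coefficients with the params' normalization applied:
# per-window z-normalization rescales each window's coefficients by its
# population sd (the mean cancels in u >= 1 coefficients; X0 of a
# z-normalized window is exactly 0). Flat windows map to all-zero rows.
sliding_norm_coeffs <- function(series, params) {
  series <- as.numeric(series)
  if (params$normalize == "series") {
    series <- znormalize_window(series)
  }
  m <- mft_sliding_coefficients(series, params)
  if (params$normalize == "window") {
    s <- sliding_pop_sd(series, params$window_size)
    scale <- 1 / s
    scale[s < .eps_flat] <- 0
    m <- m * scale
    if (!params$drop_first_coeff) {
      m[, 1:2] <- 0 # X0 of a z-normalized window
    }
  }
  m
}

#' Fit a Multiple Coefficient Binning table
#'
#' Learns per-coefficient quantization intervals by equi-depth binning: each
#' column of the training coefficient matrix is sorted and split into `c`
#' bins of (near-)equal occupancy, the interior breakpoints being the order
#' statistics at ranks `ceiling(a * N / c)` (0-based). Rows of the matrix are
#' the coefficient vectors of individual training windows.
#'
#' @param coeff_matrix Numeric matrix, N rows (training windows) x l columns
#'   (interleaved coefficient parts), N >= `alphabet_size`.
#' @param alphabet_size Number of bins/symbols `c`.
#' @return An object of class `mcb_table`: a `(c + 1) x l` breakpoint matrix
#'   whose first row is `-Inf` and last `+Inf`, plus the ordered alphabet
#'   (lowercase letters).
#' @examples
#' fit_mcb(cbind(c(1, 2, 3, 4), c(4, 3, 2, 1), 0, 0), alphabet_size = 2)
#' @export
fit_mcb <- function(coeff_matrix, alphabet_size) {
  cc <- as.integer(check_scalar_number(alphabet_size, "alphabet_size"))
  if (cc < 2L || cc > 26L) abort("`alphabet_size` must lie in [2, 26].")
  if (!is.matrix(coeff_matrix) || !is.numeric(coeff_matrix) ||
      nrow(coeff_matrix) == 0L) {
    abort("`coeff_matrix` must be a non-empty numeric matrix.")
  }
  n <- nrow(coeff_matrix)
  if (n < cc) abort("need at least `alphabet_size` training rows to fit MCB.")
  l <- ncol(coeff_matrix)
  bp <- matrix(NA_real_, cc + 1L, l)
  bp[1L, ] <- -Inf
  bp[cc + 1L, ] <- Inf
  ranks <- ceiling(seq_len(cc - 1L) * n / cc) + 1L # 1-based order statistics
  for (j in seq_len(l)) {
    bp[2:cc, j] <- sort(coeff_matrix[, j])[ranks]
  }
  structure(
    list(breakpoints = bp, alphabet = letters[seq_len(cc)],
         alphabet_size = cc, word_length = l),
    class = "mcb_table"
  )
}

#' @export
print.mcb_table <- function(x, ...) {
  cat(sprintf("<mcb_table> %d symbols x %d coefficient columns\n",
              x$alphabet_size, x$word_length))
  print(x$breakpoints)
  invisible(x)
}

#' Discretize coefficient vectors into SFA words
#'
#' Maps each coefficient to the alphabet symbol of its half-open quantization
#' interval `[beta(a - 1), beta(a))`: a value equal to an interior breakpoint
#' joins the upper interval; values below all interior breakpoints take the
#' first symbol, values at or above the last take the last symbol.
#'
#' @param coeffs Numeric vector of length `l`, or a matrix with `l` columns
#'   (one word per row).
#' @param mcb A fitted [fit_mcb()] table with matching column count.
#' @return A single word (character scalar) for a vector input, or a
#'   character vector of words for a matrix input.
#' @export
discretize <- function(coeffs, mcb) {
  stopifnot(inherits(mcb, "mcb_table"))
  if (is.matrix(coeffs)) {
    if (ncol(coeffs) != mcb$word_length) {
      abort("`coeffs` column count must equal the MCB column count.")
    }
    sym <- matrix("", nrow(coeffs), ncol(coeffs))
    for (j in seq_len(ncol(coeffs))) {
      interior <- mcb$breakpoints[2:mcb$alphabet_size, j]
      sym[, j] <- mcb$alphabet[findInterval(coeffs[, j], interior) + 1L]
    }
    do.call(paste0, asplit(sym, 2L))
  } else {
    if (length(coeffs) != mcb$word_length) {
      abort("`coeffs` length must equal the MCB column count.")
    }
    discretize(matrix(coeffs, nrow = 1L), mcb)
  }
}

#' Size of the SFA word space
#'
#' `c^l`, the number of distinct words an alphabet of size `c` can form at
#' word length `l`; e.g. `c = 4, l = 16` yields 4,294,967,296.
#'
#' @param word_length Word length `l` (>= 1).
#' @param alphabet_size Alphabet size `c` (>= 1).
#' @return The exact count as a double; errors if the count exceeds a 64-bit
#'   integer.
#' @examples
#' count_possible_words(16, 4)
#' @export
count_possible_words <- function(word_length, alphabet_size) {
  l <- as.integer(check_scalar_number(word_length, "word_length"))
  cc <- as.integer(check_scalar_number(alphabet_size, "alphabet_size"))
  if (l < 1L || cc < 1L) abort("`word_length` and `alphabet_size` must be >= 1.")
  if (l * log2(cc) > 63) {
    abort("word space exceeds a 64-bit count.")
  }
  out <- 1
  for (i in seq_len(l)) out <- out * cc
  out
}
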