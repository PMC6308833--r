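# Shared fixtures and brute-force oracles for the test suite.

# Direct per-window DFT oracle: z-normalize (optionally), take the kept
# coefficients by definition, interleave. Independent of the package's
# sliding-update transform.
oracle_window_coeffs <- function(window, l, drop_first_coeff = TRUE,
                                 znorm = FALSE) {
  if (znorm) window <- znormalize_window(window)
  n <- length(window)
  u_set <- if (drop_first_coeff) 1:(l / 2) else 0:(l / 2 - 1)
  out <- numeric(l)
  for (k in seq_along(u_set)) {
    u <- u_set[k]
    z <- sum(window * exp(-2i * pi * u * (0:(n - 1)) / n)) / n
    out[2 * k - 1] <- Re(z)
    out[2 * k] <- Im(z)
  }
  out
}

# Linear-scan discretization oracle (no binary search / findInterval).
oracle_discretize <- function(coeffs, mcb) {
  sym <- character(length(coeffs))
  for (j in seq_along(coeffs)) {
    a <- 1L
    for (b in 2:mcb$alphabet_size) {
      if (coeffs[j] >= mcb$breakpoints[b, j]) a <- b
    }
    sym[j] <- mcb$alphabet[a]
  }
  paste(sym, collapse = "")
}

# Small multi-class dataset that is quick to transform: 3 well-separated
# dynamic classes.
small_classes <- function() {
  list(
    list(name = "slow", f0 = 1.0, harmonics = c(1.0, 0.4),
         axis_gain = c(1, 0.6, 0.3), offset = c(0.1, 1, 0.2),
         noise_sd = 0.05),
    list(name = "mid", f0 = 2.5, harmonics = c(1.0, 0.3),
         axis_gain = c(0.8, 1, 0.4), offset = c(0.2, 0.9, 0.2),
         noise_sd = 0.05),
    list(name = "fast", f0 = 5.0, harmonics = c(1.0),
         axis_gain = c(1, 0.8, 0.5), offset = c(0.1, 0.9, 0.3),
         noise_sd = 0.05)
  )
}

small_dataset <- function(seed = 42, subjects = 3, instances = 4,
                          classes = small_classes(), seg_len = 64) {
  generate_dataset(generator_config(
    classes = classes, subjects = subjects, instances_per_class = instances,
    sampling_rate = 50, seg_len = seg_len, seed = seed))
}

# Two-class config of the synthetic benchmark: 1 Hz vs 3 Hz fundamentals,
# noise sd 0.05, 50 Hz sampling, 128-sample segments.
two_class_config <- function(seed, subjects = 5, instances = 4,
                             noise_scale = 1) {
  generator_config(
    classes = list(
      list(name = "one_hz", f0 = 1.0, harmonics = c(1.0, 0.3),
           axis_gain = c(1, 0.7, 0.4), offset = c(0.1, 1, 0.2),
           noise_sd = 0.05),
      list(name = "three_hz", f0 = 3.0, harmonics = c(1.0, 0.3),
           axis_gain = c(1, 0.7, 0.4), offset = c(0.1, 1, 0.2),
           noise_sd = 0.05)
    ),
    subjects = subjects, instances_per_class = instances,
    sampling_rate = 50, seg_len = 128, noise_scale = noise_scale, seed = seed)
}

# Tiny labeled histogram fixture with fully disjoint class vocabularies.
disjoint_hists <- function() {
  list(
    hists = list(
      numerosity_reduce(c("1aa", "1aa", "1ab")),
      numerosity_reduce(c("1aa", "1ab", "1ab")),
      numerosity_reduce(c("1cc", "1cd", "1cc")),
      numerosity_reduce(c("1cd", "1cd", "1cc"))
    ),
    labels = c("walk", "walk", "sit", "sit")
  )
}
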