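test_that("truncated DFT uses the 1/n convention and X0 equals the mean", {
  expect_equal(dft_coefficients(c(5, 5, 5, 5), word_length = 4,
                                drop_first_coeff = FALSE),
               c(5, 0, 0, 0))
  expect_equal(dft_coefficients(c(1, 2, 3, 4), word_length = 4,
                                drop_first_coeff = FALSE),
               c(2.5, 0, -0.5, 0.5))
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(sample(16:128, 1))
    cf <- dft_coefficients(x, word_length = 8, drop_first_coeff = FALSE)
    expect_equal(cf[1], mean(x))
  }
  expect_error(dft_coefficients(rnorm(8), word_length = 16,
                                drop_first_coeff = TRUE), "too short")
})

test_that("sliding transform equals the direct per-window DFT", {
  p <- sfa_params(30, 8)
  expect_equal(nrow(mft_sliding_coefficients(rnorm(256), p)), 227L)

  # n = w: a single vector, equal to the direct DFT
  set.seed(8)
  x <- rnorm(30)
  one <- mft_sliding_coefficients(x, p)
  expect_equal(nrow(one), 1L)
  expect_equal(drop(one), dft_coefficients(x, p))
  expect_error(mft_sliding_coefficients(rnorm(20), p), "length")

  # brute-force oracle over random series
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(64)
    p16 <- sfa_params(16, 8)
    m <- mft_sliding_coefficients(x, p16)
    d <- t(vapply(seq_len(64 - 16 + 1),
                  function(s) oracle_window_coeffs(x[s:(s + 15)], 8),
                  numeric(8)))
    expect_lt(max(abs(m - d)), 1e-8)
  }
})

test_that("equi-depth MCB breakpoints are the documented order statistics", {
  m <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1), rep(0, 4), c(10, 20, 30, 40))
  mcb <- fit_mcb(m, 2)
  expect_equal(mcb$breakpoints[2, 1], 3)
  expect_equal(mcb$breakpoints[1, ], rep(-Inf, 4))
  expect_equal(mcb$breakpoints[3, ], rep(Inf, 4))
  # values 1, 2 -> first symbol; 3, 4 -> second; the all-tie column 3
  # collapses its breakpoint onto 0, and 0 joins the upper interval
  expect_equal(discretize(c(1, 1, 0, 10), mcb), "aaba")
  expect_equal(substr(discretize(c(3, 1, 0, 10), mcb), 1, 1), "b")

  # c distinct values and c bins: one value per bin
  mcb6 <- fit_mcb(matrix(c(5, 1, 3, 2, 6, 4), ncol = 1), 6)
  expect_equal(discretize(matrix(1:6, ncol = 1), mcb6),
               letters[1:6])

  expect_error(fit_mcb(matrix(1:2, ncol = 1), 4), "at least")
  expect_error(fit_mcb(matrix(numeric(0), 0, 2), 2), "non-empty")
})

test_that("equi-depth bins hold floor(N/c) to ceiling(N/c) training values", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    cc <- sample(2:6, 1)
    col <- rnorm(n) # tie-free almost surely
    mcb <- fit_mcb(matrix(col, ncol = 1), cc)
    syms <- vapply(col, function(v) discretize(matrix(v, ncol = 1), mcb),
                   character(1))
    occ <- table(factor(syms, levels = mcb$alphabet))
    expect_true(all(occ >= floor(n / cc) & occ <= ceiling(n / cc)),
                info = sprintf("n=%d c=%d occ=%s", n, cc,
                               paste(occ, collapse = ",")))
  }
})

test_that("discretization uses half-open intervals (boundary joins upper)", {
  mcb <- fit_mcb(matrix(c(1, 2, 3, 4), ncol = 1), 2)
  # interior breakpoint is 3; a coefficient exactly equal goes up
  expect_equal(discretize(matrix(3, ncol = 1), mcb), "b")
  expect_equal(discretize(matrix(2.999, ncol = 1), mcb), "a")
  expect_error(discretize(c(1, 2), mcb), "length")
})

test_that("discretization agrees with a linear interval-scan oracle", {
  set.seed(33)
  for (i in 1:20) {
    train <- matrix(rnorm(50 * 6), ncol = 6)
    mcb <- fit_mcb(train, sample(2:8, 1))
    x <- rnorm(6) * 2
    expect_equal(discretize(x, mcb), oracle_discretize(x, mcb))
  }
})

test_that("quantization is monotone within a coefficient column", {
  set.seed(44)
  mcb <- fit_mcb(matrix(rnorm(100), ncol = 1), 5)
  vals <- sort(rnorm(50, sd = 2))
  syms <- vapply(vals, function(v) discretize(matrix(v, ncol = 1), mcb),
                 character(1))
  ranks <- match(syms, mcb$alphabet)
  expect_true(all(diff(ranks) >= 0))
})

test_that("dropping X0 yields offset-invariant words", {
  set.seed(55)
  p <- sfa_params(32, 8, 4, drop_first_coeff = TRUE, normalize = "none")
  x <- rnorm(128)
  cf <- mft_sliding_coefficients(x, p)
  # MCB fitted on independent data so no query value sits exactly on a
  # breakpoint (the invariant is about the offset, not boundary ties)
  mcb <- fit_mcb(mft_sliding_coefficients(rnorm(128), p), 4)
  for (b in c(-10, 3.7, 100)) {
    cf_b <- mft_sliding_coefficients(x + b, p)
    expect_equal(discretize(cf_b, mcb), discretize(cf, mcb))
  }
})

test_that("the word space size is the exact power c^l", {
  expect_identical(count_possible_words(16, 4), 4294967296)
  expect_identical(count_possible_words(1, 1), 1)
  expect_identical(count_possible_words(4, 6), 1296)
  expect_error(count_possible_words(16, 26), "64-bit")
})

test_that("sfa_params validates its invariants", {
  expect_error(sfa_params(30, 5), "even")
  expect_error(sfa_params(30, 18), "even integer in")
  expect_error(sfa_params(30, 8, 1), "alphabet_size")
  expect_error(sfa_params(8, 8, 4, drop_first_coeff = TRUE), "too small")
})
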