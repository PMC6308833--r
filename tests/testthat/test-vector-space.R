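test_that("term frequency is 1 + ln(count), 0 for absent words", {
  h <- mboss:::new_word_histogram(c(aa = 1L, ab = 10L))
  expect_equal(term_frequency(h, "zz"), 0)
  expect_equal(term_frequency(h, "aa"), 1)
  expect_equal(term_frequency(h, "ab"), 1 + log(10))
})

test_that("class term frequency sums counts before the log", {
  hs <- list(mboss:::new_word_histogram(c(w = 3L)),
             mboss:::new_word_histogram(c(v = 2L)),
             mboss:::new_word_histogram(c(w = 4L)))
  expect_equal(class_term_frequency(hs, "w"), 1 + log(7))
  expect_equal(class_term_frequency(hs, "absent"), 0)
  expect_equal(class_term_frequency(hs[1], "w"), term_frequency(hs[[1]], "w"))
})

test_that("idf is ln(classes / classes containing the word)", {
  mk <- function(...) list(mboss:::new_word_histogram(c(...)))
  six <- list(a = mk(p = 1L), b = mk(q = 1L), c = mk(q = 2L),
              d = mk(r = 1L), e = mk(r = 1L), f = mk(s = 1L))
  expect_equal(inverse_document_frequency("p", six), log(6))
  four <- list(a = mk(p = 1L, q = 1L), b = mk(p = 2L), c = mk(q = 1L),
               d = mk(r = 1L))
  expect_equal(inverse_document_frequency("p", four), log(2))
  all4 <- list(a = mk(p = 1L), b = mk(p = 1L), c = mk(p = 1L), d = mk(p = 1L))
  expect_equal(inverse_document_frequency("p", all4), 0)
  expect_error(inverse_document_frequency("zz", four), "no class")
})

test_that("class model weights follow tf * idf and ignore instance order", {
  h1 <- mboss:::new_word_histogram(c(only1 = 1L, shared = 2L))
  h2 <- mboss:::new_word_histogram(c(only2 = 3L, shared = 1L))
  m <- build_class_models(list(h1, h2), c("c1", "c2"))
  w1 <- m$class_models[[1]]$tfidf
  # word in all classes -> weight 0 everywhere
  expect_false("shared" %in% names(w1))
  # word only in class 1 with summed count 1: tf = 1, idf = ln 2
  expect_equal(unname(w1["only1"]), log(2))
  expect_false("only1" %in% names(m$class_models[[2]]$tfidf))
  # instance order is irrelevant
  m2 <- build_class_models(list(h2, h1), c("c2", "c1"))
  expect_equal(m2$class_models, m$class_models)
  expect_error(build_class_models(list(h1, h2), c("c1", "c1")), "2 classes")
})

test_that("model norms equal the root sum of squared weights", {
  d <- disjoint_hists()
  m <- build_class_models(d$hists, d$labels)
  for (cm in m$class_models) {
    expect_equal(cm$norm, sqrt(sum(cm$tfidf^2)), tolerance = 1e-9)
    expect_true(all(cm$tfidf >= 0))
  }
})

test_that("cosine similarity matches its closed forms", {
  model <- list(label = "m", tfidf = c(a = 1, c = 1), norm = sqrt(2))
  expect_equal(cosine_similarity(c(a = 1, b = 1), model), 0.5)
  expect_equal(cosine_similarity(c(b = 2, d = 1), model), 0)
  aligned <- list(label = "m", tfidf = c(a = 2, b = 4), norm = sqrt(20))
  expect_equal(cosine_similarity(c(a = 1, b = 2), aligned), 1)
  expect_equal(cosine_similarity(numeric(0), model), 0)
  expect_equal(cosine_similarity(c(a = 0), model), 0)
})

test_that("similarity is scale invariant in the query", {
  model <- list(label = "m", tfidf = c(a = 0.5, b = 2, c = 1), norm = sqrt(5.25))
  q <- c(a = 1.3, c = 0.4)
  for (k in c(0.1, 7, 1000)) {
    expect_equal(cosine_similarity(k * q, model), cosine_similarity(q, model))
  }
})

test_that("adding model words outside the query never raises the score", {
  q <- c(a = 1, b = 1)
  base <- list(label = "m", tfidf = c(a = 1), norm = 1)
  s0 <- cosine_similarity(q, base)
  grown <- base
  for (extra in c(0.5, 2, 10)) {
    grown$tfidf <- c(base$tfidf, z = extra)
    grown$norm <- sqrt(sum(grown$tfidf^2))
    s1 <- cosine_similarity(q, grown)
    expect_lte(s1, s0)
    s0 <- s1
  }
})

test_that("prediction assigns the argmax class with deterministic ties", {
  d <- disjoint_hists()
  m <- build_class_models(d$hists, d$labels)
  # disjoint vocabularies force similarity 0 to the other class
  pr <- predict(m, d$hists)
  expect_equal(pr$pred, d$labels)
  expect_false(any(pr$flagged))
  expect_true(all(pr$score_walk >= 0 & pr$score_walk <= 1))
  # empty / out-of-vocabulary histogram: first class in order, flagged
  empty <- mboss:::new_word_histogram(stats::setNames(integer(0), character(0)))
  pr0 <- predict(m, list(empty))
  expect_equal(pr0$pred, sort(unique(d$labels))[1])
  expect_true(pr0$flagged)
})

test_that("exact score ties go to the first class in class order", {
  sc <- matrix(c(0.9, 0.9), nrow = 1,
               dimnames = list(NULL, c("walking", "sitting")))
  out <- mboss:::score_table(sc, c("walking", "sitting"))
  expect_equal(out$pred, "walking")
  expect_false(out$flagged)
})

test_that("matrix scoring agrees with the per-word cosine definition", {
  set.seed(77)
  hists <- lapply(1:8, function(i) {
    words <- paste0("1", sample(letters[1:6], sample(3:8, 1), replace = TRUE))
    numerosity_reduce(words)
  })
  labels <- rep(c("u", "v"), each = 4)
  m <- build_class_models(hists, labels)
  pr <- predict(m, hists)
  for (i in seq_along(hists)) {
    h <- hists[[i]]
    q <- stats::setNames(vapply(names(h), function(w) term_frequency(h, w),
                                numeric(1)), names(h))
    expect_equal(pr$score_u[i], cosine_similarity(q, m$class_models[[1]]),
                 tolerance = 1e-12)
    expect_equal(pr$score_v[i], cosine_similarity(q, m$class_models[[2]]),
                 tolerance = 1e-12)
  }
})
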