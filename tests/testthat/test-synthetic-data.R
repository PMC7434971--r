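test_that("identical seed and params give byte-identical corpora", {
  p <- sim_params(n_docs = 10, vocab_size = 80, n_factors = 4,
                  doc_length_range = c(20, 50), seed = 99,
                  shift_index = 5)
  s1 <- generate_corpus(p)
  s2 <- generate_corpus(p)
  expect_identical(s1$corpus$docs$text, s2$corpus$docs$text)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_corpus(sim_params(n_docs = 10, vocab_size = 80,
                                   n_factors = 4,
                                   doc_length_range = c(20, 50),
                                   seed = 100, shift_index = 5))
  expect_false(identical(s1$corpus$docs$text, s3$corpus$docs$text))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(generate_corpus(sim_params(n_docs = 5,
    vocab_size = 40, n_factors = 2, doc_length_range = c(10, 20),
    shift_index = NA, seed = 8))); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("no shift means constant polarization and empty truth index", {
  p <- sim_params(n_docs = 8, vocab_size = 60, n_factors = 3,
                  doc_length_range = c(15, 30),
                  polarization_pre = 0.3, polarization_post = 0.3,
                  shift_index = NA, seed = 4)
  sim <- generate_corpus(p)
  expect_true(is.na(sim$truth$shift_index))
  expect_equal(unique(sim$truth$per_doc_polarization), 0.3)
  expect_length(sim$truth$per_doc_factor, 8L)
})

test_that("invalid configurations error early", {
  expect_error(sim_params(vocab_size = 20, n_factors = 10),
               "configuration error")
  expect_error(sim_params(doc_length_range = c(50, 20)))
  expect_error(sim_params(shift_index = 200))
  expect_error(generate_charge_series(95, var_ratio = 0.5), "var_ratio")
  expect_error(generate_charge_series(5))
  expect_error(generate_charge_series(95, ar = 1.2))
})

test_that("documents stay within the stated length range and vocabulary", {
  p <- sim_params(n_docs = 30, vocab_size = 120, n_factors = 4,
                  doc_length_range = c(25, 60), shift_index = 16, seed = 2)
  sim <- generate_corpus(p)
  lens <- lengths(sim$corpus$tokens)
  expect_true(all(lens >= 25 & lens <= 60))
  expect_gte(mean(lens), 25)
  expect_lte(mean(lens), 60)
  voc <- c(unlist(dreamdyn:::sim_vocabulary(p)$cores),
           dreamdyn:::sim_vocabulary(p)$background)
  expect_true(all(unlist(sim$corpus$tokens) %in% voc))
})

test_that("higher post-shift polarization raises the post-shift maximum
           squared cosine", {
  max_post_cos <- function(post, seed) {
    p <- sim_params(n_docs = 40, vocab_size = 400, n_factors = 4,
                    doc_length_range = c(40, 120),
                    polarization_pre = 0.15, polarization_post = post,
                    shift_index = 21, seed = seed)
    sim <- generate_corpus(p)
    streams <- lemmatize(sim$corpus)
    m <- suppressWarnings(
      build_binary_matrix(streams, rank_and_select_lemmas(streams)))
    sp <- suppressWarnings(fit_correspondence(m, K = 4))
    mean(apply(dream_vectors(sp)[21:40, ], 1, max))
  }
  lo <- vapply(1:20, function(s) max_post_cos(0.30, s), numeric(1))
  hi <- vapply(1:20, function(s) max_post_cos(0.90, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("inflected corpora lemmatize back to the base vocabulary", {
  p <- sim_params(n_docs = 10, vocab_size = 60, n_factors = 3,
                  doc_length_range = c(20, 40), shift_index = NA,
                  inflect = TRUE, seed = 12)
  sim <- generate_corpus(p)
  dict <- synthetic_lemma_dictionary(p)
  raw <- unlist(sim$corpus$tokens)
  voc <- c(unlist(dreamdyn:::sim_vocabulary(p)$cores),
           dreamdyn:::sim_vocabulary(p)$background)
  expect_false(all(raw %in% voc))            # inflector did something
  lem <- unlist(lemmatize(sim$corpus, dict))
  expect_true(all(lem %in% voc))
})

test_that("charge series: determinism, zero-noise, and truth metadata", {
  x1 <- generate_charge_series(50, seed = 5)
  x2 <- generate_charge_series(50, seed = 5)
  expect_identical(as.numeric(x1), as.numeric(x2))
  x0 <- generate_charge_series(20, noise_sd = 0, seed = 1)
  expect_equal(var(diff(as.numeric(x0))), 0)
  xs <- generate_charge_series(95, var_shift_index = 58, var_ratio = 4,
                               seed = 3)
  expect_equal(attr(xs, "truth")$var_shift_index, 58L)
})

test_that("null charge series rarely triggers variance CPA on the
           innovation scale", {
  fp <- vapply(1:50, function(s) {
    x <- generate_charge_series(95, ar = 0, ma = 0, var_shift_index = NA,
                                seed = s)
    !is.na(detect_change(diff(x))$index)
  }, logical(1))
  expect_gte(mean(!fp), 0.9)
})

test_that("a 9x variance shift at 58 is localized within +/-4 in most
           seeds", {
  hits <- vapply(1:50, function(s) {
    x <- generate_charge_series(95, ar = 0, ma = 0, var_shift_index = 58,
                                var_ratio = 9, seed = s)
    k <- detect_change(diff(x))$index
    !is.na(k) && abs((k + 1L) - 58) <= 4
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
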