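test_that("segmentation keeps order, lowercases, splits on non-letters", {
  corpus <- segment_corpus(c("A b, c.", "d e"))
  expect_equal(nrow(corpus$docs), 2L)
  expect_equal(corpus$docs$order_index, 1:2)
  expect_equal(corpus$tokens[[1]], c("a", "b", "c"))
  expect_equal(corpus$tokens[[2]], c("d", "e"))
})

test_that("punctuation-only documents are excluded with a warning", {
  expect_warning(
    corpus <- segment_corpus(c("a b", "?! ... --", "c d")),
    "excluding")
  expect_equal(nrow(corpus$docs), 2L)
  expect_length(corpus$excluded, 1L)
  suppressWarnings(
    expect_error(segment_corpus(c("a b", "...")), "fewer than 2"))
  expect_error(segment_corpus("only one"), "at least 2")
})

test_that("corpus round-trips through the on-disk directory layout", {
  params <- sim_params(n_docs = 12, vocab_size = 60, n_factors = 3,
                       doc_length_range = c(20, 40), shift_index = NA,
                       seed = 42)
  sim <- generate_corpus(params)
  dir <- withr::local_tempdir()
  write_corpus(sim, params, dir)
  reread <- segment_corpus(dir)
  expect_equal(reread$docs$doc_id, sim$corpus$docs$doc_id)
  expect_equal(reread$tokens, sim$corpus$tokens)
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(manifest$order, 1:12)
})

test_that("lemmatization is total and matches the dictionary", {
  corpus <- segment_corpus(c("goes went home", "child children"))
  dict <- c(goes = "go", went = "go", children = "child")
  streams <- lemmatize(corpus, dict)
  expect_equal(streams[[1]], c("go", "go", "home"))
  expect_equal(streams[[2]], c("child", "child"))
  # empty dictionary is the identity
  expect_equal(lemmatize(corpus)[[1]], c("goes", "went", "home"))
})

test_that("lemma dictionary TSV loads with lowercased keys", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Goes\tgo", "WENT\tgo"), path)
  dict <- read_lemma_dictionary(path)
  expect_equal(unname(dict[c("goes", "went")]), c("go", "go"))
})

test_that("frequency ranking drops top 5% then keeps 10% of remainder", {
  # 100 distinct lemmas, strictly decreasing frequency: lemma i occurs
  # 101 - i times -> drop ranks 1..5, keep ranks 6..15
  lemmas <- sprintf("w%03d", 1:100)
  stream <- rep(lemmas, times = 101 - (1:100))
  sel <- rank_and_select_lemmas(list(stream))
  expect_equal(sel, lemmas[6:15], ignore_attr = TRUE)
  log <- attr(sel, "selection_log")
  expect_equal(log$dropped, 5L)
  expect_equal(log$kept, 10L)
})

test_that("selection sizes follow the ceil formulas exactly", {
  for (L in c(20L, 100L, 280L, 1000L)) {
    lemmas <- sprintf("w%04d", seq_len(L))
    stream <- rep(lemmas, times = L + 1 - seq_len(L))
    sel <- rank_and_select_lemmas(list(stream))
    n_drop <- ceiling(0.05 * L)
    expect_length(sel, ceiling(0.10 * (L - n_drop)))
  }
})

test_that("frequency ties break alphabetically and are deterministic", {
  lemmas <- sprintf("w%03d", 1:40)          # all frequency 1
  sel1 <- rank_and_select_lemmas(list(lemmas))
  sel2 <- rank_and_select_lemmas(list(rev(lemmas)))
  expect_equal(sel1, sel2)
  # top 5% alphabetically-first dropped, next 10% kept
  expect_equal(as.character(sel1), lemmas[3:6])
})

test_that("exclude_top_frac = 0 keeps the top 10% of all lemmas", {
  lemmas <- sprintf("w%03d", 1:50)
  stream <- rep(lemmas, times = 51 - (1:50))
  sel <- rank_and_select_lemmas(list(stream), exclude_top_frac = 0)
  expect_equal(as.character(sel), lemmas[1:5])
})

test_that("too few distinct lemmas raises the named threshold", {
  expect_error(rank_and_select_lemmas(list(letters[1:10])), "20 distinct")
})

test_that("binary matrix has indicator semantics and drops empty columns", {
  streams <- list(d1 = c("a", "b"), d2 = c("b", "c", "c", "c"))
  m <- build_binary_matrix(streams, c("a", "b", "c"))
  expect_equal(unclass(m), matrix(c(1L, 0L, 1L, 1L, 0L, 1L), 2, 3,
                                  dimnames = list(c("d1", "d2"),
                                                  c("a", "b", "c"))),
               ignore_attr = TRUE)
  # multiplicity ignored
  expect_equal(unname(m["d2", "c"]), 1L)
  expect_warning(m2 <- build_binary_matrix(streams, c("a", "b", "zz")),
                 "all-zero column")
  expect_equal(colnames(m2), c("a", "b"))
  expect_error(build_binary_matrix(streams, c("zz")), "no overlap")
})

test_that("matrix is invariant to word order and multiplicity; rows
           recount distinct selected lemmas", {
  sim <- generate_corpus(sim_params(n_docs = 20, vocab_size = 200,
                                    n_factors = 4,
                                    doc_length_range = c(30, 60),
                                    shift_index = NA, seed = 3))
  streams <- lemmatize(sim$corpus)
  sel <- rank_and_select_lemmas(streams)
  m <- suppressWarnings(build_binary_matrix(streams, sel))
  recount <- vapply(streams, function(s)
    length(intersect(unique(s), colnames(m))), integer(1))
  expect_equal(unname(rowSums(m)), unname(recount))
  shuffled <- lapply(streams, function(s) rev(rep(s, 2)))
  names(shuffled) <- names(streams)
  m2 <- suppressWarnings(build_binary_matrix(shuffled, sel))
  expect_equal(unclass(m), unclass(m2), ignore_attr = TRUE)
})

test_that("lemma matrix TSV round-trips", {
  m <- build_binary_matrix(list(d1 = c("a", "b"), d2 = c("b", "c")),
                           c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lemma_matrix(m, path)
  m2 <- read_lemma_matrix(path)
  expect_equal(unclass(m)[, ], unclass(m2)[, ], ignore_attr = TRUE)
  expect_equal(rownames(m2), c("d1", "d2"))
})
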