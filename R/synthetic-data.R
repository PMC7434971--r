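#' Parameters of the synthetic dream-corpus generator
#'
#' The defaults restate the corpus the analysis was designed for: 95
#' ordered narratives of 29 to 1,497 words (lengths drawn log-uniformly,
#' which reproduces both extremes and a corpus total near 39k words), a
#' latent structure of 10 co-occurrence factors, and a polarization
#' regime shift at document 58 after which documents concentrate much
#' more strongly on a single topic.
#'
#' @param n_docs Number of ordered documents.
#' @param vocab_size Total vocabulary (topic cores + background);
#'   must be at least `3 * n_factors` so every topic core has >= 3 words.
#' @param n_factors Number of latent topics (disjoint core vocabularies).
#' @param doc_length_range Pair (min, max) document length in words.
#' @param polarization_pre,polarization_post Probability that a word is
#'   drawn from the document's own topic core (vs the shared background)
#'   before / from the shift onward.
#' @param shift_index First document of the post-shift regime, or `NA`
#'   for no shift.
#' @param inflect If `TRUE`, emit suffixed surface variants for a subset
#'   of tokens (exercises lemmatization; [synthetic_lemma_dictionary()]
#'   maps them back).
#' @param seed RNG seed; identical parameters and seed give
#'   byte-identical corpora.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_docs = 95L, vocab_size = 3000L, n_factors = 10L,
                       doc_length_range = c(29L, 1497L),
                       polarization_pre = 0.15, polarization_post = 0.85,
                       shift_index = 58L, inflect = FALSE, seed = 1L) {
  stopifnot(n_docs >= 2L, vocab_size >= 1L, n_factors >= 1L,
            length(doc_length_range) == 2L,
            doc_length_range[1] >= 1L,
            doc_length_range[1] <= doc_length_range[2],
            polarization_pre >= 0, polarization_pre <= 1,
            polarization_post >= 0, polarization_post <= 1)
  if (vocab_size < n_factors * 3L) {
    stop("configuration error: vocab_size must be >= 3 * n_factors ",
         "(topics need at least 3 core words each)")
  }
  if (!is.na(shift_index)) {
    stopifnot(shift_index >= 1L, shift_index <= n_docs)
  }
  structure(list(
    n_docs = as.integer(n_docs), vocab_size = as.integer(vocab_size),
    n_factors = as.integer(n_factors),
    doc_length_range = as.integer(doc_length_range),
    polarization_pre = polarization_pre,
    polarization_post = polarization_post,
    shift_index = if (is.na(shift_index)) NA_integer_
                  else as.integer(shift_index),
    inflect = isTRUE(inflect), seed = as.integer(seed)
  ), class = "sim_params")
}

# Deterministic vocabulary: disjoint topic cores ("t<topic><word>") and a
# shared background pool ("q<word>"); purely alphabetic tokens so the
# non-letter tokenizer keeps them intact.
sim_vocabulary <- function(params) {
  core_each <- max(3L, (params$vocab_size %/% 2L) %/% params$n_factors)
  n_core <- core_each * params$n_factors
  n_bg <- max(params$vocab_size - n_core, 1L)
  cores <- lapply(seq_len(params$n_factors), function(k)
    paste0("t", int2alpha(k), int2alpha(seq_len(core_each))))
  background <- paste0("q", int2alpha(seq_len(n_bg)))
  # Zipf weights: a handful of function-word-like forms dominates, so
  # the 5% exclusion rule has something realistic to remove
  list(cores = cores, background = background,
       bg_weights = 1 / seq_len(n_bg))
}

#' Generate a synthetic ordered corpus with a polarization regime shift
#'
#' Each document is assigned one latent topic; its words are drawn from
#' that topic's disjoint core vocabulary with probability equal to the
#' current polarization and otherwise from a shared Zipf-weighted
#' background pool.  From `shift_index` onward the polarization switches
#' from `polarization_pre` to `polarization_post`, so later documents
#' concentrate on single factors — raising their maximum squared cosine
#' in the recovered factor space and shifting the variance regime of the
#' affective-charge series.  Word forms are emitted pre-lemmatized
#' (lemma = surface form) unless `inflect` is set.
#'
#' @param params A [sim_params()] object.
#' @return List with `corpus` (a `document_corpus`) and `truth` (a
#'   `sim_truth`: `shift_index`, `per_doc_factor`,
#'   `per_doc_polarization`).
#' @export
generate_corpus <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  voc <- sim_vocabulary(params)
  with_seed(params$seed, {
    n <- params$n_docs
    lo <- params$doc_length_range[1]
    hi <- params$doc_length_range[2]
    lengths <- if (lo == hi) rep(lo, n) else
      as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))
    lengths <- pmin(pmax(lengths, lo), hi)
    topics <- sample.int(params$n_factors, n, replace = TRUE)
    pol <- rep(params$polarization_pre, n)
    if (!is.na(params$shift_index)) {
      pol[seq.int(params$shift_index, n)] <- params$polarization_post
    }
    texts <- character(n)
    for (i in seq_len(n)) {
      from_core <- stats::runif(lengths[i]) < pol[i]
      words <- character(lengths[i])
      if (any(from_core)) {
        words[from_core] <- sample(voc$cores[[topics[i]]],
                                   sum(from_core), replace = TRUE)
      }
      if (any(!from_core)) {
        words[!from_core] <- sample(voc$background, sum(!from_core),
                                    replace = TRUE, prob = voc$bg_weights)
      }
      if (params$inflect) {
        words <- inflect_tokens(words)
      }
      texts[i] <- paste(words, collapse = " ")
    }
    corpus <- segment_corpus(
      data.frame(id = sprintf("doc_%04d", seq_len(n)), text = texts,
                 stringsAsFactors = FALSE),
      language_tag = "zxx")
    truth <- structure(list(shift_index = params$shift_index,
                            per_doc_factor = topics,
                            per_doc_polarization = pol),
                       class = "sim_truth")
    list(corpus = corpus, truth = truth)
  })
}

# Suffix inflector: a third of the tokens get a surface variant so the
# lemmatization stage has real work to do.
.sim_suffixes <- c("en", "es")

inflect_tokens <- function(words) {
  pick <- stats::runif(length(words)) < 1 / 3
  suf <- sample(.sim_suffixes, length(words), replace = TRUE)
  words[pick] <- paste0(words[pick], suf[pick])
  words
}

#' Lemma dictionary for the synthetic inflector
#'
#' Maps every suffixed surface variant the inflector can emit back to
#' its base word form.
#' @param params A [sim_params()] object.
#' @return Named character vector (surface -> lemma) for [lemmatize()].
#' @export
synthetic_lemma_dictionary <- function(params) {
  voc <- sim_vocabulary(params)
  base <- c(unlist(voc$cores), voc$background)
  surface <- as.vector(outer(base, .sim_suffixes, paste0))
  stats::setNames(rep(base, times = length(.sim_suffixes)), surface)
}

#' Generate an integrated ARMA(1,1) charge-like series with a variance
#' regime shift
#'
#' Emulates the dynamics of an affective-charge series whose level
#' follows an integrated ARMA process: innovations
#' \eqn{e_t \sim N(0, noise\_sd^2)} have their standard deviation
#' multiplied by `sqrt(var_ratio)` from `var_shift_index` onward, the
#' ARMA(1,1) recursion \eqn{w_t = ar\,w_{t-1} + e_t + ma\,e_{t-1}} is
#' applied, and the path is the cumulative sum of the increments.  The
#' shift acts on the innovations, not on levels, so the mean trend is
#' untouched and only variance/complexity changes.
#'
#' Note the path is integrated, hence variance-nonstationary even
#' without a shift; variance-cost change-point analysis of this
#' generator's output belongs on the first difference (innovation
#' scale), where a change at `var_shift_index` appears at difference
#' index `var_shift_index - 1`.
#'
#' @param n Series length (>= 10).
#' @param ar AR(1) coefficient of the increments, `|ar| < 1`.
#' @param ma MA(1) coefficient of the increments.
#' @param noise_sd Innovation standard deviation before the shift.
#' @param var_shift_index First index of the high-variance regime, or
#'   `NA` for none.
#' @param var_ratio Innovation variance multiplier from the shift onward
#'   (must be >= 1: a shift never decreases variance by construction).
#' @param seed RNG seed.
#' @return Numeric series of length `n` with attribute `truth` (list:
#'   `var_shift_index`, `var_ratio`).
#' @export
generate_charge_series <- function(n, ar = -0.24, ma = 0.8,
                                   noise_sd = 1, var_shift_index = NA,
                                   var_ratio = 1, seed = 1L) {
  stopifnot(n >= 10L, abs(ar) < 1, noise_sd >= 0)
  if (var_ratio < 1) stop("var_ratio must be >= 1")
  if (!is.na(var_shift_index)) {
    stopifnot(var_shift_index >= 1L, var_shift_index <= n)
  }
  with_seed(seed, {
    sds <- rep(noise_sd, n)
    if (!is.na(var_shift_index)) {
      sds[seq.int(var_shift_index, n)] <- noise_sd * sqrt(var_ratio)
    }
    e <- stats::rnorm(n, sd = sds)
    w <- numeric(n)
    w[1] <- e[1]
    for (t in 2:n) w[t] <- ar * w[t - 1] + e[t] + ma * e[t - 1]
    x <- cumsum(w)
    attr(x, "truth") <- list(
      var_shift_index = if (is.na(var_shift_index)) NA_integer_
                        else as.integer(var_shift_index),
      var_ratio = var_ratio)
    x
  })
}

#' Write a synthetic corpus to disk
#'
#' One UTF-8 text file per document (`doc_0001.txt`, ...), a TSV
#' manifest with id, order and ground-truth columns, and the generating
#' parameters echoed to JSON.
#'
#' @param sim Output of [generate_corpus()].
#' @param params The [sim_params()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(sim, params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  docs <- sim$corpus$docs
  for (i in seq_len(nrow(docs))) {
    writeLines(docs$text[i], file.path(dir, paste0(docs$doc_id[i], ".txt")),
               useBytes = TRUE)
  }
  manifest <- data.frame(
    id = docs$doc_id, order = docs$order_index,
    factor = sim$truth$per_doc_factor,
    polarization = sim$truth$per_doc_polarization)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(params), file.path(dir, "params.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
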