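#' Segment raw documents into an ordered corpus of elementary context units
#'
#' Each document becomes one elementary context unit (ECU): here the unit
#' of analysis is the whole narrative, kept in temporal order.  Tokens are
#' lowercased and split on non-letter characters; documents that are empty
#' after tokenization are excluded with a warning.
#'
#' @param x One of: a directory containing one `.txt` file per document
#'   (read in lexicographic filename order, which the synthetic writer
#'   guarantees equals temporal order); a path to a tab-separated file
#'   with columns `id` and `text`; a character vector of document texts;
#'   or a data.frame with columns `id` and `text`.
#' @param language_tag Language label carried along for provenance.
#' @return A `document_corpus`: list with `docs` (data.frame `doc_id`,
#'   `order_index`, `text`), `tokens` (list of character vectors, one per
#'   ECU), `excluded` (character vector of dropped ids) and
#'   `language_tag`.
#' @export
segment_corpus <- function(x, language_tag = "und") {
  df <- as_corpus_frame(x)
  if (nrow(df) < 2L) stop("need at least 2 documents")
  tokens <- lapply(df$text, tokenize_text)
  keep <- lengths(tokens) > 0L
  if (any(!keep)) {
    warning("excluding empty document(s): ",
            paste(df$id[!keep], collapse = ", "))
  }
  if (sum(keep) < 2L) stop("fewer than 2 usable documents after exclusion")
  docs <- data.frame(
    doc_id = as.character(df$id[keep]),
    order_index = seq_len(sum(keep)),
    text = df$text[keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(docs = docs, tokens = tokens[keep],
         excluded = as.character(df$id[!keep]),
         language_tag = language_tag),
    class = "document_corpus"
  )
}

# Normalize the accepted input forms to a two-column frame.
as_corpus_frame <- function(x) {
  if (inherits(x, "document_corpus")) {
    return(data.frame(id = x$docs$doc_id, text = x$docs$text,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "text") %in% names(x)))
    return(x[, c("id", "text")])
  }
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop("no .txt files in ", x)
    return(data.frame(
      id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
              collapse = "\n"), character(1)),
      stringsAsFactors = FALSE
    ))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    df <- utils::read.delim(x, stringsAsFactors = FALSE,
                            colClasses = "character")
    stopifnot(all(c("id", "text") %in% names(df)))
    return(df[, c("id", "text")])
  }
  if (is.character(x)) {
    return(data.frame(id = sprintf("doc_%04d", seq_along(x)), text = x,
                      stringsAsFactors = FALSE))
  }
  stop("unsupported corpus input")
}

tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^[:alpha:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Read a surface-form to lemma dictionary
#'
#' Two-column tab-separated file, surface form then lemma.  Keys are
#' lowercased; lookup is total (unknown forms map to themselves).
#'
#' @param path TSV path, or `NULL` for the empty (identity) dictionary.
#' @return Named character vector usable by [lemmatize()].
#' @export
read_lemma_dictionary <- function(path = NULL) {
  if (is.null(path)) return(stats::setNames(character(0), character(0)))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(ncol(df) >= 2L)
  stats::setNames(tolower(df[[2]]), tolower(df[[1]]))
}

#' Map token streams to lemma streams
#'
#' Replaces each token by its dictionary lemma (e.g. "goes", "went" ->
#' "go"; "children" -> "child"); tokens absent from the dictionary pass
#' through unchanged, so the mapping is total.
#'
#' @param corpus A `document_corpus` from [segment_corpus()].
#' @param dict Named character vector (surface -> lemma), possibly empty.
#' @return List of lemma streams, one character vector per ECU, named by
#'   `doc_id`.
#' @export
lemmatize <- function(corpus, dict = character(0)) {
  stopifnot(inherits(corpus, "document_corpus"))
  streams <- lapply(corpus$tokens, function(toks) {
    hit <- match(toks, names(dict))
    out <- toks
    out[!is.na(hit)] <- unname(dict[hit[!is.na(hit)]])
    out
  })
  names(streams) <- corpus$docs$doc_id
  streams
}

#' Rank lemmas by corpus frequency and apply the exclusion/selection rule
#'
#' Lemmas are ranked by total corpus frequency (descending, ties broken
#' alphabetically).  The top `exclude_top_frac` share (ceiling) is
#' dropped as non-discriminative function words; from the remainder the
#' `select_frac` most frequent share (ceiling of the remainder size) is
#' kept.  The 10% share is taken of the post-exclusion remainder because
#' the procedure is sequential.
#'
#' @param lemma_streams List of lemma streams from [lemmatize()].
#' @param exclude_top_frac Fraction of distinct lemmas dropped from the
#'   top of the ranking (default 0.05).
#' @param select_frac Fraction of the remaining distinct lemmas retained
#'   (default 0.10).
#' @return Character vector of selected lemmas in rank order, with a
#'   `selection_log` attribute recording the counts.
#' @export
rank_and_select_lemmas <- function(lemma_streams, exclude_top_frac = 0.05,
                                   select_frac = 0.10) {
  stopifnot(exclude_top_frac >= 0, exclude_top_frac < 1,
            select_frac > 0, select_frac <= 1)
  freq <- table(unlist(lemma_streams, use.names = FALSE))
  L <- length(freq)
  if (L < 20L) {
    stop("need at least 20 distinct lemmas (got ", L,
         "); both fractions must amount to >= 1 lemma")
  }
  lem <- names(freq)
  ranked <- lem[order(-as.integer(freq), lem)]
  n_drop <- as.integer(ceiling(exclude_top_frac * L))
  n_rest <- L - n_drop
  n_keep <- as.integer(ceiling(select_frac * n_rest))
  selected <- ranked[seq.int(n_drop + 1L, n_drop + n_keep)]
  attr(selected, "selection_log") <- list(
    distinct = L, dropped = n_drop, remainder = n_rest, kept = n_keep)
  selected
}

#' Build the binary document-by-lemma indicator matrix
#'
#' Cell (i, j) is 1 iff lemma j occurs at least once in ECU i (indicator
#' semantics: multiplicity is ignored).  All-zero columns are removed
#' with a warning; all-zero rows are kept so the document series stays
#' full length, but their ids are flagged.
#'
#' @param lemma_streams List of lemma streams (named by doc id).
#' @param selected Character vector of retained lemmas (column order).
#' @return A 0/1 matrix with doc-id rownames and lemma colnames, class
#'   `lemma_matrix`; attribute `zero_rows` lists flagged documents.
#' @export
build_binary_matrix <- function(lemma_streams, selected) {
  stopifnot(length(selected) > 0L)
  ids <- names(lemma_streams) %||% sprintf("doc_%04d", seq_along(lemma_streams))
  m <- do.call(rbind, lapply(lemma_streams,
                             function(s) as.integer(selected %in% s)))
  dimnames(m) <- list(ids, selected)
  zero_col <- colSums(m) == 0L
  if (all(rowSums(m) == 0L)) {
    stop("no overlap between selected lemmas and the corpus")
  }
  if (any(zero_col)) {
    warning("removing all-zero column(s): ",
            paste(colnames(m)[zero_col], collapse = ", "))
    m <- m[, !zero_col, drop = FALSE]
  }
  attr(m, "zero_rows") <- rownames(m)[rowSums(m) == 0L]
  class(m) <- c("lemma_matrix", class(m))
  m
}

#' Write / read a lemma matrix as TSV
#'
#' TSV with a header row of lemmas and a first `doc_id` column.
#' @param m A `lemma_matrix`.
#' @param path Output path.
#' @export
write_lemma_matrix <- function(m, path) {
  df <- data.frame(doc_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lemma_matrix
#' @export
read_lemma_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  attr(m, "zero_rows") <- rownames(m)[rowSums(m) == 0L]
  class(m) <- c("lemma_matrix", class(m))
  m
}
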