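#' Normalize and tokenize the TM corpus
#'
#' Lowercases each text, replaces every punctuation character with a space,
#' splits on whitespace and drops empty strings. Replacing punctuation with a
#' space (rather than deleting it) fragments URLs into separate unigrams
#' ("https", "www", "com", ...), matching how high-frequency web fragments
#' surface as individual tokens in refined topic models of forum text.
#'
#' @param tm_texts A tibble with columns `post_id` and `text` (the `tm`
#'   element of a [build_dual_corpus()] object), or a named character vector.
#' @return A named list of character vectors: one lowercase unigram vector
#'   per post, named by `post_id`. Posts may tokenize to `character(0)`.
#' @examples
#' normalize_and_tokenize(c(p1 = "Hello, WORLD!", p2 = "https://x.org"))
#' @export
normalize_and_tokenize <- function(tm_texts) {
  if (is.data.frame(tm_texts)) {
    texts <- setNames(tm_texts$text, tm_texts$post_id)
  } else {
    texts <- tm_texts
  }
  norm <- gsub("[[:punct:]]+", " ", tolower(texts), perl = TRUE)
  toks <- strsplit(norm, "\\s+", perl = TRUE)
  toks <- lapply(toks, function(w) w[nzchar(w)])
  names(toks) <- names(texts)
  toks
}

#' The SMART stoplist
#'
#' Returns the 571-term SMART (System for the Mechanical Analysis and
#' Retrieval of Text) English stop list bundled with the package, the
#' standard list used to excise terms such as "the" and "of" whose
#' co-occurrences are not indicative of topics.
#'
#' @return Character vector of 571 lowercase terms.
#' @export
smart_stopwords <- function() {
  if (is.null(.fc_cache$smart)) {
    .fc_cache$smart <- readLines(fc_extdata("smart_stoplist.txt"),
                                 encoding = "UTF-8")
  }
  .fc_cache$smart
}

#' Build the modeling vocabulary and prune documents
#'
#' Counts term frequencies on the normalized tokens across all documents,
#' discards terms occurring fewer than `min_count` times, removes stoplist
#' terms, and rewrites every document to contain only surviving terms
#' (token order preserved). Counting happens on normalized forms, so the
#' frequency filter and the stoplist commute.
#'
#' @param docs Named list of token vectors from [normalize_and_tokenize()].
#' @param stoplist Character vector of terms to remove; defaults to
#'   [smart_stopwords()].
#' @param min_count Minimum corpus frequency for a term to be kept
#'   (default 3).
#' @return A list with elements `vocabulary` (tibble `term`, `frequency`,
#'   in first-appearance order) and `docs` (the pruned token lists).
#' @export
build_vocabulary <- function(docs, stoplist = smart_stopwords(),
                             min_count = 3) {
  stopifnot(min_count >= 1)
  all_tokens <- unlist(docs, use.names = FALSE)
  if (length(all_tokens) == 0) {
    stop("all tokens pruned: empty model input")
  }
  freq <- table(factor(all_tokens, levels = unique(all_tokens)))
  keep <- freq >= min_count & !(names(freq) %in% stoplist)
  vocab <- tibble::tibble(term = names(freq)[keep],
                          frequency = as.integer(freq[keep]))
  if (nrow(vocab) == 0) {
    stop("all tokens pruned: empty model input")
  }
  pruned <- lapply(docs, function(w) w[w %in% vocab$term])
  list(vocabulary = vocab, docs = pruned)
}

#' Excise a removal list from vocabulary and documents
#'
#' Removes operator-chosen high-frequency, non-topic-specific terms from the
#' vocabulary and every document, so that a refit produces the refined
#' second-pass topic model. The removal list is a curation artifact (a plain
#' list of terms decided during first-pass coding), not learned. Removing an
#' absent term is a silent no-op; pruning with a removal list is equivalent
#' to building with `stoplist` extended by that list.
#'
#' @param docs Named list of (pruned) token vectors.
#' @param vocabulary Tibble with columns `term`, `frequency`.
#' @param removal_list Character vector of terms to excise.
#' @return A list with elements `vocabulary` and `docs`, as
#'   [build_vocabulary()].
#' @export
refine_tokens <- function(docs, vocabulary, removal_list = character()) {
  vocab <- vocabulary[!(vocabulary$term %in% removal_list), , drop = FALSE]
  pruned <- lapply(docs, function(w) w[!(w %in% removal_list)])
  list(vocabulary = vocab, docs = pruned)
}
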