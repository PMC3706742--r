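#' Build the GO-term index for the thesaurus classifier
#'
#' Indexes the textual material of every non-obsolete GO term (by default
#' name plus synonyms of all scopes) as one small document per term, over
#' which the vector-space ranking runs.
#'
#' @param ontology A `go_ontology`.
#' @param fields Term fields to index, see [term_documents()].
#' @param scopes Synonym scopes to index.
#' @return A `bm25_index` whose `doc_id`s are GO accessions.
#' @export
build_term_index <- function(ontology, fields = c("name", "synonyms"),
                             scopes = c("EXACT", "RELATED", "BROAD", "NARROW")) {
  docs <- term_documents(ontology, fields = fields, scopes = scopes)
  build_index(tibble::tibble(doc_id = docs$go_id, text = docs$text))
}

#' Vector-space ranking of GO terms against a text
#'
#' Scores every GO term document against the input text with BM25 (the text
#' is the query, term name/synonym texts are the corpus) and normalizes
#' the scores to `[0, 1]` by scaling with the maximum (see
#' [normalize_run()]).  This is the first component of the
#' thesaurus-based classifier.
#'
#' @param text Input text.
#' @param ontology A `go_ontology` (used to build `term_index` when absent).
#' @param term_index A `bm25_index` from [build_term_index()]; built on the
#'   fly when `NULL` (convenient, but build it once for many queries).
#' @param top_n Keep at most this many candidates (default all).
#' @return Prediction tibble: `go_id`, `score` in `[0, 1]`, `rank`; ties
#'   broken by ascending GO id.
#' @export
classify_vs <- function(text, ontology = NULL, term_index = NULL,
                        top_n = Inf) {
  if (is.null(term_index)) {
    stopifnot(inherits(ontology, "go_ontology"))
    term_index <- build_term_index(ontology)
  }
  hits <- search_index(term_index, text, top_n = top_n)
  if (nrow(hits) == 0) return(empty_predictions())
  out <- tibble::tibble(go_id = hits$doc_id, score = hits$score)
  rank_predictions(normalize_run(out))
}

#' Recognize GO terms in text by fuzzy pattern matching
#'
#' Compiles every non-obsolete term name and EXACT synonym into a
#' case-insensitive pattern that tolerates (i) runs of whitespace, hyphens
#' or commas between words, (ii) an optional plural "s" on the final word,
#' and (iii) removal of parenthesized qualifiers, and reports every firing.
#' Overlapping matches from different names or terms are all reported.
#'
#' @param text Input text.
#' @param ontology A `go_ontology`.
#' @return Tibble of matches: `go_id`, `matched_text` (surface span),
#'   `matched_source` (the name or synonym that fired), `match_length`
#'   (character count of the source pattern).
#' @export
match_terms <- function(text, ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  live <- ontology$terms[!ontology$terms$is_obsolete, ]
  exact <- ontology$synonyms[ontology$synonyms$scope == "EXACT" &
                               ontology$synonyms$id %in% live$id, ]
  sources <- dplyr::bind_rows(
    tibble::tibble(go_id = live$id, source = live$name),
    tibble::tibble(go_id = exact$id, source = exact$synonym)
  )
  empty <- tibble::tibble(go_id = character(0), matched_text = character(0),
                          matched_source = character(0),
                          match_length = integer(0))
  if (nrow(sources) == 0) return(empty)
  pats <- vapply(sources$source, term_pattern, character(1), USE.NAMES = FALSE)
  ok <- !is.na(pats)
  if (!any(ok)) return(empty)
  sources <- sources[ok, ]
  # one vectorized pass: `text` is recycled against the pattern vector
  hits <- stringr::str_extract_all(
    text, stringr::regex(pats[ok], ignore_case = TRUE))
  n_hit <- lengths(hits)
  if (sum(n_hit) == 0) return(empty)
  tibble::tibble(
    go_id = rep(sources$go_id, n_hit),
    matched_text = unlist(hits, use.names = FALSE),
    matched_source = rep(sources$source, n_hit),
    match_length = rep(nchar(vapply(sources$source, stripped_source,
                                    character(1), USE.NAMES = FALSE)), n_hit)
  )
}

stripped_source <- function(src) {
  stringr::str_squish(stringr::str_remove_all(src, "\\s*\\([^)]*\\)"))
}

term_pattern <- function(src) {
  s <- stripped_source(src)
  words <- stringr::str_split(s, "[\\s,\\-]+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0) return(NA_character_)
  words <- regex_escape(words)
  n <- length(words)
  words[n] <- paste0(words[n], "s?")
  paste0("\\b", paste(words, collapse = "[\\s,\\-]+"), "\\b")
}

#' Thesaurus-based GO classifier
#'
#' Combines the vector-space ranking with the fuzzy-match recognizer: every
#' term recognized in the text ([match_terms()]) receives a boost
#' `1 + vs_score + 0.001 * longest_match`, after which all scores are
#' re-normalized to `[0, 1]`.  Matched terms therefore strictly outrank
#' unmatched ones; among matched terms, ties in vector-space score resolve
#' toward the longer match; unmatched terms keep their vector-space order.
#'
#' @inheritParams classify_vs
#' @param top_n Keep at most this many predictions (default all).
#' @return Prediction tibble: `go_id`, `score` in `[0, 1]`, `rank`.
#' @export
classify_tb <- function(text, ontology, term_index = NULL, top_n = Inf) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (is.null(term_index)) term_index <- build_term_index(ontology)
  vs <- classify_vs(text, ontology, term_index)
  matches <- match_terms(text, ontology)
  if (nrow(matches) == 0) {
    out <- vs
  } else {
    boost <- matches |>
      dplyr::group_by(.data$go_id) |>
      dplyr::summarise(len = max(.data$match_length))
    out <- dplyr::full_join(vs[, c("go_id", "score")], boost, by = "go_id")
    out$score[is.na(out$score)] <- 0
    hit <- !is.na(out$len)
    out$score[hit] <- 1 + out$score[hit] + 0.001 * out$len[hit]
    out$len <- NULL
    out <- rank_predictions(normalize_run(out))
  }
  if (is.finite(top_n)) out <- dplyr::slice_head(out, n = top_n)
  out
}
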