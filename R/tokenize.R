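# Text normalization shared by the document index, the query side and the
# GO-term index: lowercase, split on non-alphanumerics, drop 1-character
# tokens, remove stopwords, Porter-stem.

# Fixed English stopword list (the widely used Snowball list), frozen here
# so that rankings are reproducible across installations.
.go_stopwords <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "would", "should", "could", "ought", "a", "an", "the", "and", "but",
  "if", "or", "because", "as", "until", "while", "of", "at", "by", "for",
  "with", "about", "against", "between", "into", "through", "during",
  "before", "after", "above", "below", "to", "from", "up", "down", "in",
  "out", "on", "off", "over", "under", "again", "further", "then", "once",
  "here", "there", "when", "where", "why", "how", "all", "any", "both",
  "each", "few", "more", "most", "other", "some", "such", "no", "nor",
  "not", "only", "own", "same", "so", "than", "too", "very", "can",
  "will", "just", "don", "now"
)

#' English stopword list used by the tokenizer
#'
#' @return Character vector of stopwords (lowercase, unstemmed).
#' @export
go_stopwords <- function() .go_stopwords

#' Tokenize text for indexing and retrieval
#'
#' Lowercases, splits on any non-alphanumeric character, drops tokens of a
#' single character, removes English stopwords, and Porter-stems the
#' remainder.  Queries and documents go through this same pipeline.
#'
#' @param text Character vector; each element is tokenized independently.
#' @param stem Apply the Porter stemmer (default `TRUE`).
#' @return A list of character vectors of tokens, one per element of `text`.
#'   For convenience, `tokenize1()` returns the bare vector for a single
#'   string.
#' @examples
#' tokenize1("Regulation of secondary shoots")
#' @export
tokenize <- function(text, stem = TRUE) {
  text <- tolower(as.character(text))
  toks <- stringr::str_split(text, "[^a-z0-9]+")
  toks <- lapply(toks, function(x) {
    x[nchar(x) >= 2 & !x %in% .go_stopwords]
  })
  if (stem) {
    # stem the flattened corpus in one pass so the per-unique-token work
    # amortizes across documents
    flat <- unlist(toks, use.names = FALSE)
    if (length(flat)) {
      stems <- porter_stem(flat)
      toks <- utils::relist(stems, toks)
      toks <- lapply(toks, as.character)
    }
  }
  toks
}

#' @rdname tokenize
#' @export
tokenize1 <- function(text, stem = TRUE) {
  stopifnot(length(text) == 1)
  tokenize(text, stem = stem)[[1]]
}
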