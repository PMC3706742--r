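#' Build an inverted index over documents
#'
#' Tokenizes each document with the standard pipeline (lowercase, stopword
#' removal, Porter stemming) and builds token postings for Okapi BM25
#' scoring.  Deterministic for a fixed input order.
#'
#' @param documents Tibble (or data frame) with columns `doc_id` and `text`.
#'   For knowledge-base documents use `pmid` as `doc_id` and title +
#'   abstract as `text`.
#' @return A `bm25_index`: postings (token -> document positions and term
#'   frequencies), per-document token counts, their mean, and the corpus
#'   size `N`.
#' @examples
#' idx <- build_index(tibble::tibble(doc_id = "d1", text = "shoot shoot apex"))
#' search_index(idx, "shoot")
#' @export
build_index <- function(documents) {
  documents <- tibble::as_tibble(documents)
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  doc_ids <- as.character(documents$doc_id)
  if (anyDuplicated(doc_ids)) {
    stop(sprintf("duplicate doc_id '%s'", doc_ids[duplicated(doc_ids)][1]),
         call. = FALSE)
  }
  toks <- tokenize(documents$text)
  doc_lengths <- lengths(toks)
  n <- length(doc_ids)

  postings <- list()
  if (n > 0 && sum(doc_lengths) > 0) {
    long <- data.frame(
      doc = rep.int(seq_len(n), doc_lengths),
      token = unlist(toks, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    counts <- dplyr::count(long, .data$doc, .data$token, name = "tf")
    postings <- split(counts[, c("doc", "tf")], counts$token)
  }

  structure(
    list(postings = postings, doc_ids = doc_ids,
         doc_lengths = as.numeric(doc_lengths),
         avg_doc_length = if (n > 0) mean(doc_lengths) else 0,
         n_docs = n, version = "goclassify-bm25-1"),
    class = "bm25_index"
  )
}

bm25_idf <- function(index, df) {
  # +1 inside the log keeps idf positive even when df > N/2 on tiny corpora
  log((index$n_docs - df + 0.5) / (df + 0.5) + 1)
}

#' Okapi BM25 score of one document for a query
#'
#' Computes `sum over query tokens of idf(t) * tf (k1 + 1) /
#' (tf + k1 (1 - b + b dl / avgdl))` with
#' `idf(t) = ln((N - df + 0.5) / (df + 0.5) + 1)`.  A query token repeated
#' `q` times contributes `q` times.
#'
#' @param index A `bm25_index`.
#' @param query Query text (a single string), tokenized with the document
#'   pipeline.  Pass pre-tokenized input via `tokens` instead.
#' @param doc_id Document identifier present in the index.
#' @param k1,b BM25 constants (saturation and length normalization).
#' @param tokens Optional character vector of already-tokenized query terms;
#'   overrides `query`.
#' @return A non-negative number.
#' @export
bm25_score <- function(index, query = NULL, doc_id, k1 = 1.2, b = 0.75,
                       tokens = NULL) {
  stopifnot(inherits(index, "bm25_index"))
  pos <- match(as.character(doc_id), index$doc_ids)
  if (is.na(pos)) stop(sprintf("unknown doc_id '%s'", doc_id), call. = FALSE)
  q <- if (is.null(tokens)) tokenize1(query) else tokens
  if (length(q) == 0) return(0)
  qtab <- table(q)
  total <- 0
  dl <- index$doc_lengths[pos]
  norm <- k1 * (1 - b + b * dl / max(index$avg_doc_length, .Machine$double.eps))
  for (tok in names(qtab)) {
    p <- index$postings[[tok]]
    if (is.null(p)) next
    i <- match(pos, p$doc)
    if (is.na(i)) next
    tf <- p$tf[i]
    idf <- bm25_idf(index, nrow(p))
    total <- total + qtab[[tok]] * idf * tf * (k1 + 1) / (tf + norm)
  }
  as.numeric(total)
}

#' Rank documents against a query
#'
#' Scores every document sharing at least one token with the query and
#' returns the positive-scoring ones, sorted by score descending with ties
#' broken by ascending `doc_id`.
#'
#' @param index A `bm25_index`.
#' @param query Query text (a single string), tokenized with the document
#'   pipeline.
#' @param top_n Maximum number of results (default all).
#' @param k1,b BM25 constants.
#' @param exclude Character vector of `doc_id`s barred from the result (the
#'   leakage guard for benchmark documents).
#' @param tokens Optional pre-tokenized query; overrides `query`.
#' @return Tibble: `doc_id`, `score`, `rank`.
#' @export
search_index <- function(index, query = NULL, top_n = Inf, k1 = 1.2, b = 0.75,
                         exclude = character(0), tokens = NULL) {
  stopifnot(inherits(index, "bm25_index"), top_n >= 1)
  q <- if (is.null(tokens)) tokenize1(query) else tokens
  empty <- tibble::tibble(doc_id = character(0), score = numeric(0),
                          rank = integer(0))
  if (index$n_docs == 0 || length(q) == 0) return(empty)

  qtab <- table(q)
  scores <- numeric(index$n_docs)
  norm <- k1 * (1 - b + b * index$doc_lengths /
                  max(index$avg_doc_length, .Machine$double.eps))
  for (tok in names(qtab)) {
    p <- index$postings[[tok]]
    if (is.null(p)) next
    idf <- bm25_idf(index, nrow(p))
    contrib <- idf * p$tf * (k1 + 1) / (p$tf + norm[p$doc])
    scores[p$doc] <- scores[p$doc] + qtab[[tok]] * contrib
  }
  if (length(exclude)) scores[index$doc_ids %in% exclude] <- 0

  hit <- which(scores > 0)
  if (length(hit) == 0) return(empty)
  ord <- hit[order(-scores[hit], index$doc_ids[hit])]
  if (is.finite(top_n)) ord <- utils::head(ord, top_n)
  tibble::tibble(doc_id = index$doc_ids[ord], score = scores[ord],
                 rank = seq_along(ord))
}

#' @export
print.bm25_index <- function(x, ...) {
  cat(sprintf("<bm25_index> %d documents, %d distinct tokens, avg length %.1f\n",
              x$n_docs, length(x$postings), x$avg_doc_length))
  invisible(x)
}
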