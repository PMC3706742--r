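#' k-nearest-neighbour GO classifier
#'
#' Assigns GO terms to a free text in two stages: a related-article search
#' retrieves the `k` most similar curated abstracts from the knowledge base
#' (Okapi BM25 over title + abstract), then the gold GO terms of those
#' neighbours are aggregated into a ranked functional profile.  With the
#' default weighted vote, each neighbour votes for its curated terms with
#' its retrieval score, and votes are normalized by the total score mass of
#' the `k` neighbours; with `vote = "uniform"` every neighbour votes 1.
#' A GO term with no annotation in the (possibly temporally filtered)
#' knowledge base can never be predicted.
#'
#' @param text Input text (abstract or article section).
#' @param kb A `go_kb` whose documents are indexed in `index`.
#' @param index A `bm25_index` built over `kb$documents` (`doc_id` = PMID,
#'   text = title + abstract).
#' @param k Neighbourhood size (default 200).  If fewer than `k` documents
#'   score positively, all positive-scoring neighbours are used.
#' @param exclude_pmids PMIDs barred from the neighbour list — pass the
#'   query's own PMID (and all benchmark PMIDs) to prevent leakage.
#' @param vote `"weighted"` (similarity-weighted, default) or `"uniform"`.
#' @param k1,b BM25 constants forwarded to the search.
#' @return Tibble of predictions: `go_id`, `score` in (0, 1], `rank`;
#'   sorted by score descending, ties by ascending GO id.  Scores sum to 1
#'   when every neighbour carries at least one annotation.
#' @export
classify_knn <- function(text, kb, index, k = 200,
                         exclude_pmids = character(0),
                         vote = c("weighted", "uniform"),
                         k1 = 1.2, b = 0.75) {
  stopifnot(inherits(kb, "go_kb"), k >= 1)
  vote <- match.arg(vote)
  if (nrow(kb$documents) == 0 || nrow(kb$triples) == 0) {
    warning("empty knowledge base: no prediction possible", call. = FALSE)
    return(empty_predictions())
  }
  hits <- search_index(index, text, top_n = k, k1 = k1, b = b,
                       exclude = exclude_pmids)
  if (nrow(hits) == 0) return(empty_predictions())
  w <- if (vote == "weighted") hits$score else rep(1, nrow(hits))
  denom <- sum(w)
  votes <- tibble::tibble(pmid = hits$doc_id, w = w) |>
    dplyr::inner_join(kb$triples[, c("go_id", "pmid")], by = "pmid",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$go_id) |>
    dplyr::summarise(score = sum(.data$w) / denom)
  votes <- dplyr::filter(votes, .data$score > 0)
  rank_predictions(votes)
}

#' Per-term annotation coverage of the knowledge base
#'
#' Counts annotation triples per GO term and stratifies terms into the
#' learnability bands used to analyse k-NN behaviour: at least 10 training
#' instances, 1-9 instances, or none at all.  Terms with zero instances are
#' reported only when an ontology is supplied (every non-obsolete term not
#' seen in the knowledge base).
#'
#' @param kb A `go_kb`.
#' @param ontology Optional `go_ontology` contributing the zero stratum.
#' @return A `go_coverage` tibble: `go_id`, `n_annotations`, `stratum`
#'   (factor with levels `">=10"`, `"1-9"`, `"0"`).
#' @export
coverage_report <- function(kb, ontology = NULL) {
  stopifnot(inherits(kb, "go_kb"))
  counts <- dplyr::count(kb$triples, .data$go_id, name = "n_annotations")
  if (!is.null(ontology)) {
    live <- ontology$terms$id[!ontology$terms$is_obsolete]
    zero <- setdiff(live, counts$go_id)
    counts <- dplyr::bind_rows(
      counts, tibble::tibble(go_id = zero, n_annotations = 0L))
  }
  counts$stratum <- factor(
    ifelse(counts$n_annotations >= 10, ">=10",
           ifelse(counts$n_annotations >= 1, "1-9", "0")),
    levels = c(">=10", "1-9", "0")
  )
  out <- dplyr::arrange(counts, dplyr::desc(.data$n_annotations), .data$go_id)
  class(out) <- c("go_coverage", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.go_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$stratum)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "annotations per GO term in the knowledge base",
                  y = "GO terms",
                  title = "Knowledge-base coverage strata") +
    ggplot2::theme_minimal()
}
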