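#' Reciprocal rank of the first correct prediction
#'
#' @param ranked Character vector of predicted GO ids, best first,
#'   duplicate-free.
#' @param gold Character vector of gold GO ids.
#' @return `1 / rank` of the first gold term in `ranked`, or 0 if none
#'   appears.
#' @export
reciprocal_rank <- function(ranked, gold) {
  hit <- which(ranked %in% gold)
  if (length(hit) == 0) 0 else 1 / min(hit)
}

#' Recall at rank k
#'
#' Fraction of the gold GO terms present among the top `k` predictions
#' (inclusive of rank `k`); rankings shorter than `k` are evaluated over
#' the available ranks.
#'
#' @param ranked Character vector of predicted GO ids, best first.
#' @param gold Non-empty character vector of gold GO ids.
#' @param k Cut-off rank (`k >= 1`).
#' @return A number in `[0, 1]`.
#' @export
recall_at_k <- function(ranked, gold, k) {
  stopifnot(k >= 1)
  if (length(gold) == 0) stop("empty gold-term set: query is invalid", call. = FALSE)
  length(intersect(utils::head(ranked, k), gold)) / length(unique(gold))
}

#' Evaluate runs against relevance judgements
#'
#' Computes the Mean Reciprocal Rank and macro-averaged Recall at the given
#' cut-offs over all queries in `qrels`.  Queries for which the run is
#' empty contribute 0 to every metric (they are never dropped, so averages
#' stay comparable across classifiers).
#'
#' @param run Long tibble of predictions: `query_id`, `go_id`, `rank`
#'   (and optionally `score`); within a query, rows are ranked by `rank`.
#' @param qrels Tibble of judgements: `query_id`, `go_id`; or a benchmark
#'   tibble with a `gold_terms` list-column (see [build_benchmark()]).
#' @param ks Recall cut-offs (default 5 and 20).
#' @param average `"macro"` (per-query mean, default) or `"micro"` (pooled
#'   gold terms) for recall.
#' @return A `go_eval` one-row tibble: `n_queries`, `mrr`, and one
#'   `recall_<k>` column per cut-off.
#' @export
evaluate_runs <- function(run, qrels, ks = c(5, 20),
                          average = c("macro", "micro")) {
  average <- match.arg(average)
  qrels <- as_qrels(qrels)
  run <- tibble::as_tibble(run)
  stray <- setdiff(unique(run$query_id), unique(qrels$query_id))
  if (length(stray)) {
    stop(sprintf("run query '%s' has no relevance judgements", stray[1]),
         call. = FALSE)
  }
  gold_by_q <- split(qrels$go_id, qrels$query_id)
  if (nrow(run)) {
    run <- dplyr::arrange(run, .data$query_id, .data$rank)
    ranked_by_q <- split(run$go_id, run$query_id)
  } else {
    ranked_by_q <- list()
  }
  qids <- names(gold_by_q)
  if (length(qids) == 0) {
    out <- tibble::tibble(n_queries = 0L, mrr = NA_real_)
    for (k in ks) out[[paste0("recall_", k)]] <- NA_real_
    class(out) <- c("go_eval", class(out))
    return(out)
  }
  ranked <- lapply(qids, function(q) ranked_by_q[[q]] %||% character(0))
  gold <- gold_by_q[qids]

  rr <- mapply(reciprocal_rank, ranked, gold)
  rec <- lapply(ks, function(k) {
    if (average == "macro") {
      mean(mapply(recall_at_k, ranked, gold, MoreArgs = list(k = k)))
    } else {
      hits <- mapply(function(r, g) length(intersect(utils::head(r, k), g)),
                     ranked, gold)
      sum(hits) / sum(lengths(gold))
    }
  })
  out <- tibble::tibble(n_queries = length(qids), mrr = mean(rr))
  for (i in seq_along(ks)) out[[paste0("recall_", ks[i])]] <- rec[[i]]
  class(out) <- c("go_eval", class(out))
  out
}

as_qrels <- function(x) {
  x <- tibble::as_tibble(x)
  if ("gold_terms" %in% names(x)) {
    x <- tidyr::unnest(x[, c("query_id", "gold_terms")],
                       cols = "gold_terms") |>
      dplyr::rename(go_id = "gold_terms")
  }
  stopifnot(all(c("query_id", "go_id") %in% names(x)))
  if (any(!nzchar(x$go_id))) stop("qrels contain empty GO ids", call. = FALSE)
  dplyr::distinct(x[, c("query_id", "go_id")])
}

#' @exportS3Method generics::tidy
tidy.go_eval <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"n_queries",
                      names_to = "metric", values_to = "value")
}

#' @exportS3Method generics::glance
glance.go_eval <- function(x, ...) tibble::as_tibble(x)

#' Run a classifier over a benchmark
#'
#' Applies a per-query classifier to every benchmark query and stacks the
#' per-query predictions into one long run, truncated to `top` ranks
#' (rank-list truncation keeps run files at the conventional depth).
#'
#' @param benchmark Benchmark tibble from [build_benchmark()] (columns
#'   `query_id`, `text`).
#' @param classify A function `(text, query_id) -> prediction tibble`.
#' @param top Maximum ranks kept per query (default 100).
#' @return Long run tibble: `query_id`, `go_id`, `score`, `rank`.
#' @export
run_classifier <- function(benchmark, classify, top = 100) {
  preds <- purrr::map2(benchmark$text, benchmark$query_id, function(txt, qid) {
    p <- classify(txt, qid)
    p <- utils::head(p, top)
    if (nrow(p)) p$query_id <- qid
    p
  })
  out <- dplyr::bind_rows(preds)
  if (nrow(out) == 0) {
    return(tibble::tibble(query_id = character(0), go_id = character(0),
                          score = numeric(0), rank = integer(0)))
  }
  out[, c("query_id", "go_id", "score", "rank")]
}

#' Simulate classifier performance year by year
#'
#' Re-creates the historical state of the resources for each year `Y`:
#' the knowledge base is restored to its state before `Y`
#' ([temporal_filter()]), the document index is rebuilt, a benchmark of
#' abstracts published in `Y` is sampled, and each classifier is evaluated
#' on it.  Benchmark PMIDs are excluded from retrieval, so no query can be
#' its own neighbour.  The thesaurus classifier sees the ontology for the
#' year (a single ontology may be supplied for all years).
#'
#' @param kb The full (unfiltered) `go_kb`.
#' @param ontology A `go_ontology`, or a named list of them keyed by year.
#' @param years Integer vector of years to simulate.
#' @param n_queries Benchmark size per year.
#' @param seed Integer seed for benchmark sampling.
#' @param k Neighbourhood size of the k-NN classifier.
#' @param weight_ml Fusion weight of the combined classifier.
#' @param classifiers Subset of `c("knn", "tb", "combo")`.
#' @param ks Recall cut-offs.
#' @param top Per-query rank-list truncation.
#' @param benchmark Optional fixed benchmark tibble (`query_id`, `text`,
#'   `gold_terms`) used for every year instead of per-year sampling — e.g.
#'   a held-out synthetic set, to isolate the effect of knowledge-base
#'   growth on one query population.
#' @return A `go_simulation` tibble: one row per (year, classifier) with
#'   `n_queries`, `mrr` and `recall_<k>` columns.  Years with no eligible
#'   resources are skipped with a warning.
#' @export
simulate_years <- function(kb, ontology, years, n_queries, seed,
                           k = 200, weight_ml = 0.7,
                           classifiers = c("knn", "tb", "combo"),
                           ks = c(5, 20), top = 100, benchmark = NULL) {
  stopifnot(inherits(kb, "go_kb"))
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  single_ont <- inherits(ontology, "go_ontology")
  rows <- list()
  for (y in years) {
    ont <- if (single_ont) ontology else ontology[[as.character(y)]]
    if (is.null(ont)) {
      warning(sprintf("no ontology for year %d: skipped", y), call. = FALSE)
      next
    }
    kb_y <- temporal_filter(kb, y)
    bench <- if (!is.null(benchmark)) benchmark else tryCatch(
      build_benchmark(kb, pub_year = y, n = n_queries, seed = seed + y),
      error = function(e) {
        warning(sprintf("year %d skipped: %s", y, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(bench) || nrow(kb_y$documents) == 0) {
      if (!is.null(bench)) {
        warning(sprintf("year %d skipped: empty knowledge base", y),
                call. = FALSE)
      }
      next
    }
    guard <- bench$query_id
    docs <- dplyr::filter(kb_y$documents, !.data$pmid %in% guard)
    idx <- build_index(tibble::tibble(
      doc_id = docs$pmid,
      text = stringr::str_squish(paste(docs$title, docs$abstract))))
    # benchmark triples are dropped by design, so silence the orphan warning
    kb_idx <- suppressWarnings(build_kb(docs, kb_y$triples))
    tidx <- build_term_index(ont)

    runs <- list()
    if (any(c("knn", "combo") %in% classifiers)) {
      runs$knn <- run_classifier(bench, function(txt, qid) {
        suppressWarnings(
          classify_knn(txt, kb_idx, idx, k = k, exclude_pmids = guard))
      }, top = top)
    }
    if (any(c("tb", "combo") %in% classifiers)) {
      runs$tb <- run_classifier(bench, function(txt, qid) {
        classify_tb(txt, ont, tidx)
      }, top = top)
    }
    if ("combo" %in% classifiers) {
      runs$combo <- combine_long_runs(runs$knn, runs$tb, weight_ml, top)
    }
    for (cl in classifiers) {
      ev <- evaluate_runs(runs[[cl]], bench, ks = ks)
      row <- tibble::tibble(year = y, classifier = cl)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(row, tibble::as_tibble(ev))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("go_simulation", class(out))
  out
}

# fuse two long runs query by query
combine_long_runs <- function(run_ml, run_tb, weight_ml, top = 100) {
  qids <- union(unique(run_ml$query_id), unique(run_tb$query_id))
  out <- lapply(qids, function(q) {
    ml <- dplyr::filter(run_ml, .data$query_id == q)
    tb <- dplyr::filter(run_tb, .data$query_id == q)
    cmb <- utils::head(combine_runs(ml, tb, weight_ml), top)
    if (nrow(cmb)) cmb$query_id <- q
    cmb
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(query_id = character(0), go_id = character(0),
                          score = numeric(0), rank = integer(0)))
  }
  out[, c("query_id", "go_id", "score", "rank")]
}

#' @exportS3Method ggplot2::autoplot
autoplot.go_simulation <- function(object, metric = "recall_20", ...) {
  stopifnot(metric %in% names(object))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$year, y = .data[[metric]],
                               colour = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "simulated year", y = metric,
                  title = "Classifier performance under knowledge growth") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.go_simulation <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      cols = -c("year", "classifier", "n_queries"),
                      names_to = "metric", values_to = "value")
}
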