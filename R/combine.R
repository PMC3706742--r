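#' Normalize a prediction run to [0, 1]
#'
#' Scales scores linearly so the maximum maps to 1, preserving order and
#' the natural zero of the score scale (retrieval and vote scores are
#' non-negative, so the implicit minimum is 0).  A single-prediction run
#' and an all-equal run map to 1.0 everywhere: presence in a run is
#' evidence, so degenerate runs keep full weight rather than collapsing to
#' 0.  An empty run stays empty.
#'
#' @param predictions Prediction tibble with `go_id` and `score` columns.
#' @return The same tibble with normalized scores.
#' @export
normalize_run <- function(predictions) {
  if (nrow(predictions) == 0) return(predictions)
  s <- predictions$score
  top <- max(s)
  predictions$score <- if (top <= 0 || max(s) == min(s)) rep(1, length(s))
    else s / top
  predictions
}

#' Linear score-level fusion of the ML and TB runs
#'
#' Combines the k-NN (machine-learning) and thesaurus-based runs for the
#' same query as `w * norm_ml + (1 - w) * norm_tb` after min-max
#' normalization of each run; a term absent from one run contributes 0 from
#' that run.  The default weight of 0.7 on the ML run is the best-performing
#' mixture.
#'
#' @param run_ml,run_tb Prediction tibbles (`go_id`, `score`) for one query.
#' @param weight_ml Weight of the ML run in `[0, 1]` (default 0.7).
#' @return Prediction tibble over the union of both term sets, sorted by
#'   combined score descending, ties by ascending GO id.
#' @examples
#' ml <- tibble::tibble(go_id = c("GO:0000001", "GO:0000002"), score = c(1, 0.5))
#' tb <- tibble::tibble(go_id = c("GO:0000002", "GO:0000003"), score = c(1, 1))
#' combine_runs(ml, tb, weight_ml = 0.7)
#' @export
combine_runs <- function(run_ml, run_tb, weight_ml = 0.7) {
  stopifnot(weight_ml >= 0, weight_ml <= 1)
  ml <- normalize_run(tibble::as_tibble(run_ml)[, c("go_id", "score")])
  tb <- normalize_run(tibble::as_tibble(run_tb)[, c("go_id", "score")])
  merged <- dplyr::full_join(ml, tb, by = "go_id", suffix = c("_ml", "_tb"))
  merged$score_ml[is.na(merged$score_ml)] <- 0
  merged$score_tb[is.na(merged$score_tb)] <- 0
  out <- tibble::tibble(
    go_id = merged$go_id,
    score = weight_ml * merged$score_ml + (1 - weight_ml) * merged$score_tb
  )
  rank_predictions(out)
}
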