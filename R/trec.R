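# TREC-format interchange: run files ("<query> Q0 <doc> <rank> <score>
# <tag>") and qrels files ("<query> 0 <doc> 1"), whitespace-separated, as
# consumed by the standard trec_eval program.

#' Read and write TREC run files
#'
#' @param run Long run tibble: `query_id`, `go_id`, `score`, `rank`.
#' @param path File path.
#' @param run_tag Tag written in the sixth column.
#' @return `write_trec_run()`: `path`, invisibly.  `read_trec_run()`: a run
#'   tibble with a `run_tag` column.
#' @export
write_trec_run <- function(run, path, run_tag = "run") {
  lines <- sprintf("%s Q0 %s %d %.6f %s", run$query_id, run$go_id,
                   as.integer(run$rank), run$score, run_tag)
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_trec_run
#' @export
read_trec_run <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(query_id = character(0), go_id = character(0),
                          score = numeric(0), rank = integer(0),
                          run_tag = character(0)))
  }
  f <- stringr::str_split(stringr::str_trim(lines), "\\s+")
  bad <- which(lengths(f) != 6)
  if (length(bad)) {
    stop(sprintf("run file line %d does not have 6 fields", bad[1]),
         call. = FALSE)
  }
  m <- do.call(rbind, f)
  tibble::tibble(query_id = m[, 1], go_id = m[, 3],
                 score = as.numeric(m[, 5]), rank = as.integer(m[, 4]),
                 run_tag = m[, 6])
}

#' Read and write TREC qrels files
#'
#' @param qrels Tibble `query_id`, `go_id`, or a benchmark tibble with a
#'   `gold_terms` list-column.
#' @param path File path.
#' @return `write_qrels()`: `path`, invisibly.  `read_qrels()`: a tibble
#'   `query_id`, `go_id`.
#' @export
write_qrels <- function(qrels, path) {
  qrels <- as_qrels(qrels)
  readr::write_lines(sprintf("%s 0 %s 1", qrels$query_id, qrels$go_id), path)
  invisible(path)
}

#' @rdname write_qrels
#' @export
read_qrels <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(query_id = character(0), go_id = character(0)))
  }
  f <- stringr::str_split(stringr::str_trim(lines), "\\s+")
  bad <- which(lengths(f) != 4)
  if (length(bad)) {
    stop(sprintf("qrels file line %d does not have 4 fields", bad[1]),
         call. = FALSE)
  }
  m <- do.call(rbind, f)
  tibble::tibble(query_id = m[, 1], go_id = m[, 3])
}
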