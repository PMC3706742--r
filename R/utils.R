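# internal helpers

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# escape regex metacharacters in a literal string
regex_escape <- function(x) {
  stringr::str_replace_all(x, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1")
}

is_go_id <- function(x) grepl("^GO:\\d{7}$", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_predictions <- function() {
  tibble::tibble(go_id = character(0), score = numeric(0), rank = integer(0))
}

rank_predictions <- function(df) {
  df <- dplyr::arrange(df, dplyr::desc(.data$score), .data$go_id)
  df$rank <- seq_len(nrow(df))
  df
}
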