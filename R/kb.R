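#' Parse a GAF annotation file into (GO id, PMID, year) triples
#'
#' Reads a tab-separated Gene Association File and keeps one annotation
#' triple per distinct (GO id, PMID) pair whose reference column carries a
#' `PMID:` reference; gene-product identity is deliberately discarded (the
#' classifiers are paper-centric, not protein-centric).  GO ids are
#' normalized through the ontology's `alt_id` mappings.  The annotation year
#' is the year field of the date column (`YYYYMMDD` or `YYYY/MM/DD`); on
#' duplicate (GO id, PMID) pairs the earliest year is kept, so later updates
#' never postpone a triple.
#'
#' @param file Path to a GAF 2.x file (`!`-prefixed header lines skipped).
#' @param ontology Optional `go_ontology` used to resolve merged accessions.
#' @param text GAF content as a string, as an alternative to `file`.
#' @return Tibble of triples: `go_id`, `pmid`, `year`, `evidence`.  Rows
#'   with an unparseable date are skipped with a warning giving the count.
#' @export
read_gaf <- function(file = NULL, ontology = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(file.exists(file))
    lines <- readr::read_lines(file)
  } else {
    lines <- unlist(stringr::str_split(text, "\n"))
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) {
    return(tibble::tibble(go_id = character(0), pmid = character(0),
                          year = integer(0), evidence = character(0)))
  }
  fields <- stringr::str_split(lines, "\t")
  n_col <- lengths(fields)
  bad_cols <- n_col < 14
  if (any(bad_cols)) {
    warning(sprintf("skipped %d GAF row(s) with fewer than 14 columns",
                    sum(bad_cols)), call. = FALSE)
    fields <- fields[!bad_cols]
  }
  if (length(fields) == 0) {
    return(tibble::tibble(go_id = character(0), pmid = character(0),
                          year = integer(0), evidence = character(0)))
  }
  go_id <- vapply(fields, `[[`, character(1), 5)
  refs <- vapply(fields, `[[`, character(1), 6)
  evidence <- vapply(fields, `[[`, character(1), 7)
  date <- vapply(fields, `[[`, character(1), 14)

  # only annotations evidenced by a publication enter the knowledge base
  pmid <- stringr::str_match(refs, "PMID:(\\d+)")[, 2]
  keep <- !is.na(pmid) & is_go_id(go_id)

  year <- suppressWarnings(as.integer(
    stringr::str_match(date, "^(\\d{4})[/-]?\\d{2}[/-]?\\d{2}\\s*$")[, 2]))
  bad_date <- keep & is.na(year)
  if (any(bad_date)) {
    warning(sprintf("skipped %d GAF row(s) with unparseable dates",
                    sum(bad_date)), call. = FALSE)
  }
  keep <- keep & !is.na(year)

  out <- tibble::tibble(go_id = go_id[keep], pmid = pmid[keep],
                        year = year[keep], evidence = evidence[keep])
  if (!is.null(ontology)) out$go_id <- resolve_go_id(ontology, out$go_id)
  out |>
    dplyr::group_by(.data$go_id, .data$pmid) |>
    dplyr::slice_min(.data$year, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$pmid, .data$go_id)
}

#' Read and write the abstract store
#'
#' The abstract store is a four-column TSV (no header):
#' `pmid<TAB>pub_year<TAB>title<TAB>abstract`, one record per line, UTF-8.
#' Embedded newlines are escaped as `\n`; embedded tabs are illegal.
#'
#' @param file Path to the TSV.
#' @param text Store content as a string, as an alternative to `file`.
#' @return Tibble of documents: `pmid`, `pub_year`, `title`, `abstract`.
#' @export
read_abstract_store <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(file.exists(file))
    lines <- readr::read_lines(file)
  } else {
    lines <- unlist(stringr::str_split(text, "\n"))
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(pmid = character(0), pub_year = integer(0),
                          title = character(0), abstract = character(0)))
  }
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) != 4)
  if (length(bad)) {
    stop(sprintf("abstract store line %d has %d columns (expected 4)",
                 bad[1], lengths(fields)[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  unescape <- function(x) stringr::str_replace_all(x, stringr::fixed("\\n"), "\n")
  tibble::tibble(
    pmid = m[, 1],
    pub_year = as.integer(m[, 2]),
    title = unescape(m[, 3]),
    abstract = unescape(m[, 4])
  )
}

#' @rdname read_abstract_store
#' @param documents Tibble with `pmid`, `pub_year`, `title`, `abstract`.
#' @param path Output file path.
#' @export
write_abstract_store <- function(documents, path) {
  escape <- function(x) {
    x <- stringr::str_replace_all(x, "\t", " ")
    stringr::str_replace_all(x, "\n", "\\\\n")
  }
  lines <- sprintf("%s\t%d\t%s\t%s", documents$pmid,
                   as.integer(documents$pub_year),
                   escape(documents$title), escape(documents$abstract))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Assemble a knowledge base from documents and annotation triples
#'
#' The knowledge base pairs curated documents with their (GO id, PMID, year)
#' annotation triples; it is the training store of the k-NN classifier and
#' the source of evaluation benchmarks.  Triples whose PMID has no document
#' in the store are dropped with a warning.
#'
#' @param documents Tibble: `pmid`, `pub_year`, `title`, `abstract`.
#' @param triples Tibble: `go_id`, `pmid`, `year` (e.g. from [read_gaf()]).
#' @param exclude_iea Drop triples with evidence code `IEA` (electronic
#'   annotation) if an `evidence` column is present.  Default `FALSE`: all
#'   PMID-linked annotations count.
#' @return A `go_kb` object: list with tibbles `documents` and `triples`,
#'   plus `cutoff_year` (`NA` until [temporal_filter()] is applied).
#' @export
build_kb <- function(documents, triples, exclude_iea = FALSE) {
  stopifnot(all(c("pmid", "pub_year", "title", "abstract") %in% names(documents)),
            all(c("go_id", "pmid", "year") %in% names(triples)))
  documents <- dplyr::distinct(tibble::as_tibble(documents), .data$pmid,
                               .keep_all = TRUE)
  triples <- tibble::as_tibble(triples)
  if (exclude_iea && "evidence" %in% names(triples)) {
    triples <- dplyr::filter(triples, .data$evidence != "IEA")
  }
  dup <- duplicated(triples[, c("go_id", "pmid")])
  if (any(dup)) triples <- triples[!dup, ]
  orphan <- !triples$pmid %in% documents$pmid
  if (any(orphan)) {
    warning(sprintf("dropped %d triple(s) whose PMID has no document",
                    sum(orphan)), call. = FALSE)
    triples <- triples[!orphan, ]
  }
  structure(list(documents = documents, triples = triples,
                 cutoff_year = NA_integer_),
            class = "go_kb")
}

#' Restore the knowledge base to its state before a given year
#'
#' Keeps exactly the annotation triples created before `cutoff_year` (the
#' knowledge base "on the 1st of January" of that year); documents left with
#' no surviving triple are removed.  Used to simulate how the classifiers
#' would have performed in past years.
#'
#' @param kb A `go_kb`.
#' @param cutoff_year 4-digit year; triples with `year >= cutoff_year` are
#'   discarded.
#' @return A filtered `go_kb` with `cutoff_year` recorded.
#' @export
temporal_filter <- function(kb, cutoff_year) {
  stopifnot(inherits(kb, "go_kb"), cutoff_year >= 1000, cutoff_year <= 9999)
  triples <- dplyr::filter(kb$triples, .data$year < cutoff_year)
  documents <- dplyr::filter(kb$documents, .data$pmid %in% triples$pmid)
  structure(list(documents = documents, triples = triples,
                 cutoff_year = as.integer(cutoff_year)),
            class = "go_kb")
}

#' Sample an evaluation benchmark from the knowledge base
#'
#' Draws `n` documents of the given publication year uniformly without
#' replacement.  Each benchmark query carries the document's text (title +
#' abstract) and its gold GO-term set (the GO ids of its triples).  The
#' sampled PMIDs must be excluded from the retrieval index at evaluation
#' time; pass them as `exclude_pmids` to [classify_knn()] (done
#' automatically by [simulate_years()]).
#'
#' @param kb A `go_kb`.
#' @param pub_year Publication year to sample from.
#' @param n Number of queries.
#' @param seed Integer seed making the sample reproducible.
#' @param include_empty_abstracts Keep title-only documents (default `FALSE`).
#' @return Tibble of benchmark queries: `query_id` (PMID), `pub_year`,
#'   `text`, and list-column `gold_terms`.
#' @export
build_benchmark <- function(kb, pub_year, n, seed,
                            include_empty_abstracts = FALSE) {
  stopifnot(inherits(kb, "go_kb"), n >= 1)
  gold <- kb$triples |>
    dplyr::group_by(.data$pmid) |>
    dplyr::summarise(gold_terms = list(sort(unique(.data$go_id))))
  eligible <- kb$documents |>
    dplyr::filter(.data$pub_year == !!pub_year, .data$pmid %in% gold$pmid)
  if (!include_empty_abstracts) {
    eligible <- dplyr::filter(eligible, nzchar(stringr::str_trim(.data$abstract)))
  }
  if (nrow(eligible) < n) {
    stop(sprintf("requested %d benchmark documents for %d but only %d are eligible",
                 n, pub_year, nrow(eligible)), call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(eligible), n))
  sampled <- eligible[sort(idx), ]
  tibble::tibble(
    query_id = sampled$pmid,
    pub_year = sampled$pub_year,
    text = stringr::str_squish(paste(sampled$title, sampled$abstract)),
    gold_terms = gold$gold_terms[match(sampled$pmid, gold$pmid)]
  )
}

#' Knowledge-base summary statistics
#'
#' @param kb A `go_kb`.
#' @return One-row tibble: document, triple and distinct-term counts, and
#'   the mean/median number of triples per PMID.
#' @export
kb_stats <- function(kb) {
  stopifnot(inherits(kb, "go_kb"))
  per <- dplyr::count(kb$triples, .data$pmid)
  tibble::tibble(
    n_documents = nrow(kb$documents),
    n_triples = nrow(kb$triples),
    n_terms = dplyr::n_distinct(kb$triples$go_id),
    triples_per_pmid_mean = if (nrow(per)) mean(per$n) else NA_real_,
    triples_per_pmid_median = if (nrow(per)) stats::median(per$n) else NA_real_,
    cutoff_year = kb$cutoff_year
  )
}

#' @export
print.go_kb <- function(x, ...) {
  s <- kb_stats(x)
  cat(sprintf("<go_kb> %d documents, %d triples over %d GO terms%s\n",
              s$n_documents, s$n_triples, s$n_terms,
              if (!is.na(x$cutoff_year))
                sprintf(" (state before %d)", x$cutoff_year) else ""))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.go_kb <- function(x, ...) kb_stats(x)

#' Write annotation triples as a GAF 2.1 file
#'
#' Emits one 17-column row per triple with the PMID in the reference column
#' and the annotation year in the date column, so generated fixtures and
#' real GOA files share the [read_gaf()] code path.
#'
#' @param kb A `go_kb` (or a triples tibble with `go_id`, `pmid`, `year`).
#' @param path Output file path.
#' @export
write_gaf <- function(kb, path) {
  triples <- if (inherits(kb, "go_kb")) kb$triples else kb
  ev <- if ("evidence" %in% names(triples)) triples$evidence else "IMP"
  row <- function(i) {
    paste(c("SynthDB", sprintf("P%06d", i), sprintf("gene%d", i), "",
            triples$go_id[i], paste0("PMID:", triples$pmid[i]), ev[min(i, length(ev))],
            "", "P", "", "", "protein", "taxon:0000", sprintf("%d0101", triples$year[i]),
            "SynthDB", "", ""), collapse = "\t")
  }
  lines <- c("!gaf-version: 2.1",
             vapply(seq_len(nrow(triples)), row, character(1)))
  readr::write_lines(lines, path)
  invisible(path)
}
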