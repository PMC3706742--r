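#' Parse a Gene Ontology OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas from an OBO 1.2 file into a `go_ontology` object:
#' a set of tibbles holding terms, synonyms with their scopes, `is_a`
#' parents, and `alt_id` mappings.  Only `is_a` edges are kept; other
#' `relationship:` lines and unknown tags are ignored.  Obsolete terms are
#' retained (so `alt_id` lookups and audits still work) but expose an empty
#' parent set and are excluded from every classifier vocabulary.
#'
#' The synonym scope is read from the trailing `EXACT`/`RELATED`/`BROAD`/
#' `NARROW` token (bare or bracketed); lines without one default to
#' `RELATED`.  Synonyms identical to the primary name (after case and
#' whitespace normalization) are dropped.
#'
#' @param file Path to an OBO file.
#' @param text Alternatively, the OBO content as a single string or a
#'   character vector of lines.
#' @return A `go_ontology` object: a list with tibbles `terms`
#'   (`id`, `name`, `namespace`, `definition`, `is_obsolete`), `synonyms`
#'   (`id`, `synonym`, `scope`), `parents` (`id`, `parent`), `alt_ids`
#'   (`alt_id`, `id`), and a `release_label` string.
#' @examples
#' obo <- "[Term]\nid: GO:0000001\nname: mitochondrion inheritance\nnamespace: biological_process\n"
#' ont <- read_obo(text = obo)
#' ontology_stats(ont)
#' @export
read_obo <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(file.exists(file))
    lines <- readr::read_lines(file)
  } else {
    lines <- unlist(stringr::str_split(text, "\n"))
  }
  parse_obo_lines(lines)
}

parse_obo_lines <- function(lines) {
  # byte offset of each line start, for parse-error reporting
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))
  release_label <- ""
  dv <- grep("^data-version:", lines, value = TRUE)
  if (length(dv)) release_label <- stringr::str_squish(sub("^data-version:", "", dv[1]))

  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)

  terms <- list(); synonyms <- list(); parents <- list(); alt_ids <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[(s + 1):end]
    block <- block[nzchar(stringr::str_trim(block))]
    parsed <- parse_term_stanza(block, offsets[s])
    terms[[length(terms) + 1]] <- parsed$term
    synonyms[[length(synonyms) + 1]] <- parsed$synonyms
    parents[[length(parents) + 1]] <- parsed$parents
    alt_ids[[length(alt_ids) + 1]] <- parsed$alt_ids
  }

  terms <- dplyr::bind_rows(terms)
  if (nrow(terms) == 0) {
    terms <- tibble::tibble(id = character(0), name = character(0),
                            namespace = character(0), definition = character(0),
                            is_obsolete = logical(0))
  }
  synonyms <- dplyr::bind_rows(synonyms) %||% NULL
  if (is.null(synonyms) || nrow(synonyms) == 0) {
    synonyms <- tibble::tibble(id = character(0), synonym = character(0),
                               scope = character(0))
  }
  parents <- dplyr::bind_rows(parents)
  if (nrow(parents) == 0) {
    parents <- tibble::tibble(id = character(0), parent = character(0))
  }
  alt_ids <- dplyr::bind_rows(alt_ids)
  if (nrow(alt_ids) == 0) {
    alt_ids <- tibble::tibble(alt_id = character(0), id = character(0))
  }

  # obsolete terms expose no parents
  if (nrow(parents)) {
    obs <- terms$id[terms$is_obsolete]
    parents <- dplyr::filter(parents, !.data$id %in% obs)
  }
  # unresolvable parents of live terms are a file defect worth surfacing
  if (nrow(parents)) {
    missing <- setdiff(parents$parent, terms$id)
    if (length(missing)) {
      warning(sprintf("%d is_a parent id(s) do not resolve in this file (e.g. %s)",
                      length(missing), missing[1]), call. = FALSE)
    }
  }

  structure(
    list(terms = terms, synonyms = synonyms, parents = parents,
         alt_ids = alt_ids, release_label = release_label),
    class = "go_ontology"
  )
}

parse_term_stanza <- function(block, byte_offset) {
  tag_lines <- stringr::str_match(block, "^([A-Za-z_]+):\\s*(.*)$")
  tags <- tag_lines[, 2]
  vals <- tag_lines[, 3]

  # the printed form of GO records sometimes labels the accession "GO_id"
  id_val <- vals[!is.na(tags) & tags %in% c("id", "GO_id")]
  if (length(id_val) == 0) {
    stop(sprintf("malformed [Term] stanza at byte offset %d: missing id line",
                 byte_offset), call. = FALSE)
  }
  id <- stringr::str_extract(id_val[1], "GO:\\d{7}")
  if (is.na(id)) {
    stop(sprintf("malformed [Term] stanza at byte offset %d: id '%s' is not a GO accession",
                 byte_offset, id_val[1]), call. = FALSE)
  }

  get1 <- function(tag, default = "") {
    v <- vals[!is.na(tags) & tags == tag]
    if (length(v)) stringr::str_trim(v[1]) else default
  }
  name <- get1("name")
  namespace <- get1("namespace")
  def_raw <- get1("def")
  definition <- stringr::str_match(def_raw, "^[\"'](.*)[\"']")[, 2]
  if (is.na(definition)) definition <- stringr::str_trim(sub("\\[.*\\]$", "", def_raw))
  is_obsolete <- any(grepl("^is_obsolete:\\s*true", block))

  syn_vals <- vals[!is.na(tags) & tags %in% c("synonym", "exact_synonym",
                                              "related_synonym", "broad_synonym",
                                              "narrow_synonym")]
  syn_tags <- tags[!is.na(tags) & tags %in% c("synonym", "exact_synonym",
                                              "related_synonym", "broad_synonym",
                                              "narrow_synonym")]
  syns <- NULL
  if (length(syn_vals)) {
    m <- stringr::str_match(
      syn_vals, "^[\"'](.*?)[\"']\\s*(?:\\[?\\b(EXACT|RELATED|BROAD|NARROW)\\b\\]?)?")
    syn_text <- ifelse(is.na(m[, 2]), stringr::str_trim(syn_vals), m[, 2])
    scope <- m[, 3]
    # pre-1.2 tag spellings carry the scope in the tag name
    scope[is.na(scope) & syn_tags == "exact_synonym"] <- "EXACT"
    scope[is.na(scope) & syn_tags == "related_synonym"] <- "RELATED"
    scope[is.na(scope) & syn_tags == "broad_synonym"] <- "BROAD"
    scope[is.na(scope) & syn_tags == "narrow_synonym"] <- "NARROW"
    scope[is.na(scope)] <- "RELATED"
    keep <- stringr::str_squish(tolower(syn_text)) !=
      stringr::str_squish(tolower(name))
    if (any(keep)) {
      syns <- tibble::tibble(id = id, synonym = syn_text[keep],
                             scope = scope[keep])
      syns <- dplyr::distinct(syns)
    }
  }

  isa_vals <- vals[!is.na(tags) & tags == "is_a"]
  pars <- stringr::str_extract(isa_vals, "GO:\\d{7}")
  pars <- unique(pars[!is.na(pars)])

  alt_vals <- vals[!is.na(tags) & tags == "alt_id"]
  alts <- stringr::str_extract(alt_vals, "GO:\\d{7}")
  alts <- unique(alts[!is.na(alts)])

  list(
    term = tibble::tibble(id = id, name = name, namespace = namespace,
                          definition = definition, is_obsolete = is_obsolete),
    synonyms = syns,
    parents = if (length(pars)) tibble::tibble(id = id, parent = pars) else NULL,
    alt_ids = if (length(alts)) tibble::tibble(alt_id = alts, id = id) else NULL
  )
}

#' Write an ontology back to OBO 1.2
#'
#' Serializes a `go_ontology` so that a parse/serialize/parse round trip
#' reproduces the object field-wise.
#'
#' @param ontology A `go_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "go_ontology"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  if (nzchar(ontology$release_label))
    writeLines(paste0("data-version: ", ontology$release_label), con)
  writeLines("", con)
  for (i in seq_len(nrow(ontology$terms))) {
    t <- ontology$terms[i, ]
    out <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (nzchar(t$namespace)) out <- c(out, paste0("namespace: ", t$namespace))
    if (!is.na(t$definition) && nzchar(t$definition))
      out <- c(out, sprintf("def: \"%s\" []", t$definition))
    al <- ontology$alt_ids$alt_id[ontology$alt_ids$id == t$id]
    out <- c(out, if (length(al)) paste0("alt_id: ", al))
    sy <- ontology$synonyms[ontology$synonyms$id == t$id, ]
    if (nrow(sy))
      out <- c(out, sprintf("synonym: \"%s\" %s []", sy$synonym, sy$scope))
    pa <- ontology$parents$parent[ontology$parents$id == t$id]
    out <- c(out, if (length(pa)) paste0("is_a: ", pa))
    if (t$is_obsolete) out <- c(out, "is_obsolete: true")
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Resolve GO accessions through alt_id mappings
#'
#' Merged (secondary) accessions map to their surviving primary id;
#' accessions that are already primary, or unknown, pass through unchanged.
#'
#' @param ontology A `go_ontology`.
#' @param ids Character vector of GO accessions.
#' @return Character vector of resolved accessions.
#' @export
resolve_go_id <- function(ontology, ids) {
  stopifnot(inherits(ontology, "go_ontology"))
  i <- match(ids, ontology$alt_ids$alt_id)
  out <- ids
  out[!is.na(i)] <- ontology$alt_ids$id[i[!is.na(i)]]
  out
}

#' Look up a term by primary or alternative accession
#'
#' @param ontology A `go_ontology`.
#' @param id One GO accession (primary or `alt_id`).
#' @return A one-row tibble from `ontology$terms`, or zero rows if unknown.
#' @export
get_term <- function(ontology, id) {
  id <- resolve_go_id(ontology, id)
  ontology$terms[ontology$terms$id == id, ]
}

#' Indexable text of GO terms
#'
#' Concatenates the selected text fields of each non-obsolete term, in the
#' order name, synonyms, definition, to form the per-term document that the
#' thesaurus classifier indexes.
#'
#' @param ontology A `go_ontology`.
#' @param fields Subset of `c("name", "synonyms", "definition")`.
#' @param scopes Synonym scopes to include when `"synonyms"` is selected
#'   (default: all scopes).
#' @return `term_documents()`: tibble with `go_id` and `text` for every
#'   non-obsolete term.  `term_document()`: a single string for one term
#'   (an obsolete or unknown accession is an error).
#' @export
term_documents <- function(ontology, fields = c("name", "synonyms"),
                           scopes = c("EXACT", "RELATED", "BROAD", "NARROW")) {
  stopifnot(inherits(ontology, "go_ontology"))
  fields <- match.arg(fields, c("name", "synonyms", "definition"),
                      several.ok = TRUE)
  live <- ontology$terms[!ontology$terms$is_obsolete, ]
  text <- rep("", nrow(live))
  pieces <- list()
  if ("name" %in% fields) pieces$name <- live$name
  if ("synonyms" %in% fields) {
    sy <- ontology$synonyms
    sy <- sy[sy$scope %in% scopes, ]
    agg <- sy |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(syn = paste(.data$synonym, collapse = " "))
    pieces$synonyms <- agg$syn[match(live$id, agg$id)]
  }
  if ("definition" %in% fields) pieces$definition <- live$definition
  if (length(pieces)) {
    mat <- do.call(cbind, lapply(pieces, function(p) {
      p[is.na(p)] <- ""
      p
    }))
    text <- apply(mat, 1, function(r) stringr::str_squish(paste(r, collapse = " ")))
    if (nrow(live) == 0) text <- character(0)
  }
  tibble::tibble(go_id = live$id, text = as.character(text))
}

#' @rdname term_documents
#' @param id One GO accession.
#' @export
term_document <- function(ontology, id, fields = c("name", "synonyms"),
                          scopes = c("EXACT", "RELATED", "BROAD", "NARROW")) {
  t <- get_term(ontology, id)
  if (nrow(t) == 0) stop(sprintf("unknown GO accession '%s'", id), call. = FALSE)
  if (t$is_obsolete)
    stop(sprintf("term %s is obsolete and has no indexable text", t$id),
         call. = FALSE)
  if (length(fields) == 0) return("")
  docs <- term_documents(ontology, fields = fields, scopes = scopes)
  docs$text[docs$go_id == t$id]
}

#' Ontology summary counts
#'
#' Counts non-obsolete terms, their EXACT synonyms, and synonyms of every
#' scope — the per-release statistics used to track vocabulary growth.
#'
#' @param ontology A `go_ontology`.
#' @return One-row tibble: `n_terms`, `n_exact_synonyms`, `n_synonyms`.
#' @export
ontology_stats <- function(ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  live <- ontology$terms$id[!ontology$terms$is_obsolete]
  sy <- ontology$synonyms[ontology$synonyms$id %in% live, ]
  tibble::tibble(
    n_terms = length(live),
    n_exact_synonyms = sum(sy$scope == "EXACT"),
    n_synonyms = nrow(sy)
  )
}

#' @export
print.go_ontology <- function(x, ...) {
  s <- ontology_stats(x)
  cat(sprintf("<go_ontology> %d terms (%d obsolete), %d synonyms (%d EXACT)%s\n",
              nrow(x$terms), sum(x$terms$is_obsolete), nrow(x$synonyms),
              s$n_exact_synonyms,
              if (nzchar(x$release_label)) paste0(", release ", x$release_label) else ""))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.go_ontology <- function(x, ...) ontology_stats(x)
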