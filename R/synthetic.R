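#' Configuration of the synthetic corpus generator
#'
#' The generator emulates, at desk scale, a curated-literature knowledge
#' base: a mini-ontology whose terms own disjoint signature vocabularies,
#' and abstracts whose tokens are a mixture of their curated terms'
#' signatures and a shared background vocabulary.  Because the
#' term-to-vocabulary mapping is known, recovery of the curated terms by
#' the classifiers can be measured exactly.
#'
#' Defaults describe a corpus in which each of 50 terms has 40 curated
#' abstracts, abstracts carry 2.8 curated terms on average (the typical
#' curation density of GOA-annotated abstracts), 60% of an abstract's 120
#' tokens come from its terms' signatures, and publication years span
#' 2006-2012 so temporal filtering has non-trivial strata.
#'
#' @param n_terms Number of GO terms in the mini-ontology.
#' @param n_synonyms_per_term EXACT synonyms per term (3-word phrases drawn
#'   from the term's signature, distinct from the name).
#' @param signature_vocab_size Signature tokens per term; must be at least
#'   `3 * (1 + n_synonyms_per_term)` so name and synonym phrases are
#'   disjoint.
#' @param background_vocab_size Shared background tokens.
#' @param docs_per_term Curated abstracts for which each term is the
#'   primary annotation.
#' @param terms_per_doc Mean curated terms per abstract (Poisson-like,
#'   minimum 1).
#' @param signature_fraction Fraction of an abstract's tokens drawn from
#'   its terms' signatures (the rest are background noise).
#' @param doc_length Tokens per abstract.
#' @param year_range Length-2 integer vector, first and last publication
#'   year.
#' @param seed Integer seed; all outputs are reproducible under it.
#' @param inject_name Append each held-out abstract's term name verbatim,
#'   so the fuzzy-match recognizer is guaranteed to fire.
#' @param overlap_fraction Fraction of each term's signature slots filled
#'   with background tokens instead of term-private ones (0 keeps
#'   signatures fully disjoint; larger values make the task harder).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_terms = 50, n_synonyms_per_term = 2,
                         signature_vocab_size = 12,
                         background_vocab_size = 500,
                         docs_per_term = 40, terms_per_doc = 2.8,
                         signature_fraction = 0.6, doc_length = 120,
                         year_range = c(2006, 2012), seed = 42,
                         inject_name = FALSE, overlap_fraction = 0) {
  cfg <- list(n_terms = n_terms, n_synonyms_per_term = n_synonyms_per_term,
              signature_vocab_size = signature_vocab_size,
              background_vocab_size = background_vocab_size,
              docs_per_term = docs_per_term, terms_per_doc = terms_per_doc,
              signature_fraction = signature_fraction,
              doc_length = doc_length, year_range = as.integer(year_range),
              seed = seed, inject_name = inject_name,
              overlap_fraction = overlap_fraction)
  stopifnot(n_terms >= 1, docs_per_term >= 1, doc_length >= 1,
            terms_per_doc >= 1, signature_fraction > 0,
            signature_fraction <= 1, length(year_range) == 2,
            year_range[1] <= year_range[2],
            overlap_fraction >= 0, overlap_fraction < 1)
  if (signature_vocab_size < 3 * (1 + n_synonyms_per_term)) {
    stop(sprintf(
      "signature_vocab_size %d is too small for a name plus %d synonym phrase(s); need >= %d",
      signature_vocab_size, n_synonyms_per_term,
      3 * (1 + n_synonyms_per_term)), call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# pipeline-stable pseudo-words: consonant-only strings (no vowels, y, s, l)
# pass through tokenization and the Porter stemmer unchanged
synth_tokens <- function(n) {
  alphabet <- c("b", "c", "d", "f", "g", "h", "j", "k", "m", "n",
                "p", "q", "r", "t", "v", "w", "x", "z")
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(2 * (n - length(out))), function(i) {
      paste(sample(alphabet, 7, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate a synthetic ontology, knowledge base and held-out benchmark
#'
#' See [synth_config()] for the generative model.  Term names are 3-word
#' phrases from the term's signature vocabulary; synonyms are further
#' disjoint signature phrases (scope EXACT).  Each abstract draws each of
#' its tokens from its terms' pooled signatures with probability
#' `signature_fraction`, otherwise from the background; annotation years
#' equal the publication year plus a 0-2 year curation delay.  One held-out
#' abstract per term (gold term = that term) is generated with the same
#' model and excluded from the knowledge base; synthetic PMIDs are 9-digit
#' integers above 900000000.
#'
#' @param config A `synth_config`.
#' @return A `synth_corpus` list: `ontology` (`go_ontology`), `kb`
#'   (`go_kb`), and `heldout` (benchmark tibble with `query_id`, `pub_year`,
#'   `text`, `gold_terms`).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  n_sig_total <- cfg$n_terms * cfg$signature_vocab_size
  pool <- synth_tokens(n_sig_total + cfg$background_vocab_size)
  background <- pool[seq_len(cfg$background_vocab_size)]
  sig_pool <- pool[-seq_len(cfg$background_vocab_size)]
  signatures <- split(sig_pool,
                      rep(seq_len(cfg$n_terms), each = cfg$signature_vocab_size))
  if (cfg$overlap_fraction > 0) {
    n_swap <- floor(cfg$overlap_fraction * cfg$signature_vocab_size)
    signatures <- lapply(signatures, function(s) {
      if (n_swap > 0) s[seq_len(n_swap)] <- sample(background, n_swap)
      s
    })
  }

  go_ids <- sprintf("GO:%07d", 9000000 + seq_len(cfg$n_terms))
  names_ <- vapply(signatures, function(s) paste(s[1:3], collapse = " "),
                   character(1))
  syn_rows <- list()
  if (cfg$n_synonyms_per_term > 0) {
    for (i in seq_len(cfg$n_terms)) {
      for (j in seq_len(cfg$n_synonyms_per_term)) {
        phrase <- paste(signatures[[i]][(3 * j + 1):(3 * j + 3)], collapse = " ")
        syn_rows[[length(syn_rows) + 1]] <-
          tibble::tibble(id = go_ids[i], synonym = phrase, scope = "EXACT")
      }
    }
  }
  ontology <- structure(list(
    terms = tibble::tibble(id = go_ids, name = unname(names_),
                           namespace = "biological_process",
                           definition = "", is_obsolete = FALSE),
    synonyms = if (length(syn_rows)) dplyr::bind_rows(syn_rows) else
      tibble::tibble(id = character(0), synonym = character(0),
                     scope = character(0)),
    parents = tibble::tibble(id = character(0), parent = character(0)),
    alt_ids = tibble::tibble(alt_id = character(0), id = character(0)),
    release_label = sprintf("synthetic-seed%d", cfg$seed)
  ), class = "go_ontology")

  make_doc <- function(term_idx) {
    sig <- unique(unlist(signatures[term_idx], use.names = FALSE))
    from_sig <- stats::runif(cfg$doc_length) < cfg$signature_fraction
    toks <- character(cfg$doc_length)
    toks[from_sig] <- sample(sig, sum(from_sig), replace = TRUE)
    toks[!from_sig] <- sample(background, sum(!from_sig), replace = TRUE)
    # the title is the head of the same mixture stream, so the signature
    # fraction governs the whole indexed text (title + abstract)
    n_title <- min(3, cfg$doc_length)
    list(title = paste(toks[seq_len(n_title)], collapse = " "),
         abstract = paste(toks[-seq_len(n_title)], collapse = " "))
  }

  n_docs <- cfg$n_terms * cfg$docs_per_term
  years <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n_docs,
                  replace = TRUE)
  primary <- rep(seq_len(cfg$n_terms), each = cfg$docs_per_term)
  docs <- vector("list", n_docs)
  triples <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    extra <- stats::rpois(1, max(cfg$terms_per_doc - 1, 0))
    extra <- min(extra, cfg$n_terms - 1)
    others <- setdiff(seq_len(cfg$n_terms), primary[d])
    terms_d <- c(primary[d],
                 if (extra > 0) sample(others, extra) else integer(0))
    doc <- make_doc(terms_d)
    pmid <- as.character(900000000 + d)
    docs[[d]] <- tibble::tibble(pmid = pmid, pub_year = years[d],
                                title = doc$title, abstract = doc$abstract)
    triples[[d]] <- tibble::tibble(
      go_id = go_ids[terms_d], pmid = pmid,
      year = years[d] + sample(0:2, length(terms_d), replace = TRUE))
  }
  kb <- build_kb(dplyr::bind_rows(docs), dplyr::bind_rows(triples))

  held <- vector("list", cfg$n_terms)
  for (i in seq_len(cfg$n_terms)) {
    doc <- make_doc(i)
    text <- stringr::str_squish(paste(doc$title, doc$abstract))
    if (cfg$inject_name) text <- paste(text, names_[[i]])
    held[[i]] <- tibble::tibble(
      query_id = as.character(910000000 + i),
      pub_year = cfg$year_range[2],
      text = text,
      gold_terms = list(go_ids[i]))
  }

  structure(list(ontology = ontology, kb = kb,
                 heldout = dplyr::bind_rows(held), config = cfg),
            class = "synth_corpus")
}

#' Write a synthetic corpus as the standard file formats
#'
#' Emits `go.obo` (OBO 1.2), `annotations.gaf` (GAF 2.1), `abstracts.tsv`
#' (the abstract-store TSV, including the held-out abstracts) and
#' `qrels.txt` (TREC qrels for the held-out benchmark) into a directory, so
#' synthetic fixtures exercise exactly the readers the real data go
#' through.
#'
#' @param corpus A `synth_corpus` from [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_files <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synth_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(obo = file.path(dir, "go.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             abstracts = file.path(dir, "abstracts.tsv"),
             qrels = file.path(dir, "qrels.txt"))
  write_obo(corpus$ontology, paths[["obo"]])
  write_gaf(corpus$kb, paths[["gaf"]])
  heldout_docs <- tibble::tibble(
    pmid = corpus$heldout$query_id,
    pub_year = corpus$heldout$pub_year,
    title = "",
    abstract = corpus$heldout$text)
  write_abstract_store(dplyr::bind_rows(corpus$kb$documents, heldout_docs),
                       paths[["abstracts"]])
  write_qrels(corpus$heldout, paths[["qrels"]])
  invisible(paths)
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf("<synth_corpus> %d terms, %d documents, %d triples, %d held-out queries\n",
              nrow(x$ontology$terms), nrow(x$kb$documents),
              nrow(x$kb$triples), nrow(x$heldout)))
  invisible(x)
}
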