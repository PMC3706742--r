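# Independent oracles used across the suite.  These deliberately avoid the
# package's own computation paths: plain loops and literal formulas only.

# Evaluate a TREC run file against a TREC qrels file the way the standard
# trec_eval program does: within a query, results are ordered by score
# descending with ties broken by document id *descending*; recip_rank and
# recall_k are averaged over every query in the qrels (queries absent from
# the run score 0).
oracle_eval_trec <- function(run_path, qrels_path, ks = c(5, 20)) {
  qr <- strsplit(trimws(readLines(qrels_path)), "\\s+")
  gold <- list()
  for (f in qr) gold[[f[1]]] <- c(gold[[f[1]]], f[3])

  rl <- strsplit(trimws(readLines(run_path)), "\\s+")
  docs <- list(); scores <- list()
  for (f in rl) {
    docs[[f[1]]] <- c(docs[[f[1]]], f[3])
    scores[[f[1]]] <- c(scores[[f[1]]], as.numeric(f[5]))
  }

  qids <- names(gold)
  rr <- numeric(length(qids))
  rec <- matrix(0, length(qids), length(ks))
  for (i in seq_along(qids)) {
    q <- qids[i]
    g <- unique(gold[[q]])
    d <- docs[[q]]
    if (is.null(d)) next
    o <- order(-scores[[q]], -xtfrm(d))
    d <- d[o]
    pos <- which(d %in% g)
    rr[i] <- if (length(pos)) 1 / pos[1] else 0
    for (j in seq_along(ks)) {
      rec[i, j] <- length(intersect(d[seq_len(min(ks[j], length(d)))], g)) /
        length(g)
    }
  }
  list(mrr = mean(rr), recall = colMeans(rec))
}

# Brute-force Okapi BM25 over a tokenized corpus: score every document by
# direct evaluation of the formula, rank by score descending / doc id
# ascending.
oracle_bm25_rank <- function(doc_tokens, doc_ids, query_tokens,
                             k1 = 1.2, b = 0.75) {
  n <- length(doc_tokens)
  dl <- vapply(doc_tokens, length, integer(1))
  avgdl <- mean(dl)
  scores <- numeric(n)
  for (qt in query_tokens) {
    df <- sum(vapply(doc_tokens, function(d) qt %in% d, logical(1)))
    if (df == 0) next
    idf <- log((n - df + 0.5) / (df + 0.5) + 1)
    for (i in seq_len(n)) {
      tf <- sum(doc_tokens[[i]] == qt)
      if (tf == 0) next
      scores[i] <- scores[i] +
        idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl[i] / avgdl))
    }
  }
  keep <- which(scores > 0)
  o <- keep[order(-scores[keep], doc_ids[keep])]
  data.frame(doc_id = doc_ids[o], score = scores[o],
             stringsAsFactors = FALSE)
}

# small pseudo-text corpus for randomized retrieval tests
random_corpus <- function(n_docs, vocab = oracle_vocab, min_len = 3,
                          max_len = 30) {
  tibble::tibble(
    doc_id = sprintf("d%03d", seq_len(n_docs)),
    text = vapply(seq_len(n_docs), function(i) {
      paste(sample(vocab, sample(min_len:max_len, 1), replace = TRUE),
            collapse = " ")
    }, character(1))
  )
}

oracle_vocab <- c(
  "protein", "kinase", "membrane", "transport", "signal", "binding",
  "nucleus", "mitochondrion", "transcription", "ribosome", "apoptosis",
  "growth", "division", "repair", "pathway", "receptor", "enzyme",
  "metabolism", "oxidation", "phosphorylation", "regulation", "shoot",
  "root", "formation", "development", "response", "stress", "calcium",
  "glucose", "lipid"
)

# the GO record printed as a flat-file example, in its printed dialect
table1_stanza <- paste(
  "[Term]",
  "GO_id: GO:2000032",
  "name: regulation of secondary shoot formation",
  "namespace: biological_process",
  "def: 'Any process that modulates the frequency, rate or extent of secondary shoot formation.'",
  "synonym: 'regulation of auxiliary shoot formation' [EXACT]",
  "synonym: 'regulation of auxillary shoot formation' [EXACT]",
  "is_a: GO:0022603 ! regulation of anatomical structure morphogenesis",
  "is_a: GO:0048831 ! regulation of shoot development",
  sep = "\n")

# the corresponding annotation-database entry as a GAF row
table3_gaf_row <- paste(
  c("UniProtKB", "A0AQW4", "TCP12", "", "GO:2000032", "PMID:17307924",
    "IMP", "", "P", "", "", "protein", "taxon:3702", "2010/08/23",
    "UniProt", "", ""),
  collapse = "\t")

# tiny standard-format ontology shared by several tests
mini_obo <- paste(
  "format-version: 1.2",
  "data-version: releases/2012-01-01",
  "",
  "[Term]",
  "id: GO:0000001",
  "name: alpha beta process",
  "namespace: biological_process",
  "synonym: \"alpha beta pathway\" EXACT []",
  "synonym: \"broad alpha activity\" BROAD []",
  "",
  "[Term]",
  "id: GO:0000002",
  "name: gamma delta transport",
  "namespace: biological_process",
  "alt_id: GO:0000099",
  "is_a: GO:0000001",
  "",
  "[Term]",
  "id: GO:0000003",
  "name: old defunct process",
  "namespace: biological_process",
  "is_obsolete: true",
  "",
  sep = "\n")

small_corpus <- function(...) {
  generate_corpus(synth_config(n_terms = 10, docs_per_term = 8,
                               background_vocab_size = 120,
                               terms_per_doc = 1.8, doc_length = 60,
                               seed = 7, ...))
}

kb_doc_index <- function(kb) {
  build_index(tibble::tibble(
    doc_id = kb$documents$pmid,
    text = paste(kb$documents$title, kb$documents$abstract)))
}
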