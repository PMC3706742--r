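test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_terms = 10, docs_per_term = 20,
                      background_vocab_size = 100, seed = 7)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$ontology, b$ontology)
  expect_identical(a$kb$documents, b$kb$documents)
  expect_identical(a$kb$triples, b$kb$triples)
  expect_identical(a$heldout, b$heldout)
  # and a different seed changes the corpus
  c <- generate_corpus(synth_config(n_terms = 10, docs_per_term = 20,
                                    background_vocab_size = 100, seed = 8))
  expect_false(identical(a$kb$documents$abstract, c$kb$documents$abstract))
})

test_that("pure signatures with one term per doc stay inside the signature", {
  cor <- generate_corpus(synth_config(
    n_terms = 5, docs_per_term = 4, terms_per_doc = 1,
    signature_fraction = 1, background_vocab_size = 50, seed = 3))
  sigs <- lapply(cor$ontology$terms$id, function(id) {
    syn <- cor$ontology$synonyms$synonym[cor$ontology$synonyms$id == id]
    unique(unlist(strsplit(
      c(cor$ontology$terms$name[cor$ontology$terms$id == id], syn), " ")))
  })
  names(sigs) <- cor$ontology$terms$id
  for (i in seq_len(nrow(cor$kb$documents))) {
    pmid <- cor$kb$documents$pmid[i]
    terms <- cor$kb$triples$go_id[cor$kb$triples$pmid == pmid]
    expect_length(terms, 1)
    # every abstract token must come from the signature pool of its term;
    # the name/synonym phrases cover 9 of the 12 signature tokens, so
    # check the abstract draws nothing from other terms' signatures
    toks <- unique(strsplit(cor$kb$documents$abstract[i], " ")[[1]])
    other <- unlist(sigs[setdiff(names(sigs), terms)])
    expect_length(intersect(toks, other), 0)
  }
})

test_that("signature vocabularies of distinct terms are disjoint", {
  cor <- small_corpus()
  docs <- term_documents(cor$ontology, fields = c("name", "synonyms"))
  toks <- lapply(docs$text, function(t) unique(strsplit(t, " ")[[1]]))
  for (i in seq_along(toks)) {
    for (j in seq_len(i - 1)) {
      expect_length(intersect(toks[[i]], toks[[j]]), 0)
    }
  }
})

test_that("synthetic tokens survive the tokenizer unchanged", {
  cor <- small_corpus()
  nm <- cor$ontology$terms$name[1]
  expect_identical(tokenize1(nm), strsplit(nm, " ")[[1]])
})

test_that("every document carries at least one term and a valid year", {
  cor <- small_corpus()
  expect_true(all(cor$kb$documents$pmid %in% cor$kb$triples$pmid))
  expect_true(all(cor$kb$triples$year >= 2006))
  expect_true(all(nchar(cor$kb$triples$pmid) == 9))
  expect_true(all(as.numeric(cor$kb$documents$pmid) > 9e8))
})

test_that("an infeasible synonym budget is rejected", {
  expect_error(synth_config(signature_vocab_size = 5),
               "too small")
})

test_that("fixture files round-trip through the real readers", {
  cor <- small_corpus()
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(cor, dir)
  ont <- read_obo(paths[["obo"]])
  expect_equal(ontology_stats(ont), ontology_stats(cor$ontology))
  triples <- read_gaf(paths[["gaf"]], ontology = ont)
  expect_equal(nrow(triples), nrow(cor$kb$triples))
  docs <- read_abstract_store(paths[["abstracts"]])
  expect_equal(nrow(docs), nrow(cor$kb$documents) + nrow(cor$heldout))
  kb <- build_kb(docs, triples)
  expect_equal(dplyr::arrange(kb$triples[, c("go_id", "pmid", "year")],
                              .data$pmid, .data$go_id),
               dplyr::arrange(cor$kb$triples[, c("go_id", "pmid", "year")],
                              .data$pmid, .data$go_id))
  qrels <- read_qrels(paths[["qrels"]])
  expect_setequal(qrels$query_id, cor$heldout$query_id)
})

test_that("held-out names injected verbatim give the TB classifier rank 1", {
  cor <- generate_corpus(synth_config(
    n_terms = 8, docs_per_term = 4, background_vocab_size = 80,
    seed = 13, inject_name = TRUE))
  tidx <- build_term_index(cor$ontology)
  for (i in seq_len(nrow(cor$heldout))) {
    tb <- classify_tb(cor$heldout$text[i], cor$ontology, tidx)
    expect_equal(reciprocal_rank(tb$go_id, cor$heldout$gold_terms[[i]]), 1.0)
  }
})

test_that("degrading the signature fraction degrades mean recall", {
  # more terms than the rank-20 cutoff, so recall@20 can actually vary
  r20 <- vapply(c(0.5, 0.12, 0.05), function(sf) {
    cor <- generate_corpus(synth_config(
      n_terms = 40, docs_per_term = 5, doc_length = 40,
      background_vocab_size = 150, signature_fraction = sf, seed = 99))
    idx <- kb_doc_index(cor$kb)
    run <- run_classifier(cor$heldout, function(txt, qid) {
      classify_knn(txt, cor$kb, idx, k = 30)
    })
    evaluate_runs(run, cor$heldout)$recall_20
  }, numeric(1))
  expect_true(all(diff(r20) <= 0))
  expect_gt(r20[1], r20[3])
})
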