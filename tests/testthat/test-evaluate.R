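test_that("reciprocal rank and recall follow their definitions", {
  gold <- c("GO:0000002", "GO:0000009")
  ranked <- sprintf("GO:%07d", c(5, 7, 8, 2, 9))
  expect_equal(reciprocal_rank(ranked, gold), 0.25)
  expect_equal(reciprocal_rank(c("GO:0000002", "GO:0000005"), gold), 1.0)
  expect_equal(reciprocal_rank(sprintf("GO:%07d", 10:12), gold), 0.0)

  expect_equal(recall_at_k(ranked, gold, 20), 1.0)
  expect_equal(recall_at_k(ranked, gold, 4), 0.5)
  expect_equal(recall_at_k(ranked, gold, 3), 0.0)
  # rankings shorter than k are evaluated over the available ranks
  expect_equal(recall_at_k("GO:0000002", gold, 20), 0.5)
  expect_error(recall_at_k(ranked, character(0), 5), "empty gold")
})

test_that("evaluate_runs macro-averages over the qrels queries", {
  run <- tibble::tibble(
    query_id = c("q1", "q2", "q2"),
    go_id = c("GO:0000001", "GO:0000009", "GO:0000002"),
    score = c(1, 1, 0.5), rank = c(1L, 1L, 2L))
  qrels <- tibble::tibble(query_id = c("q1", "q2"),
                          go_id = c("GO:0000001", "GO:0000002"))
  ev <- evaluate_runs(run, qrels)
  expect_equal(ev$mrr, mean(c(1, 0.5)))
  expect_equal(ev$recall_5, 1.0)
  expect_equal(ev$n_queries, 2L)
})

test_that("queries with an empty run contribute zero, not dropped", {
  run <- tibble::tibble(query_id = "q1", go_id = "GO:0000001",
                        score = 1, rank = 1L)
  qrels <- tibble::tibble(query_id = c("q1", "q2"),
                          go_id = c("GO:0000001", "GO:0000002"))
  ev <- evaluate_runs(run, qrels)
  expect_equal(ev$mrr, 0.5)
  expect_equal(ev$recall_20, 0.5)
})

test_that("a run query without judgements is an error naming the query", {
  run <- tibble::tibble(query_id = "mystery", go_id = "GO:0000001",
                        score = 1, rank = 1L)
  qrels <- tibble::tibble(query_id = "q1", go_id = "GO:0000001")
  expect_error(evaluate_runs(run, qrels), "mystery")
})

test_that("metrics are permutation-invariant over query order", {
  set.seed(31)
  qrels <- tibble::tibble(query_id = rep(sprintf("q%02d", 1:10), each = 2),
                          go_id = sprintf("GO:%07d", sample(100, 20)))
  run <- dplyr::bind_rows(lapply(sprintf("q%02d", 1:10), function(q) {
    n <- sample(3:8, 1)
    tibble::tibble(query_id = q, go_id = sprintf("GO:%07d", sample(100, n)),
                   score = sort(runif(n), decreasing = TRUE),
                   rank = seq_len(n))
  }))
  a <- evaluate_runs(run, qrels)
  b <- evaluate_runs(run[sample(nrow(run)), ], qrels[sample(nrow(qrels)), ])
  expect_equal(a, b)
})

test_that("recall is monotone non-decreasing in k", {
  set.seed(77)
  for (i in 1:20) {
    ranked <- sprintf("GO:%07d", sample(50, 30))
    gold <- sprintf("GO:%07d", sample(50, 4))
    rec <- vapply(1:30, function(k) recall_at_k(ranked, gold, k), numeric(1))
    expect_true(all(diff(rec) >= 0))
  }
})

test_that("file-based evaluation matches the trec_eval-style oracle", {
  set.seed(2024)
  for (rep in 1:5) {
    n_q <- sample(5:20, 1)
    qids <- sprintf("9000%05d", seq_len(n_q))
    qrels <- dplyr::bind_rows(lapply(qids, function(q) {
      tibble::tibble(query_id = q,
                     go_id = sprintf("GO:%07d", sample(60, sample(1:5, 1))))
    }))
    run <- dplyr::bind_rows(lapply(qids, function(q) {
      n <- sample(1:25, 1)
      tibble::tibble(query_id = q,
                     go_id = sprintf("GO:%07d", sample(60, n)),
                     score = sort(sample(seq(0.01, 1, by = 0.01), n),
                                  decreasing = TRUE),
                     rank = seq_len(n))
    }))
    run_path <- withr::local_tempfile(fileext = ".run")
    qrels_path <- withr::local_tempfile(fileext = ".qrels")
    write_trec_run(run, run_path)
    write_qrels(qrels, qrels_path)

    got <- evaluate_runs(read_trec_run(run_path), read_qrels(qrels_path))
    want <- oracle_eval_trec(run_path, qrels_path)
    expect_equal(got$mrr, want$mrr, tolerance = 1e-10)
    expect_equal(got$recall_5, want$recall[1], tolerance = 1e-10)
    expect_equal(got$recall_20, want$recall[2], tolerance = 1e-10)
  }
})

test_that("TREC run and qrels files round-trip", {
  run <- tibble::tibble(query_id = c("q1", "q1"), go_id = c("GO:0000001", "GO:0000002"),
                        score = c(0.5, 0.25), rank = 1:2)
  p <- withr::local_tempfile()
  write_trec_run(run, p, run_tag = "ml")
  back <- read_trec_run(p)
  expect_equal(back$go_id, run$go_id)
  expect_equal(back$score, run$score)
  expect_equal(unique(back$run_tag), "ml")

  qr <- tibble::tibble(query_id = "q1", go_id = c("GO:0000001", "GO:0000002"))
  q <- withr::local_tempfile()
  write_qrels(qr, q)
  expect_equal(read_qrels(q), qr)
})

test_that("a single simulated year equals the hand-composed pipeline", {
  cor <- small_corpus()
  y <- 2010
  sim <- suppressWarnings(simulate_years(
    cor$kb, cor$ontology, years = y, n_queries = 3, seed = 50,
    classifiers = "knn"))
  # manual composition of the stage operations
  kb_y <- temporal_filter(cor$kb, y)
  bench <- build_benchmark(cor$kb, y, 3, seed = 50 + y)
  docs <- dplyr::filter(kb_y$documents, !.data$pmid %in% bench$query_id)
  idx <- build_index(tibble::tibble(
    doc_id = docs$pmid, text = stringr::str_squish(
      paste(docs$title, docs$abstract))))
  kb_f <- suppressWarnings(build_kb(docs, kb_y$triples))
  run <- run_classifier(bench, function(txt, qid) {
    suppressWarnings(classify_knn(txt, kb_f, idx, k = 200,
                                  exclude_pmids = bench$query_id))
  })
  ev <- evaluate_runs(run, bench)
  expect_equal(sim$mrr, ev$mrr)
  expect_equal(sim$recall_20, ev$recall_20)
})

test_that("no benchmark query is retrievable as its own neighbour", {
  cor <- small_corpus()
  y <- 2011
  kb_y <- temporal_filter(cor$kb, y)
  bench <- build_benchmark(cor$kb, y, 3, seed = 8)
  docs <- dplyr::filter(kb_y$documents, !.data$pmid %in% bench$query_id)
  idx <- build_index(tibble::tibble(
    doc_id = docs$pmid, text = paste(docs$title, docs$abstract)))
  for (i in seq_len(nrow(bench))) {
    hits <- search_index(idx, bench$text[i], exclude = bench$query_id)
    expect_false(bench$query_id[i] %in% hits$doc_id)
  }
})

test_that("tidiers reshape evaluation results", {
  ev <- evaluate_runs(
    tibble::tibble(query_id = "q1", go_id = "GO:0000001", score = 1, rank = 1L),
    tibble::tibble(query_id = "q1", go_id = "GO:0000001"))
  td <- tidy(ev)
  expect_setequal(td$metric, c("mrr", "recall_5", "recall_20"))
  expect_s3_class(glance(ev), "tbl_df")
})
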