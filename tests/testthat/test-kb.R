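gaf_row <- function(go = "GO:0000001", ref = "PMID:900000001",
                    date = "20080101", ev = "IMP") {
  paste(c("DB", "ACC1", "GENE1", "", go, ref, ev, "", "P", "", "",
          "protein", "taxon:1", date, "DB", "", ""), collapse = "\t")
}

test_that("the printed annotation entry reduces to its triple", {
  tr <- read_gaf(text = table3_gaf_row)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$go_id, "GO:2000032")
  expect_equal(tr$pmid, "17307924")
  expect_equal(tr$year, 2010L)
})

test_that("rows without a PMID reference are dropped", {
  txt <- paste(gaf_row(ref = "GO_REF:0000002"), gaf_row(ref = "PMID:123"),
               sep = "\n")
  tr <- read_gaf(text = txt)
  expect_equal(tr$pmid, "123")
})

test_that("duplicate (GO id, PMID) pairs keep the earliest year", {
  txt <- paste(gaf_row(date = "20100501"), gaf_row(date = "20080301"),
               sep = "\n")
  tr <- read_gaf(text = txt)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$year, 2008L)
})

test_that("both compact and slashed date formats parse; bad dates warn", {
  tr <- read_gaf(text = paste(gaf_row(date = "2010/08/23"),
                              gaf_row(go = "GO:0000002", date = "20100823"),
                              sep = "\n"))
  expect_equal(tr$year, c(2010L, 2010L))
  expect_warning(bad <- read_gaf(text = gaf_row(date = "August 2010")),
                 "1 GAF row")
  expect_equal(nrow(bad), 0)
})

test_that("GAF accessions are normalized through alt_id mappings", {
  ont <- read_obo(text = mini_obo)
  tr <- read_gaf(text = gaf_row(go = "GO:0000099"), ontology = ont)
  expect_equal(tr$go_id, "GO:0000002")
})

test_that("abstract store round-trips, including escaped newlines", {
  docs <- tibble::tibble(pmid = c("900000001", "900000002"),
                         pub_year = c(2010L, 2012L),
                         title = c("T one", "T two"),
                         abstract = c("line a\nline b", "plain"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abstract_store(docs, path)
  expect_equal(read_abstract_store(path), docs)
  expect_equal(nrow(read_abstract_store(text = "")), 0)
  expect_error(read_abstract_store(text = "a\t2000\tonly-three"), "line 1")
})

make_kb <- function(years = c(2008, 2010, 2012)) {
  docs <- tibble::tibble(
    pmid = sprintf("9%08d", seq_along(years)),
    pub_year = as.integer(years),
    title = paste("title", seq_along(years)),
    abstract = paste("abstract text", seq_along(years)))
  triples <- tibble::tibble(
    go_id = sprintf("GO:%07d", seq_along(years)),
    pmid = docs$pmid, year = as.integer(years))
  build_kb(docs, triples)
}

test_that("temporal_filter keeps exactly the triples before the cutoff", {
  kb <- make_kb(c(2008, 2010, 2012))
  f <- temporal_filter(kb, 2010)
  expect_equal(f$triples$year, 2008L)
  expect_equal(f$documents$pmid, f$triples$pmid)
  expect_equal(f$cutoff_year, 2010L)
  # cutoff above all years: identity on triples/documents
  all_kept <- temporal_filter(kb, 2013)
  expect_equal(all_kept$triples, kb$triples)
  expect_equal(all_kept$documents, kb$documents)
  # cutoff at or below minimum: annihilation
  none <- temporal_filter(kb, 2008)
  expect_equal(nrow(none$triples), 0)
  expect_equal(nrow(none$documents), 0)
})

test_that("temporal_filter is idempotent and monotone in the cutoff", {
  kb <- small_corpus()$kb
  f <- temporal_filter(kb, 2010)
  expect_equal(temporal_filter(f, 2010)$triples, f$triples)
  for (a in c(2008, 2010, 2012)) {
    fa <- temporal_filter(kb, a)
    fb <- temporal_filter(kb, a + 1)
    expect_true(all(do.call(paste, fa$triples[, c("go_id", "pmid")]) %in%
                      do.call(paste, fb$triples[, c("go_id", "pmid")])))
  }
})

test_that("build_kb enforces uniqueness and drops orphan triples", {
  docs <- tibble::tibble(pmid = "1", pub_year = 2010L, title = "t",
                         abstract = "a")
  triples <- tibble::tibble(go_id = c("GO:0000001", "GO:0000001", "GO:0000002"),
                            pmid = c("1", "1", "2"),
                            year = c(2009L, 2010L, 2010L))
  expect_warning(kb <- build_kb(docs, triples), "1 triple")
  expect_equal(nrow(kb$triples), 1)
  expect_equal(kb$triples$year, 2009L)
})

test_that("benchmark sampling is seeded, exhaustive and leak-checked", {
  kb <- small_corpus()$kb
  yr <- kb$documents$pub_year[1]
  eligible <- sum(kb$documents$pub_year == yr)
  b1 <- build_benchmark(kb, yr, 3, seed = 1)
  b2 <- build_benchmark(kb, yr, 3, seed = 1)
  expect_equal(b1, b2)
  b3 <- build_benchmark(kb, yr, 3, seed = 2)
  # same seed identical; different seeds generally differ
  expect_false(identical(b1$query_id, b3$query_id))
  # exhaustive case returns everything
  all_q <- build_benchmark(kb, yr, eligible, seed = 9)
  expect_equal(nrow(all_q), eligible)
  # asking beyond availability reports the eligible count
  expect_error(build_benchmark(kb, yr, eligible + 1, seed = 9),
               sprintf("only %d", eligible))
})

test_that("benchmark gold terms equal the document's triple set", {
  kb <- small_corpus()$kb
  yr <- kb$documents$pub_year[5]
  b <- build_benchmark(kb, yr, 2, seed = 4)
  for (i in seq_len(nrow(b))) {
    expect_setequal(b$gold_terms[[i]],
                    kb$triples$go_id[kb$triples$pmid == b$query_id[i]])
  }
})

test_that("kb statistics compute exactly on toy sets", {
  docs <- tibble::tibble(pmid = "1", pub_year = 2010L, title = "t",
                         abstract = "a")
  triples <- tibble::tibble(go_id = sprintf("GO:%07d", 1:3),
                            pmid = "1", year = 2009L)
  s <- kb_stats(build_kb(docs, triples))
  expect_equal(s$triples_per_pmid_mean, 3)
  expect_equal(s$triples_per_pmid_median, 3)
})
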