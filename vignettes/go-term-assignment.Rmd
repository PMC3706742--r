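---
title: "Assigning Gene Ontology terms to free text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning Gene Ontology terms to free text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goclassify)
```

## The task

Curating the biomedical literature into Gene Ontology (GO) annotations is
slow, expert work: for each publication a curator selects, from tens of
thousands of controlled-vocabulary terms, the handful (typically around
three) that describe the gene-product functions the publication reports.
`goclassify` implements the two families of text categorizers that support
this work, plus their fusion and the evaluation harness needed to measure
them honestly:

* a **thesaurus-based (TB) classifier**, which ranks GO terms by lexical
  similarity between the input text and the terms' own names and synonyms,
  boosted when a term is recognized verbatim (fuzzily) in the text; and
* a **machine-learning (ML) classifier**, a k-nearest-neighbour scheme
  that retrieves the curated abstracts most similar to the input from a
  knowledge base and aggregates *their* curated GO terms into a ranked
  profile.

The two have opposite failure modes.  The TB route needs no training data
but is limited by how rarely GO terms occur literally in prose; the ML
route can propose any term that has ever been used in curation, but only
those — a term with no curated example is unreachable.  Because the
knowledge base grows with every GOA release while term names change
slowly, the ML route improves over time and the package includes a
year-by-year simulation harness to measure exactly that effect.

## Resources and their readers

**Ontology.** `read_obo()` parses OBO 1.2 `[Term]` stanzas into tidy
tibbles (terms, synonyms with scopes, `is_a` parents, `alt_id` maps).
Only `is_a` edges are kept: neither classifier traverses the graph, so
richer relationship types would be dead weight.  Obsolete terms stay in
the object — they are legitimate `alt_id`/audit targets — but are excluded
from every classifier vocabulary, since they cannot be curation targets.
Merged accessions resolve through `alt_id` at lookup time.

**Annotations.** `read_gaf()` reduces a Gene Association File to the atom
the paper-centric task needs: triples *(GO id, PMID, annotation year)*.
Rows whose reference column carries no PMID are dropped (the gene-product
identity is deliberately discarded).  Updates are ignored: on duplicate
(GO id, PMID) pairs the earliest year wins, which makes temporal
filtering conservative — an annotation is never considered younger than
its first appearance.  Evidence codes are parsed and stored;
`build_kb(exclude_iea = TRUE)` optionally drops electronic annotations,
but the default uses every PMID-linked annotation.

**Abstracts.** The abstract store is a deliberately plain four-column TSV
(`pmid`, `pub_year`, `title`, `abstract`, newlines escaped as `\n`).  A
PubMed XML reader would be a welcome extension; the TSV keeps desk-scale
testing trivial and the reader code path identical for real and synthetic
data.

**Temporal restoration.** `temporal_filter(kb, Y)` keeps exactly the
triples with `year < Y` — the knowledge base "as of 1 January of year Y"
— and drops documents left without any triple.  The operation is
idempotent and monotone in the cutoff, and the test suite asserts both.

## The retrieval engine

Both classifiers stand on one retrieval pipeline:

1. **Tokenization** — lowercase, split on non-alphanumerics, drop
   single-character tokens, remove a fixed English stopword list (shipped
   with the package so results are reproducible across installations),
   then stem with the original Porter algorithm.  The stemmer is
   implemented in full from its published definition; its behaviour is
   pinned by canonical input/output pairs in the test suite.  Queries and
   documents share this pipeline exactly — no query expansion.
2. **Okapi BM25** — a document `d` scores, for query `q`,
   `sum over t in q of idf(t) * tf(t,d) (k1 + 1) / (tf(t,d) + k1 (1 - b + b |d|/avgdl))`
   with `idf(t) = ln((N - df(t) + 0.5)/(df(t) + 0.5) + 1)`.  The constants
   default to the canonical `k1 = 1.2`, `b = 0.75` and are configurable.
   The `+1` inside the logarithm keeps idf positive on tiny corpora
   (with the classical form, any token present in more than half the
   documents would get a *negative* weight — irrelevant at literature
   scale, poisonous on ten-document fixtures).  Ties in ranking break by
   ascending document id, so every assertion in the tests can be exact.

`search_index()` is verified against brute-force evaluation of the same
formula on randomized corpora (tolerance 1e-9), and the three-document
worked example in the tests is evaluated by literal arithmetic.

## The k-NN classifier

`classify_knn()` retrieves the `k = 200` most similar curated abstracts
(the default follows the observation that performance is stable for
neighbourhoods between roughly 100 and 250) and lets each neighbour vote
for its curated terms.  Votes are weighted by the neighbour's retrieval
score and normalized by the total score mass of the neighbourhood:

```
score(t) = sum over neighbours d annotated with t of bm25(d, q)
           -------------------------------------------------
           sum over all k neighbours d' of bm25(d', q)
```

Similarity weighting is the standard refinement of k-NN text
categorization and degrades gracefully to plain counting when scores are
flat; `vote = "uniform"` exposes the counting variant.  When fewer than
`k` documents score positively, all positive-scoring neighbours are used.
Two properties follow by construction and are asserted on fixtures: the
**closed world** (a term with no knowledge-base support is never
predicted) and the **leakage guard** (`exclude_pmids` removes benchmark
documents from retrieval, so no query can be its own neighbour).  With
multi-label neighbours the scores of a prediction list can sum to more
than 1 — each neighbour votes once per term it carries; the sum equals 1
exactly when every neighbour carries a single annotation.

## The thesaurus classifier

`classify_tb()` combines two components:

* **Vector space** (`classify_vs()`): the input text is the query, each
  non-obsolete term's name + synonyms (all scopes, configurable via
  `fields`/`scopes`; definitions can be indexed too but are off by
  default) is a tiny document, BM25 ranks them, and scores are scaled to
  `[0, 1]`.
* **Fuzzy recognition** (`match_terms()`): each term name and EXACT
  synonym compiles to a case-insensitive pattern tolerating whitespace/
  hyphen/comma runs between words, an optional plural `s` on the final
  word, and removal of parenthesized qualifiers.  Edit-distance matching
  was considered and rejected: over tens of thousands of patterns it is
  quadratic work with unbounded false positives, and no distance
  threshold is principled at that scale.  Only names and EXACT synonyms
  feed the recognizer — looser scopes produce too many spurious spans.

Recognized terms must outrank everything else, so the boost is
rank-dominant and deterministic:
`score' = 1 + vs_score + 0.001 * longest_match_length`, after which all
scores are rescaled to `[0, 1]`.  Matched terms therefore sort strictly
above unmatched ones, order among matched terms follows (vs score, match
length), and unmatched terms keep their vector-space order.  The exact
arithmetic is this package's contract, chosen for testability rather than
claimed fidelity to any particular legacy system.

## Score fusion

`combine_runs()` normalizes both runs and mixes them linearly:
`combined(t) = w * norm_ml(t) + (1 - w) * norm_tb(t)`, default
`w = 0.7` on the ML side — the mixture that performs best.  A term absent
from a run contributes 0 from that run, consistent with the ML
closed-world reading.  **Normalization** divides by the maximum score,
preserving the natural zero of retrieval/vote scales (an explicit
min-to-zero rescaling would zero out every run's weakest member and
change the fused order; division by the max keeps ratios intact).
Degenerate runs — a single prediction, or all-equal scores — normalize to
1.0 everywhere: presence in a run is evidence and should not collapse to
no-confidence.

## Evaluation

`evaluate_runs()` computes Mean Reciprocal Rank (the average inverse rank
of the first correct term) and macro-averaged Recall at 5 and 20 (the
per-query fraction of gold terms in the top ranks, averaged over
queries).  Rank 20 is inclusive, matching the standard evaluator's
semantics; micro-averaging is available behind `average = "micro"` for
diagnostics.  Queries for which a classifier returns nothing contribute 0
rather than being dropped — dropping them would silently inflate the
averages.  Run and judgement files read and write the standard TREC
formats, and the suite checks the metrics against an independent
file-level oracle that replays the standard evaluator's conventions
(score-descending order, ties by document id descending); runs written
with distinct scores make the two tie-break conventions coincide.
Rankings are truncated to 100 entries per query by default before runs
are written.

`simulate_years()` drives the historical experiment: for each year it
restores the knowledge base, rebuilds the index, samples (or accepts) a
benchmark, runs each classifier with the leakage guard, and emits one
tidy row per (year, classifier).  `autoplot()` on the result draws the
performance-over-time curves.

## The synthetic corpus generator

Real GOA + MEDLINE resources are far too large to ship, so
`generate_corpus()` builds a miniature world with *known* structure:

* each of `n_terms` GO terms owns a private signature vocabulary
  (disjoint across terms by default; an `overlap_fraction` knob makes the
  task harder); its name and EXACT synonyms are disjoint 3-word phrases
  from that signature;
* each curated abstract carries on average `terms_per_doc = 2.8` terms
  (the typical curation density of annotated abstracts) and draws each
  token from its terms' pooled signatures with probability
  `signature_fraction`, otherwise from a shared background vocabulary —
  the title is simply the head of the same token stream, so the fraction
  governs the entire indexed text;
* publication years are uniform over `year_range` so temporal filtering
  has non-trivial strata, and each annotation's year is its document's
  publication year plus a small (0–2 year) curation delay, which keeps
  "published in Y" and "annotated before Y" coherently related;
* one held-out abstract per term (excluded from the knowledge base) forms
  the benchmark; `inject_name = TRUE` appends the term's name verbatim so
  the fuzzy recognizer is guaranteed to fire;
* synthetic PMIDs are nine-digit integers above 900000000, away from real
  PMIDs; tokens are consonant-only pseudo-words chosen to pass through
  tokenization and stemming unchanged, so the generating signature issues
  survive indexing exactly.

Everything is reproducible from the seed, and `write_fixture_files()`
emits the corpus as `go.obo`, `annotations.gaf`, `abstracts.tsv` and
`qrels.txt` so synthetic data exercise precisely the readers real data
would.

**What passing these tests shows — and what it does not.**  The defaults
(50 terms, 40 documents per term, signature fraction 0.6, 120-token
abstracts, seed 42) describe a *separable* task: signatures are disjoint,
so near-perfect held-out recovery is the expected outcome and the tests
require it (recall@20 ≥ 0.9, exactly 1.0 at signature fraction 1).  Real
abstracts share vocabulary across related GO terms, mention many
functions incidentally, and use term wording far looser than EXACT
synonyms; absolute metric values on this generator therefore say nothing
about absolute performance on MEDLINE.  What the generator does validate
is *mechanism*: retrieval correctness, vote bookkeeping, leakage and
closed-world behaviour, metric arithmetic, and the qualitative signatures
of the two classifier families — k-NN recall degrades as the signature
fraction falls (tested at three levels) and rises as the knowledge base
grows across simulated years, while the thesaurus route, fed the same
ontology throughout, stays constant.

## Numerical and design choices worth knowing

* **Problem sizes.** The test suite and the acceptance script run the
  generator at its defaults (2 000 knowledge-base documents, 50 held-out
  queries) and smaller; randomized retrieval checks use corpora of up to
  50 documents against a brute-force oracle, and metric checks use 20
  randomized run/judgement file pairs.  These sizes were chosen as the
  smallest at which every mechanism (growth trends included) is
  observable.
* **Tie-breaks everywhere are deterministic**: ascending document id in
  retrieval, ascending GO id in prediction lists.  Fixtures with distinct
  scores sidestep the one convention difference with the standard
  evaluator (which breaks score ties by *descending* id).
* **Degenerate inputs**: empty text tokenizes to an empty query and
  returns empty rankings; an empty knowledge base warns and predicts
  nothing; an empty prediction run evaluates to 0, not NA; a
  single-entry or all-equal run normalizes to 1.0.
* **Cutoff semantics**: `temporal_filter(kb, Y)` keeps `year < Y` — the
  state on 1 January of `Y`.
* **GAF dates** accept both `YYYYMMDD` and `YYYY/MM/DD`; unparseable
  dates skip the row with a counted warning rather than failing the
  whole file.
* **The OBO parser** accepts the `GO_id:` accession-tag variant seen in
  printed renderings of GO records, scope tokens both bare (`EXACT`) and
  bracketed (`[EXACT]`), and pre-1.2 scoped synonym tags
  (`exact_synonym:`); unknown tags are ignored, and a stanza without an
  id is reported with its byte offset.

## Limitations

* No ontology-graph reasoning: votes are not propagated to ancestors,
  and no information-content measures are computed.  The classifiers
  predict curated terms as curators used them.
* The stopword list is fixed and shipped; it is *a* standard English
  list, and results depend on it only reproducibly, not sensitively.
* The fuzzy recognizer does not stem inside patterns and does not do
  edit-distance matching; a term worded loosely in text is the vector
  space module's job, not the recognizer's.
* Paper-centric only: gene products are not modelled, and annotations
  arriving through non-PMID references are invisible.
* The synthetic generator produces linguistically meaningless tokens by
  design; it validates mechanisms, not absolute performance claims.
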