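# hand-built corpus: explicit control of sentences and mention multiplicity
hand_corpus <- function() {
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    text = c("p53 p53 binds cancer here. p53 alone here.",
             "p53 meets cancer. p53 meets cancer again.",
             "cancer alone in this one."),
    year = c(2000L, 2000L, 2005L))
  sents <- data.frame(
    doc_id = c("d1", "d1", "d2", "d2", "d3"),
    sentence_index = c(0L, 1L, 0L, 1L, 0L),
    start = c(0L, 27L, 0L, 18L, 0L),
    end = c(26L, 42L, 17L, 41L, 25L))
  mk <- function(doc, si, start, surface, id)
    data.frame(doc_id = doc, sentence_index = si, start = start,
               end = start + nchar(surface), surface = surface,
               entity_type = if (id == "GENE:p53") "Gene" else "Disease",
               entity_id = id)
  mentions <- rbind(
    mk("d1", 0L, 0L, "p53", "GENE:p53"),
    mk("d1", 0L, 4L, "p53", "GENE:p53"),      # duplicate mention, same sentence
    mk("d1", 0L, 14L, "cancer", "MESH:can"),
    mk("d1", 1L, 27L, "p53", "GENE:p53"),
    mk("d2", 0L, 0L, "p53", "GENE:p53"),
    mk("d2", 0L, 10L, "cancer", "MESH:can"),
    mk("d2", 1L, 18L, "p53", "GENE:p53"),
    mk("d2", 1L, 28L, "cancer", "MESH:can"),
    mk("d3", 0L, 0L, "cancer", "MESH:can"))
  lbd_corpus(docs, mentions, sents)
}

test_that("instances count once per sentence regardless of multiplicity", {
  inst <- extract_instances(hand_corpus())
  # d1 sentence 0: p53 twice + cancer once -> exactly one instance
  expect_equal(nrow(inst[doc_id == "d1"]), 1L)
  # d1 sentence 1: single entity -> no instance
  expect_equal(nrow(inst[doc_id == "d1" & sentence_index == 1L]), 0L)
  # d2: same pair in two sentences -> two sentence instances
  expect_equal(nrow(inst[doc_id == "d2"]), 2L)
})

test_that("aggregation produces exact sentence/document counts and totals", {
  cnt <- aggregate_counts(hand_corpus())
  pc <- pair_counts(cnt)
  expect_equal(pc[id1 == "GENE:p53" & id2 == "MESH:can", n_ab], 3L)
  expect_equal(pc[id1 == "GENE:p53" & id2 == "MESH:can", d_ab], 2L)
  ec <- entity_counts(cnt)
  expect_equal(ec[entity_id == "GENE:p53", n], 4L)  # 4 distinct sentences
  expect_equal(ec[entity_id == "GENE:p53", d], 2L)
  expect_equal(ec[entity_id == "MESH:can", n], 4L)
  expect_equal(ec[entity_id == "MESH:can", d], 3L)
  expect_equal(counts_totals(cnt), list(n_sent = 5L, n_doc = 3L))
  # per-year audit
  pcy <- pair_counts(cnt, by_year = TRUE)
  expect_equal(pcy[year == 2000, sum(n_ab)], 3L)
  ecy <- entity_counts(cnt, by_year = TRUE)
  expect_equal(ecy[entity_id == "MESH:can" & year == 2005, d], 1L)

  # empty corpus -> all-zero stats
  e <- aggregate_counts(lbd_corpus(data.frame(doc_id = character(),
                                              text = character(),
                                              year = integer())))
  expect_equal(counts_totals(e), list(n_sent = 0L, n_doc = 0L))
  expect_equal(nrow(pair_counts(e)), 0L)
})

test_that("count invariants hold on generated corpora", {
  g <- random_corpus_graph(3L, n_entities = 30L, n_pairs = 60L)
  n_of <- function(id) g$nodes[entity_id == id, n]
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k]
    expect_lte(e$n_ab, min(n_of(e$id1), n_of(e$id2)))
    expect_lte(n_of(e$id1) + n_of(e$id2) - e$n_ab, g$n_sent)
  }
})

test_that("snapshot restricts by year and is the identity at cutoff infinity", {
  corp <- hand_corpus()
  cnt <- aggregate_counts(corp)
  snap <- snapshot(cnt, cutoff_year = 2000L)
  expect_equal(counts_totals(snap)$n_doc, 2L)
  expect_equal(entity_counts(snap)[entity_id == "MESH:can", d], 2L)
  full <- snapshot(cnt, cutoff_year = Inf)
  expect_tables_equal(pair_counts(full), pair_counts(cnt))
  expect_tables_equal(entity_counts(full), entity_counts(cnt))
  # corpus method agrees with counts method
  expect_tables_equal(pair_counts(snapshot(corp, 2000L)), pair_counts(snap))
})

test_that("pair exclusion removes whole documents before aggregation", {
  # d1 and d2 contain the excluded pair; d2 also carries the pair's
  # sentences; an extra doc links p53 to a third entity B
  corp <- hand_corpus()
  extra <- generate_corpus(corpus_spec(
    data.frame(entity_id = c("GENE:p53", "B:1"), entity_type = "Gene",
               surface = c("p53", "bee")),
    pairs = data.frame(id1 = "GENE:p53", id2 = "B:1", count = 1L,
                       year = 2000L)))
  corp <- lbd_corpus(rbind(corp$documents, extra$documents),
                     rbind(corp$mentions, extra$mentions),
                     rbind(corp$sentences, extra$sentences))
  cnt <- aggregate_counts(corp)
  snap <- snapshot(cnt, cutoff_year = Inf,
                   exclude_pair = c("GENE:p53", "MESH:can"))
  # excluded pair vanished entirely
  expect_equal(nrow(pair_counts(snap)[id1 == "GENE:p53" &
                                        id2 == "MESH:can"]), 0L)
  # no surviving document contains both entities
  expect_length(pair_documents(snap, "GENE:p53", "MESH:can"), 0L)
  # collateral: p53's counts now come only from the extra doc, and the
  # co-excluded doc's other contributions vanished too
  ec <- entity_counts(snap)
  expect_equal(ec[entity_id == "GENE:p53", n], 1L)
  expect_equal(ec[entity_id == "MESH:can", d], 1L)  # only d3 survives
  expect_equal(counts_totals(snap)$n_doc, 2L)
  # recount audit: totals equal an aggregate over the surviving documents
  keep <- snap$docs$doc_id
  sub <- lbd_corpus(corp$documents[corp$documents$doc_id %in% keep],
                    corp$mentions[corp$mentions$doc_id %in% keep],
                    corp$sentences[corp$sentences$doc_id %in% keep])
  expect_tables_equal(pair_counts(aggregate_counts(sub)), pair_counts(snap))
})

test_that("document-level dialect flag widens d_ab to anywhere-in-document", {
  # pair in the same document but never the same sentence
  docs <- data.frame(doc_id = "dx", text = "aaa here. bbb there.",
                     year = 2000L)
  sents <- data.frame(doc_id = "dx", sentence_index = 0:1,
                      start = c(0L, 10L), end = c(9L, 20L))
  mentions <- data.frame(
    doc_id = "dx", sentence_index = 0:1, start = c(0L, 10L),
    end = c(3L, 13L), surface = c("aaa", "bbb"), entity_type = "Gene",
    entity_id = c("A:1", "B:1"))
  corp <- lbd_corpus(docs, mentions, sents)
  strict <- pair_counts(aggregate_counts(corp, doc_cooccur = "same_sentence"))
  expect_equal(nrow(strict), 0L)  # no sentence co-occurrence, no pair row
  # but exclusion still sees the document-level pair
  expect_equal(pair_documents(aggregate_counts(corp), "A:1", "B:1"), "dx")
})

test_that("unknown-year documents are excluded from aggregation with warning", {
  docs <- data.frame(doc_id = c("k1", "k2"), text = c("aaa.", "bbb."),
                     year = c(2000L, NA_integer_))
  sents <- data.frame(doc_id = c("k1", "k2"), sentence_index = 0L,
                      start = 0L, end = 4L)
  corp <- lbd_corpus(docs, NULL, sents)
  expect_warning(cnt <- aggregate_counts(corp), "unknown year")
  expect_equal(counts_totals(cnt)$n_doc, 1L)
})
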