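test_that("worked example reproduces the reference path scores", {
  g <- worked_example_graph()
  closed <- closed_discovery(g, "a1", "c1", scoring_config("count",
                                                           fg = "sum"))
  expect_equal(closed$candidates$id, c("b1", "b2"))
  expect_identical(closed$candidates$score, c(12, 4))
  expect_identical(closed$candidates$rank, 1:2)

  open <- open_discovery(g, "a1", scoring_config("count", fg = "sum",
                                                 fc = "sum"))
  expect_equal(open$candidates[id == "c1", score], 16)
  expect_equal(open$candidates[id == "c1", n_paths], 2L)

  # fg=min ties b1 and b2 at 2; tie broken by ascending identifier
  tied <- closed_discovery(g, "a1", "c1", scoring_config("count",
                                                         fg = "min"))
  expect_identical(tied$candidates$score, c(2, 2))
  expect_equal(tied$candidates$id, c("b1", "b2"))
  # fg=min, fc=max: best bottleneck over the two paths
  om <- open_discovery(g, "a1", scoring_config("count", fg = "min",
                                               fc = "max"))
  expect_equal(om$candidates[id == "c1", score], 2)
})

test_that("degenerate queries behave and errors are raised", {
  g <- worked_example_graph()
  # a and c with no common neighbor -> empty result
  expect_equal(nrow(closed_discovery(g, "a1", "b1")$candidates), 0L)
  expect_error(closed_discovery(g, "a1", "a1"), "distinct")
  expect_error(closed_discovery(g, "a1", "nope"), "unknown node")
  expect_error(open_discovery(g, "nope"), "unknown node")
  # all neighbors connect only back to a -> empty open result
  ents <- data.frame(entity_id = c("A", "B"), entity_type = "Gene",
                     surface = c("aa", "bb"))
  g2 <- build_graph(aggregate_counts(generate_corpus(
    corpus_spec(ents, pairs = data.frame(id1 = "A", id2 = "B",
                                         count = 2L)))))
  expect_equal(nrow(open_discovery(g2, "A")$candidates), 0L)
})

test_that("rank_candidates is deterministic with identifier tie-break", {
  r <- rank_candidates(data.frame(id = c("X", "Y"), score = c(5, 3)))
  expect_equal(r$rank, 1:2)
  expect_equal(r$id, c("X", "Y"))
  tie <- rank_candidates(data.frame(id = c("Y", "X"), score = c(5, 5)))
  expect_equal(tie$id, c("X", "Y"))
  one <- rank_candidates(data.frame(id = "Z", score = 0.1))
  expect_equal(one$rank, 1L)
})

test_that("defaults are jaccard / min / sum and are recorded in results", {
  cfg <- scoring_config()
  expect_equal(cfg$metric, "jaccard")
  expect_equal(cfg$fg, "min")
  expect_equal(cfg$fc, "sum")
  g <- worked_example_graph()
  open <- open_discovery(g, "a1")
  expect_equal(open$config$metric, "jaccard")
  expect_equal(open$config$fg, "min")
  expect_equal(open$config$fc, "sum")
  closed <- closed_discovery(g, "a1", "c1")
  expect_equal(closed$config$metric, "jaccard")
  expect_equal(closed$config$fg, "min")
})

test_that("closed discovery is symmetric in the query pair", {
  g <- random_corpus_graph(21L, n_entities = 40L, n_pairs = 120L)
  picked <- 0L
  for (a in g$nodes$entity_id[1:10]) for (c in g$nodes$entity_id[11:20]) {
    if (a == c) next
    r1 <- closed_discovery(g, a, c, scoring_config("npmi", "avg"))
    r2 <- closed_discovery(g, c, a, scoring_config("npmi", "avg"))
    expect_equal(r1$candidates$id, r2$candidates$id)
    expect_equal(r1$candidates$score, r2$candidates$score,
                 tolerance = 1e-12)
    picked <- picked + 1L
  }
  expect_gt(picked, 0L)
})

test_that("open candidates never include the query or its direct neighbors", {
  for (seed in c(5L, 6L)) {
    g <- random_corpus_graph(seed, n_entities = 50L, n_pairs = 140L)
    for (a in g$nodes$entity_id[1:5]) {
      cand <- open_discovery(g, a)$candidates$id
      expect_false(a %in% cand)
      expect_length(intersect(cand, graph_neighbors(g, a)), 0L)
      # every candidate shares at least one neighbor with a
      for (c in cand)
        expect_gt(length(intersect(graph_neighbors(g, a),
                                   graph_neighbors(g, c))), 0L)
    }
  }
})

test_that("fc=max with fg=min equals an independent widest-path computation", {
  g <- random_corpus_graph(31L, n_entities = 40L, n_pairs = 120L)
  # max-min matrix "product" over exactly two hops, written from scratch
  ids <- g$nodes$entity_id
  W <- matrix(-Inf, length(ids), length(ids), dimnames = list(ids, ids))
  wt <- edge_weights(g, "count")
  for (k in seq_len(nrow(wt))) {
    W[wt$id1[k], wt$id2[k]] <- wt$w[k]
    W[wt$id2[k], wt$id1[k]] <- wt$w[k]
  }
  a <- ids[1]
  bottleneck <- sapply(ids, function(c)
    max(pmin(W[a, ], W[, c])))     # widest 2-hop path a -> c
  res <- open_discovery(g, a, scoring_config("count", fg = "min",
                                             fc = "max"))
  for (k in seq_len(nrow(res$candidates)))
    expect_equal(res$candidates$score[k],
                 unname(bottleneck[res$candidates$id[k]]))
})

test_that("negative weights rank below positive ones, unclamped", {
  # construct an edge with negative association: pair co-occurs once while
  # both entities are frequent
  ents <- data.frame(entity_id = c("A", "B", "C", "F1", "F2"),
                     entity_type = "Gene", surface = paste0("w", 1:5))
  spec <- corpus_spec(ents, pairs = data.frame(
    id1 = c("A", "B", "A", "B", "B"),
    id2 = c("B", "C", "F1", "F2", "F1"),
    count = c(1L, 30L, 40L, 40L, 2L)))
  g <- build_graph(aggregate_counts(generate_corpus(spec)))
  expect_lt(edge_weight(g, "npmi", "A", "B"), 0)
  closed <- closed_discovery(g, "A", "C", scoring_config("npmi", "min"))
  expect_true(any(closed$candidates$score < 0))
})

test_that("optimized discovery equals the brute-force oracle on the worked example", {
  g <- worked_example_graph()
  for (m in c("count", "jaccard")) for (fg in c("min", "sum")) {
    cfg <- scoring_config(m, fg, "sum")
    expect_tables_equal(closed_discovery(g, "a1", "c1", cfg)$candidates,
                        discovery_oracle(g, "a1", "c1", cfg)$candidates)
    expect_tables_equal(open_discovery(g, "a1", cfg)$candidates,
                        discovery_oracle(g, "a1", config = cfg)$candidates)
  }
  # empty graph -> empty oracle results
  ge <- build_graph(aggregate_counts(lbd_corpus(
    data.frame(doc_id = "d", text = "nothing.", year = 2000L),
    sentences = data.frame(doc_id = "d", sentence_index = 0L, start = 0L,
                           end = 8L))))
  expect_equal(nrow(ge$nodes), 0L)
})

test_that("result serialization embeds query, config and candidates", {
  g <- worked_example_graph()
  res <- closed_discovery(g, "a1", "c1", scoring_config("count", "sum"))
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(jf, tf)))
  write_result(res, jf, "json")
  obj <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(obj$query$mode, "closed")
  expect_equal(obj$config$metric, "count")
  expect_equal(obj$candidates$score, c(12, 4))
  write_result(res, tf, "tsv")
  expect_equal(data.table::fread(tf)$id, c("b1", "b2"))
})
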