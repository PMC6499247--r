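# Shared fixture builders; everything is generated in code.

# 5-node illustration graph: one strong edge (a1,b1)=10, three edges of
# weight 2, two disjoint paths a1-b1-c1 and a1-b2-c1
worked_example_spec <- function() {
  corpus_spec(
    entities = data.frame(
      entity_id = c("a1", "b1", "b2", "c1"),
      entity_type = "Gene",
      surface = c("alpha", "betaone", "betatwo", "gammaone")),
    pairs = data.frame(id1 = c("a1", "a1", "b1", "b2"),
                       id2 = c("b1", "b2", "c1", "c1"),
                       count = c(10L, 2L, 2L, 2L)))
}

worked_example_graph <- function() {
  build_graph(aggregate_counts(generate_corpus(worked_example_spec())))
}

# random entity graph backed by a generated corpus; reproducible per seed
random_corpus_graph <- function(seed, n_entities = 100L, n_pairs = 220L,
                                max_count = 3L) {
  withr_seed(seed, {
    ids <- sprintf("E%03d", seq_len(n_entities))
    all_pairs <- t(utils::combn(n_entities, 2L))
    sel <- sample(nrow(all_pairs), n_pairs)
    ents <- data.frame(entity_id = ids,
                       entity_type = sample(c("Gene", "Chemical", "Disease"),
                                            n_entities, replace = TRUE),
                       surface = paste0("name_", ids))
    pairs <- data.frame(id1 = ids[all_pairs[sel, 1]],
                        id2 = ids[all_pairs[sel, 2]],
                        count = sample(seq_len(max_count), n_pairs,
                                       replace = TRUE))
    build_graph(aggregate_counts(generate_corpus(corpus_spec(ents, pairs))))
  })
}

# planted A-B-C discovery over a random background of weaker associations
planted_discovery_corpus <- function(seed = 42L, n_background = 50L,
                                     ab = 100L, bc = 100L,
                                     pre_year = 2000L, post_year = 2010L,
                                     ac = 0L) {
  withr_seed(seed, {
    bg_ids <- sprintf("BG%03d", seq_len(n_background))
    ids <- c("AAA", "BBB", "CCC", bg_ids)
    ents <- data.frame(entity_id = ids, entity_type = "Chemical",
                       surface = paste0("name", ids))
    # weak random background associations among background entities and to
    # the planted nodes (but never A-C)
    n_bg_pairs <- 150L
    p1 <- sample(ids, n_bg_pairs, replace = TRUE)
    p2 <- sample(ids, n_bg_pairs, replace = TRUE)
    keep <- p1 != p2 &
      !(pmin(p1, p2) == "AAA" & pmax(p1, p2) == "CCC")
    pairs <- data.frame(id1 = p1[keep], id2 = p2[keep],
                        count = sample(1:5, sum(keep), replace = TRUE),
                        year = pre_year)
    spec <- corpus_spec(ents, pairs, default_year = pre_year)
    spec <- plant_discovery(spec, "AAA", "BBB", "CCC",
                            ab_count = ab, bc_count = bc, ac_count = ac,
                            pre_cutoff_year = pre_year,
                            post_cutoff_year = post_year)
    generate_corpus(spec)
  })
}

# run code under a seed without clobbering the session RNG state
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# a small PubTator record set used across corpus-io tests
tiny_pubtator_lines <- function() {
  c("123|t|p53 and cancer.",
    "123|a|TP53 regulates apoptosis.",
    "123\t0\t3\tp53\tGene\tPR:000003035",
    "123\t16\t20\tTP53\tGene\tPR:000003035",
    "",
    "456|t|Magnesium helps migraine.",
    "456|a|A second sentence here.",
    "456\t0\t9\tMagnesium\tChemical\tMESH:D008274",
    "456\t16\t24\tmigraine\tDisease\t-",
    "")
}

withr_tempfile <- function(lines) {
  tf <- tempfile()
  writeLines(lines, tf)
  tf
}

expect_tables_equal <- function(x, y, tolerance = NULL) {
  args <- list(as.data.frame(x), as.data.frame(y),
               ignore_attr = TRUE)
  if (!is.null(tolerance)) args$tolerance <- tolerance
  do.call(expect_equal, args)
}
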