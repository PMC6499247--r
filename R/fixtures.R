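#' Specification of a synthetic annotated corpus
#'
#' Describes a corpus with controlled co-occurrence structure. In
#' `deterministic` mode the generator emits one template sentence per
#' requested co-occurrence or solo event, so aggregated sentence counts
#' realize the requested counts exactly. In `sampled` mode each generated
#' sentence includes each entity independently with its stated inclusion
#' probability, reproducibly from `seed`.
#'
#' @param entities data.frame with columns `entity_id`, `entity_type`,
#'   `surface` (several rows per id allowed; the first surface is used in
#'   generated text)
#' @param pairs data.frame of requested sentence co-occurrence events:
#'   columns `id1`, `id2`, `count`, optional `year`
#' @param singletons data.frame of requested solo-sentence events: columns
#'   `id`, `count`, optional `year`
#' @param default_year year for events without one
#' @param sentences_per_doc events per generated document (default 1, so
#'   sentence and document counts coincide; larger values exercise the
#'   doc-count vs count divergence)
#' @param mode `"deterministic"` or `"sampled"`
#' @param n_docs,inclusion_probs sampled mode: number of single-sentence
#'   documents and a named numeric vector of per-entity Bernoulli inclusion
#'   probabilities
#' @param seed integer seed for sampled mode
#' @return a `corpus_spec` object
#' @export
corpus_spec <- function(entities, pairs = NULL, singletons = NULL,
                        default_year = 2000L, sentences_per_doc = 1L,
                        mode = c("deterministic", "sampled"),
                        n_docs = 0L, inclusion_probs = NULL, seed = 1L) {
  mode <- match.arg(mode)
  entities <- as.data.table(entities)
  stopifnot(all(c("entity_id", "entity_type", "surface") %in% names(entities)))
  fix <- function(x, empty) {
    if (is.null(x) || !nrow(as.data.table(x))) return(empty)
    x <- as.data.table(x)[, intersect(names(empty), names(x)), with = FALSE]
    if (!"year" %in% names(x)) x[, year := as.integer(default_year)]
    x[is.na(year), year := as.integer(default_year)]
    x[, year := as.integer(year)]
    x[, count := as.integer(count)]
    x
  }
  pairs <- fix(pairs, data.table(id1 = character(), id2 = character(),
                                 count = integer(), year = integer()))
  singletons <- fix(singletons, data.table(id = character(),
                                           count = integer(),
                                           year = integer()))
  known <- unique(entities$entity_id)
  unknown <- setdiff(c(pairs$id1, pairs$id2, singletons$id), known)
  if (length(unknown))
    stop("unknown entity in requested counts: ",
         paste(unknown, collapse = ", "))
  if (nrow(pairs) && any(pairs$id1 == pairs$id2))
    stop("pair counts require two distinct entities")
  if (any(c(pairs$count, singletons$count) < 0))
    stop("requested counts must be non-negative")
  structure(list(entities = entities, pairs = pairs, singletons = singletons,
                 default_year = as.integer(default_year),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 mode = mode, n_docs = as.integer(n_docs),
                 inclusion_probs = inclusion_probs, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Plant an indirect A-B-C association into a corpus specification
#'
#' Adds `ab_count` A-B and `bc_count` B-C sentence co-occurrence events
#' dated `pre_cutoff_year`, and, when `ac_count > 0`, A-C events dated
#' `post_cutoff_year`. With `ac_count = 0` no generated document contains
#' both A and C (in deterministic mode each event document holds only its
#' own pair), mirroring the curation constraint that a valid discovery case
#' has strong A-B and B-C literatures but no A-C co-occurrence before the
#' discovery.
#'
#' @param spec a [corpus_spec()]
#' @param a_id,b_id,c_id entity identifiers present in `spec`
#' @param ab_count,bc_count positive event counts (default 100, the
#'   curation threshold used for the evaluation triples)
#' @param ac_count A-C events after the cutoff (0 for a clean case)
#' @param pre_cutoff_year,post_cutoff_year event years
#' @return the augmented `corpus_spec`
#' @export
plant_discovery <- function(spec, a_id, b_id, c_id,
                            ab_count = 100L, bc_count = 100L, ac_count = 0L,
                            pre_cutoff_year = 2000L,
                            post_cutoff_year = 2010L) {
  stopifnot(inherits(spec, "corpus_spec"))
  known <- unique(spec$entities$entity_id)
  missing <- setdiff(c(a_id, b_id, c_id), known)
  if (length(missing))
    stop("plant_discovery: entities not in spec: ",
         paste(missing, collapse = ", "))
  if (ac_count > 0 && post_cutoff_year <= pre_cutoff_year)
    stop("ac_count > 0 requires post_cutoff_year > pre_cutoff_year")
  add <- data.table(id1 = c(a_id, b_id), id2 = c(b_id, c_id),
                    count = as.integer(c(ab_count, bc_count)),
                    year = as.integer(pre_cutoff_year))
  if (ac_count > 0)
    add <- rbind(add, data.table(id1 = a_id, id2 = c_id,
                                 count = as.integer(ac_count),
                                 year = as.integer(post_cutoff_year)))
  spec$pairs <- rbind(spec$pairs, add)
  spec
}

# evaluate `expr` under a private RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# template sentence embedding the given surfaces with filler tokens;
# returns text plus 0-based mention offsets
.template_sentence <- function(surfaces) {
  fill <- " and "
  body <- paste(surfaces, collapse = fill)
  text <- paste0(body, " interact in this study.")
  starts <- integer(length(surfaces))
  pos <- 0L
  for (k in seq_along(surfaces)) {
    starts[k] <- pos
    pos <- pos + nchar(surfaces[k]) + nchar(fill)
  }
  list(text = text, start = starts,
       end = starts + nchar(surfaces))
}

#' Generate a synthetic annotated corpus
#'
#' Realizes a [corpus_spec()]: deterministic mode emits the requested
#' pair/solo events as template sentences with recorded mention offsets
#' (grouped `sentences_per_doc` per document within a year); sampled mode
#' draws `n_docs` single-sentence documents with independent per-entity
#' Bernoulli inclusion. The output is a fully segmented [lbd_corpus()].
#'
#' @param spec a [corpus_spec()]
#' @return an [lbd_corpus()]
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  ent <- spec$entities[!duplicated(entity_id)]
  setkey(ent, entity_id)
  events <- list()   # each: list(ids, year)
  if (spec$mode == "deterministic") {
    for (i in seq_len(nrow(spec$pairs))) {
      p <- spec$pairs[i]
      if (p$count > 0)
        events <- c(events, rep(list(list(ids = c(p$id1, p$id2),
                                          year = p$year)), p$count))
    }
    for (i in seq_len(nrow(spec$singletons))) {
      s <- spec$singletons[i]
      if (s$count > 0)
        events <- c(events, rep(list(list(ids = s$id, year = s$year)),
                                s$count))
    }
  } else {
    probs <- spec$inclusion_probs
    if (is.null(probs) || is.null(names(probs)))
      stop("sampled mode requires named inclusion_probs")
    ids <- names(probs)
    draws <- .with_seed(spec$seed, {
      matrix(stats::runif(spec$n_docs * length(ids)) < rep(probs, each = spec$n_docs),
             nrow = spec$n_docs)
    })
    for (d in seq_len(spec$n_docs)) {
      inc <- ids[draws[d, ]]
      events[[length(events) + 1L]] <- list(ids = inc,
                                            year = spec$default_year)
    }
  }
  if (!length(events))
    return(lbd_corpus(data.table(doc_id = character(), text = character(),
                                 year = integer())))
  # group events into documents, never across years
  years <- vapply(events, `[[`, integer(1), "year")
  ord <- order(years, seq_along(events))
  events <- events[ord]; years <- years[ord]
  k <- max(1L, spec$sentences_per_doc)
  grp <- integer(length(events)); g <- 0L; n_in <- 0L; last_year <- NA_integer_
  for (i in seq_along(events)) {
    if (n_in == 0L || n_in >= k || !identical(years[i], last_year)) {
      g <- g + 1L; n_in <- 0L
    }
    grp[i] <- g; n_in <- n_in + 1L; last_year <- years[i]
  }
  docs <- list(); sents <- list(); ments <- list()
  for (gid in unique(grp)) {
    ev <- events[grp == gid]
    doc_id <- sprintf("SYN%07d", gid)
    pos <- 0L
    texts <- character(length(ev))
    for (si in seq_along(ev)) {
      ids <- ev[[si]]$ids
      surfaces <- if (length(ids)) ent[J(ids), surface] else character()
      ts <- if (length(ids)) .template_sentence(surfaces) else
        list(text = "Nothing of note happened.", start = integer(),
             end = integer())
      texts[si] <- ts$text
      sents[[length(sents) + 1L]] <- data.table(
        doc_id = doc_id, sentence_index = si - 1L,
        start = pos, end = pos + nchar(ts$text))
      if (length(ids))
        ments[[length(ments) + 1L]] <- data.table(
          doc_id = doc_id, sentence_index = si - 1L,
          start = pos + ts$start, end = pos + ts$end,
          surface = surfaces, entity_type = ent[J(ids), entity_type],
          entity_id = ids)
      pos <- pos + nchar(ts$text) + 1L   # single joining space
    }
    docs[[length(docs) + 1L]] <- data.table(
      doc_id = doc_id, text = paste(texts, collapse = " "),
      year = ev[[1]]$year)
  }
  lbd_corpus(rbindlist(docs),
             if (length(ments)) rbindlist(ments) else NULL,
             rbindlist(sents))
}
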