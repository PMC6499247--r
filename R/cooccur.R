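#' Extract sentence-level co-occurrence instances
#'
#' A pair of entities co-occurs in a sentence iff each has at least one
#' grounded mention in that sentence; the instance is counted once per
#' (document, sentence, pair) regardless of mention multiplicity. Entities
#' of any type pair up; filtering happens at query time.
#'
#' @param corpus an [lbd_corpus()] with sentence indices assigned (see
#'   [segment_corpus()])
#' @return data.table `doc_id`, `sentence_index`, `id1`, `id2` with the
#'   pair in canonical (lexicographically sorted) order, one row per
#'   instance
#' @export
extract_instances <- function(corpus) {
  stopifnot(inherits(corpus, "lbd_corpus"))
  occ <- .entity_sentence_occurrences(corpus)
  if (!nrow(occ))
    return(data.table(doc_id = character(), sentence_index = integer(),
                      id1 = character(), id2 = character()))
  pairs <- occ[occ, on = .(doc_id, sentence_index), allow.cartesian = TRUE][
    entity_id < i.entity_id,
    .(doc_id, sentence_index, id1 = entity_id, id2 = i.entity_id)]
  unique(pairs)
}

# unique grounded (doc, sentence, entity) occurrences
.entity_sentence_occurrences <- function(corpus) {
  unique(corpus$mentions[!is.na(entity_id),
                         .(doc_id, sentence_index, entity_id)])
}

#' Aggregate a corpus into co-occurrence count statistics
#'
#' Produces the sufficient statistics behind every association metric:
#' per-entity and per-pair sentence counts, document counts, and corpus
#' totals, retained at document granularity (with doc-id postings per pair)
#' so that time-sliced snapshots and document-level pair exclusion are
#' exact recounts rather than approximations.
#'
#' Document-level pair co-occurrence follows `doc_cooccur`:
#' `"same_sentence"` (default) counts a document when the pair co-occurs in
#' at least one of its sentences, consistent with the sentence-centric
#' metrics; `"anywhere"` counts a document when both entities appear in it
#' at all, even in different sentences.
#'
#' Documents with an unknown (`NA`) year are excluded with a warning.
#'
#' @param corpus an [lbd_corpus()] with sentences populated
#' @param doc_cooccur document-level co-occurrence dialect
#' @return an `lbd_counts` object
#' @export
aggregate_counts <- function(corpus,
                             doc_cooccur = c("same_sentence", "anywhere")) {
  stopifnot(inherits(corpus, "lbd_corpus"))
  doc_cooccur <- match.arg(doc_cooccur)
  docs <- corpus$documents
  if (nrow(docs) && anyNA(docs$year)) {
    n_na <- sum(is.na(docs$year))
    warning(sprintf("aggregate_counts: %d document(s) with unknown year excluded",
                    n_na), call. = FALSE)
    keep <- docs[!is.na(year), doc_id]
    corpus <- lbd_corpus(docs[doc_id %in% keep],
                         corpus$mentions[doc_id %in% keep],
                         corpus$sentences[doc_id %in% keep])
    docs <- corpus$documents
  }
  n_sent_per_doc <- corpus$sentences[, .(n_sentences = .N), by = doc_id]
  doc_tab <- merge(docs[, .(doc_id, year)], n_sent_per_doc,
                   by = "doc_id", all.x = TRUE)
  doc_tab[is.na(n_sentences), n_sentences := 0L]
  occ <- .entity_sentence_occurrences(corpus)
  types <- corpus$mentions[!is.na(entity_id),
                           .N, by = .(entity_id, entity_type)][
    order(entity_id, -N, entity_type)][!duplicated(entity_id),
                                       .(entity_id, entity_type)]
  structure(list(docs = doc_tab,
                 occurrences = occ,
                 instances = extract_instances(corpus),
                 entity_types = types,
                 doc_cooccur = doc_cooccur),
            class = "lbd_counts")
}

#' @export
print.lbd_counts <- function(x, ...) {
  t <- counts_totals(x)
  cat(sprintf("<lbd_counts> %d documents, %d sentences, %d entities, %d pairs (doc_cooccur=%s)\n",
              t$n_doc, t$n_sent, nrow(entity_counts(x)),
              nrow(pair_counts(x)), x$doc_cooccur))
  invisible(x)
}

#' Corpus totals of a count object
#'
#' @param counts an `lbd_counts`
#' @return list with `n_sent` (total sentences) and `n_doc`
#' @export
counts_totals <- function(counts) {
  list(n_sent = sum(counts$docs$n_sentences),
       n_doc = nrow(counts$docs))
}

#' Per-entity sentence and document counts
#'
#' @param counts an `lbd_counts`
#' @param by_year if `TRUE`, counts are reported per publication year
#' @return data.table `entity_id` (, `year`), `n` (sentences), `d`
#'   (documents)
#' @export
entity_counts <- function(counts, by_year = FALSE) {
  occ <- counts$occurrences[counts$docs, on = "doc_id", nomatch = NULL]
  grp <- if (by_year) c("entity_id", "year") else "entity_id"
  out <- occ[, .(n = .N, d = uniqueN(doc_id)), by = grp]
  setorderv(out, grp)
  out[]
}

#' Per-pair sentence and document counts
#'
#' @inheritParams entity_counts
#' @return data.table `id1`, `id2` (, `year`), `n_ab` (sentences), `d_ab`
#'   (documents, per the count object's `doc_cooccur` dialect)
#' @export
pair_counts <- function(counts, by_year = FALSE) {
  inst <- counts$instances[counts$docs, on = "doc_id", nomatch = NULL]
  grp <- if (by_year) c("id1", "id2", "year") else c("id1", "id2")
  out <- inst[, .(n_ab = .N, d_ab = uniqueN(doc_id)), by = grp]
  if (counts$doc_cooccur == "anywhere") {
    d <- .doc_pairs_anywhere(counts)[counts$docs, on = "doc_id",
                                     nomatch = NULL]
    dcnt <- d[, .(d_ab2 = uniqueN(doc_id)), by = grp]
    out[dcnt, d_ab := i.d_ab2, on = grp]
  }
  setorderv(out, grp)
  out[]
}

# document-level pairs under the "anywhere in the document" dialect
.doc_pairs_anywhere <- function(counts) {
  docc <- unique(counts$occurrences[, .(doc_id, entity_id)])
  j <- docc[docc, on = "doc_id", allow.cartesian = TRUE]
  unique(j[entity_id < i.entity_id,
           .(doc_id, id1 = entity_id, id2 = i.entity_id)])
}

#' Documents in which a pair co-occurs at document level
#'
#' Always uses the strict "both entities appear anywhere in the document"
#' sense, so that exclusion built on it guarantees that no surviving
#' document contains both entities.
#'
#' @param counts an `lbd_counts`
#' @param id_a,id_b entity identifiers
#' @return character vector of doc_ids
#' @export
pair_documents <- function(counts, id_a, id_b) {
  occ <- counts$occurrences
  intersect(occ[entity_id == id_a, unique(doc_id)],
            occ[entity_id == id_b, unique(doc_id)])
}

#' Time-sliced (and pair-excluded) snapshot of count statistics
#'
#' Restricts the counts to documents published in or before `cutoff_year`
#' (inclusive). When `exclude_pair` is given, every document in which the
#' two entities co-occur at document level is removed entirely *before*
#' aggregation, so the excluded pair's snapshot count is zero and all other
#' counts contributed by those documents vanish too — the evaluation
#' protocol's A–C exclusion.
#'
#' @param x an `lbd_counts` or an [lbd_corpus()] (aggregated on the fly)
#' @param cutoff_year inclusive year cutoff (`Inf` = no cutoff)
#' @param exclude_pair optional character vector of two entity identifiers
#' @param ... passed to [aggregate_counts()] for the corpus method
#' @return an `lbd_counts` restricted to the surviving documents
#' @export
snapshot <- function(x, cutoff_year = Inf, exclude_pair = NULL, ...) {
  UseMethod("snapshot")
}

#' @export
snapshot.lbd_corpus <- function(x, cutoff_year = Inf, exclude_pair = NULL,
                                ...) {
  snapshot(aggregate_counts(x, ...), cutoff_year, exclude_pair)
}

#' @export
snapshot.lbd_counts <- function(x, cutoff_year = Inf, exclude_pair = NULL,
                                ...) {
  keep <- x$docs[year <= cutoff_year, doc_id]
  if (!is.null(exclude_pair)) {
    stopifnot(length(exclude_pair) == 2L)
    keep <- setdiff(keep, pair_documents(x, exclude_pair[1],
                                         exclude_pair[2]))
  }
  out <- x
  out$docs <- x$docs[doc_id %in% keep]
  out$occurrences <- x$occurrences[doc_id %in% keep]
  out$instances <- x$instances[doc_id %in% keep]
  out$entity_types <- x$entity_types[
    entity_id %in% out$occurrences$entity_id]
  out
}

#' Export count tables as TSV
#'
#' Writes `<prefix>_entities.tsv` (`entity_id`, `year`, `sentence_count`,
#' `doc_count`) and `<prefix>_pairs.tsv` (`id1`, `id2`, `year`,
#' `sentence_count`, `doc_count`).
#'
#' @param counts an `lbd_counts`
#' @param prefix output path prefix
#' @return the two paths, invisibly
#' @export
write_count_tables <- function(counts, prefix) {
  ep <- paste0(prefix, "_entities.tsv")
  pp <- paste0(prefix, "_pairs.tsv")
  e <- entity_counts(counts, by_year = TRUE)
  setnames(e, c("n", "d"), c("sentence_count", "doc_count"))
  fwrite(e, ep, sep = "\t")
  p <- pair_counts(counts, by_year = TRUE)
  setnames(p, c("n_ab", "d_ab"), c("sentence_count", "doc_count"))
  fwrite(p, pp, sep = "\t")
  invisible(c(ep, pp))
}
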