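#' Build a string-to-identifier index from grounded mentions
#'
#' Counts, over the grounded mentions of a corpus, how often each surface
#' string is grounded to each identifier. The index drives query resolution
#' (which identifiers does "p53" commonly refer to?) and display labels
#' (which string best names PR:000003035?). Ungrounded mentions contribute
#' nothing.
#'
#' @param x an [lbd_corpus()] or a mention table
#' @return an `lbd_string_index`: a keyed table `surface`, `entity_id`, `n`
#' @export
build_string_index <- function(x) {
  mentions <- if (inherits(x, "lbd_corpus")) x$mentions else as.data.table(x)
  idx <- mentions[!is.na(entity_id),
                  .(n = .N), by = .(surface, entity_id)]
  setkey(idx, surface, entity_id)
  structure(idx, class = c("lbd_string_index", class(idx)))
}

#' Resolve a query string to candidate identifiers
#'
#' Candidates are ranked by descending grounding frequency, ties broken by
#' ascending identifier. Each candidate carries the alternative surface
#' strings grounded to the same identifier (most frequent first), which is
#' what disambiguates e.g. a species sense from a disease sense of the same
#' name.
#'
#' @param index an index from [build_string_index()]
#' @param string query surface string
#' @return data.table `entity_id`, `n`, `alt_surfaces` (list column);
#'   zero rows for an unknown string
#' @export
resolve_query <- function(index, string) {
  hits <- index[surface == string][order(-n, entity_id)]
  if (!nrow(hits))
    return(data.table(entity_id = character(), n = integer(),
                      alt_surfaces = list()))
  hits[, alt_surfaces := lapply(entity_id, function(id)
    index[entity_id == id][order(-n, surface), surface])]
  hits[, .(entity_id, n, alt_surfaces)]
}

#' Preferred display label for an identifier
#'
#' The surface string most frequently grounded to the identifier; ties are
#' broken lexicographically.
#'
#' @param index an index from [build_string_index()]
#' @param id entity identifier
#' @return a single string
#' @export
preferred_label <- function(index, id) {
  hits <- index[entity_id == id]
  if (!nrow(hits)) stop("unknown identifier: ", id)
  hits[order(-n, surface), surface][1]
}

#' Export a string index as TSV
#'
#' Columns `string`, `identifier`, `frequency`.
#' @param index an `lbd_string_index`
#' @param path output path
#' @export
write_string_index <- function(index, path) {
  out <- as.data.table(index)[order(surface, -n, entity_id),
                              .(string = surface, identifier = entity_id,
                                frequency = n)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Identifier generalization mapping
#'
#' A single-step source-to-target identifier table (e.g. NCBI Gene to
#' Protein Ontology at homolog-abstracting level). The mapping is a
#' function — one target per source — and is applied once, with no
#' transitive chasing; pre-compose chains before loading.
#'
#' `policy` controls grounded identifiers that share a namespace prefix
#' (the part before `:`) with some mapping source but have no entry:
#' `keep_unmapped` (default) passes them through so they remain graph nodes
#' under their original id; `drop_unmapped_from_graph` un-grounds them, so
#' they stay in the mention-level data but are excluded from the
#' entity-level graph.
#'
#' @param table data.frame with columns `source_id`, `target_id`
#' @param policy unmapped-source policy, see above
#' @return an `id_mapping` object
#' @export
id_mapping <- function(table,
                       policy = c("keep_unmapped",
                                  "drop_unmapped_from_graph")) {
  policy <- match.arg(policy)
  table <- as.data.table(table)[, .(source_id = as.character(source_id),
                                    target_id = as.character(target_id))]
  table <- unique(table)
  if (anyDuplicated(table$source_id))
    stop("id_mapping: multiple targets for source(s): ",
         paste(unique(table$source_id[duplicated(table$source_id)]),
               collapse = ", "))
  structure(list(table = table, policy = policy,
                 prefixes = unique(sub(":.*$", "", table$source_id))),
            class = "id_mapping")
}

#' Read an identifier mapping table
#'
#' Two-column TSV `source_id`, `target_id`; `#` comment lines allowed.
#'
#' @param path TSV path
#' @inheritParams id_mapping
#' @return an [id_mapping()]
#' @export
read_id_mapping <- function(path, policy = "keep_unmapped") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines))
    return(id_mapping(data.table(source_id = character(),
                                 target_id = character()), policy))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("read_id_mapping: malformed line(s): ",
         paste(head(bad, 5), collapse = ", "))
  hdr <- identical(tolower(parts[[1]][1:2]), c("source_id", "target_id"))
  if (hdr) parts <- parts[-1]
  id_mapping(data.table(source_id = vapply(parts, `[`, "", 1),
                        target_id = vapply(parts, `[`, "", 2)),
             policy)
}

#' Apply identifier generalization to mentions
#'
#' Mentions whose `entity_id` is a mapping source receive the target id;
#' other grounded ids pass through (or are un-grounded under the
#' `drop_unmapped_from_graph` policy when they share a source namespace);
#' ungrounded mentions always pass through untouched. Idempotent whenever
#' mapping targets are not themselves sources.
#'
#' @param x an [lbd_corpus()] or a mention table
#' @param mapping an [id_mapping()]
#' @return object of the same type with generalized identifiers
#' @export
apply_id_mapping <- function(x, mapping) {
  stopifnot(inherits(mapping, "id_mapping"))
  if (inherits(x, "lbd_corpus")) {
    x$mentions <- apply_id_mapping(x$mentions, mapping)
    return(x)
  }
  mentions <- copy(as.data.table(x))
  if (!nrow(mentions) || !nrow(mapping$table)) return(mentions)
  tab <- mapping$table
  m <- match(mentions$entity_id, tab$source_id)
  mapped <- !is.na(m)
  mentions[mapped, entity_id := tab$target_id[m[mapped]]]
  if (mapping$policy == "drop_unmapped_from_graph") {
    pref <- sub(":.*$", "", mentions$entity_id)
    mentions[!mapped & !is.na(entity_id) & pref %in% mapping$prefixes,
             entity_id := NA_character_]
  }
  mentions[]
}

#' Mapping coverage of the distinct source identifiers in a corpus
#'
#' The fraction of distinct grounded identifiers in the source namespaces
#' of the mapping that have a mapping entry (the statistic behind coverage
#' claims like "the merged mapping identifies a target for ~95% of source
#' gene identifiers").
#'
#' @param x an [lbd_corpus()] or a mention table
#' @param mapping an [id_mapping()]
#' @return list with `n_source_ids`, `n_mapped`, `coverage` (proportion)
#' @export
mapping_coverage <- function(x, mapping) {
  mentions <- if (inherits(x, "lbd_corpus")) x$mentions else as.data.table(x)
  ids <- unique(mentions[!is.na(entity_id), entity_id])
  ids <- ids[sub(":.*$", "", ids) %in% mapping$prefixes]
  n_mapped <- sum(ids %in% mapping$table$source_id)
  list(n_source_ids = length(ids), n_mapped = n_mapped,
       coverage = if (length(ids)) n_mapped / length(ids) else NA_real_)
}
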