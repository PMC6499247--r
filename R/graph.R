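#' Build the entity-level co-occurrence graph
#'
#' Materializes the simple weighted graph G = (N, E): one node per entity
#' with at least one grounded mention in the snapshot, one undirected edge
#' per pair with sentence co-occurrence count `n_ab >= 1` (the system's
#' only edge-existence rule; `min_count` raises the threshold for noise
#' studies). Each edge carries its full contingency counts; weights for any
#' metric are computed lazily at query time.
#'
#' @param counts an `lbd_counts` (typically a [snapshot()])
#' @param min_count minimum sentence co-occurrence count for an edge
#'   (default 1)
#' @param labels optional `lbd_string_index` used to attach display labels
#'   via [preferred_label()]
#' @return an `lbd_graph`
#' @export
build_graph <- function(counts, min_count = 1L, labels = NULL) {
  stopifnot(inherits(counts, "lbd_counts"))
  tot <- counts_totals(counts)
  nodes <- entity_counts(counts)
  nodes <- merge(nodes, counts$entity_types, by = "entity_id", all.x = TRUE)
  nodes[, label := entity_id]
  if (!is.null(labels)) {
    have <- unique(as.data.table(labels)$entity_id)
    nodes[entity_id %in% have,
          label := vapply(entity_id, preferred_label, "", index = labels)]
  }
  setcolorder(nodes, c("entity_id", "entity_type", "label", "n", "d"))
  setkey(nodes, entity_id)
  edges <- pair_counts(counts)[n_ab >= min_count]
  setkey(edges, id1, id2)
  adj <- rbind(edges[, .(node = id1, nbr = id2)],
               edges[, .(node = id2, nbr = id1)])
  setkey(adj, node)
  structure(list(nodes = nodes, edges = edges, adjacency = adj,
                 n_sent = tot$n_sent, n_doc = tot$n_doc),
            class = "lbd_graph")
}

#' @export
print.lbd_graph <- function(x, ...) {
  cat(sprintf("<lbd_graph> %d nodes, %d edges (N_sent=%d, N_doc=%d)\n",
              nrow(x$nodes), nrow(x$edges), x$n_sent, x$n_doc))
  invisible(x)
}

#' Neighbors of a node
#'
#' @param graph an `lbd_graph`
#' @param node entity identifier in the graph
#' @return sorted character vector of adjacent entity identifiers
#' @export
graph_neighbors <- function(graph, node) {
  .check_node(graph, node)
  .query_id <- node   # avoid capture by the adjacency table's own columns
  sort(graph$adjacency[J(.query_id), nbr, nomatch = NULL])
}

.check_node <- function(graph, node) {
  if (!node %in% graph$nodes$entity_id)
    stop("unknown node: ", node)
  invisible(TRUE)
}

#' Contingency counts attached to an edge
#'
#' @param graph an `lbd_graph`
#' @param i,j entity identifiers joined by an edge
#' @return a [contingency_counts()]
#' @export
edge_contingency <- function(graph, i, j) {
  key <- sort(c(i, j))
  e <- graph$edges[J(key[1], key[2]), nomatch = NULL]
  if (!nrow(e)) stop(sprintf("no edge between %s and %s", i, j))
  na <- graph$nodes[J(key[1])]
  nb <- graph$nodes[J(key[2])]
  contingency_counts(n_ab = e$n_ab, n_a = na$n, n_b = nb$n,
                     n_sent = graph$n_sent,
                     d_ab = e$d_ab, d_a = na$d, d_b = nb$d,
                     n_doc = graph$n_doc)
}

#' Edge weight under a metric
#'
#' Symmetric in `(i, j)`; an absent edge is an error, distinct from a zero
#' weight.
#'
#' @param graph an `lbd_graph`
#' @param metric metric name, see [lbd_metrics()]
#' @param i,j entity identifiers joined by an edge
#' @return numeric weight
#' @export
edge_weight <- function(graph, metric, i, j) {
  compute_metric(metric, edge_contingency(graph, i, j))
}

#' Weights of all edges under a metric
#'
#' Vectorized evaluation over the whole edge set; used internally by the
#' discovery queries.
#'
#' @param graph an `lbd_graph`
#' @param metric metric name
#' @return data.table `id1`, `id2`, `w`, keyed on the pair
#' @export
edge_weights <- function(graph, metric) {
  metric <- match.arg(metric, lbd_metrics())
  e <- graph$edges
  if (!nrow(e))
    return(setkey(data.table(id1 = character(), id2 = character(),
                             w = numeric()), id1, id2))
  cc <- list(n_ab = e$n_ab,
             n_a = graph$nodes[J(e$id1), n],
             n_b = graph$nodes[J(e$id2), n],
             n_sent = graph$n_sent,
             d_ab = e$d_ab,
             d_a = graph$nodes[J(e$id1), d],
             d_b = graph$nodes[J(e$id2), d],
             n_doc = graph$n_doc)
  out <- data.table(id1 = e$id1, id2 = e$id2,
                    w = compute_metric(metric, cc))
  setkey(out, id1, id2)
  out
}

#' Export the graph as TSV tables
#'
#' Writes `<prefix>_nodes.tsv` (`id`, `type`, `label`, `n`, `d`) and
#' `<prefix>_edges.tsv` (`id_i`, `id_j`, `n_ab`, `d_ab`).
#'
#' @param graph an `lbd_graph`
#' @param prefix output path prefix
#' @return the two paths, invisibly
#' @export
write_graph_tables <- function(graph, prefix) {
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  fwrite(graph$nodes[, .(id = entity_id, type = entity_type, label, n, d)],
         np, sep = "\t")
  fwrite(graph$edges[, .(id_i = id1, id_j = id2, n_ab, d_ab)],
         ep, sep = "\t")
  invisible(c(np, ep))
}
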