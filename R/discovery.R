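#' Scoring configuration for discovery queries
#'
#' Bundles the edge-weight metric, the aggregation function `fg` that turns
#' the two edge weights of one A-B-C path into a path score, and the
#' accumulation function `fc` that combines the scores of all paths
#' reaching one open-discovery candidate. The defaults — Jaccard, `min`,
#' `sum` — are the configuration that performed most consistently across
#' both discovery settings in the system this design follows.
#'
#' `fg = "sum"` is accepted beyond the interactive trio `min`/`avg`/`max`
#' so that pure co-occurrence-frequency scoring is expressible.
#'
#' @param metric metric name, see [lbd_metrics()]
#' @param fg aggregation function: `"min"`, `"avg"`, `"max"` or `"sum"`
#' @param fc accumulation function: `"sum"` or `"max"`
#' @param type_filter optional character vector of entity types; candidates
#'   of other types are dropped before ranking
#' @return a `scoring_config` object
#' @export
scoring_config <- function(metric = "jaccard", fg = "min", fc = "sum",
                           type_filter = NULL) {
  structure(list(metric = match.arg(metric, lbd_metrics()),
                 fg = match.arg(fg, c("min", "avg", "max", "sum")),
                 fc = match.arg(fc, c("sum", "max")),
                 type_filter = type_filter),
            class = "scoring_config")
}

# vectorized path aggregation over the two edge weights of each path
.fg_apply <- function(fg, w1, w2) {
  switch(fg,
         min = pmin(w1, w2),
         max = pmax(w1, w2),
         avg = (w1 + w2) / 2,
         sum = w1 + w2)
}

#' Deterministic ranking of scored candidates
#'
#' Stable sort by descending score, ties broken by ascending entity
#' identifier; `rank` is the 1-based position. The tie rule is a package
#' convention — determinism is required for reproducible evaluation ranks.
#'
#' @param candidates data.table with columns `id` and `score`
#' @return the table ordered, with a `rank` column prepended
#' @export
rank_candidates <- function(candidates) {
  candidates <- as.data.table(candidates)
  setorder(candidates, -score, id)
  candidates[, rank := seq_len(.N)]
  setcolorder(candidates, "rank")
  candidates[]
}

#' Closed discovery: rank the intermediates linking two entities
#'
#' Given query nodes `a` and `c`, finds B = neighbors(a) n neighbors(c)
#' (minus the query nodes themselves) and scores each b by
#' `fg(w(a,b), w(b,c))` under the configured metric.
#'
#' @param graph an `lbd_graph`
#' @param a,c entity identifiers in the graph, `a != c`
#' @param config a [scoring_config()] (`fc` is not used in closed mode)
#' @return a `closed_result`: list with `a`, `c`, `config` and `candidates`
#'   (data.table `rank`, `id`, `score`, `w_ab`, `w_bc`)
#' @export
closed_discovery <- function(graph, a, c, config = scoring_config()) {
  .check_node(graph, a); .check_node(graph, c)
  if (a == c) stop("closed discovery requires two distinct query nodes")
  b <- setdiff(intersect(graph_neighbors(graph, a),
                         graph_neighbors(graph, c)), c(a, c))
  empty <- data.table(rank = integer(), id = character(),
                      score = numeric(), w_ab = numeric(),
                      w_bc = numeric())
  if (length(b)) {
    w <- edge_weights(graph, config$metric)
    w_ab <- .lookup_weights(w, a, b)
    w_bc <- .lookup_weights(w, b, c)
    cand <- data.table(id = b, score = .fg_apply(config$fg, w_ab, w_bc),
                       w_ab = w_ab, w_bc = w_bc)
    if (!is.null(config$type_filter))
      cand <- cand[graph$nodes[J(id), entity_type] %in% config$type_filter]
    cand <- rank_candidates(cand)
  } else cand <- empty
  structure(list(a = a, c = c, config = config, candidates = cand),
            class = "closed_result")
}

# weight of each (x_k, y_k) edge from a keyed weight table (canonical order)
.lookup_weights <- function(w, x, y) {
  k1 <- pmin(x, y); k2 <- pmax(x, y)
  w[J(k1, k2), w]
}

#' Open discovery: rank entities indirectly associated with a query
#'
#' Given a query node `a`, candidates are every node `c` at distance
#' exactly two from `a` (no direct edge, at least one shared neighbor,
#' `c != a`). Each two-edge path a-b-c is scored by `fg(w(a,b), w(b,c))`
#' and the path scores reaching one candidate are combined by `fc`.
#'
#' @param graph an `lbd_graph`
#' @param a entity identifier in the graph
#' @param config a [scoring_config()]
#' @return an `open_result`: list with `a`, `config` and `candidates`
#'   (data.table `rank`, `id`, `score`, `n_paths`)
#' @export
open_discovery <- function(graph, a, config = scoring_config()) {
  .check_node(graph, a)
  adj <- graph$adjacency
  b <- adj[J(a), nbr, nomatch = NULL]
  paths <- adj[J(b), .(b = node, id = nbr), nomatch = NULL]
  paths <- paths[id != a & !id %in% b]
  empty <- data.table(rank = integer(), id = character(),
                      score = numeric(), n_paths = integer())
  if (nrow(paths)) {
    w <- edge_weights(graph, config$metric)
    paths[, path_score := .fg_apply(config$fg,
                                    .lookup_weights(w, a, b),
                                    .lookup_weights(w, b, id))]
    cand <- paths[, .(score = if (config$fc == "sum") sum(path_score) else
      max(path_score), n_paths = .N), by = id]
    if (!is.null(config$type_filter))
      cand <- cand[graph$nodes[J(id), entity_type] %in% config$type_filter]
    cand <- rank_candidates(cand)
  } else cand <- empty
  structure(list(a = a, config = config, candidates = cand),
            class = "open_result")
}

#' @export
print.closed_result <- function(x, ...) {
  cat(sprintf("<closed_result> a=%s c=%s metric=%s fg=%s: %d candidate(s)\n",
              x$a, x$c, x$config$metric, x$config$fg, nrow(x$candidates)))
  if (nrow(x$candidates)) print(head(x$candidates, 10))
  invisible(x)
}

#' @export
print.open_result <- function(x, ...) {
  cat(sprintf("<open_result> a=%s metric=%s fg=%s fc=%s: %d candidate(s)\n",
              x$a, x$config$metric, x$config$fg, x$config$fc,
              nrow(x$candidates)))
  if (nrow(x$candidates)) print(head(x$candidates, 10))
  invisible(x)
}

#' Brute-force discovery oracle
#'
#' Reference implementation by exhaustive enumeration over all candidate
#' triples, using per-edge [edge_weight()] calls and no shared machinery
#' with the optimized query path beyond the metric definitions. Intended
#' for small graphs in tests; the optimized operations must match it
#' exactly.
#'
#' @param graph an `lbd_graph` (small)
#' @param a query node
#' @param c end node for closed mode, `NULL` for open mode
#' @param config a [scoring_config()]
#' @return a `closed_result` or `open_result`
#' @export
discovery_oracle <- function(graph, a, c = NULL, config = scoring_config()) {
  .check_node(graph, a)
  nodes <- graph$nodes$entity_id
  n <- length(nodes)
  # dense symmetric adjacency and weight matrices, assembled edge by edge
  # from the stored counts (small graphs only)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  W <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e)) {
    ii <- match(e$id1, nodes); jj <- match(e$id2, nodes)
    w <- compute_metric(config$metric, list(
      n_ab = e$n_ab, n_a = graph$nodes$n[ii], n_b = graph$nodes$n[jj],
      n_sent = graph$n_sent, d_ab = e$d_ab, d_a = graph$nodes$d[ii],
      d_b = graph$nodes$d[jj], n_doc = graph$n_doc))
    A[cbind(ii, jj)] <- A[cbind(jj, ii)] <- TRUE
    W[cbind(ii, jj)] <- W[cbind(jj, ii)] <- w
  }
  fg1 <- function(w1, w2) switch(config$fg, min = pmin(w1, w2),
                                 max = pmax(w1, w2), avg = (w1 + w2) / 2,
                                 sum = w1 + w2)
  if (!is.null(c)) {
    .check_node(graph, c)
    if (a == c) stop("closed discovery requires two distinct query nodes")
    rows <- list()
    for (b in nodes) {
      if (b == a || b == c) next
      if (A[a, b] && A[b, c])
        rows[[length(rows) + 1L]] <- data.table(
          id = b, score = fg1(W[a, b], W[b, c]),
          w_ab = W[a, b], w_bc = W[b, c])
    }
    cand <- if (length(rows)) rank_candidates(rbindlist(rows)) else
      data.table(rank = integer(), id = character(), score = numeric(),
                 w_ab = numeric(), w_bc = numeric())
    return(structure(list(a = a, c = c, config = config, candidates = cand),
                     class = "closed_result"))
  }
  rows <- list()
  for (cc in nodes) {
    if (cc == a || A[a, cc]) next
    bs <- nodes[A[a, ] & A[, cc]]
    bs <- setdiff(bs, c(a, cc))
    if (!length(bs)) next
    scores <- fg1(W[a, bs], W[bs, cc])
    rows[[length(rows) + 1L]] <- data.table(
      id = cc,
      score = if (config$fc == "sum") sum(scores) else max(scores),
      n_paths = length(scores))
  }
  cand <- if (length(rows)) rank_candidates(rbindlist(rows)) else
    data.table(rank = integer(), id = character(), score = numeric(),
               n_paths = integer())
  structure(list(a = a, config = config, candidates = cand),
            class = "open_result")
}

#' Serialize a discovery result
#'
#' JSON carries the query, the full resolved scoring configuration (for
#' provenance) and the ranked candidates; TSV carries the candidate table.
#'
#' @param result a `closed_result` or `open_result`
#' @param path output path (`.json` or `.tsv` chosen by `format`)
#' @param format `"json"` or `"tsv"`
#' @param top cap on the number of candidates written (ranks are computed
#'   on the full set first); `Inf` = all
#' @export
write_result <- function(result, path, format = c("json", "tsv"),
                         top = Inf) {
  format <- match.arg(format)
  cand <- result$candidates
  if (is.finite(top)) cand <- head(cand, top)
  if (format == "tsv") {
    fwrite(cand, path, sep = "\t")
    return(invisible(path))
  }
  obj <- list(query = if (inherits(result, "closed_result"))
    list(mode = "closed", a = result$a, c = result$c) else
      list(mode = "open", a = result$a),
    config = list(metric = result$config$metric, fg = result$config$fg,
                  fc = result$config$fc,
                  type_filter = result$config$type_filter),
    candidates = cand)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
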