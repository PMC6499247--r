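#' Load discovery evaluation cases
#'
#' Reads a TSV of (A, B, C, year) evaluation triples with columns `a_id`,
#' `b_id`, `c_id`, `discovery_year`, `mode` (`open`, `closed` or `both`).
#' `b_id` may be `-` or empty for open-only cases; closed (or `both`) mode
#' requires it. The evaluation cutoff for each case is
#' `discovery_year - 5`, inclusive: the snapshot uses literature up to five
#' years before the discovery report.
#'
#' @param path TSV path (`#` comment lines allowed)
#' @return data.table of validated cases with a `cutoff_year` column
#' @export
load_cases <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines))
    return(data.table(a_id = character(), b_id = character(),
                      c_id = character(), discovery_year = integer(),
                      mode = character(), cutoff_year = integer()))
  cases <- fread(text = lines, sep = "\t", header = TRUE,
                 colClasses = "character")
  need <- c("a_id", "b_id", "c_id", "discovery_year", "mode")
  missing <- setdiff(need, names(cases))
  if (length(missing))
    stop("case file missing column(s): ", paste(missing, collapse = ", "))
  cases <- cases[, ..need]
  cases[b_id %in% c("", "-"), b_id := NA_character_]
  cases[, discovery_year := as.integer(discovery_year)]
  if (!all(cases$mode %in% c("open", "closed", "both")))
    stop("mode must be one of open/closed/both")
  bad <- cases[mode %in% c("closed", "both") & is.na(b_id)]
  if (nrow(bad))
    stop("closed-mode case(s) without b_id: ",
         paste(bad$a_id, bad$c_id, sep = "~", collapse = ", "))
  cases[, cutoff_year := discovery_year - 5L]
  cases[]
}

#' Run one evaluation case
#'
#' Builds the time-sliced snapshot (years `<= discovery_year - 5`) with all
#' documents in which A and C co-occur excluded, builds the graph, runs the
#' query, and reports the 1-based rank of the expected node among the
#' retrieved candidates. In open mode the query is A and the expected node
#' is C; in closed mode the query is (A, C) and the expected node is B.
#'
#' @param corpus an [lbd_corpus()] (or a pre-aggregated `lbd_counts`)
#' @param case one row of [load_cases()] (or a list with the same fields)
#' @param config a [scoring_config()]
#' @param mode `"open"` or `"closed"` (required when the case says `both`)
#' @return list with `rank` (integer, `NA` when the target was not
#'   retrieved), `n_candidates`, `found`, `skipped` (TRUE when a query
#'   node is absent from the snapshot graph, with `reason`)
#' @export
run_case <- function(corpus, case, config = scoring_config(),
                     mode = NULL) {
  case <- as.list(case)
  mode <- mode %||% case$mode
  if (is.null(mode) || mode == "both")
    stop("run_case: specify mode 'open' or 'closed'")
  counts <- if (inherits(corpus, "lbd_counts")) corpus else
    aggregate_counts(corpus)
  snap <- snapshot(counts, cutoff_year = case$cutoff_year %||%
                     (case$discovery_year - 5L),
                   exclude_pair = c(case$a_id, case$c_id))
  graph <- build_graph(snap)
  present <- graph$nodes$entity_id
  need <- if (mode == "closed") c(case$a_id, case$c_id) else case$a_id
  absent <- setdiff(need, present)
  if (length(absent))
    return(list(rank = NA_integer_, n_candidates = 0L, found = FALSE,
                skipped = TRUE,
                reason = paste("absent from snapshot graph:",
                               paste(absent, collapse = ", "))))
  if (mode == "open") {
    res <- open_discovery(graph, case$a_id, config)
    target <- case$c_id
  } else {
    res <- closed_discovery(graph, case$a_id, case$c_id, config)
    target <- case$b_id
  }
  hit <- res$candidates[id == target]
  list(rank = if (nrow(hit)) hit$rank[1] else NA_integer_,
       n_candidates = nrow(res$candidates),
       found = nrow(hit) > 0L, skipped = FALSE, reason = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median rank summary
#'
#' Median of the finite ranks: middle value for an odd count, mean of the
#' two middle values for an even count. `NA` ("not found") entries are
#' excluded from the median and reported separately rather than assigned a
#' sentinel rank.
#'
#' @param ranks integer vector, `NA` = target not retrieved
#' @return list with `median` (`NA` when nothing was found), `n_found`,
#'   `n_not_found`
#' @export
median_rank <- function(ranks) {
  found <- ranks[!is.na(ranks)]
  list(median = if (length(found)) median(found) else NA_real_,
       n_found = length(found), n_not_found = sum(is.na(ranks)))
}

#' Evaluate a case set over a grid of scoring configurations
#'
#' Runs every case under every metric x fg (x fc, open mode) combination
#' and summarizes each configuration by the median rank of the expected
#' node, the shape of the headline evaluation tables of co-occurrence LBD
#' systems. Snapshots and graphs are built once per case and reused across
#' configurations, so grid evaluation is bit-for-bit reproducible given
#' the corpus and case list.
#'
#' @param corpus an [lbd_corpus()] or `lbd_counts`
#' @param cases case table from [load_cases()]
#' @param metrics metric names (default: all eight)
#' @param fg_set aggregation functions (default `min`, `avg`, `max`)
#' @param fc_set accumulation functions for open mode (default `sum`,
#'   `max`)
#' @return an `lbd_evaluation`: list with `per_case` (long table of ranks)
#'   and `medians` (per mode x metric x fg x fc)
#' @export
grid_evaluate <- function(corpus, cases, metrics = lbd_metrics(),
                          fg_set = c("min", "avg", "max"),
                          fc_set = c("sum", "max")) {
  counts <- if (inherits(corpus, "lbd_counts")) corpus else
    aggregate_counts(corpus)
  rows <- list()
  for (ci in seq_len(nrow(cases))) {
    case <- as.list(cases[ci])
    modes <- if (case$mode == "both") c("open", "closed") else case$mode
    snap <- snapshot(counts, cutoff_year = case$cutoff_year,
                     exclude_pair = c(case$a_id, case$c_id))
    graph <- build_graph(snap)
    present <- graph$nodes$entity_id
    for (mode in modes) {
      need <- if (mode == "closed") c(case$a_id, case$c_id) else case$a_id
      skip <- length(setdiff(need, present)) > 0L
      for (metric in metrics) {
        for (fg in fg_set) for (fc in if (mode == "open") fc_set else "sum") {
          cfg <- scoring_config(metric, fg, fc)
          r <- if (skip) list(rank = NA_integer_, n_candidates = 0L,
                              found = FALSE, skipped = TRUE) else
            .run_case_on_graph(graph, case, cfg, mode)
          rows[[length(rows) + 1L]] <- data.table(
            case = ci, a_id = case$a_id, target = if (mode == "open")
              case$c_id else case$b_id,
            mode = mode, metric = metric, fg = fg,
            fc = if (mode == "open") fc else NA_character_,
            rank = r$rank, n_candidates = r$n_candidates,
            skipped = isTRUE(r$skipped))
        }
      }
    }
  }
  per_case <- rbindlist(rows)
  medians <- per_case[, {
    s <- median_rank(rank)
    .(median_rank = s$median, n_found = s$n_found,
      n_not_found = s$n_not_found, n_skipped = sum(skipped))
  }, by = .(mode, metric, fg, fc)]
  structure(list(per_case = per_case, medians = medians),
            class = "lbd_evaluation")
}

# run_case when snapshot graph is already built
.run_case_on_graph <- function(graph, case, config, mode) {
  if (mode == "open") {
    res <- open_discovery(graph, case$a_id, config)
    target <- case$c_id
  } else {
    res <- closed_discovery(graph, case$a_id, case$c_id, config)
    target <- case$b_id
  }
  hit <- res$candidates[id == target]
  list(rank = if (nrow(hit)) hit$rank[1] else NA_integer_,
       n_candidates = nrow(res$candidates), found = nrow(hit) > 0L,
       skipped = FALSE)
}

#' @export
print.lbd_evaluation <- function(x, ...) {
  cat(sprintf("<lbd_evaluation> %d case-config runs, %d configurations\n",
              nrow(x$per_case), nrow(x$medians)))
  print(x$medians)
  invisible(x)
}

#' Write an evaluation report
#'
#' `<prefix>_per_case.tsv` holds every case x configuration rank;
#' `<prefix>_medians.tsv` holds the median-rank grid in wide form (metrics
#' as rows, function combinations as columns, closed as `fg`, open as
#' `fc(fg)`); `<prefix>.json` holds both plus skip counts.
#'
#' @param report an `lbd_evaluation`
#' @param prefix output path prefix
#' @return written paths, invisibly
#' @export
write_evaluation <- function(report, prefix) {
  pc <- paste0(prefix, "_per_case.tsv")
  md <- paste0(prefix, "_medians.tsv")
  js <- paste0(prefix, ".json")
  fwrite(report$per_case, pc, sep = "\t")
  m <- copy(report$medians)
  m[, column := ifelse(is.na(fc), fg, sprintf("%s(%s)", fc, fg))]
  wide <- dcast(m, mode + metric ~ column, value.var = "median_rank")
  fwrite(wide, md, sep = "\t")
  jsonlite::write_json(list(per_case = report$per_case,
                            medians = report$medians),
                       js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(pc, md, js))
}
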