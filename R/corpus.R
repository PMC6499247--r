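#' @import data.table
#' @importFrom stats median setNames
#' @importFrom utils write.table head
NULL

#' Corpus container
#'
#' An `lbd_corpus` bundles three tables:
#'
#' * `documents`: `doc_id`, `text` (title + abstract, space-joined), `year`
#' * `sentences`: `doc_id`, `sentence_index` (0-based), `start`, `end`
#'   (0-based half-open character offsets into the document text)
#' * `mentions`: `doc_id`, `sentence_index`, `start`, `end`, `surface`,
#'   `entity_type`, `entity_id` (`NA` = ungrounded)
#'
#' All offsets follow the PubTator convention: 0-based, half-open, into the
#' title+abstract concatenation joined by a single space.
#'
#' @param documents,mentions,sentences data.frames with the columns above
#' @return an `lbd_corpus` object
#' @export
lbd_corpus <- function(documents, mentions = NULL, sentences = NULL) {
  documents <- as.data.table(documents)
  if (nrow(documents) && anyDuplicated(documents$doc_id))
    stop("duplicate doc_id in corpus")
  if (is.null(mentions) || !nrow(as.data.table(mentions))) {
    mentions <- data.table(doc_id = character(), sentence_index = integer(),
                           start = integer(), end = integer(),
                           surface = character(), entity_type = character(),
                           entity_id = character())
  } else {
    mentions <- as.data.table(mentions)
    if (!"sentence_index" %in% names(mentions))
      mentions[, sentence_index := NA_integer_]
  }
  if (is.null(sentences))
    sentences <- data.table(doc_id = character(), sentence_index = integer(),
                            start = integer(), end = integer())
  structure(list(documents = documents,
                 sentences = as.data.table(sentences),
                 mentions = mentions),
            class = "lbd_corpus")
}

#' @export
print.lbd_corpus <- function(x, ...) {
  cat(sprintf("<lbd_corpus> %d documents, %d sentences, %d mentions (%d grounded)\n",
              nrow(x$documents), nrow(x$sentences), nrow(x$mentions),
              sum(!is.na(x$mentions$entity_id))))
  invisible(x)
}

#' Default abbreviation guard list for the sentence splitter
#'
#' Tokens (ending in a period) after which a period + space + capital is not
#' treated as a sentence boundary. Covers genus-name initials and common
#' scholarly abbreviations.
#' @return character vector
#' @export
lbd_abbreviations <- function() {
  c(paste0(LETTERS, "."),            # genus initials: E. coli, B. subtilis
    "al.", "e.g.", "i.e.", "cf.", "vs.", "ca.", "approx.",
    "Fig.", "Figs.", "Eq.", "Ref.", "No.", "Dr.", "St.", "Mr.", "Mrs.",
    "sp.", "spp.", "subsp.", "var.")
}

#' Split a document text into sentence spans
#'
#' Deterministic rule-based splitting: a boundary is sentence-final
#' punctuation (`.`, `!` or `?`) followed by whitespace and an uppercase
#' letter or digit, unless the token ending at the punctuation is on the
#' abbreviation guard list. If no boundary is found the whole text is one
#' sentence. Spans are trimmed of surrounding whitespace, 0-based half-open.
#'
#' @param text a single string (non-empty)
#' @param abbreviations guard list, see [lbd_abbreviations()]
#' @return data.table with columns `sentence_index`, `start`, `end`
#' @examples
#' segment_sentences("p53 and cancer. TP53 regulates apoptosis.")
#' @export
segment_sentences <- function(text, abbreviations = lbd_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  m <- gregexpr("[.!?][\")\\]]*(\\s+)(?=[A-Z0-9])", text, perl = TRUE)[[1]]
  starts1 <- 1L   # 1-based start positions of sentences
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      punct_pos <- m[k]
      # token ending at the punctuation mark (greedy back to whitespace)
      tok <- sub(".*\\s", "", substr(text, 1L, punct_pos))
      if (tok %in% abbreviations) next
      nxt <- punct_pos + attr(m, "match.length")[k]
      starts1 <- c(starts1, nxt)
    }
  }
  ends1 <- c(starts1[-1L] - 1L, nchar(text))
  # trim whitespace at both ends of each raw span
  spans <- lapply(seq_along(starts1), function(k) {
    s <- starts1[k]; e <- ends1[k]
    while (s <= e && grepl("^\\s$", substr(text, s, s))) s <- s + 1L
    while (e >= s && grepl("^\\s$", substr(text, e, e))) e <- e - 1L
    if (s > e) NULL else c(s, e)
  })
  spans <- do.call(rbind, spans[!vapply(spans, is.null, logical(1))])
  data.table(sentence_index = seq_len(nrow(spans)) - 1L,
             start = spans[, 1] - 1L,   # to 0-based half-open
             end = spans[, 2])
}

#' Assign mentions to sentences by start offset
#'
#' Each mention belongs to the sentence whose span contains its start
#' offset; a mention crossing a boundary belongs to the sentence of its
#' start.
#'
#' @param sentences sentence span table for one document (0-based offsets)
#' @param mentions mention table for the same document
#' @return `mentions` with `sentence_index` filled in
#' @export
assign_mentions_to_sentences <- function(sentences, mentions) {
  mentions <- as.data.table(mentions)
  if (!nrow(mentions)) return(mentions)
  sentences <- as.data.table(sentences)[order(start)]
  text_end <- max(sentences$end)
  if (any(mentions$start >= text_end))
    stop(sprintf("mention start %d beyond text in doc %s",
                 max(mentions$start), mentions$doc_id[1]))
  idx <- findInterval(mentions$start, sentences$start)
  idx[idx < 1L] <- 1L
  mentions[, sentence_index := sentences$sentence_index[idx]]
  mentions[]
}

#' Segment every document of a corpus and attach mentions to sentences
#'
#' @param corpus an [lbd_corpus()]
#' @param abbreviations guard list for [segment_sentences()]
#' @return the corpus with `sentences` populated and mention
#'   `sentence_index` assigned
#' @export
segment_corpus <- function(corpus, abbreviations = lbd_abbreviations()) {
  stopifnot(inherits(corpus, "lbd_corpus"))
  docs <- corpus$documents
  if (!nrow(docs)) return(corpus)
  sent_list <- lapply(seq_len(nrow(docs)), function(i) {
    s <- segment_sentences(docs$text[i], abbreviations)
    s[, doc_id := docs$doc_id[i]]
    s
  })
  sentences <- rbindlist(sent_list)[, .(doc_id, sentence_index, start, end)]
  mn <- corpus$mentions
  if (nrow(mn)) {
    mn <- rbindlist(lapply(split(mn, by = "doc_id"), function(part) {
      assign_mentions_to_sentences(sentences[doc_id == part$doc_id[1]], part)
    }))
  }
  lbd_corpus(docs, mn, sentences)
}

#' Read a PubTator-format corpus
#'
#' Parses blank-line-separated records of the form `PMID|t|<title>`,
#' `PMID|a|<abstract>` followed by TAB-separated annotation lines
#' (`PMID  start  end  surface  type  id`). Document text is
#' `title + " " + abstract`; offsets are 0-based half-open into that
#' concatenation. Annotation lines whose offsets do not match the surface
#' text, and malformed lines, are reported (with line numbers, via a single
#' summary warning) and skipped; a record with duplicate title or abstract
#' lines is rejected. An id field of `-` or empty means ungrounded.
#'
#' Publication years are not part of the format; supply them through
#' `years` (a data.frame `doc_id`/`year`, e.g. from [read_year_table()]).
#' Documents without a year are excluded (`on_missing_year = "exclude"`,
#' the default, with a warning count) or kept with `year = NA`.
#'
#' @param path file path or connection
#' @param years optional sidecar table with columns `doc_id`, `year`
#' @param on_missing_year `"exclude"` or `"keep"`
#' @param segment if `TRUE` (default) sentence-segment the result
#' @return an [lbd_corpus()]
#' @export
read_pubtator <- function(path, years = NULL,
                          on_missing_year = c("exclude", "keep"),
                          segment = TRUE) {
  on_missing_year <- match.arg(on_missing_year)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  issues <- character()
  docs <- list(); ments <- list()
  rec_start <- 1L
  breaks <- c(which(!nzchar(trimws(lines))), length(lines) + 1L)
  prev <- 0L
  for (b in breaks) {
    idx <- (prev + 1L):(b - 1L)
    prev <- b
    idx <- idx[idx >= 1 & idx <= length(lines) & nzchar(trimws(lines[idx]))]
    if (!length(idx)) next
    rec <- .parse_pubtator_record(lines[idx], idx)
    issues <- c(issues, rec$issues)
    if (!is.null(rec$document)) {
      docs[[length(docs) + 1L]] <- rec$document
      if (!is.null(rec$mentions)) ments[[length(ments) + 1L]] <- rec$mentions
    }
  }
  if (length(issues))
    warning(sprintf("read_pubtator: %d problem(s) skipped:\n  %s",
                    length(issues), paste(head(issues, 10), collapse = "\n  ")),
            call. = FALSE)
  documents <- if (length(docs)) rbindlist(docs) else
    data.table(doc_id = character(), text = character())
  documents[, year := NA_integer_]
  if (!is.null(years)) {
    years <- as.data.table(years)[, .(doc_id = as.character(doc_id),
                                      year = as.integer(year))]
    documents[years, year := i.year, on = "doc_id"]
  }
  mentions <- if (length(ments)) rbindlist(ments) else NULL
  if (on_missing_year == "exclude" && !is.null(years)) {
    n_missing <- sum(is.na(documents$year))
    if (n_missing > 0) {
      warning(sprintf("read_pubtator: %d document(s) without a year excluded",
                      n_missing), call. = FALSE)
      keep <- documents[!is.na(year), doc_id]
      documents <- documents[doc_id %in% keep]
      if (!is.null(mentions)) mentions <- mentions[doc_id %in% keep]
    }
  }
  corpus <- lbd_corpus(documents, mentions)
  if (segment) segment_corpus(corpus) else corpus
}

.parse_pubtator_record <- function(rl, line_nos) {
  issues <- character()
  piped <- grepl("^[^\t|]+\\|[ta]\\|", rl)
  title <- rl[piped & grepl("^[^|]+\\|t\\|", rl)]
  abstr <- rl[piped & grepl("^[^|]+\\|a\\|", rl)]
  if (length(title) != 1L || length(abstr) > 1L) {
    return(list(issues = sprintf(
      "line %d: record rejected (%d title / %d abstract lines)",
      line_nos[1], length(title), length(abstr))))
  }
  pmid <- sub("\\|.*$", "", title)
  ttl <- sub("^[^|]+\\|t\\|", "", title)
  abs_ <- if (length(abstr)) sub("^[^|]+\\|a\\|", "", abstr) else ""
  text <- if (nzchar(abs_)) paste(ttl, abs_) else ttl
  doc <- data.table(doc_id = pmid, text = text)
  ann_lines <- which(!piped)
  ments <- list()
  for (k in ann_lines) {
    f <- strsplit(rl[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) {
      issues <- c(issues, sprintf("line %d: malformed annotation line",
                                  line_nos[k]))
      next
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start) {
      issues <- c(issues, sprintf("line %d: bad offsets", line_nos[k]))
      next
    }
    surface <- f[4]
    if (substr(text, start + 1L, end) != surface) {
      issues <- c(issues, sprintf(
        "line %d: offsets [%d,%d) do not match surface %s in doc %s",
        line_nos[k], start, end, dQuote(surface, FALSE), pmid))
      next
    }
    id <- if (length(f) >= 6L) f[6] else ""
    if (id %in% c("", "-")) id <- NA_character_
    ments[[length(ments) + 1L]] <- data.table(
      doc_id = pmid, sentence_index = NA_integer_,
      start = start, end = end, surface = surface,
      entity_type = f[5], entity_id = id)
  }
  list(document = doc,
       mentions = if (length(ments)) rbindlist(ments) else NULL,
       issues = issues)
}

#' Write a corpus in PubTator format
#'
#' Inverse of [read_pubtator()] for round-tripping. The title is recovered
#' as the text of the first sentence when sentence spans are present,
#' otherwise the text up to the first period-space; the abstract is the
#' remainder.
#'
#' @param corpus an [lbd_corpus()]
#' @param path output file path or connection
#' @export
write_pubtator <- function(corpus, path) {
  stopifnot(inherits(corpus, "lbd_corpus"))
  out <- character()
  for (i in seq_len(nrow(corpus$documents))) {
    d <- corpus$documents[i]
    sent <- corpus$sentences[doc_id == d$doc_id][order(sentence_index)]
    split_at <- if (nrow(sent)) sent$end[1] else {
      p <- regexpr("\\. ", d$text)
      if (p > 0) p + 1L else nchar(d$text)
    }
    title <- substr(d$text, 1L, split_at)
    abstr <- trimws(substr(d$text, split_at + 1L, nchar(d$text)), "left")
    out <- c(out, paste0(d$doc_id, "|t|", title),
             paste0(d$doc_id, "|a|", abstr))
    mn <- corpus$mentions[doc_id == d$doc_id][order(start)]
    for (j in seq_len(nrow(mn))) {
      m <- mn[j]
      out <- c(out, paste(m$doc_id, m$start, m$end, m$surface, m$entity_type,
                          if (is.na(m$entity_id)) "-" else m$entity_id,
                          sep = "\t"))
    }
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a year sidecar table
#'
#' @param path TSV with columns `doc_id`, `year` (header optional)
#' @return data.table with `doc_id` (character), `year` (integer)
#' @export
read_year_table <- function(path) {
  dt <- fread(path, sep = "\t", header = "auto",
              colClasses = list(character = 1))
  setnames(dt, 1:2, c("doc_id", "year"))
  dt[, .(doc_id = as.character(doc_id), year = as.integer(year))]
}

#' Write / read the internal JSON-lines corpus format
#'
#' One JSON object per line: `doc_id`, `text`, `year`, `sentences`
#' (array of `{index, start, end}`), `mentions` (array of
#' `{sentence_index, start, end, surface, entity_type, entity_id}`;
#' `entity_id` omitted when ungrounded). Write-then-read is a field-for-field
#' identity.
#'
#' @param corpus an [lbd_corpus()]
#' @param path file path
#' @return `read_corpus_jsonl` returns an [lbd_corpus()]
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "lbd_corpus"))
  lines <- vapply(seq_len(nrow(corpus$documents)), function(i) {
    d <- corpus$documents[i]
    sent <- corpus$sentences[doc_id == d$doc_id][order(sentence_index)]
    mn <- corpus$mentions[doc_id == d$doc_id][order(start)]
    obj <- list(doc_id = d$doc_id, text = d$text, year = d$year,
                sentences = lapply(seq_len(nrow(sent)), function(j)
                  list(index = sent$sentence_index[j], start = sent$start[j],
                       end = sent$end[j])),
                mentions = lapply(seq_len(nrow(mn)), function(j) {
                  m <- as.list(mn[j])
                  m$doc_id <- NULL
                  if (is.na(m$entity_id)) m$entity_id <- NULL
                  if (is.na(m$sentence_index)) m$sentence_index <- NULL
                  m
                }))
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  docs <- list(); sents <- list(); ments <- list()
  for (ln in lines) {
    obj <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                    error = function(e) stop("invalid JSON-lines corpus: ",
                                             conditionMessage(e)))
    if (is.null(obj$doc_id) || is.null(obj$text))
      stop("JSON-lines record missing doc_id/text",
           if (!is.null(obj$doc_id)) paste0(" (doc ", obj$doc_id, ")"))
    docs[[length(docs) + 1L]] <- data.table(
      doc_id = obj$doc_id, text = obj$text,
      year = if (is.null(obj$year)) NA_integer_ else as.integer(obj$year))
    for (s in obj$sentences)
      sents[[length(sents) + 1L]] <- data.table(
        doc_id = obj$doc_id, sentence_index = as.integer(s$index),
        start = as.integer(s$start), end = as.integer(s$end))
    for (m in obj$mentions)
      ments[[length(ments) + 1L]] <- data.table(
        doc_id = obj$doc_id,
        sentence_index = if (is.null(m$sentence_index)) NA_integer_ else
          as.integer(m$sentence_index),
        start = as.integer(m$start), end = as.integer(m$end),
        surface = m$surface, entity_type = m$entity_type,
        entity_id = if (is.null(m$entity_id)) NA_character_ else m$entity_id)
  }
  lbd_corpus(
    if (length(docs)) rbindlist(docs) else
      data.table(doc_id = character(), text = character(),
                 year = integer()),
    if (length(ments)) rbindlist(ments) else NULL,
    if (length(sents)) rbindlist(sents) else NULL)
}
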