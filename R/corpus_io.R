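# PubTator corpus reading/writing, sentence splitting, tokenization and
# BIO label conversion. Offsets are 0-based half-open over title + " " + abstract.

#' Construct a document
#'
#' A document is a title/abstract pair with character-offset disease mention
#' annotations. Offsets are 0-based, half-open, over the full text defined as
#' `title`, a single space, then `abstract`.
#'
#' @param doc_id Document identifier (e.g. a PMID).
#' @param title Title text.
#' @param abstract Abstract text.
#' @param mentions Data frame with columns `start`, `end`, `surface`, `type`,
#'   `concept_id`, or `NULL` for no annotations.
#' @param validate Check invariants (offset/surface agreement, no overlap)?
#' @return An object of class `dner_document`.
#' @export
dner_document <- function(doc_id, title, abstract, mentions = NULL,
                          validate = TRUE) {
  if (is.null(mentions)) mentions <- empty_mentions()
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  rownames(mentions) <- NULL
  doc <- structure(
    list(doc_id = as.character(doc_id), title = title, abstract = abstract,
         mentions = mentions),
    class = "dner_document")
  if (validate) validate_document(doc)
  doc
}

empty_mentions <- function() {
  data.frame(start = integer(0), end = integer(0), surface = character(0),
             type = character(0), concept_id = character(0),
             stringsAsFactors = FALSE)
}

#' Full text of a document
#'
#' @param doc A `dner_document`.
#' @return Title and abstract joined by a single space.
#' @export
full_text <- function(doc) paste(doc$title, doc$abstract)

# substring with 0-based half-open offsets
slice_text <- function(text, start, end) substring(text, start + 1L, end)

validate_document <- function(doc) {
  txt <- full_text(doc)
  m <- doc$mentions
  if (nrow(m) == 0) return(invisible(doc))
  if (any(m$start < 0 | m$end > nchar(txt) | m$start >= m$end))
    stop(sprintf("document %s: mention offsets out of range", doc$doc_id))
  got <- slice_text(txt, m$start, m$end)
  bad <- which(got != m$surface)
  if (length(bad))
    stop(sprintf(
      "document %s: mention %d slice %s does not equal surface %s",
      doc$doc_id, bad[1], dQuote(got[bad[1]]), dQuote(m$surface[bad[1]])))
  if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)]))
    stop(sprintf("document %s: overlapping mentions", doc$doc_id))
  invisible(doc)
}

#' Parse a PubTator-format corpus
#'
#' Reads blank-line-separated blocks of the form `id|t|title`, `id|a|abstract`
#' followed by tab-separated mention lines
#' (`doc_id  start  end  surface  type  concept_id`).
#'
#' @param x Path to a file, or a character vector of lines (length > 1), or a
#'   single string containing the whole stream (if it contains a newline).
#' @return List of [dner_document()] objects.
#' @export
parse_pubtator <- function(x) {
  lines <- pubtator_lines(x)
  docs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$title) || is.null(cur$abstract))
      stop(sprintf("incomplete PubTator block for document %s", cur$doc_id))
    m <- if (length(cur$mentions)) do.call(rbind, cur$mentions) else NULL
    dner_document(cur$doc_id, cur$title, cur$abstract, m)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      d <- flush(cur); if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      cur <- NULL
      next
    }
    tm <- regmatches(line, regexec("^([^|\t]+)\\|(t|a)\\|(.*)$", line))[[1]]
    if (length(tm) == 4) {
      if (is.null(cur)) cur <- list(doc_id = tm[2], mentions = list())
      if (tm[3] == "t") cur$title <- tm[4] else cur$abstract <- tm[4]
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6)
      stop(sprintf("line %d: malformed PubTator line: %s", i, line))
    if (is.null(cur) || f[1] != cur$doc_id)
      stop(sprintf("line %d: mention line for unknown document %s", i, f[1]))
    cur$mentions[[length(cur$mentions) + 1L]] <- data.frame(
      start = as.integer(f[2]), end = as.integer(f[3]), surface = f[4],
      type = f[5], concept_id = f[6], stringsAsFactors = FALSE)
  }
  d <- flush(cur); if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  docs
}

pubtator_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  x
}

#' Serialize documents to PubTator format
#'
#' Inverse of [parse_pubtator()]: `parse_pubtator(write_pubtator(docs))`
#' returns documents equal to `docs`. Output is byte-stable for equal input.
#'
#' @param docs List of `dner_document` objects.
#' @param path Optional file path; when given, the text is also written there.
#' @return The PubTator text as a single string (invisibly when `path` given).
#' @export
write_pubtator <- function(docs, path = NULL) {
  blocks <- vapply(docs, function(doc) {
    validate_document(doc)
    m <- doc$mentions
    lines <- c(paste0(doc$doc_id, "|t|", doc$title),
               paste0(doc$doc_id, "|a|", doc$abstract))
    if (nrow(m))
      lines <- c(lines, paste(doc$doc_id, m$start, m$end, m$surface, m$type,
                              m$concept_id, sep = "\t"))
    paste(lines, collapse = "\n")
  }, character(1))
  out <- paste0(paste(blocks, collapse = "\n\n"), "\n")
  if (length(docs) == 0) out <- ""
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

# Abbreviations after which a period never ends a sentence.
NONBREAK_ABBREV <- c("e.g", "i.e", "vs", "etc", "fig", "figs", "dr", "al",
                     "ca", "approx", "no", "st")

#' Split a document into sentence spans
#'
#' Rule-based splitting: a boundary is placed after `.`, `?` or `!` followed by
#' whitespace and an uppercase letter or digit, except inside parentheses or
#' after a known non-breaking abbreviation. The title/abstract join is always a
#' boundary. Any boundary that would bisect a gold mention is suppressed.
#'
#' @param doc A `dner_document`.
#' @return Data frame of 0-based half-open `start`/`end` spans tiling the full
#'   text (inter-sentence whitespace attached to neither side).
#' @export
split_sentences <- function(doc) {
  txt <- full_text(doc)
  n <- nchar(txt)
  chars <- strsplit(txt, "")[[1]]
  depth <- cumsum((chars == "(") - c(0, (chars == ")")[-n]))
  # candidate boundary after position i (1-based char index)
  cand <- integer(0)
  title_end <- nchar(doc$title)
  if (title_end > 0 && title_end < n) cand <- c(cand, title_end)
  for (i in seq_len(n - 1L)) {
    if (!(chars[i] %in% c(".", "?", "!"))) next
    if (depth[i] > 0) next
    rest <- substring(txt, i + 1L)
    if (!grepl("^\\s+[A-Z0-9]", rest)) next
    if (chars[i] == ".") {
      pre <- sub(".*?([A-Za-z.]*)$", "\\1", substring(txt, max(1L, i - 12L), i - 1L))
      word <- tolower(sub("\\.$", "", pre))
      if (word %in% NONBREAK_ABBREV) next
      # single uppercase initial like "J. Smith"
      if (grepl("^[A-Z]$", pre)) next
    }
    cand <- c(cand, i)
  }
  cand <- sort(unique(cand))
  # suppress boundaries inside a mention: char positions 1..n map to offsets
  # [i-1, i); boundary after char i splits [.., i) | [i, ..) i.e. offset i
  if (nrow(doc$mentions)) {
    m <- doc$mentions
    keep <- vapply(cand, function(b)
      !any(m$start < b & b < m$end), logical(1))
    cand <- cand[keep]
  }
  bounds <- c(0L, cand, n)
  spans <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  # trim whitespace off both ends of each span
  for (k in seq_len(nrow(spans))) {
    while (spans$start[k] < spans$end[k] &&
           grepl("^\\s$", substring(txt, spans$start[k] + 1L, spans$start[k] + 1L)))
      spans$start[k] <- spans$start[k] + 1L
    while (spans$end[k] > spans$start[k] &&
           grepl("^\\s$", substring(txt, spans$end[k], spans$end[k])))
      spans$end[k] <- spans$end[k] - 1L
  }
  spans <- spans[spans$end > spans$start, , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

#' Tokenize a sentence span
#'
#' Alphanumeric runs become word tokens; every other non-space character is a
#' single token (hyphens split, so "ANCA-positive" tokenizes to three tokens).
#'
#' @param span One row of [split_sentences()] output (list or data.frame row
#'   with `start` and `end`), or a numeric `c(start, end)` pair.
#' @param text The document full text.
#' @param sentence_index Integer stored on each token.
#' @return Data frame of tokens: `surface`, `start`, `end`, `sentence_index`.
#' @export
tokenize <- function(span, text, sentence_index = 0L) {
  if (is.numeric(span) && is.null(names(span)))
    span <- list(start = span[1], end = span[2])
  seg <- slice_text(text, span$start, span$end)
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", seg)[[1]]
  if (m[1] == -1)
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), sentence_index = integer(0)))
  starts <- span$start + as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(surface = regmatches(seg, list(m))[[1]],
             start = starts, end = starts + lens,
             sentence_index = as.integer(sentence_index),
             stringsAsFactors = FALSE)
}

#' Tokenize a whole document
#'
#' Convenience wrapper: sentence-split then tokenize each span.
#'
#' @param doc A `dner_document`.
#' @return Data frame of tokens over all sentences, with `sentence_index`.
#' @export
tokenize_document <- function(doc) {
  spans <- split_sentences(doc)
  txt <- full_text(doc)
  toks <- lapply(seq_len(nrow(spans)), function(k)
    tokenize(spans[k, ], txt, k))
  out <- do.call(rbind, toks)
  if (is.null(out)) out <- tokenize(list(start = 0L, end = 0L), txt, 1L)
  rownames(out) <- NULL
  out
}

#' Convert character-offset mentions to token-level BIO labels
#'
#' The first token of each mention is labeled `B`, subsequent tokens `I`, all
#' others `O`. A mention not aligned with token boundaries is snapped outward
#' to the smallest covering token span (and reported via a "dnerlink_snap"
#' condition), never dropped.
#'
#' @param tokens Token data frame (any subset of a document's tokens, e.g. one
#'   sentence).
#' @param mentions Mention data frame.
#' @return Character vector of labels in `{"B","I","O"}`, one per token.
#' @export
mentions_to_bio <- function(tokens, mentions) {
  labels <- rep("O", nrow(tokens))
  if (is.null(mentions) || nrow(mentions) == 0) return(labels)
  for (k in seq_len(nrow(mentions))) {
    s <- mentions$start[k]; e <- mentions$end[k]
    hit <- which(tokens$start < e & tokens$end > s)
    if (!length(hit)) next
    if (tokens$start[hit[1]] < s || tokens$end[hit[length(hit)]] > e) {
      cond <- simpleCondition(
        sprintf("mention [%d,%d) snapped to token span [%d,%d)",
                s, e, tokens$start[hit[1]], tokens$end[hit[length(hit)]]))
      class(cond) <- c("dnerlink_snap", "condition")
      signalCondition(cond)
    }
    labels[hit[1]] <- "B"
    if (length(hit) > 1) labels[hit[-1]] <- "I"
  }
  labels
}

#' Convert token-level BIO labels back to mentions
#'
#' Each maximal `B I*` run becomes one mention spanning the first token's start
#' to the last token's end. An orphan `I` (at sequence start or after `O`) is
#' treated as `B`.
#'
#' @param tokens Token data frame.
#' @param labels Character vector of BIO labels, same length as `tokens` rows.
#' @param text Document full text (for surface extraction).
#' @param type Entity type stored on each mention.
#' @param concept_id Concept identifier stored on each mention.
#' @return Mention data frame.
#' @export
bio_to_mentions <- function(tokens, labels, text, type = "Disease",
                            concept_id = "-1") {
  if (length(labels) != nrow(tokens))
    stop("labels and tokens have different lengths")
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] %in% c("B", "I")) {   # orphan I repaired to B
      j <- i
      while (j + 1L <= n && labels[j + 1L] == "I" &&
             tokens$sentence_index[j + 1L] == tokens$sentence_index[j]) j <- j + 1L
      s <- tokens$start[i]; e <- tokens$end[j]
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, surface = slice_text(text, s, e),
        type = type, concept_id = concept_id, stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.dner_document <- function(x, ...) {
  cat(sprintf("<dner_document %s: %d chars, %d mentions>\n",
              x$doc_id, nchar(full_text(x)), nrow(x$mentions)))
  invisible(x)
}

# equality used in round-trip tests
docs_equal <- function(a, b) {
  isTRUE(all.equal(a$doc_id, b$doc_id)) && a$title == b$title &&
    a$abstract == b$abstract &&
    isTRUE(all.equal(a$mentions, b$mentions, check.attributes = FALSE))
}
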