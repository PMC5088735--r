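# Rule-based recall boosters applied to CRF output: repeated-entity
# propagation within an abstract, and Schwartz-Hearst abbreviation resolution
# against the disease lexicon. Both only ever add mentions.

# case-insensitive occurrences of `surface` in `text` at token boundaries
# (adjacent characters must not be alphanumeric); 0-based half-open offsets
find_occurrences <- function(text, surface) {
  m <- gregexpr(tolower(surface), tolower(text), fixed = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  ok <- vapply(seq_along(starts), function(k) {
    before <- if (starts[k] > 0) substring(text, starts[k], starts[k]) else ""
    after <- if (ends[k] < nchar(text))
      substring(text, ends[k] + 1L, ends[k] + 1L) else ""
    !grepl("[A-Za-z0-9]", before) && !grepl("[A-Za-z0-9]", after)
  }, logical(1))
  data.frame(start = starts[ok], end = ends[ok])
}

add_mentions <- function(doc, mentions, add, rule) {
  if (!nrow(add)) return(mentions)
  txt <- full_text(doc)
  for (k in seq_len(nrow(add))) {
    s <- add$start[k]; e <- add$end[k]
    if (any(mentions$start < e & mentions$end > s)) next  # overlaps existing
    mentions <- rbind(mentions, data.frame(
      start = s, end = e, surface = slice_text(txt, s, e),
      type = add$type[k] %||% "Disease",
      concept_id = add$concept_id[k] %||% "-1", stringsAsFactors = FALSE))
    cond <- simpleCondition(sprintf(
      "postprocess/%s: added mention %s at [%d,%d) in document %s",
      rule, dQuote(slice_text(txt, s, e)), s, e, doc$doc_id))
    class(cond) <- c("dnerlink_postprocess", "condition")
    signalCondition(cond)
  }
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  rownames(mentions) <- NULL
  mentions
}

#' Propagate repeated entities within a document
#'
#' If a surface string is tagged as an entity at least `min_count` times in
#' one document, every other occurrence of that string (case-insensitive, at
#' token boundaries) is also tagged. Mentions are only added, never removed.
#'
#' @param doc A `dner_document` (for its text).
#' @param mentions Mention data frame from a base tagger.
#' @param min_count Occurrence threshold that triggers propagation.
#' @return Augmented mention data frame, sorted by start.
#' @export
propagate_repeated_entities <- function(doc, mentions, min_count = 2L) {
  if (nrow(mentions) == 0) return(mentions)
  txt <- full_text(doc)
  key <- tolower(mentions$surface)
  counts <- table(key)
  for (surf in names(counts[counts >= min_count])) {
    rows <- which(key == surf)
    occ <- find_occurrences(txt, mentions$surface[rows[1]])
    if (!nrow(occ)) next
    occ$type <- mentions$type[rows[1]]
    occ$concept_id <- mentions$concept_id[rows[1]]
    mentions <- add_mentions(doc, mentions, occ, "propagation")
    key <- tolower(mentions$surface)
  }
  mentions
}

# Schwartz-Hearst short-form validity
valid_short_form <- function(sf) {
  n <- nchar(sf)
  n >= 2 && n <= 10 &&
    length(strsplit(trimws(sf), "[[:space:]]+")[[1]]) <= 2 &&
    grepl("[A-Za-z]", sf) &&
    grepl("^[A-Za-z0-9]", sf)
}

# Schwartz-Hearst right-to-left character alignment: find the best long form
# for short form `sf` inside candidate text `long`; returns the 1-based char
# index where the long form starts, or NA
sh_best_long_form <- function(long, sf) {
  lchars <- strsplit(tolower(long), "")[[1]]
  schars <- strsplit(tolower(sf), "")[[1]]
  li <- length(lchars); si <- length(schars)
  while (si >= 1) {
    c <- schars[si]
    if (!grepl("[a-z0-9]", c)) { si <- si - 1; next }
    while (li >= 1 &&
           (lchars[li] != c ||
            (si == 1 && li > 1 && grepl("[a-z0-9]", lchars[li - 1]))))
      li <- li - 1
    if (li < 1) return(NA_integer_)
    si <- si - 1; li <- li - 1
  }
  li + 1L
}

#' Find abbreviation definitions (Schwartz-Hearst)
#'
#' Detects `<definition> (<abbreviation>)` patterns: a parenthesized candidate
#' short form (2-10 characters, at most 2 words, contains a letter, first
#' character alphanumeric) aligned right-to-left against the preceding words
#' (at most `min(|A| + 5, |A| * 2)` words, `|A|` = short-form character
#' count).
#'
#' @param text Full document text.
#' @return Data frame of pairs: `def_start`, `def_end`, `definition`,
#'   `abbr_start`, `abbr_end`, `abbreviation` (0-based half-open offsets).
#' @export
find_abbreviation_pairs <- function(text) {
  out <- data.frame(def_start = integer(0), def_end = integer(0),
                    definition = character(0), abbr_start = integer(0),
                    abbr_end = integer(0), abbreviation = character(0),
                    stringsAsFactors = FALSE)
  m <- gregexpr("\\(([^()]+)\\)", text)[[1]]
  if (m[1] == -1) return(out)
  for (k in seq_along(m)) {
    open <- as.integer(m[k])                      # 1-based "(" position
    len <- attr(m, "match.length")[k]
    sf <- substring(text, open + 1L, open + len - 2L)
    if (!valid_short_form(sf)) next
    # preceding context: up to min(|A|+5, 2|A|) words before "("
    pre <- substring(text, 1, open - 1L)
    wm <- gregexpr("[^[:space:]]+", pre)[[1]]
    if (wm[1] == -1) next
    nw <- length(wm)
    maxw <- min(nchar(sf) + 5L, nchar(sf) * 2L)
    first_w <- max(1L, nw - maxw + 1L)
    ctx_start <- as.integer(wm[first_w])          # 1-based
    ctx <- substring(pre, ctx_start, nchar(pre))
    ctx <- sub("[[:space:]]+$", "", ctx)
    pos <- sh_best_long_form(ctx, sf)
    if (is.na(pos)) next
    # extend left to the start of the word containing pos
    abs_pos <- ctx_start + pos - 1L
    while (abs_pos > 1 &&
           !grepl("[[:space:]]", substring(text, abs_pos - 1L, abs_pos - 1L)))
      abs_pos <- abs_pos - 1L
    def <- sub("[[:space:]]+$", "",
               substring(text, abs_pos, open - 2L))
    if (!nchar(def)) next
    nw_def <- length(strsplit(def, "[[:space:]]+")[[1]])
    if (nw_def > maxw || nchar(sf) > nchar(def)) next
    out <- rbind(out, data.frame(
      def_start = abs_pos - 1L, def_end = abs_pos - 1L + nchar(def),
      definition = def, abbr_start = open, abbr_end = open + len - 2L,
      abbreviation = sf, stringsAsFactors = FALSE))
  }
  out
}

#' Abbreviation resolution against the lexicon
#'
#' For each detected `<definition> (<abbreviation>)` pair whose definition is
#' either a lexicon term (after normalization) or already covered by a tagged
#' mention, every occurrence of the abbreviation in the document is added as a
#' mention. Mentions are only added, never removed.
#'
#' @param doc A `dner_document`.
#' @param mentions Mention data frame from a base tagger.
#' @param lexicon A `dner_lexicon`.
#' @return Augmented mention data frame.
#' @export
resolve_abbreviations <- function(doc, mentions, lexicon) {
  txt <- full_text(doc)
  pairs <- find_abbreviation_pairs(txt)
  if (!nrow(pairs)) return(mentions)
  for (k in seq_len(nrow(pairs))) {
    def <- pairs$definition[k]
    key <- paste(lex_norm(lexicon, term_to_tokens(def)), collapse = " ")
    covered <- any(mentions$start <= pairs$def_start[k] &
                   mentions$end >= pairs$def_end[k])
    concept <- "-1"
    if (covered) {
      row <- which(mentions$start <= pairs$def_start[k] &
                   mentions$end >= pairs$def_end[k])[1]
      concept <- mentions$concept_id[row]
    }
    if (!(key %in% lexicon$term_set) && !covered) next
    occ <- find_occurrences(txt, pairs$abbreviation[k])
    if (!nrow(occ)) next
    occ$type <- "Disease"
    occ$concept_id <- concept
    mentions <- add_mentions(doc, mentions, occ, "abbreviation")
  }
  mentions
}

#' Apply both post-processing rules
#'
#' Repeated-entity propagation followed by abbreviation resolution. Both are
#' monotone (the mention set only grows) and idempotent.
#'
#' @inheritParams resolve_abbreviations
#' @param min_count Propagation threshold.
#' @return Augmented mention data frame.
#' @export
postprocess_mentions <- function(doc, mentions, lexicon, min_count = 2L) {
  mentions <- propagate_repeated_entities(doc, mentions, min_count)
  resolve_abbreviations(doc, mentions, lexicon)
}
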