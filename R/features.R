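# Disease lexicon handling and the CRF feature families: word, POS, chunk,
# word shape, word type, prefixes/suffixes, and the two dictionary look-ups.

#' Construct a disease lexicon
#'
#' @param entries Named list: concept ID -> list(name = preferred name,
#'   synonyms = character vector of synonym terms).
#' @param normalize Normalize terms (lower-case + Porter stem) for matching?
#' @return Object of class `dner_lexicon` with precomputed normalized term and
#'   word sets.
#' @export
dner_lexicon <- function(entries, normalize = TRUE) {
  stopifnot(length(entries) > 0, !is.null(names(entries)))
  norm <- if (normalize) norm_tokens else tolower
  term_strings <- unlist(lapply(entries, function(e)
    c(e$name, e$synonyms %||% character(0))), use.names = FALSE)
  term_tokens <- lapply(term_strings, term_to_tokens)
  if (any(!lengths(term_tokens)))
    stop("lexicon contains a term that is empty after tokenization")
  norm_terms <- vapply(term_tokens, function(tk) paste(norm(tk), collapse = " "),
                       character(1))
  words <- unique(unlist(lapply(term_tokens, norm), use.names = FALSE))
  structure(list(
    entries = entries,
    normalize = normalize,
    term_set = unique(norm_terms),
    word_set = words,
    max_term_len = max(lengths(term_tokens))), class = "dner_lexicon")
}

#' @export
print.dner_lexicon <- function(x, ...) {
  cat(sprintf("<dner_lexicon: %d concepts, %d terms, %d words>\n",
              length(x$entries), length(x$term_set), length(x$word_set)))
  invisible(x)
}

# split a lexicon term into word tokens (same regex as the corpus tokenizer)
term_to_tokens <- function(term) {
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", term)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(term, list(m))[[1]]
}

# lowercase + stem; the shared normalizer for dictionary matching
norm_tokens <- function(tokens) stem_words(tokens)

lex_norm <- function(lexicon, tokens)
  if (lexicon$normalize) norm_tokens(tokens) else tolower(tokens)

#' Read a lexicon TSV
#'
#' One row per concept: `concept_id  preferred_name  synonyms` where synonyms
#' are pipe-delimited (`|`) and may be empty.
#'
#' @param path File path.
#' @param normalize Passed to [dner_lexicon()].
#' @return A `dner_lexicon`.
#' @export
read_lexicon <- function(path, normalize = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  entries <- list()
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed lexicon line: ", line)
    syn <- if (length(f) >= 3 && nzchar(f[3]))
      strsplit(f[3], "|", fixed = TRUE)[[1]] else character(0)
    entries[[f[1]]] <- list(name = f[2], synonyms = syn)
  }
  dner_lexicon(entries, normalize = normalize)
}

#' Write a lexicon TSV
#'
#' @param lexicon A `dner_lexicon`.
#' @param path File path.
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- vapply(names(lexicon$entries), function(id) {
    e <- lexicon$entries[[id]]
    paste(id, e$name, paste(e$synonyms %||% character(0), collapse = "|"),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Word shape feature
#'
#' Each character is mapped to `U` (upper case), `L` (lower case), `D` (digit)
#' or `S` (anything else), so "delirium" becomes "LLLLLLLL".
#'
#' @param word Non-empty string.
#' @return Shape string of the same length.
#' @export
word_shape <- function(word) {
  if (!nchar(word)) stop("word_shape: empty word")
  chars <- strsplit(word, "")[[1]]
  out <- ifelse(grepl("[A-Z]", chars), "U",
         ifelse(grepl("[a-z]", chars), "L",
         ifelse(grepl("[0-9]", chars), "D", "S")))
  paste(out, collapse = "")
}

#' Word type feature
#'
#' Classifies a word into one of a closed set of orthographic categories
#' (first matching in order): AllDigit, AllSymbol, AllUpper, AllLower,
#' AllLetter, UpperAndDigit, LetterAndDigit, Mixed.
#'
#' @param word Non-empty string.
#' @return One category label.
#' @export
word_type <- function(word) {
  if (!nchar(word)) stop("word_type: empty word")
  if (grepl("^[0-9]+$", word)) return("AllDigit")
  if (!grepl("[A-Za-z0-9]", word)) return("AllSymbol")
  if (grepl("^[A-Z]+$", word)) return("AllUpper")
  if (grepl("^[a-z]+$", word)) return("AllLower")
  if (grepl("^[A-Za-z]+$", word)) return("AllLetter")
  if (grepl("^[A-Z0-9]+$", word)) return("UpperAndDigit")
  if (grepl("^[A-Za-z0-9]+$", word)) return("LetterAndDigit")
  "Mixed"
}

#' Prefix and suffix features
#'
#' @param word Non-empty string.
#' @param lengths Affix lengths to emit, subset of 1:4.
#' @return Data frame with columns `kind` ("pre"/"suf"), `length`, `string`;
#'   only lengths not exceeding the word length are emitted.
#' @export
affixes <- function(word, lengths = 1:4) {
  stopifnot(all(lengths %in% 1:4))
  lengths <- sort(unique(lengths[lengths <= nchar(word)]))
  if (!length(lengths))
    return(data.frame(kind = character(0), length = integer(0),
                      string = character(0)))
  data.frame(
    kind = rep(c("pre", "suf"), each = length(lengths)),
    length = c(lengths, lengths),
    string = c(substring(word, 1, lengths),
               substring(word, nchar(word) - lengths + 1)),
    stringsAsFactors = FALSE)
}

#' Dictionary word flag
#'
#' "Y" iff the normalized word occurs as a single word in any lexicon term.
#'
#' @param word A word.
#' @param lexicon A `dner_lexicon`.
#' @return "Y" or "N".
#' @export
dict_flag <- function(word, lexicon) {
  if (lex_norm(lexicon, word) %in% lexicon$word_set) "Y" else "N"
}

#' Dictionary BIO tagging by longest contiguous term match
#'
#' Greedy left-to-right longest match of normalized lexicon terms over the
#' normalized token sequence; matched spans get `B I*`, everything else `O`.
#' Overlapping candidates are resolved longest-then-leftmost.
#'
#' @param tokens Character vector of token surfaces, or a token data frame.
#' @param lexicon A `dner_lexicon`.
#' @return Character vector of BIO labels.
#' @export
dict_bio <- function(tokens, lexicon) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  n <- length(tokens)
  labels <- rep("O", n)
  if (!n) return(labels)
  norm <- lex_norm(lexicon, tokens)
  maxlen <- min(lexicon$max_term_len, n)
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (m in seq(min(maxlen, n - i + 1L), 1L)) {
      key <- paste(norm[i:(i + m - 1L)], collapse = " ")
      if (key %in% lexicon$term_set) { matched <- m; break }
    }
    if (matched > 0L) {
      labels[i] <- "B"
      if (matched > 1L) labels[(i + 1L):(i + matched - 1L)] <- "I"
      i <- i + matched
    } else i <- i + 1L
  }
  labels
}

#' Feature configuration
#'
#' Window radii per feature family (each in 1..3), affix lengths, and POS /
#' chunk toggles.
#'
#' @param n_word,n_pos,n_chunk,n_shape,n_type Window radius for the scalar
#'   families.
#' @param n_affix,n_dict Window radius for the affix and dictionary families.
#' @param affix_lengths Subset of 1:4.
#' @param use_pos,use_chunk Emit POS / chunk features?
#' @return A `feature_config` list.
#' @export
feature_config <- function(n_word = 2L, n_pos = 2L, n_chunk = 2L,
                           n_shape = 2L, n_type = 2L, n_affix = 1L,
                           n_dict = 1L, affix_lengths = 1:4,
                           use_pos = TRUE, use_chunk = TRUE) {
  radii <- c(n_word, n_pos, n_chunk, n_shape, n_type, n_affix, n_dict)
  stopifnot(all(radii >= 1 & radii <= 3), all(affix_lengths %in% 1:4))
  structure(list(n_word = n_word, n_pos = n_pos, n_chunk = n_chunk,
                 n_shape = n_shape, n_type = n_type, n_affix = n_affix,
                 n_dict = n_dict, affix_lengths = affix_lengths,
                 use_pos = use_pos, use_chunk = use_chunk),
            class = "feature_config")
}

# window expansion of scalar per-token values: list over tokens of
# "fam[d]=value" strings, with __BOS__/__EOS__ sentinels beyond the edges
window_feats <- function(fam, vals, n) {
  T <- length(vals)
  lapply(seq_len(T), function(t) {
    d <- (-n):n
    pos <- t + d
    v <- ifelse(pos < 1, "__BOS__", ifelse(pos > T, "__EOS__", vals[pmax(pmin(pos, T), 1)]))
    sprintf("%s[%+d]=%s", fam, d, v)
  })
}

# window expansion for multi-valued families (a character vector per token)
window_feats_multi <- function(fam, vals_list, n) {
  T <- length(vals_list)
  lapply(seq_len(T), function(t) {
    out <- character(0)
    for (d in (-n):n) {
      pos <- t + d
      if (pos < 1) out <- c(out, sprintf("%s[%+d]=__BOS__", fam, d))
      else if (pos > T) out <- c(out, sprintf("%s[%+d]=__EOS__", fam, d))
      else if (length(vals_list[[pos]]))
        out <- c(out, sprintf("%s[%+d]=%s", fam, d, vals_list[[pos]]))
    }
    out
  })
}

#' Build per-token CRF feature maps for one sentence
#'
#' Assembles all seven feature families with their context windows. Each token
#' yields a character vector of `"name=value"` features; feature extraction is
#' pure (equal inputs give identical maps).
#'
#' @param tokens Character vector of token surfaces, or a token data frame.
#' @param pos Optional character vector of POS tags (aligned) or NULL.
#' @param chunk Optional character vector of chunk tags (aligned) or NULL.
#' @param lexicon A `dner_lexicon`.
#' @param config A [feature_config()].
#' @return List (one element per token) of character vectors.
#' @export
build_token_features <- function(tokens, pos = NULL, chunk = NULL,
                                 lexicon = NULL,
                                 config = feature_config()) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  T <- length(tokens)
  if (!T) return(list())
  if (!is.null(pos) && length(pos) != T)
    stop("POS tags not aligned with tokens")
  if (!is.null(chunk) && length(chunk) != T)
    stop("chunk tags not aligned with tokens")

  fams <- list(window_feats("w", tokens, config$n_word))
  if (config$use_pos && !is.null(pos))
    fams <- c(fams, list(window_feats("pos", pos, config$n_pos)))
  if (config$use_chunk && !is.null(chunk))
    fams <- c(fams, list(window_feats("chk", chunk, config$n_chunk)))
  shapes <- vapply(tokens, word_shape, character(1), USE.NAMES = FALSE)
  types <- vapply(tokens, word_type, character(1), USE.NAMES = FALSE)
  fams <- c(fams, list(window_feats("shape", shapes, config$n_shape)),
            list(window_feats("type", types, config$n_type)))

  aff <- lapply(tokens, function(wd) {
    a <- affixes(wd, config$affix_lengths)
    sprintf("%s%d=%s", a$kind, a$length, a$string)
  })
  fams <- c(fams, list(window_feats_multi("affix", aff, config$n_affix)))

  if (!is.null(lexicon)) {
    flags <- vapply(tokens, dict_flag, character(1), lexicon = lexicon,
                    USE.NAMES = FALSE)
    dbio <- dict_bio(tokens, lexicon)
    fams <- c(fams, list(window_feats("dictA", flags, config$n_dict)),
              list(window_feats("dictB", dbio, config$n_dict)))
  }

  lapply(seq_len(T), function(t)
    unlist(lapply(fams, `[[`, t), use.names = FALSE))
}
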