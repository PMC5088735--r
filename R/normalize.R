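# Vector-space-model normalization: each concept's preferred name plus all
# synonyms form one "document"; mentions are queries; TF-IDF weighting with
# cosine ranking selects the concept ID. Zero-overlap queries map to "-1".

#' Preprocess a term or mention for normalization
#'
#' Tokenize, lower-case and Porter-stem every token. Deterministic.
#'
#' @param text A term or mention surface string.
#' @return Character vector of stemmed tokens (empty for an empty string).
#' @export
preprocess_term <- function(text) {
  if (!nchar(trimws(text))) return(character(0))
  stem_words(term_to_tokens(text))
}

#' Build a TF-IDF concept index from a lexicon
#'
#' One document per concept (preferred name + synonyms, stemmed and
#' lower-cased, as a token multiset); tf = raw term count, idf = ln(N / df)
#' with N the number of concept documents.
#'
#' @param lexicon A `dner_lexicon`.
#' @return Object of class `concept_index` with precomputed TF-IDF vectors
#'   and norms.
#' @export
build_concept_index <- function(lexicon) {
  ids <- sort(names(lexicon$entries))
  docs <- lapply(ids, function(id) {
    e <- lexicon$entries[[id]]
    unlist(lapply(c(e$name, e$synonyms %||% character(0)), preprocess_term),
           use.names = FALSE)
  })
  empty <- which(!lengths(docs))
  if (length(empty))
    stop("concept ", ids[empty[1]], " is empty after preprocessing")
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  N <- length(ids)
  df <- numeric(length(vocab))
  names(df) <- vocab
  for (d in docs) {
    u <- unique(d)
    df[u] <- df[u] + 1
  }
  idf <- log(N / df)
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_len(N)) {
    tf <- table(docs[[k]])
    j <- match(names(tf), vocab)
    ii[[k]] <- rep.int(k, length(j))
    jj[[k]] <- j
    xx[[k]] <- as.numeric(tf) * idf[j]
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, length(vocab)),
                            dimnames = list(ids, vocab))
  norms <- sqrt(Matrix::rowSums(M^2))
  zero <- norms == 0
  if (any(zero))
    stop("concept ", ids[which(zero)[1]],
         " has a zero TF-IDF vector (all terms have idf 0)")
  structure(list(ids = ids, vocab = vocab, idf = idf, M = M, norms = norms,
                 N = N), class = "concept_index")
}

#' @export
print.concept_index <- function(x, ...) {
  cat(sprintf("<concept_index: %d concepts, %d vocabulary terms>\n",
              x$N, length(x$vocab)))
  invisible(x)
}

#' Rank concepts for a mention query
#'
#' The query vector uses the index's idf (terms unseen in the index
#' contribute 0); cosine = dot / (|q| |d|), defined as 0 for an empty query.
#' Full descending ranking; ties broken by ascending concept ID.
#'
#' @param surface Mention surface string.
#' @param index A `concept_index`.
#' @return Data frame `concept_id`, `score`, ordered by rank.
#' @export
rank_concepts <- function(surface, index) {
  toks <- preprocess_term(surface)
  toks <- toks[toks %in% index$vocab]
  if (!length(toks)) {
    return(data.frame(concept_id = index$ids, score = 0,
                      stringsAsFactors = FALSE))
  }
  tf <- table(toks)
  j <- match(names(tf), index$vocab)
  qw <- as.numeric(tf) * index$idf[j]
  qnorm <- sqrt(sum(qw^2))
  if (qnorm == 0) {
    scores <- rep(0, index$N)
  } else {
    q <- numeric(length(index$vocab))
    q[j] <- qw
    scores <- as.numeric(index$M %*% q) / (index$norms * qnorm)
  }
  ord <- order(-scores, index$ids)
  data.frame(concept_id = index$ids[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

#' Normalize one mention to a concept ID
#'
#' The top-ranked concept is returned; a top score of exactly 0 yields
#' concept ID "-1". Exact score ties are resolved by ascending concept ID by
#' default (deterministic), or by a seeded random draw among the tied IDs.
#'
#' @param surface Mention surface string (or a mention data frame row).
#' @param index A `concept_index`.
#' @param ties "id" (deterministic, default) or "random".
#' @param seed Seed used when `ties = "random"`.
#' @return List: `surface`, `concept_id`, `score`, `ranking` (data frame).
#' @export
normalize_mention <- function(surface, index, ties = c("id", "random"),
                              seed = 1L) {
  ties <- match.arg(ties)
  if (is.data.frame(surface)) surface <- surface$surface[1]
  ranking <- rank_concepts(surface, index)
  top <- ranking$score[1]
  if (top <= 0)
    return(list(surface = surface, concept_id = "-1", score = 0,
                ranking = ranking))
  tied <- ranking$concept_id[ranking$score == top]
  id <- if (ties == "random" && length(tied) > 1)
    with_seed(seed, sample(tied, 1)) else tied[1]
  list(surface = surface, concept_id = id, score = top, ranking = ranking)
}

#' Normalize all mentions of a document
#'
#' Each mention is normalized independently; the document-level concept set
#' is the union of non-"-1" IDs (the unit of concept-level evaluation).
#'
#' @param doc A `dner_document`.
#' @param index A `concept_index`.
#' @param ties,seed Passed to [normalize_mention()].
#' @return List: `doc` (with mention `concept_id`s filled in), `ids`
#'   (character vector, the document's concept ID set).
#' @export
normalize_document <- function(doc, index, ties = "id", seed = 1L) {
  m <- doc$mentions
  if (nrow(m)) {
    m$concept_id <- vapply(m$surface, function(s)
      normalize_mention(s, index, ties = ties, seed = seed)$concept_id,
      character(1), USE.NAMES = FALSE)
    doc$mentions <- m
  }
  ids <- unique(m$concept_id[m$concept_id != "-1"])
  list(doc = doc, ids = sort(ids))
}
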