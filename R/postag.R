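# A small rule-based part-of-speech and chunk tagger. The pipeline treats the
# tagger as pluggable: any function returning aligned POS/chunk vectors can be
# substituted (the original system used an external biomedical tagger).

POS_CLOSED <- list(
  DT = c("the", "a", "an", "this", "that", "these", "those", "no", "each",
         "every", "some", "any", "all", "both"),
  IN = c("in", "of", "on", "at", "by", "with", "from", "to", "for", "after",
         "before", "during", "under", "over", "between", "without", "into",
         "through", "against", "among"),
  CC = c("and", "or", "but", "nor", "while", "whereas"),
  PRP = c("we", "they", "it", "he", "she", "i", "you", "who", "which", "its",
          "their", "our"),
  MD = c("can", "could", "may", "might", "must", "shall", "should", "will",
         "would"),
  VB = c("is", "are", "was", "were", "be", "been", "being", "has", "have",
         "had", "do", "does", "did", "show", "showed", "shown", "found",
         "observed", "reported", "studied", "developed", "received",
         "treated", "presented", "describes", "describe", "occurred",
         "remains", "suggest", "suggests", "indicate", "indicates"))

#' Rule-based POS tagging
#'
#' A deterministic approximation good enough to exercise the POS feature
#' family: closed-class word lists, orthographic rules (digits, punctuation,
#' capitalization) and suffix heuristics; default is `NN`.
#'
#' @param tokens Character vector of token surfaces, or a token data frame.
#' @return Character vector of coarse Penn-style tags.
#' @export
pos_tag <- function(tokens) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  vapply(tokens, function(w) {
    lw <- tolower(w)
    if (grepl("^[0-9]+$", w)) return("CD")
    if (!grepl("[A-Za-z0-9]", w)) return("PUNCT")
    for (tag in names(POS_CLOSED)) if (lw %in% POS_CLOSED[[tag]]) return(tag)
    if (grepl("ly$", lw)) return("RB")
    if (grepl("ing$", lw) && nchar(lw) > 4) return("VBG")
    if (grepl("ed$", lw) && nchar(lw) > 3) return("VBD")
    if (grepl("(ous|ive|ic|al|ar|ile|ant|ent)$", lw) && nchar(lw) > 3)
      return("JJ")
    if (grepl("s$", lw) && !grepl("(ss|us|is)$", lw) && nchar(lw) > 3)
      return("NNS")
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

#' Rule-based chunk tagging
#'
#' Maximal runs of determiner/adjective/noun tags become noun-phrase chunks
#' (`B-NP`, `I-NP`); verbs become `B-VP`; everything else `O`.
#'
#' @param tokens Token surfaces or data frame.
#' @param pos Optional precomputed POS tags.
#' @return Character vector of chunk tags.
#' @export
chunk_tag <- function(tokens, pos = NULL) {
  if (is.null(pos)) pos <- pos_tag(tokens)
  np <- pos %in% c("DT", "JJ", "NN", "NNS", "CD")
  vp <- pos %in% c("VB", "VBD", "VBG", "MD")
  out <- rep("O", length(pos))
  out[vp] <- "B-VP"
  if (any(np)) {
    starts <- np & !c(FALSE, np[-length(np)])
    out[np] <- "I-NP"
    out[starts] <- "B-NP"
  }
  out
}
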