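# Porter (1980) stemmer. Implemented here because term normalization must be
# identical between dictionary features and concept-index construction, and a
# plain-R implementation keeps both deterministic and dependency-free.

.porter_vowel_mask <- function(chars) {
  n <- length(chars)
  isv <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) isv[i] <- TRUE
    else if (ch == "y") isv[i] <- (i > 1 && !isv[i - 1])
  }
  isv
}

# measure m of a stem: number of vowel->consonant transitions
.porter_m <- function(stem) {
  if (!nchar(stem)) return(0L)
  isv <- .porter_vowel_mask(strsplit(stem, "")[[1]])
  r <- rle(isv)$values
  sum(r[-length(r)] & !r[-1])
}

.porter_has_vowel <- function(stem) {
  nchar(stem) > 0 && any(.porter_vowel_mask(strsplit(stem, "")[[1]]))
}

.porter_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2) return(FALSE)
  a <- substring(w, n - 1, n - 1); b <- substring(w, n, n)
  a == b && !.porter_vowel_mask(strsplit(w, "")[[1]])[n]
}

# *o condition: stem ends cvc where final c is not w, x or y
.porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  isv <- .porter_vowel_mask(strsplit(w, "")[[1]])
  !isv[n] && isv[n - 1] && !isv[n - 2] &&
    !(substring(w, n, n) %in% c("w", "x", "y"))
}

.porter_ends <- function(w, suf) {
  nchar(w) >= nchar(suf) &&
    substring(w, nchar(w) - nchar(suf) + 1) == suf
}

.porter_chop <- function(w, suf) substring(w, 1, nchar(w) - nchar(suf))

# apply first matching (suffix -> replacement) rule whose stem passes cond(m)
.porter_rule <- function(w, rules, cond) {
  for (r in rules) {
    if (.porter_ends(w, r[[1]])) {
      stem <- .porter_chop(w, r[[1]])
      if (cond(.porter_m(stem))) return(paste0(stem, r[[2]]))
      return(w)
    }
  }
  w
}

#' Porter stem a single word
#'
#' Classic Porter (1980) suffix-stripping. Words of length <= 2 are returned
#' unchanged; input is expected to be lower case.
#'
#' @param word A single lower-case word.
#' @return The stemmed word.
#' @export
porter_stem <- function(word) {
  w <- word
  if (nchar(w) <= 2) return(w)

  # step 1a
  if (.porter_ends(w, "sses")) w <- .porter_chop(w, "es")
  else if (.porter_ends(w, "ies")) w <- paste0(.porter_chop(w, "ies"), "i")
  else if (!.porter_ends(w, "ss") && .porter_ends(w, "s"))
    w <- .porter_chop(w, "s")

  # step 1b
  if (.porter_ends(w, "eed")) {
    if (.porter_m(.porter_chop(w, "eed")) > 0) w <- .porter_chop(w, "d")
  } else {
    fix <- FALSE
    if (.porter_ends(w, "ed") && .porter_has_vowel(.porter_chop(w, "ed"))) {
      w <- .porter_chop(w, "ed"); fix <- TRUE
    } else if (.porter_ends(w, "ing") &&
               .porter_has_vowel(.porter_chop(w, "ing"))) {
      w <- .porter_chop(w, "ing"); fix <- TRUE
    }
    if (fix) {
      if (.porter_ends(w, "at") || .porter_ends(w, "bl") ||
          .porter_ends(w, "iz")) w <- paste0(w, "e")
      else if (.porter_double_cons(w) &&
               !(substring(w, nchar(w)) %in% c("l", "s", "z")))
        w <- substring(w, 1, nchar(w) - 1)
      else if (.porter_m(w) == 1 && .porter_cvc(w)) w <- paste0(w, "e")
    }
  }

  # step 1c
  if (.porter_ends(w, "y") && .porter_has_vowel(.porter_chop(w, "y")))
    w <- paste0(.porter_chop(w, "y"), "i")

  # step 2 (m > 0)
  w <- .porter_rule(w, list(
    list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
    list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
    list("alli", "al"), list("entli", "ent"), list("eli", "e"),
    list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
    list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
    list("iviti", "ive"), list("biliti", "ble"), list("logi", "log")),
    function(m) m > 0)

  # step 3 (m > 0)
  w <- .porter_rule(w, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""),
    list("ness", "")),
    function(m) m > 0)

  # step 4 (m > 1)
  matched <- FALSE
  for (suf in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")) {
    if (.porter_ends(w, suf)) {
      stem <- .porter_chop(w, suf)
      ok <- .porter_m(stem) > 1
      if (suf == "ion")
        ok <- ok && nchar(stem) > 0 &&
          substring(stem, nchar(stem)) %in% c("s", "t")
      if (ok) w <- stem
      matched <- TRUE
      break
    }
  }

  # step 5a
  if (.porter_ends(w, "e")) {
    stem <- .porter_chop(w, "e")
    m <- .porter_m(stem)
    if (m > 1 || (m == 1 && !.porter_cvc(stem))) w <- stem
  }
  # step 5b
  if (.porter_m(w) > 1 && .porter_double_cons(w) && .porter_ends(w, "l"))
    w <- substring(w, 1, nchar(w) - 1)

  w
}

#' Stem a vector of words
#'
#' @param words Character vector (lower-cased internally).
#' @return Character vector of stems.
#' @export
stem_words <- function(words) {
  vapply(tolower(words), porter_stem, character(1), USE.NAMES = FALSE)
}
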