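# Feature families: shape, type, affixes, dictionary look-ups and the
# assembled windowed feature maps.

test_that("word_shape maps characters to U/L/D/S and preserves length", {
  expect_equal(word_shape("delirium"), "LLLLLLLL")
  expect_equal(word_shape("AKI"), "UUU")
  expect_equal(word_shape("3-mg"), "DSLL")
  expect_error(word_shape(""), "empty")
  for (w in c("Abc1", "X", "a-b-c", "Na2CO3"))
    expect_equal(nchar(word_shape(w)), nchar(w))
})

test_that("word_type assigns the first matching closed-set category", {
  cases <- list("123" = "AllDigit", "AKI9" = "UpperAndDigit",
                "..," = "AllSymbol", "AKI" = "AllUpper",
                "pain" = "AllLower", "Pain" = "AllLetter",
                "mg5" = "LetterAndDigit", "p-3" = "Mixed")
  for (w in names(cases)) expect_equal(word_type(w), cases[[w]])
  expect_error(word_type(""), "empty")
})

test_that("affixes emits realizable prefix/suffix lengths only", {
  a <- affixes("pain", 1:4)
  expect_setequal(a$string[a$kind == "pre"], c("p", "pa", "pai", "pain"))
  expect_setequal(a$string[a$kind == "suf"], c("n", "in", "ain", "pain"))
  a2 <- affixes("at", 1:4)
  expect_setequal(a2$length, c(1, 2))
  # counting identity: 2 * |{l in lengths : l <= nchar(word)}|
  for (w in c("a", "be", "word", "longword"))
    for (ls in list(1:4, c(2, 3), 4))
      expect_equal(nrow(affixes(w, ls)), 2 * sum(ls <= nchar(w)))
})

test_that("dict_flag agrees with naive normalized set membership", {
  lex <- toy_lexicon()
  expect_equal(dict_flag("psychosis", lex), "Y")
  expect_equal(dict_flag("the", lex), "N")
  ss <- small_synth(seed = 21, n_docs = 10)
  words <- unique(unlist(lapply(ss$docs, function(d)
    tokenize_document(d)$surface)))
  naive <- vapply(words, function(w)
    stem_words(w) %in% ss$lexicon$word_set, logical(1))
  flags <- vapply(words, dict_flag, character(1), lexicon = ss$lexicon)
  expect_equal(unname(flags == "Y"), unname(naive))
})

test_that("dict_bio performs greedy longest-then-leftmost term matching", {
  lex <- toy_lexicon()
  expect_equal(dict_bio(c("acute", "kidney", "injury", "occurred"), lex),
               c("B", "I", "I", "O"))
  # the longer of two nested terms wins
  lex2 <- dner_lexicon(list(
    A = list(name = "kidney injury", synonyms = character(0)),
    B = list(name = "acute kidney injury", synonyms = character(0))))
  expect_equal(dict_bio(c("acute", "kidney", "injury"), lex2),
               c("B", "I", "I"))
  # never emits I after O
  ss <- small_synth(seed = 23, n_docs = 10)
  for (d in ss$docs[1:5]) {
    lb <- dict_bio(tokenize_document(d), ss$lexicon)
    prev <- c("O", lb[-length(lb)])
    expect_false(any(lb == "I" & prev == "O"))
  }
})

test_that("dict_bio equals exhaustive span matching on short sentences", {
  ss <- small_synth(seed = 25, n_docs = 15)
  lex <- ss$lexicon
  # oracle: enumerate every [i, j] span, test membership of the normalized
  # join in the term set, then consume spans longest-then-leftmost
  oracle <- function(tokens) {
    n <- length(tokens)
    norm <- stem_words(tokens)
    spans <- list()
    for (i in seq_len(n)) for (j in i:n)
      if (paste(norm[i:j], collapse = " ") %in% lex$term_set)
        spans[[length(spans) + 1L]] <- c(i, j)
    labels <- rep("O", n)
    i <- 1L
    while (i <= n) {
      here <- Filter(function(s) s[1] == i, spans)
      if (length(here)) {
        j <- max(vapply(here, `[`, integer(1), 2))
        labels[i] <- "B"
        if (j > i) labels[(i + 1):j] <- "I"
        i <- j + 1L
      } else i <- i + 1L
    }
    labels
  }
  checked <- 0
  for (d in ss$docs) {
    tk <- tokenize_document(d)
    for (s in unique(tk$sentence_index)) {
      toks <- tk$surface[tk$sentence_index == s]
      if (length(toks) > 10) next
      expect_equal(dict_bio(toks, lex), oracle(toks))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("build_token_features produces windowed keys with sentinels", {
  lex <- toy_lexicon()
  fm <- build_token_features(c("chest", "pain"), lexicon = lex,
                             config = feature_config(n_word = 1))
  f2 <- fm[[2]]
  expect_true("w[-1]=chest" %in% f2)
  expect_true("w[+0]=pain" %in% f2)
  expect_true("w[+1]=__EOS__" %in% f2)
  expect_true("dictB[+0]=B" %in% fm[[1]])  # "chest pain" is a lexicon term
})

test_that("absent POS/chunk streams drop those families", {
  lex <- toy_lexicon()
  fm <- build_token_features(c("chest", "pain"), pos = NULL, chunk = NULL,
                             lexicon = lex)
  expect_false(any(grepl("^pos\\[", unlist(fm))))
  expect_false(any(grepl("^chk\\[", unlist(fm))))
  fm2 <- build_token_features(c("chest", "pain"), pos = c("NN", "NN"),
                              chunk = c("B-NP", "I-NP"), lexicon = lex)
  expect_true(any(grepl("^pos\\[", unlist(fm2))))
  expect_error(build_token_features(c("a", "b"), pos = "NN", lexicon = lex),
               "aligned")
})

test_that("feature-map key counts match the closed form", {
  lex <- toy_lexicon()
  cfg <- feature_config(n_word = 2, n_pos = 2, n_chunk = 2, n_shape = 2,
                        n_type = 2, n_affix = 1, n_dict = 1,
                        affix_lengths = 1:4)
  set.seed(31)
  words <- c("We", "saw", "acute", "kidney", "injury", "in", "3", "cases")
  for (rep in 1:5) {
    toks <- sample(words, sample(2:6, 1), replace = TRUE)
    T <- length(toks)
    pos <- pos_tag(toks); chk <- chunk_tag(toks, pos)
    fm <- build_token_features(toks, pos, chk, lex, cfg)
    for (t in seq_len(T)) {
      # scalar families: word/pos/chunk/shape/type (2n+1 each), dictA/dictB
      scalar <- 5 * 5 + 2 * 3
      # affix family at offsets -1,0,+1: in-range positions contribute
      # 2*|{l <= len}|, out-of-range one sentinel
      affix <- 0
      for (d in -1:1) {
        pp <- t + d
        affix <- affix + if (pp < 1 || pp > T) 1 else
          2 * sum(cfg$affix_lengths <= nchar(toks[pp]))
      }
      expect_length(fm[[t]], scalar + affix)
    }
  }
})

test_that("feature extraction is pure", {
  lex <- toy_lexicon()
  toks <- c("Severe", "chest", "pain", ".")
  a <- build_token_features(toks, pos_tag(toks), chunk_tag(toks), lex)
  b <- build_token_features(toks, pos_tag(toks), chunk_tag(toks), lex)
  expect_identical(a, b)
})
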