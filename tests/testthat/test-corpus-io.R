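# PubTator parsing/serialization, sentence splitting, tokenization and the
# mention <-> BIO conversions.

test_that("parse_pubtator maps a block to a document with exact offsets", {
  txt <- paste0("1|t|Pain study\n1|a|We saw pain.\n",
                "1\t18\t22\tpain\tDisease\tD010146\n")
  docs <- parse_pubtator(txt)
  expect_length(docs, 1)
  d <- docs[[1]]
  expect_equal(d$doc_id, "1")
  expect_equal(d$title, "Pain study")
  expect_equal(d$abstract, "We saw pain.")
  expect_equal(nrow(d$mentions), 1)
  expect_equal(d$mentions$surface, "pain")
  expect_equal(d$mentions$start, 18L)
  expect_equal(d$mentions$end, 22L)
  expect_equal(substring(full_text(d), 19, 22), "pain")
})

test_that("parse_pubtator handles empty input and rejects bad blocks", {
  expect_length(parse_pubtator(""), 0)
  expect_error(parse_pubtator("1|t|T\n1|a|A\n1\t0\t1\n"), "malformed")
  # offset that does not slice to the surface is an integrity error
  bad <- "1|t|Pain study\n1|a|We saw pain.\n1\t0\t4\tpain\tDisease\tD1\n"
  expect_error(parse_pubtator(bad), "does not equal surface")
  # mention line referencing an unknown document
  expect_error(parse_pubtator("1|t|T\n1|a|A body.\n2\t0\t1\tT\tDisease\tD1\n"),
               "unknown document")
})

test_that("write_pubtator is the inverse of parse_pubtator", {
  txt <- paste0("1|t|Pain study\n1|a|We saw pain.\n",
                "1\t18\t22\tpain\tDisease\tD010146\n")
  docs <- parse_pubtator(txt)
  expect_equal(write_pubtator(docs), txt)
  # no mentions -> only the |t| and |a| lines
  d0 <- dner_document("7", "A title", "A body.")
  expect_equal(write_pubtator(list(d0)), "7|t|A title\n7|a|A body.\n")
})

test_that("write-then-parse round trip is the identity on synthetic corpora", {
  ss <- small_synth(seed = 3, n_docs = 40)
  rt <- parse_pubtator(write_pubtator(ss$docs))
  expect_length(rt, length(ss$docs))
  for (k in seq_along(rt)) expect_docs_equal(ss$docs[[k]], rt[[k]])
  # byte stability
  expect_identical(write_pubtator(ss$docs), write_pubtator(rt))
})

test_that("split_sentences tiles the text and respects parentheses", {
  d <- dner_document("1", "A study.", "We saw pain.")
  expect_equal(nrow(split_sentences(d)), 2)
  d2 <- dner_document("2", "Report.",
                      "We saw a lesion (AKI. Severe) today. More text.")
  spans <- split_sentences(d2)
  txt <- full_text(d2)
  # the parenthesized segment must not be split despite the inner ". S"
  po <- as.integer(regexpr("(", txt, fixed = TRUE)) - 1L
  pc <- as.integer(regexpr(")", txt, fixed = TRUE))
  covering <- spans[spans$start <= po & spans$end >= pc, ]
  expect_equal(nrow(covering), 1)
  # spans tile the text up to inter-sentence whitespace
  joined <- paste(substring(txt, spans$start + 1, spans$end), collapse = " ")
  expect_equal(joined, txt)
})

test_that("sentence boundaries never bisect a mention on synthetic corpora", {
  ss <- small_synth(seed = 5, n_docs = 30)
  for (d in ss$docs) {
    spans <- split_sentences(d)
    joined <- paste(substring(full_text(d), spans$start + 1, spans$end),
                    collapse = " ")
    expect_equal(joined, full_text(d))
    for (k in seq_len(nrow(d$mentions))) {
      s <- d$mentions$start[k]; e <- d$mentions$end[k]
      expect_true(any(spans$start <= s & spans$end >= e))
    }
  }
})

test_that("tokenize splits punctuation and hyphens with exact offsets", {
  txt <- "vision loss."
  tk <- tokenize(c(0, nchar(txt)), txt)
  expect_equal(tk$surface, c("vision", "loss", "."))
  expect_equal(tk$start, c(0L, 7L, 11L))
  tk2 <- tokenize(c(0, 13), "ANCA-positive")
  expect_equal(tk2$surface, c("ANCA", "-", "positive"))
})

test_that("every token slices to its surface on synthetic corpora", {
  ss <- small_synth(seed = 7, n_docs = 30)
  n_sent <- 0
  for (d in ss$docs) {
    txt <- full_text(d)
    tk <- tokenize_document(d)
    n_sent <- n_sent + length(unique(tk$sentence_index))
    expect_equal(substring(txt, tk$start + 1, tk$end), tk$surface)
  }
  expect_gt(n_sent, 50)
})

test_that("mentions_to_bio labels mention spans B I* and the rest O", {
  d <- dner_document("1", "Note.", "We saw acute kidney injury .")
  tk <- tokenize_document(d)
  m <- data.frame(start = 13, end = 32, surface = "acute kidney injury",
                  type = "Disease", concept_id = "-1")
  labels <- mentions_to_bio(tk, m)
  expect_equal(labels[tk$surface == "acute"], "B")
  expect_equal(labels[tk$surface %in% c("kidney", "injury")], c("I", "I"))
  expect_equal(sum(labels != "O"), 3)
  expect_true(all(mentions_to_bio(tk, NULL) == "O"))
})

test_that("bio_to_mentions extracts spans and repairs orphan I labels", {
  txt <- "We chest pain ."
  tk <- tokenize(c(0, nchar(txt)), txt)
  m <- bio_to_mentions(tk, c("O", "B", "I", "O"), txt)
  expect_equal(m$surface, "chest pain")
  expect_equal(c(m$start, m$end), c(3L, 13L))
  # orphan I at sequence start becomes a mention
  m2 <- bio_to_mentions(tk[1:2, ], c("I", "O"), txt)
  expect_equal(m2$surface, "We")
  expect_error(bio_to_mentions(tk, c("O", "B"), txt), "length")
})

test_that("mentions_to_bio and bio_to_mentions are mutually inverse", {
  ss <- small_synth(seed = 13, n_docs = 40)
  for (d in ss$docs) {
    tk <- tokenize_document(d)
    labels <- mentions_to_bio(tk, d$mentions)
    back <- bio_to_mentions(tk, labels, full_text(d))
    expect_equal(back$start, d$mentions$start)
    expect_equal(back$end, d$mentions$end)
    expect_equal(back$surface, d$mentions$surface)
  }
})
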