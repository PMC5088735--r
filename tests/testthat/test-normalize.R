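# Porter stemming, TF-IDF concept indexing and cosine ranking.

test_that("the stemmer handles classic suffix families", {
  cases <- c(caresses = "caress", ponies = "poni", ties = "ti",
             caress = "caress", cats = "cat", feed = "feed",
             agreed = "agre", plastered = "plaster", motoring = "motor",
             sing = "sing", conflated = "conflat", hopping = "hop",
             happy = "happi", relational = "relat", conditional = "condit",
             vietnamization = "vietnam", formalize = "formal",
             electricity = "electr", hopefulness = "hope",
             delirium = "delirium", losses = "loss")
  for (w in names(cases)) expect_equal(porter_stem(w), unname(cases[w]))
})

test_that("preprocess_term lower-cases, tokenizes and stems", {
  expect_equal(preprocess_term("Delirium"), "delirium")
  expect_equal(preprocess_term("hearing loss"),
               preprocess_term("Hearing Losses"))
  expect_equal(preprocess_term(""), character(0))
  expect_equal(preprocess_term("  "), character(0))
})

test_that("index idf follows ln(N/df) closed forms", {
  lex2 <- dner_lexicon(list(A = list(name = "delirium"),
                            B = list(name = "asthma")))
  idx2 <- build_concept_index(lex2)
  expect_equal(unname(idx2$idf), rep(log(2), 2))
  # a term present in every document has idf 0 and contributes nothing
  lex3 <- dner_lexicon(list(
    A = list(name = "acute delirium"),
    B = list(name = "acute asthma"),
    C = list(name = "acute migraine")))
  idx3 <- build_concept_index(lex3)
  expect_equal(unname(idx3$idf["acut"]), 0)
  r <- rank_concepts("acute", idx3)
  expect_true(all(r$score == 0))
})

test_that("tf-idf vectors equal hand computation on a 3-concept lexicon", {
  lex <- dner_lexicon(list(
    A = list(name = "chest pain", synonyms = "chest ache"),
    B = list(name = "head pain", synonyms = character(0)),
    C = list(name = "asthma", synonyms = "asthma attack")))
  idx <- build_concept_index(lex)
  N <- 3
  # document A tokens: chest chest pain ache
  expect_equal(idx$M["A", "chest"], 2 * log(N / 1))
  expect_equal(idx$M["A", "pain"], 1 * log(N / 2))
  expect_equal(idx$M["A", "ach"], 1 * log(N / 1))
  expect_equal(idx$M["B", "head"], log(3))
  expect_equal(idx$M["C", "asthma"], 2 * log(N / 1))
  expect_equal(unname(idx$norms["A"]),
               sqrt((2 * log(3))^2 + log(3 / 2)^2 + log(3)^2))
  # a concept that stems to nothing is an error
  expect_error(build_concept_index(
    dner_lexicon(list(A = list(name = "x"), B = list(name = " ")))),
    "empty")
})

test_that("ranking follows brute-force cosine on random toy indexes", {
  words <- c("pain", "ache", "chest", "head", "renal", "injury", "failure",
             "acute", "loss", "vision")
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    entries <- lapply(seq_len(n), function(i)
      list(name = paste(sample(words, sample(1:3, 1), replace = TRUE),
                        collapse = " "),
           synonyms = paste(sample(words, 2), collapse = " ")))
    names(entries) <- sprintf("C%02d", seq_len(n))
    idx <- build_concept_index(dner_lexicon(entries))
    q <- paste(sample(words, sample(1:3, 1)), collapse = " ")
    got <- rank_concepts(q, idx)
    # brute force: explicit dense vectors
    qt <- table(preprocess_term(q))
    qv <- numeric(length(idx$vocab)); names(qv) <- idx$vocab
    qv[names(qt)[names(qt) %in% idx$vocab]] <-
      as.numeric(qt[names(qt) %in% idx$vocab]) *
      idx$idf[names(qt)[names(qt) %in% idx$vocab]]
    for (k in seq_len(n)) {
      dv <- as.numeric(idx$M[k, ])
      expected <- if (sqrt(sum(qv^2)) == 0) 0 else
        sum(dv * qv) / (sqrt(sum(dv^2)) * sqrt(sum(qv^2)))
      expect_equal(got$score[got$concept_id == idx$ids[k]], expected,
                   tolerance = 1e-12)
    }
    expect_true(all(got$score >= -1e-12 & got$score <= 1 + 1e-12))
  }
})

test_that("normalize_mention picks the top concept and handles ties/zeros", {
  lex <- dner_lexicon(list(
    D1 = list(name = "delirium"),
    D2 = list(name = "chest pain")))
  idx <- build_concept_index(lex)
  r <- normalize_mention("delirium", idx)
  expect_equal(r$concept_id, "D1")
  expect_equal(r$score, 1.0)
  expect_equal(normalize_mention("unrelated words", idx)$concept_id, "-1")
  expect_equal(normalize_mention("unrelated words", idx)$score, 0)
  # identical documents tie; the smaller ID wins deterministically
  lexT <- dner_lexicon(list(Z9 = list(name = "asthma"),
                            A1 = list(name = "asthma"),
                            M5 = list(name = "migraine")))
  idxT <- build_concept_index(lexT)
  expect_equal(normalize_mention("asthma", idxT)$concept_id, "A1")
  # seeded random tie mode stays within the tied set and is reproducible
  r1 <- normalize_mention("asthma", idxT, ties = "random", seed = 7)
  r2 <- normalize_mention("asthma", idxT, ties = "random", seed = 7)
  expect_identical(r1$concept_id, r2$concept_id)
  expect_true(r1$concept_id %in% c("A1", "Z9"))
})

test_that("every lexicon term self-retrieves at rank 1", {
  ss <- small_synth(seed = 63, n_docs = 1, lexicon_size = 20)
  idx <- build_concept_index(ss$lexicon)
  for (id in names(ss$lexicon$entries)) {
    e <- ss$lexicon$entries[[id]]
    for (term in c(e$name, e$synonyms))
      expect_equal(normalize_mention(term, idx)$concept_id, id)
  }
})

test_that("document-level normalization returns the union of non-missing IDs", {
  lex <- dner_lexicon(list(D1 = list(name = "delirium"),
                           D2 = list(name = "chest pain")))
  idx <- build_concept_index(lex)
  d <- dner_document("1", "Two cases.",
                     "We saw delirium. More delirium and chest pain. qqq zz.")
  txt <- full_text(d)
  occ1 <- gregexpr("delirium", txt, fixed = TRUE)[[1]]
  m <- rbind(
    data.frame(start = as.integer(occ1) - 1L,
               end = as.integer(occ1) - 1L + 8L, surface = "delirium",
               type = "Disease", concept_id = "-1"),
    data.frame(start = regexpr("chest pain", txt, fixed = TRUE) - 1L,
               end = regexpr("chest pain", txt, fixed = TRUE) + 9L,
               surface = "chest pain", type = "Disease", concept_id = "-1"),
    data.frame(start = regexpr("qqq", txt, fixed = TRUE) - 1L,
               end = regexpr("qqq", txt, fixed = TRUE) + 2L,
               surface = "qqq", type = "Disease", concept_id = "-1"))
  d2 <- dner_document("1", d$title, d$abstract, m)
  res <- normalize_document(d2, idx)
  expect_setequal(res$ids, c("D1", "D2"))     # duplicates collapse; qqq -> -1
  expect_equal(sum(res$doc$mentions$concept_id == "-1"), 1)
  # all "-1" gives an empty set
  d3 <- dner_document("2", "None.", "Only qqq here.",
    data.frame(start = regexpr("qqq", "None. Only qqq here.") - 1L,
               end = regexpr("qqq", "None. Only qqq here.") + 2L,
               surface = "qqq", type = "Disease", concept_id = "-1"))
  expect_length(normalize_document(d3, idx)$ids, 0)
})

test_that("adding an unrelated concept preserves relative ranking", {
  lex <- dner_lexicon(list(
    A = list(name = "chest pain"),
    B = list(name = "renal failure")))
  lex2 <- dner_lexicon(list(
    A = list(name = "chest pain"),
    B = list(name = "renal failure"),
    C = list(name = "ocular migraine")))
  i1 <- build_concept_index(lex)
  i2 <- build_concept_index(lex2)
  for (q in c("chest pain", "severe renal failure", "pain")) {
    r1 <- rank_concepts(q, i1)
    r2 <- rank_concepts(q, i2)
    old1 <- r1$concept_id[r1$score > 0]
    old2 <- r2$concept_id[r2$score > 0 & r2$concept_id %in% c("A", "B")]
    expect_equal(old1, old2)
  }
})
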