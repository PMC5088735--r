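# Bi-RNN: softmax, forward pass (against a scalar re-implementation),
# gradients, training behavior, tagging and penultimate-state export.

test_that("softmax is a shift-invariant probability map", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  set.seed(1)
  for (rep in 1:10) {
    v <- stats::rnorm(sample(2:6, 1)) * 3
    p <- softmax(v)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_equal(softmax(v + 7.3), p, tolerance = 1e-12)
    # direct formula at small magnitudes
    expect_equal(p, exp(v) / sum(exp(v)), tolerance = 1e-12)
  }
})

test_that("zero-weight network outputs f(0) states and uniform y", {
  p <- birnn_init(2, H = 3, seed = 1)
  for (nm in c("U_f", "W_f", "b_f", "U_b", "W_b", "b_b", "V"))
    p[[nm]] <- p[[nm]] * 0
  fp <- forward_pass(p, matrix(c(0.5, -0.5), 2, 1))
  expect_equal(unname(fp$states[, 1]), rep(tanh(0), 6))
  expect_equal(unname(fp$y[, 1]), rep(1 / 3, 3))
})

test_that("1-unit recurrence matches hand recursion", {
  p <- birnn_init(1, H = 1, seed = 1)
  p$U_f[] <- 1; p$W_f[] <- 1; p$b_f[] <- 0
  fp <- forward_pass(p, matrix(c(1, 1), 1, 2))
  # h1 = f(1), h2 = f(1 + h1)
  expect_equal(fp$hf[1, 1], tanh(1))
  expect_equal(fp$hf[1, 2], tanh(1 + tanh(1)))
  # backward direction runs right to left
  p$U_b[] <- 1; p$W_b[] <- 1; p$b_b[] <- 0
  fp2 <- forward_pass(p, matrix(c(1, 1), 1, 2))
  expect_equal(fp2$hb[1, 2], tanh(1))
  expect_equal(fp2$hb[1, 1], tanh(1 + tanh(1)))
})

test_that("forward pass matches the scalar re-implementation", {
  set.seed(8)
  for (act in c("tanh", "logistic")) {
    p <- birnn_init(4, H = 3, activation = act, seed = 42)
    X <- matrix(stats::rnorm(12), 4, 3)
    fp <- forward_pass(p, X)
    rf <- ref_birnn_forward(p, X)
    expect_lt(max(abs(fp$y - rf$y)), 1e-10)
    expect_lt(max(abs(fp$states - rf$states)), 1e-10)
    expect_equal(unname(colSums(fp$y)), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("analytic gradients match central finite differences", {
  p <- birnn_init(3, H = 4, seed = 9)
  set.seed(10)
  X <- matrix(stats::rnorm(9), 3, 3)
  yidx <- c(1, 3, 2)
  pnames <- c("U_f", "W_f", "b_f", "U_b", "W_b", "b_b", "V")
  ana <- unlist(dnerlink:::birnn_grad(p, X, yidx)$grads[pnames])
  num <- unlist(lapply(pnames, function(nm) {
    vapply(seq_along(p[[nm]]), function(i) {
      up <- p; up[[nm]][i] <- up[[nm]][i] + 1e-6
      dn <- p; dn[[nm]][i] <- dn[[nm]][i] - 1e-6
      (dnerlink:::birnn_grad(up, X, yidx)$loss -
         dnerlink:::birnn_grad(dn, X, yidx)$loss) / 2e-6
    }, numeric(1))
  }))
  expect_lt(max(abs(ana - num) / (abs(num) + 1e-6)), 1e-4)
})

test_that("embedding lookup covers known tokens and falls back to OOV", {
  vec <- matrix(1:6 / 10, 2, 3, dimnames = list(NULL, c("pain", "we", "saw")))
  tab <- embedding_table(vec, oov = c(9, 9))
  X <- embed_tokens(tab, c("Pain", "unknownword", "saw"))
  expect_equal(X[, 1], vec[, "pain"])   # lower-cased lookup
  expect_equal(X[, 2], c(9, 9))
  expect_equal(X[, 3], vec[, "saw"])
  # coverage equals direct set intersection on a synthetic corpus
  ss <- small_synth(seed = 33, n_docs = 10)
  toks <- tolower(unlist(lapply(ss$docs, function(d)
    tokenize_document(d)$surface)))
  tab2 <- train_toy_embeddings(list(unique(toks)[1:30]), D = 4, seed = 1)
  cov <- mean(toks %in% colnames(tab2$vectors))
  known <- vapply(toks, function(w)
    !identical(unname(embed_tokens(tab2, w)[, 1]), unname(tab2$oov)),
    logical(1))
  expect_equal(mean(known), cov)
})

test_that("embedding files round trip through the text format", {
  tab <- train_toy_embeddings(list(c("chest", "pain", "was", "seen")),
                              D = 5, seed = 2)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  write_embeddings(tab, f)
  tab2 <- read_embeddings(f)
  expect_equal(dim(tab2$vectors), dim(tab$vectors))
  expect_equal(tab2$vectors, tab$vectors, tolerance = 1e-6)
  # header line tolerated
  writeLines(c("2 3", "a 1 2 3", "b 4 5 6"), f)
  tab3 <- read_embeddings(f)
  expect_equal(unname(tab3$vectors[, "b"]), c(4, 5, 6))
  writeLines(c("a 1 2 3", "b 4 5"), f)
  expect_error(read_embeddings(f), "dimension")
})

test_that("training memorizes a tiny corpus and is seed-deterministic", {
  set.seed(77)
  vocabs <- c("we", "saw", "pain", "no", "chest", "ache", "today", "mild")
  sents <- lapply(1:10, function(i) {
    n <- sample(3:5, 1)
    toks <- sample(vocabs, n, replace = TRUE)
    labels <- sample(c("B", "O"), n, replace = TRUE)
    labels[labels == "B"][-1] <- "O"   # at most one B, keep it simple
    list(tokens = toks, labels = labels)
  })
  tab <- train_toy_embeddings(lapply(sents, `[[`, "tokens"), D = 8, seed = 3)
  m1 <- train_birnn(sents, tab, H = 16, epochs = 200, dropout = 0,
                    lr = 0.02, seed = 5)
  acc <- mean(unlist(lapply(sents, function(s)
    tag_with_confidence(m1, s$tokens, tab)$labels == s$labels)))
  expect_gte(acc, 0.99)
  # loss decreases over the first epochs
  tl <- attr(m1, "train_loss")
  expect_lt(tl[5], tl[1])
  # bit-identical retraining under the same seed (dropout on)
  m2 <- train_birnn(sents, tab, H = 8, epochs = 3, dropout = 0.25, seed = 9)
  m3 <- train_birnn(sents, tab, H = 8, epochs = 3, dropout = 0.25, seed = 9)
  for (nm in c("U_f", "W_f", "b_f", "U_b", "W_b", "b_b", "V"))
    expect_identical(m2[[nm]], m3[[nm]])
})

test_that("validation log-likelihood is recorded each epoch", {
  sents <- list(list(tokens = c("we", "saw", "pain"),
                     labels = c("O", "O", "B")))
  tab <- train_toy_embeddings(lapply(sents, `[[`, "tokens"), D = 4, seed = 1)
  m <- train_birnn(sents, tab, H = 4, epochs = 4, dropout = 0, seed = 2,
                   validation = sents)
  expect_length(attr(m, "validation_loglik"), 4)
  expect_true(all(is.finite(attr(m, "validation_loglik"))))
})

test_that("tagging uses argmax with B-first tie-break and bounded confidence", {
  p <- birnn_init(2, H = 3, seed = 4)
  for (nm in c("U_f", "W_f", "b_f", "U_b", "W_b", "b_b", "V"))
    p[[nm]] <- p[[nm]] * 0
  vec <- matrix(0.1, 2, 2, dimnames = list(NULL, c("a", "b")))
  tab <- embedding_table(vec)
  tg <- tag_with_confidence(p, c("a", "b"), tab)
  expect_equal(tg$labels, c("B", "B"))       # exact tie -> first label
  expect_equal(tg$confidences, c(1 / 3, 1 / 3))
  # trained or random: confidences in [1/C, 1]
  p2 <- birnn_init(2, H = 3, seed = 6)
  tg2 <- tag_with_confidence(p2, c("a", "b", "a"), tab)
  expect_true(all(tg2$confidences >= 1 / 3 - 1e-12 & tg2$confidences <= 1))
  # argmax agrees with an independent recomputation of the forward pass
  rf <- ref_birnn_forward(p2, embed_tokens(tab, c("a", "b", "a")))
  expect_equal(tg2$labels, c("B", "I", "O")[apply(rf$y, 2, which.max)])
})

test_that("penultimate states are the 2H inputs of the output layer", {
  p <- birnn_init(3, H = 5, seed = 11)
  vec <- matrix(stats::rnorm(9), 3, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  tab <- embedding_table(vec)
  toks <- c("x", "z", "y", "x")
  S <- penultimate_states(p, toks, tab)
  expect_equal(dim(S), c(10L, 4L))
  y <- apply(p$V %*% S, 2, softmax)
  expect_equal(y, tag_with_confidence(p, toks, tab)$y, tolerance = 1e-12)
  # and they match the scalar reference
  rf <- ref_birnn_forward(p, embed_tokens(tab, toks))
  expect_lt(max(abs(S - rf$states)), 1e-10)
})

test_that("toy embeddings reflect shared contexts and are deterministic", {
  expect_error(train_toy_embeddings(list(c("a", "b")), D = 0), "positive")
  # "pain" and "ache" in identical contexts by construction
  ctx <- list()
  set.seed(12)
  for (i in 1:40) {
    left <- sample(c("felt", "reported", "had"), 1)
    right <- sample(c("today", "often", "badly"), 1)
    ctx[[length(ctx) + 1]] <- c("they", left, "pain", right)
    ctx[[length(ctx) + 1]] <- c("they", left, "ache", right)
    ctx[[length(ctx) + 1]] <- c("the", "dose", "placebo", sample(c("rose", "fell"), 1))
  }
  tab <- train_toy_embeddings(ctx, D = 12, window = 2, epochs = 8, seed = 4)
  expect_setequal(colnames(tab$vectors),
                  unique(unlist(ctx)))
  expect_true(all(apply(tab$vectors, 2, length) == 12))
  cs <- function(a, b) {
    va <- tab$vectors[, a]; vb <- tab$vectors[, b]
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  expect_gt(cs("pain", "ache"), cs("pain", "placebo"))
  tab2 <- train_toy_embeddings(ctx, D = 12, window = 2, epochs = 8, seed = 4)
  expect_identical(tab$vectors, tab2$vectors)
})

test_that("removing the backward recurrence yields the unidirectional model", {
  # zeroing the backward block makes outputs independent of future tokens
  p <- birnn_init(2, H = 4, seed = 13)
  p$U_b[] <- 0; p$W_b[] <- 0; p$b_b[] <- 0
  vec <- matrix(stats::rnorm(8), 2, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  tab <- embedding_table(vec)
  y1 <- tag_with_confidence(p, c("a", "b", "c"), tab)$y
  y2 <- tag_with_confidence(p, c("a", "b", "d"), tab)$y
  expect_equal(y1[, 1:2], y2[, 1:2], tolerance = 1e-12)
})
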