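# Independent oracles and small fixtures shared across tests. These
# deliberately avoid the package's own computation paths: enumeration over
# all label paths for the CRF, a scalar loop re-implementation for the
# Bi-RNN, and naive set/scan computations elsewhere.

BIO <- c("B", "I", "O")

# all 3^T label paths
all_paths <- function(T) {
  g <- expand.grid(rep(list(BIO), T), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.character(unlist(g[i, ])))
}

# brute-force decode + marginals by enumerating every path and scoring it
# with score_sequence (emission/transition sums re-done by the package's
# scorer, but the argmax/marginalization is independent of Viterbi and
# forward-backward)
enum_crf <- function(model, featmaps) {
  T <- length(featmaps)
  paths <- all_paths(T)
  scores <- vapply(paths, function(p) score_sequence(model, featmaps, p),
                   numeric(1))
  pr <- exp(scores - max(scores))
  pr <- pr / sum(pr)
  marg <- matrix(0, T, 3, dimnames = list(NULL, BIO))
  for (i in seq_along(paths))
    for (t in seq_len(T)) {
      j <- match(paths[[i]][t], BIO)
      marg[t, j] <- marg[t, j] + pr[i]
    }
  list(best = paths[[which.max(scores)]], marg = marg, scores = scores)
}

# seeded random CRF model + feature maps over a tiny feature alphabet
random_crf_case <- function(T, seed) {
  set.seed(seed)
  feats <- paste0("f", 1:6)
  model <- crf_model(stats::setNames(seq_along(feats), feats),
                     matrix(stats::rnorm(length(feats) * 3), length(feats), 3),
                     matrix(stats::rnorm(9), 3, 3))
  fm <- lapply(seq_len(T), function(t) sample(feats, sample(1:3, 1)))
  list(model = model, featmaps = fm)
}

# scalar-loop re-implementation of the Bi-RNN forward pass
ref_birnn_forward <- function(p, X) {
  D <- p$D; H <- p$H; C <- p$C; T <- ncol(X)
  act <- function(a) if (p$activation == "tanh") tanh(a) else stats::plogis(a)
  hf <- matrix(0, H, T); hb <- matrix(0, H, T)
  for (t in seq_len(T)) {
    prev <- if (t == 1) rep(0, H) else hf[, t - 1]
    for (i in seq_len(H)) {
      s <- p$b_f[i]
      for (j in seq_len(D)) s <- s + p$U_f[i, j] * X[j, t]
      for (j in seq_len(H)) s <- s + p$W_f[i, j] * prev[j]
      hf[i, t] <- act(s)
    }
  }
  for (t in rev(seq_len(T))) {
    nxt <- if (t == T) rep(0, H) else hb[, t + 1]
    for (i in seq_len(H)) {
      s <- p$b_b[i]
      for (j in seq_len(D)) s <- s + p$U_b[i, j] * X[j, t]
      for (j in seq_len(H)) s <- s + p$W_b[i, j] * nxt[j]
      hb[i, t] <- act(s)
    }
  }
  y <- matrix(0, C, T)
  for (t in seq_len(T)) {
    z <- rep(0, C)
    for (i in seq_len(C)) {
      for (j in seq_len(H)) z[i] <- z[i] + p$V[i, j] * hf[j, t]
      for (j in seq_len(H)) z[i] <- z[i] + p$V[i, H + j] * hb[j, t]
    }
    e <- exp(z - max(z))
    y[, t] <- e / sum(e)
  }
  list(y = y, states = rbind(hf, hb))
}

# numeric central-difference gradient of f at par
numeric_gradient <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# tiny hand-built lexicon used across modules
toy_lexicon <- function() {
  dner_lexicon(list(
    T0001 = list(name = "acute kidney injury", synonyms = "AKI"),
    T0002 = list(name = "chest pain", synonyms = character(0)),
    T0003 = list(name = "psychosis", synonyms = "psychotic disorder")))
}

# default small synthetic corpus for property tests
small_synth <- function(seed = 11, n_docs = 25, lexicon_size = 10, ...) {
  cfg <- generator_config(seed = seed, n_docs = n_docs,
                          lexicon_size = lexicon_size, ...)
  lex <- make_lexicon(cfg)
  list(config = cfg, lexicon = lex, docs = generate_corpus(lex, cfg))
}

expect_docs_equal <- function(a, b) {
  expect_equal(a$doc_id, b$doc_id)
  expect_equal(a$title, b$title)
  expect_equal(a$abstract, b$abstract)
  expect_equal(a$mentions, b$mentions, ignore_attr = TRUE)
}
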