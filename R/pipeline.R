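# End-to-end orchestration: preprocessing, feature extraction, base tagger
# training and tagging, post-processing, ensemble combination, normalization
# and evaluation, with a JSON report capturing all seeds and settings.

POS_LEVELS <- c("CD", "PUNCT", "DT", "IN", "CC", "PRP", "MD", "VB", "RB",
                "VBG", "VBD", "JJ", "NNS", "NN")

#' Preprocess one document for tagging
#'
#' Sentence-splits, tokenizes, POS/chunk-tags and featurizes a document, and
#' aligns its gold mentions to token-level BIO labels.
#'
#' @param doc A `dner_document`.
#' @param lexicon A `dner_lexicon`.
#' @param config A [feature_config()].
#' @return A `prepared_document`: the document plus `text`, `tokens`, `pos`,
#'   `chunk`, `bio` (gold labels), `featmaps` and per-sentence token index
#'   lists.
#' @export
prepare_document <- function(doc, lexicon, config = feature_config()) {
  text <- full_text(doc)
  tokens <- tokenize_document(doc)
  pos <- pos_tag(tokens)
  chunk <- chunk_tag(tokens, pos)
  sent_ids <- unique(tokens$sentence_index)
  sent_tokens <- lapply(sent_ids, function(s)
    which(tokens$sentence_index == s))
  featmaps <- lapply(sent_tokens, function(idx)
    build_token_features(tokens$surface[idx], pos[idx], chunk[idx],
                         lexicon, config))
  bio <- mentions_to_bio(tokens, doc$mentions)
  structure(list(doc = doc, doc_id = doc$doc_id, text = text,
                 tokens = tokens, pos = pos, chunk = chunk, bio = bio,
                 sentences = sent_tokens, featmaps = featmaps,
                 dict_flags = vapply(tokens$surface, dict_flag, character(1),
                                     lexicon = lexicon, USE.NAMES = FALSE),
                 dict_bio = dict_bio(tokens, lexicon)),
            class = "prepared_document")
}

# flatten prepared documents into the CRF training corpus
crf_corpus <- function(pdocs) {
  out <- list()
  for (pd in pdocs)
    for (k in seq_along(pd$sentences)) {
      idx <- pd$sentences[[k]]
      out[[length(out) + 1L]] <- list(features = pd$featmaps[[k]],
                                      labels = pd$bio[idx])
    }
  out
}

# flatten prepared documents into the Bi-RNN training corpus
birnn_corpus <- function(pdocs) {
  out <- list()
  for (pd in pdocs)
    for (idx in pd$sentences)
      out[[length(out) + 1L]] <- list(tokens = pd$tokens$surface[idx],
                                      labels = pd$bio[idx])
  out
}

#' Tag a prepared document with the CRF
#'
#' @param model A `dner_crf`.
#' @param pdoc A [prepare_document()] result.
#' @return `list(labels, confidences, mentions)` over the document's tokens.
#' @export
crf_tag_document <- function(model, pdoc) {
  labels <- character(nrow(pdoc$tokens))
  conf <- numeric(nrow(pdoc$tokens))
  for (k in seq_along(pdoc$sentences)) {
    idx <- pdoc$sentences[[k]]
    tg <- crf_tag(model, pdoc$featmaps[[k]])
    labels[idx] <- tg$labels
    conf[idx] <- tg$confidences
  }
  list(labels = labels, confidences = conf,
       mentions = bio_to_mentions(pdoc$tokens, labels, pdoc$text))
}

#' Tag a prepared document with the Bi-RNN
#'
#' @param params Trained `birnn_params`.
#' @param pdoc A [prepare_document()] result.
#' @param table An [embedding_table()].
#' @param states Also return the penultimate-layer states?
#' @return `list(labels, confidences, mentions[, states])`.
#' @export
birnn_tag_document <- function(params, pdoc, table, states = TRUE) {
  n <- nrow(pdoc$tokens)
  labels <- character(n)
  conf <- numeric(n)
  S <- if (states) matrix(0, 2L * params$H, n) else NULL
  for (idx in pdoc$sentences) {
    toks <- pdoc$tokens$surface[idx]
    fp <- forward_pass(params, embed_tokens(table, toks))
    pick <- apply(fp$y, 2, which.max)
    labels[idx] <- params$labels[pick]
    conf[idx] <- fp$y[cbind(pick, seq_along(pick))]
    if (states) S[, idx] <- fp$states
  }
  out <- list(labels = labels, confidences = conf,
              mentions = bio_to_mentions(pdoc$tokens, labels, pdoc$text))
  if (states) out$states <- S
  out
}

# ensemble instance matrix for one prepared document
document_instances <- function(pdoc, crf_out, rnn_out, error_rates) {
  build_instances(crf_out$labels, crf_out$confidences,
                  rnn_out$labels, rnn_out$confidences,
                  pdoc$pos, pdoc$dict_flags, pdoc$dict_bio,
                  penult = rnn_out$states, error_rates = error_rates,
                  pos_levels = POS_LEVELS)
}

#' Default pipeline configuration
#'
#' All knobs of [run_pipeline()] with their defaults; any entry can be
#' overridden via `...` (nested lists are merged shallowly).
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param ... Overrides, e.g. `n_docs = 300`, `crf = list(maxit = 50)`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_docs = 120L,
    lexicon_size = 20L,
    fractions = c(2 / 3, 0, 1 / 3),
    generator = list(abbrev_prob = 0.5, repeat_prob = 0.5,
                     mention_density = 1.5),
    features = list(),           # feature_config() overrides
    crf = list(l2 = 1.0, maxit = 100L),
    embeddings = list(D = 16L, window = 2L, epochs = 3L),
    birnn = list(H = 32L, epochs = 25L, dropout = 0.25, lr = 0.01),
    ensemble = list(k = 3L, cost = 1,
                    fold_crf_maxit = 40L, fold_birnn_epochs = 8L),
    min_count = 2L,
    output_dir = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full recognition + normalization pipeline
#'
#' Generates (or loads) a corpus, trains the CRF and Bi-RNN base taggers,
#' applies post-processing to the CRF output, trains the SVM combiner on the
#' training documents, tags the held-out test documents, normalizes the
#' combined mentions against the lexicon, and evaluates at the mention and
#' concept level. Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param docs,lexicon Optional pre-built corpus and lexicon (bypasses the
#'   generator; `docs` must be a list of `dner_document`).
#' @param verbose Print stage progress?
#' @return A report list: metrics for every model, the configuration, and
#'   (when `config$output_dir` is set) paths of the written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), docs = NULL,
                         lexicon = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- config$seed

  gen <- do.call(generator_config, c(
    list(seed = seed, n_docs = config$n_docs,
         lexicon_size = config$lexicon_size), config$generator))
  if (is.null(lexicon))
    lexicon <- stage("lexicon", make_lexicon(gen))
  if (is.null(docs))
    docs <- stage("corpus", generate_corpus(lexicon, gen))
  splits <- stage("split", split_corpus(docs, config$fractions, seed))
  say("corpus: %d train / %d dev / %d test documents",
      length(splits$train), length(splits$dev), length(splits$test))

  fc <- do.call(feature_config, config$features)
  prep <- function(ds) lapply(ds, prepare_document, lexicon = lexicon,
                              config = fc)
  ptrain <- stage("preprocess", prep(splits$train))
  pdev <- stage("preprocess", prep(splits$dev))
  ptest <- stage("preprocess", prep(splits$test))

  say("training CRF ...")
  crf <- stage("crf_train",
               train_crf(crf_corpus(ptrain), l2 = config$crf$l2,
                         maxit = config$crf$maxit))

  say("training embeddings + Bi-RNN ...")
  emb_sentences <- unlist(lapply(ptrain, function(pd)
    lapply(pd$sentences, function(idx) pd$tokens$surface[idx])),
    recursive = FALSE)
  table <- stage("embeddings", train_toy_embeddings(
    emb_sentences, D = config$embeddings$D,
    window = config$embeddings$window,
    epochs = config$embeddings$epochs, seed = derive_seed(seed, 37L)))
  rnn <- stage("birnn_train", train_birnn(
    birnn_corpus(ptrain), table, H = config$birnn$H,
    epochs = config$birnn$epochs, dropout = config$birnn$dropout,
    lr = config$birnn$lr, seed = derive_seed(seed, 41L),
    validation = if (length(pdev)) birnn_corpus(pdev) else NULL))

  say("estimating base error rates ...")
  err <- stage("error_rates", c(
    crf = estimate_error_rate(
      ptrain,
      function(ds) train_crf(crf_corpus(ds), l2 = config$crf$l2,
                             maxit = config$ensemble$fold_crf_maxit),
      function(m, pd) crf_tag_document(m, pd)$labels,
      k = config$ensemble$k, seed = derive_seed(seed, 43L)),
    rnn = estimate_error_rate(
      ptrain,
      function(ds) train_birnn(birnn_corpus(ds), table,
                               H = config$birnn$H,
                               epochs = config$ensemble$fold_birnn_epochs,
                               dropout = config$birnn$dropout,
                               lr = config$birnn$lr,
                               seed = derive_seed(seed, 47L)),
      function(m, pd) birnn_tag_document(m, pd, table,
                                         states = FALSE)$labels,
      k = config$ensemble$k, seed = derive_seed(seed, 43L))))

  tag_all <- function(pdocs) lapply(pdocs, function(pd) {
    crf_out <- crf_tag_document(crf, pd)
    ppm <- postprocess_mentions(pd$doc, crf_out$mentions, lexicon,
                                min_count = config$min_count)
    pp_labels <- mentions_to_bio(pd$tokens, ppm)
    pp_conf <- ifelse(pp_labels == crf_out$labels, crf_out$confidences,
                      1 - crf_out$confidences)
    rnn_out <- birnn_tag_document(rnn, pd, table)
    list(pd = pd, crf_raw = crf_out,
         crf_pp = list(labels = pp_labels, confidences = pp_conf,
                       mentions = ppm),
         rnn = rnn_out,
         X = document_instances(
           pd, list(labels = pp_labels, confidences = pp_conf),
           rnn_out, err))
  })

  say("tagging ...")
  ttrain <- stage("tag_train", tag_all(ptrain))
  ttest <- stage("tag_test", tag_all(ptest))

  say("training combiner ...")
  Xtr <- do.call(rbind, lapply(ttrain, `[[`, "X"))
  ytr <- unlist(lapply(ttrain, function(x) x$pd$bio))
  layout <- attr(ttrain[[1]]$X, "layout")
  attr(Xtr, "layout") <- layout
  combiner <- stage("combiner", train_combiner(
    Xtr, ytr, cost = config$ensemble$cost, seed = derive_seed(seed, 53L)))

  with_mentions <- function(pd, mentions)
    dner_document(pd$doc_id, pd$doc$title, pd$doc$abstract, mentions)
  gold_test <- lapply(ptest, `[[`, "doc")
  pred_docs <- function(field) lapply(ttest, function(x)
    with_mentions(x$pd, x[[field]]$mentions))

  say("combining + evaluating ...")
  ens_docs <- stage("combine", lapply(ttest, function(x)
    with_mentions(x$pd, combine_predictions(x$pd, x$X, combiner))))

  m_crf_raw <- evaluate_mentions(pred_docs("crf_raw"), gold_test)
  m_crf_pp <- evaluate_mentions(pred_docs("crf_pp"), gold_test)
  m_rnn <- evaluate_mentions(pred_docs("rnn"), gold_test)
  m_ens <- evaluate_mentions(ens_docs, gold_test)
  # post-processing must never lower mention-level recall
  stopifnot(m_crf_pp$recall >= m_crf_raw$recall - 1e-12)

  say("normalizing ...")
  index <- stage("index", build_concept_index(lexicon))
  norm_docs <- stage("normalize", lapply(ens_docs, function(d)
    normalize_document(d, index)$doc))
  c_ens <- evaluate_concepts(norm_docs, gold_test)

  metric <- function(e) list(precision = e$precision, recall = e$recall,
                             f1 = e$f1, tp = e$tp, fp = e$fp, fn = e$fn)
  report <- list(
    config = unclass(config),
    corpus = list(n_train = length(splits$train),
                  n_dev = length(splits$dev),
                  n_test = length(splits$test),
                  lexicon_size = length(lexicon$entries)),
    error_rates = as.list(err),
    mention_level = list(crf = metric(m_crf_raw),
                         crf_postprocessed = metric(m_crf_pp),
                         birnn = metric(m_rnn),
                         ensemble = metric(m_ens)),
    concept_level = list(ensemble = metric(c_ens)))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_pubtator(docs, file.path(config$output_dir, "corpus.txt"))
    write_lexicon(lexicon, file.path(config$output_dir, "lexicon.tsv"))
    write_pubtator(ens_docs, file.path(config$output_dir, "tagged.txt"))
    write_pubtator(norm_docs, file.path(config$output_dir, "normalized.txt"))
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    report$artifacts <- list(
      corpus = file.path(config$output_dir, "corpus.txt"),
      lexicon = file.path(config$output_dir, "lexicon.tsv"),
      tagged = file.path(config$output_dir, "tagged.txt"),
      normalized = file.path(config$output_dir, "normalized.txt"),
      report = file.path(config$output_dir, "report.json"))
  }
  report
}
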