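# SVM meta-classifier fusing per-token outputs of the CRF (post-processed)
# and Bi-RNN taggers: one instance per token, with one-hot base labels, base
# confidences, base error rates, POS tags, dictionary look-ups and the
# Bi-RNN penultimate-layer states as feature blocks.

BIO_LEVELS <- c("B", "I", "O")

#' Cross-validated token error rate of a base tagger
#'
#' k-fold cross-validation over documents: the tagger is retrained on k-1
#' folds and its token-level misclassification rate is measured on the held
#' out fold; the pooled rate over all folds is returned. Used (rather than
#' resubstitution) because a memorizing base model would otherwise report a
#' near-zero rate.
#'
#' @param docs List of prepared documents (see [prepare_document()]), each
#'   carrying tokens and gold BIO labels.
#' @param train_fun `function(docs) -> model`.
#' @param tag_fun `function(model, doc) -> character vector` of predicted
#'   per-token labels for one prepared document.
#' @param k Number of folds (must not exceed the document count).
#' @param seed Seed for the fold assignment.
#' @return Token-level error rate in [0, 1].
#' @export
estimate_error_rate <- function(docs, train_fun, tag_fun, k = 5L, seed = 1L) {
  n <- length(docs)
  if (k > n) stop("k exceeds the number of documents")
  folds <- with_seed(derive_seed(seed, 17L),
                     sample(rep_len(seq_len(k), n)))
  wrong <- 0L; total <- 0L
  for (f in seq_len(k)) {
    model <- train_fun(docs[folds != f])
    for (doc in docs[folds == f]) {
      pred <- tag_fun(model, doc)
      gold <- doc$bio
      if (length(pred) != length(gold))
        stop("tagger output not aligned with gold labels")
      wrong <- wrong + sum(pred != gold)
      total <- total + length(gold)
    }
  }
  if (total == 0) return(0)
  wrong / total
}

#' Build per-token ensemble instances for one document
#'
#' Feature blocks per token: one-hot CRF label (3), one-hot Bi-RNN label (3),
#' the two confidences, the two (constant) base error rates, one-hot POS tag,
#' dictionary word flag and one-hot dictionary BIO tag, and the Bi-RNN
#' penultimate-layer state (2H). All streams must be aligned to the same
#' token sequence.
#'
#' @param crf_labels,crf_conf CRF per-token labels and confidences.
#' @param rnn_labels,rnn_conf Bi-RNN per-token labels and confidences.
#' @param pos Per-token POS tags.
#' @param dict_flags Per-token "Y"/"N" word flags.
#' @param dict_bio_labels Per-token dictionary BIO tags.
#' @param penult 2H x T penultimate-state matrix (or NULL to omit the block).
#' @param error_rates Numeric length-2 vector `c(crf, rnn)`.
#' @param pos_levels POS tag alphabet for the one-hot block.
#' @return T x dim numeric matrix; attribute `"layout"` records block sizes.
#' @export
build_instances <- function(crf_labels, crf_conf, rnn_labels, rnn_conf,
                            pos, dict_flags, dict_bio_labels,
                            penult = NULL, error_rates = c(0, 0),
                            pos_levels = NULL) {
  T <- length(crf_labels)
  lens <- c(length(crf_conf), length(rnn_labels), length(rnn_conf),
            length(pos), length(dict_flags), length(dict_bio_labels))
  if (any(lens != T)) stop("ensemble feature streams are not aligned")
  if (!is.null(penult) && ncol(penult) != T)
    stop("penultimate states not aligned")
  if (is.null(pos_levels)) pos_levels <- sort(unique(pos))
  onehot <- function(x, levels) {
    M <- matrix(0, length(x), length(levels),
                dimnames = list(NULL, levels))
    hit <- match(x, levels)
    ok <- !is.na(hit)
    M[cbind(which(ok), hit[ok])] <- 1
    M
  }
  blocks <- list(
    crf_label = onehot(crf_labels, BIO_LEVELS),
    rnn_label = onehot(rnn_labels, BIO_LEVELS),
    confidence = cbind(crf = crf_conf, rnn = rnn_conf),
    error_rate = matrix(rep(error_rates, each = T), T, 2,
                        dimnames = list(NULL, c("err_crf", "err_rnn"))),
    pos = onehot(pos, pos_levels),
    dictA = matrix(as.numeric(dict_flags == "Y"), T, 1,
                   dimnames = list(NULL, "dictA")),
    dictB = onehot(dict_bio_labels, BIO_LEVELS))
  if (!is.null(penult))
    blocks$embedding <- t(penult)
  X <- do.call(cbind, blocks)
  attr(X, "layout") <- list(blocks = vapply(blocks, ncol, integer(1)),
                            pos_levels = pos_levels)
  X
}

#' Train the SVM combiner
#'
#' Multi-class RBF-kernel SVM over B/I/O with standardized features and
#' balanced class weights (O dominates). Deterministic given seed and data.
#'
#' @param X Instance matrix from [build_instances()] (rows stacked over the
#'   training corpus).
#' @param y Gold BIO labels (length `nrow(X)`).
#' @param cost,gamma SVM hyperparameters (`gamma` defaults to 1/dim).
#' @param seed RNG seed.
#' @return Object of class `dner_combiner` carrying the SVM, the scaling
#'   parameters and the feature-layout manifest.
#' @export
train_combiner <- function(X, y, cost = 1, gamma = NULL, seed = 1L) {
  if (!nrow(X)) stop("empty training set")
  y <- factor(y, levels = BIO_LEVELS)
  present <- table(droplevels(y))
  if (length(present) < 2) stop("single-class training set")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = center, scale = scl)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  wts <- sum(present) / (length(present) * as.numeric(present))
  names(wts) <- names(present)
  fit <- with_seed(derive_seed(seed, 19L),
    e1071::svm(Xs, droplevels(y), kernel = "radial", cost = cost,
               gamma = gamma, class.weights = wts, scale = FALSE))
  structure(list(svm = fit, center = center, scale = scl,
                 layout = attr(X, "layout"), labels = BIO_LEVELS),
            class = "dner_combiner")
}

#' @export
print.dner_combiner <- function(x, ...) {
  cat(sprintf("<dner_combiner: %d support vectors, %d features>\n",
              x$svm$tot.nSV, length(x$center)))
  invisible(x)
}

#' Predict combined labels for instances
#'
#' @param model A `dner_combiner`.
#' @param X Instance matrix with the same layout as at training time.
#' @return Character vector of BIO labels.
#' @export
predict_combiner <- function(model, X) {
  lay <- attr(X, "layout")
  if (!is.null(lay) && !identical(lay$blocks, model$layout$blocks))
    stop("instance layout does not match the combiner's training layout")
  if (ncol(X) != length(model$center))
    stop("instance dimension does not match the combiner")
  Xs <- scale(X, center = model$center, scale = model$scale)
  as.character(stats::predict(model$svm, Xs))
}

#' Repair a BIO sequence
#'
#' Turns orphan `I` labels (at sequence start or following `O`) into `B`.
#'
#' @param labels Character vector of BIO labels.
#' @return Repaired label vector.
#' @export
repair_bio <- function(labels) {
  n <- length(labels)
  if (!n) return(labels)
  prev <- c("O", labels[-n])
  orphan <- labels == "I" & prev == "O"
  labels[orphan] <- "B"
  labels
}

#' Combine base tagger outputs into final mentions
#'
#' Per-token SVM prediction, BIO repair, then span extraction.
#'
#' @param doc A prepared document (see [prepare_document()]).
#' @param X Instance matrix for this document's tokens.
#' @param model A `dner_combiner`.
#' @return Mention data frame satisfying all document invariants.
#' @export
combine_predictions <- function(doc, X, model) {
  labels <- repair_bio(predict_combiner(model, X))
  bio_to_mentions(doc$tokens, labels, doc$text)
}
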