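# Mention-level (exact span) and concept-level (per-document ID set)
# precision / recall / F1, micro-averaged over the corpus.

#' Build an evaluation result from confusion counts
#'
#' Precision and recall are defined as 0 when their denominators are 0; F1 is
#' the harmonic mean (0 when p + r = 0).
#'
#' @param tp,fp,fn True positive, false positive, false negative counts.
#' @return An `eval_result` list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
eval_result <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f1 = f1), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (TP %d / FP %d / FN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

check_aligned <- function(pred_docs, gold_docs) {
  pid <- vapply(pred_docs, `[[`, character(1), "doc_id")
  gid <- vapply(gold_docs, `[[`, character(1), "doc_id")
  if (!identical(sort(pid), sort(gid)))
    stop("document IDs differ between predictions and gold: ",
         paste(union(setdiff(pid, gid), setdiff(gid, pid)), collapse = ", "))
  list(pred = pred_docs[order(pid)], gold = gold_docs[order(gid)])
}

#' Mention-level evaluation (exact span match)
#'
#' A predicted mention is a true positive iff a gold mention with identical
#' (doc_id, start, end) exists; counts are pooled over the corpus.
#'
#' @param pred_docs,gold_docs Lists of `dner_document` with the same IDs.
#' @return An [eval_result()].
#' @export
evaluate_mentions <- function(pred_docs, gold_docs) {
  al <- check_aligned(pred_docs, gold_docs)
  tp <- fp <- fn <- 0L
  for (k in seq_along(al$pred)) {
    pk <- with(al$pred[[k]]$mentions,
               paste(start, end, sep = ":"))
    gk <- with(al$gold[[k]]$mentions,
               paste(start, end, sep = ":"))
    tp <- tp + length(intersect(pk, gk))
    fp <- fp + length(setdiff(pk, gk))
    fn <- fn + length(setdiff(gk, pk))
  }
  eval_result(tp, fp, fn)
}

#' Concept-level evaluation (per-document ID sets)
#'
#' Each document contributes its set of distinct predicted concept IDs
#' ("-1" excluded) against its set of gold concept IDs; TP/FP/FN are summed
#' over documents.
#'
#' @param pred_docs,gold_docs Lists of `dner_document` whose mentions carry
#'   concept IDs.
#' @return An [eval_result()].
#' @export
evaluate_concepts <- function(pred_docs, gold_docs) {
  al <- check_aligned(pred_docs, gold_docs)
  tp <- fp <- fn <- 0L
  for (k in seq_along(al$pred)) {
    p <- setdiff(unique(al$pred[[k]]$mentions$concept_id), "-1")
    g <- setdiff(unique(al$gold[[k]]$mentions$concept_id), "-1")
    tp <- tp + length(intersect(p, g))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  eval_result(tp, fp, fn)
}
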