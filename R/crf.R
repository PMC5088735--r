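# Linear-chain conditional random field over BIO labels: scoring, Viterbi
# decoding, forward-backward marginals and L-BFGS maximum-likelihood training.
# Everything is computed in log space; stability is guaranteed for weights of
# magnitude up to ~50.

CRF_LABELS <- c("B", "I", "O")

#' Construct a CRF model from explicit weights
#'
#' Mostly used for tests and constructed examples; [train_crf()] returns the
#' same structure with fitted weights.
#'
#' @param feat_index Named integer vector mapping feature strings
#'   (`"name=value"`) to rows of `W`.
#' @param W Emission weight matrix, `length(feat_index)` x 3 (columns B, I, O).
#' @param Tm Transition weight matrix, 3 x 3 (`Tm[i, j]` scores label `i`
#'   followed by label `j`).
#' @param l2 L2 regularization strength used at training time.
#' @return Object of class `dner_crf`.
#' @export
crf_model <- function(feat_index, W, Tm, l2 = 1.0) {
  W <- as.matrix(W); Tm <- as.matrix(Tm)
  stopifnot(nrow(W) == length(feat_index), ncol(W) == 3,
            all(dim(Tm) == c(3, 3)), all(is.finite(W)), all(is.finite(Tm)))
  colnames(W) <- CRF_LABELS
  dimnames(Tm) <- list(CRF_LABELS, CRF_LABELS)
  structure(list(labels = CRF_LABELS, feat_index = feat_index, W = W,
                 Tm = Tm, l2 = l2), class = "dner_crf")
}

#' @export
print.dner_crf <- function(x, ...) {
  cat(sprintf("<dner_crf: %d features, l2 = %g>\n", length(x$feat_index), x$l2))
  invisible(x)
}

# per-token emission score matrix (T x 3); unknown features contribute 0
crf_emissions <- function(model, featmaps) {
  T <- length(featmaps)
  E <- matrix(0, T, 3)
  for (t in seq_len(T)) {
    ids <- model$feat_index[featmaps[[t]]]
    ids <- ids[!is.na(ids)]
    if (length(ids)) E[t, ] <- colSums(model$W[ids, , drop = FALSE])
  }
  E
}

#' Score a labeling under the CRF
#'
#' Sum of emission weights of active features plus transition weights along
#' the label path.
#'
#' @param model A `dner_crf`.
#' @param featmaps List of per-token feature vectors (see
#'   [build_token_features()]).
#' @param labels Character vector over B/I/O, same length.
#' @return The (unnormalized) path score.
#' @export
score_sequence <- function(model, featmaps, labels) {
  if (length(labels) != length(featmaps))
    stop("labels and feature maps have different lengths")
  if (!all(labels %in% CRF_LABELS)) stop("unknown label in sequence")
  if (!length(labels)) return(0)
  E <- crf_emissions(model, featmaps)
  li <- match(labels, CRF_LABELS)
  s <- sum(E[cbind(seq_along(li), li)])
  if (length(li) > 1)
    s <- s + sum(model$Tm[cbind(li[-length(li)], li[-1])])
  s
}

# column/row log-sum-exp for 3x3 score matrices
.lse_cols <- function(S) {
  m <- pmax(S[1, ], S[2, ], S[3, ])
  m + log(exp(S[1, ] - m) + exp(S[2, ] - m) + exp(S[3, ] - m))
}
.lse_rows <- function(S) {
  m <- pmax(S[, 1], S[, 2], S[, 3])
  m + log(exp(S[, 1] - m) + exp(S[, 2] - m) + exp(S[, 3] - m))
}

#' Viterbi decoding
#'
#' Returns the labeling maximizing [score_sequence()] over all 3^T paths.
#' Ties are broken lexicographically (B < I < O) at each position.
#'
#' @param model A `dner_crf`.
#' @param featmaps List of per-token feature vectors.
#' @return Character vector of labels (empty for an empty sentence).
#' @export
viterbi_decode <- function(model, featmaps) {
  T <- length(featmaps)
  if (!T) return(character(0))
  E <- crf_emissions(model, featmaps)
  delta <- E[1, ]
  back <- matrix(0L, T, 3)
  if (T > 1) for (t in 2:T) {
    S <- model$Tm + delta            # S[i, j] = delta[i] + Tm[i, j]
    best <- apply(S, 2, which.max)   # first max -> lexicographic tie-break
    delta <- E[t, ] + S[cbind(best, 1:3)]
    back[t, ] <- best
  }
  path <- integer(T)
  path[T] <- which.max(delta)
  if (T > 1) for (t in T:2) path[t - 1] <- back[t, path[t]]
  CRF_LABELS[path]
}

# forward-backward in log space; returns marginals, pairwise expectations
# and the log partition function
crf_forward_backward <- function(E, Tm, pairwise = FALSE) {
  T <- nrow(E)
  alpha <- matrix(0, T, 3)
  beta <- matrix(0, T, 3)
  alpha[1, ] <- E[1, ]
  if (T > 1) for (t in 2:T)
    alpha[t, ] <- E[t, ] + .lse_cols(Tm + alpha[t - 1, ])
  if (T > 1) for (t in (T - 1):1) {
    v <- E[t + 1, ] + beta[t + 1, ]
    beta[t, ] <- .lse_rows(Tm + matrix(v, 3, 3, byrow = TRUE))
  }
  logZ <- logsumexp(alpha[T, ])
  marg <- exp(alpha + beta - logZ)
  pair <- NULL
  if (pairwise) {
    pair <- matrix(0, 3, 3)
    if (T > 1) for (t in 2:T) {
      v <- E[t, ] + beta[t, ]
      M <- (Tm + alpha[t - 1, ]) + matrix(v, 3, 3, byrow = TRUE)
      pair <- pair + exp(M - logZ)
    }
  }
  list(marg = marg, logZ = logZ, pair = pair)
}

#' Per-token posterior label marginals
#'
#' Forward-backward posteriors `p(label_t | sentence)`; each row sums to 1.
#' The marginal of a token's assigned label is the tagger's confidence score.
#'
#' @param model A `dner_crf`.
#' @param featmaps List of per-token feature vectors.
#' @return T x 3 matrix with columns B, I, O.
#' @export
token_marginals <- function(model, featmaps) {
  T <- length(featmaps)
  if (!T) return(matrix(0, 0, 3, dimnames = list(NULL, CRF_LABELS)))
  E <- crf_emissions(model, featmaps)
  marg <- crf_forward_backward(E, model$Tm)$marg
  colnames(marg) <- CRF_LABELS
  marg
}

# compile a training corpus into sparse structures:
#   M (Ntok x nfeat) feature incidence, y label indices, sentence boundaries
crf_compile <- function(corpus) {
  all_feats <- unique(unlist(lapply(corpus, function(s)
    unlist(s$features, use.names = FALSE)), use.names = FALSE))
  feat_index <- stats::setNames(seq_along(all_feats), all_feats)
  ii <- list(); jj <- list()
  y <- integer(0); sent_len <- integer(length(corpus))
  tok <- 0L
  for (k in seq_along(corpus)) {
    s <- corpus[[k]]
    if (length(s$features) != length(s$labels))
      stop("sentence ", k, ": features/labels length mismatch")
    sent_len[k] <- length(s$features)
    for (t in seq_along(s$features)) {
      tok <- tok + 1L
      ids <- feat_index[s$features[[t]]]
      ii[[tok]] <- rep.int(tok, length(ids))
      jj[[tok]] <- as.integer(ids)
    }
    y <- c(y, match(s$labels, CRF_LABELS))
  }
  if (anyNA(y)) stop("unknown label in training corpus")
  M <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = 1,
    dims = c(tok, length(feat_index)))
  list(M = M, y = y, sent_len = sent_len, feat_index = feat_index)
}

#' Train a linear-chain CRF
#'
#' Maximizes the L2-regularized conditional log-likelihood with L-BFGS
#' (analytic gradients). Deterministic given the data order.
#'
#' @param corpus List of sentences, each `list(features = <list of per-token
#'   feature vectors>, labels = <BIO vector>)`.
#' @param l2 L2 regularization strength (0 disables).
#' @param maxit Optimizer iteration cap.
#' @param verbose Print optimizer progress?
#' @return A fitted `dner_crf`; attribute `"nll"` holds the final penalized
#'   negative log-likelihood.
#' @export
train_crf <- function(corpus, l2 = 1.0, maxit = 200L, verbose = FALSE) {
  if (!length(corpus)) stop("empty training corpus")
  cc <- crf_compile(corpus)
  nf <- length(cc$feat_index)
  ntok <- nrow(cc$M)
  Y <- Matrix::sparseMatrix(i = seq_len(ntok), j = cc$y, x = 1,
                            dims = c(ntok, 3))
  emp_W <- as.matrix(Matrix::crossprod(cc$M, Y))    # nf x 3
  emp_T <- matrix(0, 3, 3)
  off <- 0L
  for (len in cc$sent_len) {
    if (len > 1) {
      yi <- cc$y[(off + 1L):(off + len)]
      for (t in 2:len) emp_T[yi[t - 1], yi[t]] <- emp_T[yi[t - 1], yi[t]] + 1
    }
    off <- off + len
  }
  sent_start <- cumsum(c(0L, cc$sent_len))

  unpack <- function(par)
    list(W = matrix(par[seq_len(nf * 3)], nf, 3),
         Tm = matrix(par[nf * 3 + 1:9], 3, 3))

  last <- new.env()
  evaluate <- function(par) {
    p <- unpack(par)
    Eall <- as.matrix(cc$M %*% p$W)
    nll <- 0
    P <- matrix(0, ntok, 3)
    pair <- matrix(0, 3, 3)
    for (k in seq_along(cc$sent_len)) {
      idx <- (sent_start[k] + 1L):sent_start[k + 1L]
      fb <- crf_forward_backward(Eall[idx, , drop = FALSE], p$Tm,
                                 pairwise = TRUE)
      nll <- nll + fb$logZ
      P[idx, ] <- fb$marg
      pair <- pair + fb$pair
    }
    nll <- nll - sum(emp_W * p$W) - sum(emp_T * p$Tm) +
      0.5 * l2 * sum(par^2)
    gW <- as.matrix(Matrix::crossprod(cc$M, P)) - emp_W + l2 * p$W
    gT <- pair - emp_T + l2 * p$Tm
    last$par <- par
    last$grad <- c(gW, gT)
    nll
  }
  fn <- function(par) evaluate(par)
  gr <- function(par) {
    if (is.null(last$par) || !identical(par, last$par)) evaluate(par)
    last$grad
  }
  par0 <- numeric(nf * 3 + 9)
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7,
                                     trace = if (verbose) 1 else 0))
  p <- unpack(opt$par)
  model <- crf_model(cc$feat_index, p$W, p$Tm, l2 = l2)
  attr(model, "nll") <- opt$value
  attr(model, "convergence") <- opt$convergence
  model
}

# penalized negative log-likelihood and gradient at given parameters
# (exposed internally for the numerical-gradient tests)
crf_nll_grad <- function(corpus, par, l2 = 0) {
  cc <- crf_compile(corpus)
  nf <- length(cc$feat_index)
  W <- matrix(par[seq_len(nf * 3)], nf, 3)
  Tm <- matrix(par[nf * 3 + 1:9], 3, 3)
  ntok <- nrow(cc$M)
  Y <- Matrix::sparseMatrix(i = seq_len(ntok), j = cc$y, x = 1,
                            dims = c(ntok, 3))
  emp_W <- as.matrix(Matrix::crossprod(cc$M, Y))
  emp_T <- matrix(0, 3, 3)
  sent_start <- cumsum(c(0L, cc$sent_len))
  off <- 0L
  for (len in cc$sent_len) {
    if (len > 1) {
      yi <- cc$y[(off + 1L):(off + len)]
      for (t in 2:len) emp_T[yi[t - 1], yi[t]] <- emp_T[yi[t - 1], yi[t]] + 1
    }
    off <- off + len
  }
  Eall <- as.matrix(cc$M %*% W)
  nll <- 0; P <- matrix(0, ntok, 3); pair <- matrix(0, 3, 3)
  for (k in seq_along(cc$sent_len)) {
    idx <- (sent_start[k] + 1L):sent_start[k + 1L]
    fb <- crf_forward_backward(Eall[idx, , drop = FALSE], Tm, pairwise = TRUE)
    nll <- nll + fb$logZ; P[idx, ] <- fb$marg; pair <- pair + fb$pair
  }
  nll <- nll - sum(emp_W * W) - sum(emp_T * Tm) + 0.5 * l2 * sum(par^2)
  gW <- as.matrix(Matrix::crossprod(cc$M, P)) - emp_W + l2 * W
  gT <- pair - emp_T + l2 * Tm
  list(nll = nll, grad = c(gW, gT), feat_index = cc$feat_index)
}

#' Tag a sentence with the CRF
#'
#' Viterbi labels plus per-token confidence scores (the posterior marginal of
#' each assigned label).
#'
#' @param model A `dner_crf`.
#' @param featmaps List of per-token feature vectors.
#' @return `list(labels, confidences)`.
#' @export
crf_tag <- function(model, featmaps) {
  labels <- viterbi_decode(model, featmaps)
  if (!length(labels)) return(list(labels = labels, confidences = numeric(0)))
  marg <- token_marginals(model, featmaps)
  conf <- marg[cbind(seq_along(labels), match(labels, CRF_LABELS))]
  list(labels = labels, confidences = conf)
}
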