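# Bidirectional RNN token classifier: embedding lookup, forward and backward
# recurrences h_t = f(U x_t + W h_(t-1|t+1) + b), softmax output over the
# concatenated directional states, Adam training with input dropout, and
# penultimate-layer state export for the ensemble.

#' Numerically stable softmax
#'
#' `softmax(v)_i = exp(v_i) / sum_j exp(v_j)`, computed with a max shift so it
#' is invariant to adding a constant to all components.
#'
#' @param v Finite numeric vector.
#' @return Probability vector of the same length.
#' @export
softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

#' Construct an embedding table
#'
#' @param vectors D x V matrix with column names = (lower-cased) tokens.
#' @param oov Out-of-vocabulary vector (length D); defaults to zeros.
#' @return Object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, oov = NULL) {
  vectors <- as.matrix(vectors)
  D <- nrow(vectors)
  if (is.null(oov)) oov <- numeric(D)
  if (length(oov) != D) stop("OOV vector dimension mismatch")
  structure(list(vectors = vectors, oov = oov, D = D),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d tokens, dimension %d>\n",
              ncol(x$vectors), x$D))
  invisible(x)
}

#' Read word embeddings from whitespace-delimited text
#'
#' One `token v1 ... vD` line per word; an optional leading `V D` count header
#' is tolerated.
#'
#' @param path File path.
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (length(parts) > 1 && length(parts[[1]]) == 2 &&
      !is.na(suppressWarnings(as.numeric(parts[[1]][1]))))
    parts <- parts[-1]
  D <- length(parts[[1]]) - 1L
  if (any(lengths(parts) != D + 1L))
    stop("embedding file has inconsistent vector dimensions")
  vec <- vapply(parts, function(p) as.numeric(p[-1]), numeric(D))
  if (anyNA(vec)) stop("non-numeric value in embedding file")
  vec <- matrix(vec, nrow = D)
  colnames(vec) <- tolower(vapply(parts, `[[`, character(1), 1))
  embedding_table(vec)
}

#' Write an embedding table as whitespace-delimited text
#'
#' @param table An [embedding_table()].
#' @param path File path.
#' @export
write_embeddings <- function(table, path) {
  lines <- vapply(seq_len(ncol(table$vectors)), function(j)
    paste(colnames(table$vectors)[j],
          paste(format(table$vectors[, j], digits = 8, trim = TRUE),
                collapse = " ")), character(1))
  writeLines(lines, path)
}

#' Embed a token sequence
#'
#' Tokens are lower-cased before lookup; unknown tokens map to the table's
#' OOV vector.
#'
#' @param table An [embedding_table()].
#' @param tokens Character vector of token surfaces, or a token data frame.
#' @return D x T matrix of input vectors.
#' @export
embed_tokens <- function(table, tokens) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  lw <- tolower(tokens)
  X <- matrix(0, table$D, length(tokens))
  hit <- match(lw, colnames(table$vectors))
  known <- !is.na(hit)
  if (any(known)) X[, known] <- table$vectors[, hit[known], drop = FALSE]
  if (any(!known)) X[, !known] <- table$oov
  X
}

#' Initialize Bi-RNN parameters
#'
#' All matrices drawn uniformly from (-0.08, 0.08); initial hidden states
#' (h_0 forward, h_(T+1) backward) are zero vectors.
#'
#' @param D Input (embedding) dimension.
#' @param H Hidden size per direction.
#' @param C Number of classes (3 for B/I/O).
#' @param activation "tanh" or "logistic".
#' @param seed RNG seed.
#' @return Object of class `birnn_params`.
#' @export
birnn_init <- function(D, H = 32L, C = 3L, activation = c("tanh", "logistic"),
                       seed = 1L) {
  activation <- match.arg(activation)
  if (D <= 0 || H <= 0 || C <= 0) stop("dimensions must be positive")
  with_seed(seed, {
    rmat <- function(r, c) matrix(stats::runif(r * c, -0.08, 0.08), r, c)
    structure(list(
      U_f = rmat(H, D), W_f = rmat(H, H), b_f = stats::runif(H, -0.08, 0.08),
      U_b = rmat(H, D), W_b = rmat(H, H), b_b = stats::runif(H, -0.08, 0.08),
      V = rmat(C, 2L * H),
      D = D, H = H, C = C, activation = activation,
      labels = CRF_LABELS[seq_len(C)]), class = "birnn_params")
  })
}

#' @export
print.birnn_params <- function(x, ...) {
  cat(sprintf("<birnn_params: D=%d H=%d C=%d activation=%s>\n",
              x$D, x$H, x$C, x$activation))
  invisible(x)
}

.act <- function(a, kind) if (kind == "tanh") tanh(a) else stats::plogis(a)
.act_prime_from_h <- function(h, kind)
  if (kind == "tanh") 1 - h^2 else h * (1 - h)

#' Bi-RNN forward pass
#'
#' Computes `hf_t = f(U_f x_t + W_f hf_(t-1) + b_f)` left-to-right,
#' `hb_t = f(U_b x_t + W_b hb_(t+1) + b_b)` right-to-left, and
#' `y_t = softmax(V [hf_t; hb_t])`. The two recurrences are independent until
#' the output layer. Dropout is inactive here (inference mode).
#'
#' @param params A `birnn_params`.
#' @param X D x T input matrix (see [embed_tokens()]).
#' @return List with `hf`, `hb` (H x T), `states` (2H x T), `y` (C x T, each
#'   column a probability vector).
#' @export
forward_pass <- function(params, X) {
  X <- as.matrix(X)
  if (nrow(X) != params$D) stop("input dimension mismatch")
  T <- ncol(X)
  H <- params$H
  hf <- matrix(0, H, T); hb <- matrix(0, H, T)
  prev <- numeric(H)
  for (t in seq_len(T)) {
    prev <- .act(params$U_f %*% X[, t] + params$W_f %*% prev + params$b_f,
                 params$activation)
    hf[, t] <- prev
  }
  nxt <- numeric(H)
  for (t in rev(seq_len(T))) {
    nxt <- .act(params$U_b %*% X[, t] + params$W_b %*% nxt + params$b_b,
                params$activation)
    hb[, t] <- nxt
  }
  states <- rbind(hf, hb)
  y <- apply(params$V %*% states, 2, softmax)
  if (T == 0) y <- matrix(0, params$C, 0)
  y <- matrix(y, nrow = params$C)
  list(hf = hf, hb = hb, states = states, y = y)
}

# loss and analytic gradients for one sentence; X may already be dropout-masked
birnn_grad <- function(params, X, yidx) {
  T <- ncol(X)
  H <- params$H
  fp <- forward_pass(params, X)
  onehot <- matrix(0, params$C, T)
  onehot[cbind(yidx, seq_len(T))] <- 1
  loss <- -sum(log(pmax(fp$y[cbind(yidx, seq_len(T))], 1e-300)))
  dlog <- fp$y - onehot                       # C x T
  gV <- dlog %*% t(fp$states)
  dS <- t(params$V) %*% dlog                  # 2H x T
  gU_f <- matrix(0, H, params$D); gW_f <- matrix(0, H, H); gb_f <- numeric(H)
  gU_b <- matrix(0, H, params$D); gW_b <- matrix(0, H, H); gb_b <- numeric(H)
  carry <- numeric(H)
  for (t in rev(seq_len(T))) {                # forward direction BPTT
    da <- (dS[seq_len(H), t] + carry) *
      .act_prime_from_h(fp$hf[, t], params$activation)
    gU_f <- gU_f + da %*% t(X[, t])
    hprev <- if (t > 1) fp$hf[, t - 1] else numeric(H)
    gW_f <- gW_f + da %*% t(hprev)
    gb_f <- gb_f + da
    carry <- as.numeric(crossprod(params$W_f, da))
  }
  carry <- numeric(H)
  for (t in seq_len(T)) {                     # backward direction BPTT
    da <- (dS[H + seq_len(H), t] + carry) *
      .act_prime_from_h(fp$hb[, t], params$activation)
    gU_b <- gU_b + da %*% t(X[, t])
    hnext <- if (t < T) fp$hb[, t + 1] else numeric(H)
    gW_b <- gW_b + da %*% t(hnext)
    gb_b <- gb_b + da
    carry <- as.numeric(crossprod(params$W_b, da))
  }
  list(loss = loss,
       grads = list(U_f = gU_f, W_f = gW_f, b_f = gb_f,
                    U_b = gU_b, W_b = gW_b, b_b = gb_b, V = gV))
}

#' Train the Bi-RNN
#'
#' Per-sentence Adam updates of the cross-entropy loss, with inverted dropout
#' applied to the input embedding sequences (training mode only). Fully
#' reproducible given the seed. When a validation set is supplied, its
#' log-likelihood is recorded each epoch for convergence monitoring.
#'
#' @param corpus List of sentences, each `list(tokens = <character vector>,
#'   labels = <BIO vector>)`.
#' @param table An [embedding_table()].
#' @param params Initial `birnn_params` (or NULL to initialize from `seed`).
#' @param epochs Number of passes over the corpus.
#' @param dropout Input dropout rate (paper setting 0.25).
#' @param lr,beta1,beta2,eps Adam settings.
#' @param seed RNG seed (initialization, shuffling, dropout masks).
#' @param H Hidden size used when `params` is NULL.
#' @param validation Optional held-out sentence list.
#' @param shuffle Reshuffle sentences each epoch?
#' @param verbose Print per-epoch loss?
#' @return Trained `birnn_params`; attributes `"train_loss"` and
#'   `"validation_loglik"` record per-epoch trajectories.
#' @export
train_birnn <- function(corpus, table, params = NULL, epochs = 20L,
                        dropout = 0.25, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, seed = 1L, H = 32L,
                        validation = NULL, shuffle = TRUE, verbose = FALSE) {
  if (!length(corpus)) stop("empty training corpus")
  if (is.null(params))
    params <- birnn_init(table$D, H = H, seed = derive_seed(seed, 11L))
  Xs <- lapply(corpus, function(s) embed_tokens(table, s$tokens))
  Ys <- lapply(corpus, function(s) match(s$labels, params$labels))
  if (anyNA(unlist(Ys))) stop("unknown label in training corpus")
  pnames <- c("U_f", "W_f", "b_f", "U_b", "W_b", "b_b", "V")
  m <- lapply(params[pnames], function(p) p * 0)
  v <- m
  step <- 0L
  train_loss <- numeric(epochs)
  val_ll <- if (is.null(validation)) NULL else numeric(epochs)
  with_seed(derive_seed(seed, 13L), {
    for (ep in seq_len(epochs)) {
      ord <- if (shuffle) sample(seq_along(corpus)) else seq_along(corpus)
      total <- 0
      for (k in ord) {
        X <- Xs[[k]]
        if (!ncol(X)) next
        if (dropout > 0) {
          mask <- matrix(stats::rbinom(length(X), 1, 1 - dropout),
                         nrow(X), ncol(X)) / (1 - dropout)
          X <- X * mask
        }
        g <- birnn_grad(params, X, Ys[[k]])
        if (!is.finite(g$loss))
          stop(sprintf("NaN/Inf loss at epoch %d, sentence %d", ep, k))
        total <- total + g$loss
        step <- step + 1L
        for (nm in pnames) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g$grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g$grads[[nm]]^2
          mhat <- m[[nm]] / (1 - beta1^step)
          vhat <- v[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      train_loss[ep] <- total
      if (!is.null(validation))
        val_ll[ep] <- birnn_loglik(params, validation, table)
      if (verbose)
        message(sprintf("epoch %d: training loss %.4f%s", ep, total,
                        if (is.null(validation)) "" else
                          sprintf(", validation loglik %.4f", val_ll[ep])))
    }
  })
  attr(params, "train_loss") <- train_loss
  attr(params, "validation_loglik") <- val_ll
  params
}

#' Log-likelihood of a sentence set under the Bi-RNN
#'
#' @param params A `birnn_params`.
#' @param corpus Sentence list as in [train_birnn()].
#' @param table An [embedding_table()].
#' @return Sum of per-token log-probabilities of the gold labels.
#' @export
birnn_loglik <- function(params, corpus, table) {
  total <- 0
  for (s in corpus) {
    if (!length(s$tokens)) next
    fp <- forward_pass(params, embed_tokens(table, s$tokens))
    yi <- match(s$labels, params$labels)
    total <- total + sum(log(pmax(fp$y[cbind(yi, seq_along(yi))], 1e-300)))
  }
  total
}

#' Tag a sentence with the Bi-RNN
#'
#' `label_t = argmax y_t` (ties broken lexicographically B < I < O, i.e. first
#' maximum), `confidence_t = max(y_t)`.
#'
#' @param params A trained `birnn_params`.
#' @param tokens Character vector of token surfaces.
#' @param table An [embedding_table()].
#' @return `list(labels, confidences, y)`.
#' @export
tag_with_confidence <- function(params, tokens, table) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  if (!length(tokens))
    return(list(labels = character(0), confidences = numeric(0),
                y = matrix(0, params$C, 0)))
  fp <- forward_pass(params, embed_tokens(table, tokens))
  idx <- apply(fp$y, 2, which.max)
  list(labels = params$labels[idx],
       confidences = fp$y[cbind(idx, seq_along(idx))],
       y = fp$y)
}

#' Penultimate-layer states
#'
#' The concatenated directional hidden states `[hf_t; hb_t]` (dimension 2H)
#' that feed the output projection; exported as an ensemble feature block.
#'
#' @param params A trained `birnn_params`.
#' @param tokens Character vector of token surfaces.
#' @param table An [embedding_table()].
#' @return 2H x T matrix.
#' @export
penultimate_states <- function(params, tokens, table) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  if (!length(tokens)) return(matrix(0, 2L * params$H, 0))
  forward_pass(params, embed_tokens(table, tokens))$states
}

#' Train toy skip-gram embeddings
#'
#' Skip-gram with negative sampling over a small corpus: for each
#' (center, context) pair within the window, the center vector is pushed
#' toward the context's output vector and away from sampled negatives.
#' Deterministic given the seed. Intended to stand in for large-corpus
#' pre-trained vectors at desk scale.
#'
#' @param sentences List of character vectors (tokenized sentences), or a
#'   character vector of raw texts (whitespace-tokenized after lower-casing).
#' @param D Embedding dimension.
#' @param window Context window radius.
#' @param epochs Passes over the pair list.
#' @param negative Negative samples per pair.
#' @param lr Learning rate.
#' @param seed RNG seed.
#' @return An [embedding_table()] over the corpus vocabulary; the OOV vector
#'   is a seeded random vector.
#' @export
train_toy_embeddings <- function(sentences, D = 16L, window = 2L,
                                 epochs = 5L, negative = 3L, lr = 0.05,
                                 seed = 1L) {
  if (D <= 0) stop("embedding dimension must be positive")
  if (is.character(sentences))
    sentences <- strsplit(tolower(sentences), "[[:space:]]+")
  sentences <- lapply(sentences, function(s) tolower(s[nzchar(s)]))
  vocab <- sort(unique(unlist(sentences, use.names = FALSE)))
  V <- length(vocab)
  if (!V) stop("empty corpus")
  counts <- table(factor(unlist(sentences, use.names = FALSE),
                         levels = vocab))
  neg_prob <- as.numeric(counts)^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  with_seed(seed, {
    Win <- matrix(stats::runif(D * V, -0.5, 0.5) / D, D, V)
    Wout <- matrix(0, D, V)
    # precompute center/context index pairs
    ctr <- integer(0); ctx <- integer(0)
    for (s in sentences) {
      ids <- match(s, vocab)
      T <- length(ids)
      for (t in seq_len(T)) {
        lo <- max(1L, t - window); hi <- min(T, t + window)
        js <- setdiff(lo:hi, t)
        ctr <- c(ctr, rep.int(ids[t], length(js)))
        ctx <- c(ctx, ids[js])
      }
    }
    npair <- length(ctr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(npair)
      negs <- matrix(sample.int(V, npair * negative, replace = TRUE,
                                prob = neg_prob), negative, npair)
      for (q in seq_len(npair)) {
        k <- ord[q]
        wi <- ctr[k]
        targets <- c(ctx[k], negs[, q])
        labels <- c(1, rep(0, negative))
        vin <- Win[, wi]
        outs <- Wout[, targets, drop = FALSE]
        p <- stats::plogis(as.numeric(crossprod(outs, vin)))
        gscale <- p - labels
        Win[, wi] <- vin - lr * as.numeric(outs %*% gscale)
        Wout[, targets] <- outs - lr * outer(vin, gscale)
      }
    }
    colnames(Win) <- vocab
    embedding_table(Win, oov = stats::runif(D, -0.08, 0.08))
  })
}
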