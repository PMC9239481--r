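#' Context encoder configuration
#'
#' Settings for the desk-scale trainable context encoder: an embedding table
#' followed by a bidirectional LSTM, optionally augmented with a
#' character-level bidirectional LSTM composed into each word representation
#' and a scaled dot-product self-attention layer over the hidden states. The
#' encoder fills the role a pretrained transformer plays at full scale; it
#' honours the same contract (one hidden vector per token) so heavier
#' encoders can be swapped in behind [wcrf].
#'
#' @param vocab_size number of word types (including the reserved UNK id 1).
#' @param embed_dim word embedding dimensionality; default 32.
#' @param hidden_dim LSTM hidden size per direction; default 32 (hidden
#'   states have `2 * hidden_dim` columns).
#' @param use_char add a character-level composition to each word embedding.
#' @param char_dim character LSTM hidden size per direction; default 16.
#' @param char_vocab_size number of character types (including UNK id 1).
#' @param use_attention apply self-attention after the BiLSTM.
#' @param dropout_rate dropout on hidden states during training, in `[0, 1)`;
#'   default 0.1.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(vocab_size, embed_dim = 32L, hidden_dim = 32L,
                           use_char = FALSE, char_dim = 16L,
                           char_vocab_size = 0L, use_attention = FALSE,
                           dropout_rate = 0.1, seed = 1L) {
  stopifnot(vocab_size >= 1L, embed_dim >= 1L, hidden_dim >= 1L,
            char_dim >= 1L, dropout_rate >= 0, dropout_rate < 1)
  if (use_char && char_vocab_size < 1L) {
    stop("use_char requires char_vocab_size >= 1")
  }
  structure(list(vocab_size = as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 use_char = isTRUE(use_char),
                 char_dim = as.integer(char_dim),
                 char_vocab_size = as.integer(char_vocab_size),
                 use_attention = isTRUE(use_attention),
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

runif_mat <- function(n, m) matrix(stats::runif(n * m, -0.25, 0.25), n, m)

init_lstm <- function(in_dim, H) {
  list(W = runif_mat(4L * H, in_dim), U = runif_mat(4L * H, H),
       b = numeric(4L * H))
}

# all trainable encoder parameters; embeddings uniform(-0.25, 0.25) as for
# out-of-vocabulary words
init_encoder_params <- function(config) {
  set.seed(config$seed)
  in_dim <- config$embed_dim + if (config$use_char) 2L * config$char_dim else 0L
  p <- list(E = runif_mat(config$vocab_size, config$embed_dim),
            fwd = init_lstm(in_dim, config$hidden_dim),
            bwd = init_lstm(in_dim, config$hidden_dim))
  if (config$use_char) {
    p$Ec <- runif_mat(config$char_vocab_size, config$char_dim)
    p$cfwd <- init_lstm(config$char_dim, config$char_dim)
    p$cbwd <- init_lstm(config$char_dim, config$char_dim)
  }
  p
}

sigm <- function(x) 1 / (1 + exp(-x))

# one-direction LSTM over X (N x d); returns hidden states and a cache for
# the backward pass
lstm_forward <- function(X, p) {
  N <- nrow(X); H <- ncol(p$U)
  XW <- X %*% t(p$W)                    # N x 4H
  hs <- matrix(0, N, H)
  cache <- vector("list", N)
  h <- numeric(H); cc <- numeric(H)
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  for (t in seq_len(N)) {
    z <- XW[t, ] + as.vector(p$U %*% h) + p$b
    i <- sigm(z[idx_i]); f <- sigm(z[idx_f])
    g <- tanh(z[idx_g]); o <- sigm(z[idx_o])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cc,
                       h_prev = h, tc = tc)
    cc <- c_new
    h <- h_new
    hs[t, ] <- h
  }
  list(h = hs, cache = cache, X = X)
}

# reverse-mode through lstm_forward; dH is N x H upstream gradient
lstm_backward <- function(fw, dH, p) {
  X <- fw$X
  N <- nrow(X); H <- ncol(dH)
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, nrow(p$U), ncol(p$U))
  db <- numeric(length(p$b))
  dX <- matrix(0, N, ncol(X))
  dh <- numeric(H); dc <- numeric(H)
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  for (t in N:1) {
    cc <- fw$cache[[t]]
    dh <- dh + dH[t, ]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc <- dc * cc$f                      # flows to c_{t-1}
    dz <- numeric(4L * H)
    dz[idx_i] <- di * cc$i * (1 - cc$i)
    dz[idx_f] <- df * cc$f * (1 - cc$f)
    dz[idx_g] <- dg * (1 - cc$g^2)
    dz[idx_o] <- do_ * cc$o * (1 - cc$o)
    dW <- dW + tcrossprod(dz, X[t, ])
    dU <- dU + tcrossprod(dz, cc$h_prev)
    db <- db + dz
    dX[t, ] <- as.vector(crossprod(p$W, dz))
    dh <- as.vector(crossprod(p$U, dz))
  }
  list(W = dW, U = dU, b = db, dX = dX)
}

bilstm_forward <- function(X, pf, pb) {
  N <- nrow(X)
  fw <- lstm_forward(X, pf)
  rv <- X[N:1, , drop = FALSE]
  bw <- lstm_forward(rv, pb)
  H <- cbind(fw$h, bw$h[N:1, , drop = FALSE])
  list(H = H, fw = fw, bw = bw)
}

bilstm_backward <- function(bi, dH, pf, pb) {
  N <- nrow(dH)
  Hd <- ncol(bi$fw$h)
  g_fw <- lstm_backward(bi$fw, dH[, 1:Hd, drop = FALSE], pf)
  g_bw <- lstm_backward(bi$bw,
                        dH[N:1, (Hd + 1):(2 * Hd), drop = FALSE], pb)
  dX <- g_fw$dX + g_bw$dX[N:1, , drop = FALSE]
  list(fwd = g_fw[c("W", "U", "b")], bwd = g_bw[c("W", "U", "b")], dX = dX)
}

#' Scaled dot-product self-attention over hidden states
#'
#' Aligns each token to its contexts: attention logits are the scaled inner
#' products `H H' / sqrt(D)`, each row is normalized by softmax, and the
#' output is the attention-weighted mixture of the input states, so the
#' output has the same shape as the input. A sequence of one token attends
#' only to itself and is returned unchanged.
#'
#' @param hidden numeric `N x D` matrix of hidden states.
#' @return An `N x D` matrix with attribute `"attention"` holding the
#'   `N x N` row-stochastic attention weight matrix.
#' @export
self_attention <- function(hidden) {
  hidden <- as.matrix(hidden)
  if (nrow(hidden) == 0L) stop("empty input")
  att <- attention_forward(hidden)
  structure(att$out, attention = att$Wt)
}

attention_forward <- function(H) {
  s <- sqrt(ncol(H))
  G <- tcrossprod(H) / s
  Wt <- row_softmax(G)
  list(out = Wt %*% H, Wt = Wt, H = H, s = s)
}

attention_backward <- function(att, dOut) {
  dWt <- tcrossprod(dOut, att$H)        # dOut %*% t(H)
  dH <- crossprod(att$Wt, dOut)         # t(Wt) %*% dOut
  # softmax rows
  dG <- att$Wt * (dWt - rowSums(dWt * att$Wt))
  dH <- dH + (dG + t(dG)) %*% att$H / att$s
  dH
}

# full encoder forward: ids -> embeddings (+ char composition) -> BiLSTM
# (-> attention) (-> dropout in training); returns hidden states + cache
encode_forward <- function(token_ids, params, config, char_ids = NULL,
                           train = FALSE) {
  token_ids <- as.integer(token_ids)
  if (any(token_ids < 1L | token_ids > config$vocab_size)) {
    stop("token id out of vocabulary (map unknown tokens to the UNK id)")
  }
  N <- length(token_ids)
  X <- params$E[token_ids, , drop = FALSE]
  char_caches <- NULL
  if (config$use_char) {
    if (is.null(char_ids)) stop("use_char encoder needs char_ids")
    char_caches <- vector("list", N)
    feats <- matrix(0, N, 2L * config$char_dim)
    for (t in seq_len(N)) {
      cid <- as.integer(char_ids[[t]])
      Xc <- params$Ec[cid, , drop = FALSE]
      bi <- bilstm_forward(Xc, params$cfwd, params$cbwd)
      # final forward state and final (position-1) backward state
      feats[t, ] <- c(bi$fw$h[length(cid), ], bi$bw$h[length(cid), ])
      char_caches[[t]] <- list(bi = bi, cid = cid, n = length(cid))
    }
    X <- cbind(X, feats)
  }
  bi <- bilstm_forward(X, params$fwd, params$bwd)
  H <- bi$H
  att <- NULL
  if (config$use_attention) {
    att <- attention_forward(H)
    H <- att$out
  }
  drop_mask <- NULL
  if (train && config$dropout_rate > 0) {
    keep <- 1 - config$dropout_rate
    drop_mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                        nrow(H), ncol(H))
    H <- H * drop_mask
  }
  list(H = H, bi = bi, att = att, drop_mask = drop_mask,
       token_ids = token_ids, char_caches = char_caches)
}

# reverse-mode through encode_forward; returns gradients shaped like params
encode_backward <- function(cache, dH, params, config) {
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  if (!is.null(cache$att)) dH <- attention_backward(cache$att, dH)
  g <- bilstm_backward(cache$bi, dH, params$fwd, params$bwd)
  grads <- list(E = matrix(0, nrow(params$E), ncol(params$E)),
                fwd = g$fwd, bwd = g$bwd)
  d <- config$embed_dim
  dXe <- g$dX[, 1:d, drop = FALSE]
  for (t in seq_along(cache$token_ids)) {
    id <- cache$token_ids[[t]]
    grads$E[id, ] <- grads$E[id, ] + dXe[t, ]
  }
  if (config$use_char) {
    grads$Ec <- matrix(0, nrow(params$Ec), ncol(params$Ec))
    zl <- function(p) list(W = p$W * 0, U = p$U * 0, b = p$b * 0)
    grads$cfwd <- zl(params$cfwd)
    grads$cbwd <- zl(params$cbwd)
    cd <- config$char_dim
    dFeat <- g$dX[, (d + 1):(d + 2L * cd), drop = FALSE]
    for (t in seq_along(cache$char_caches)) {
      cc <- cache$char_caches[[t]]
      # the word feature is (forward final state, backward final state); in
      # the combined original-order layout the backward final state sits in
      # row 1 of the second block
      dHc <- matrix(0, cc$n, cd)
      dHc_bwd <- matrix(0, cc$n, cd)
      dHc[cc$n, ] <- dFeat[t, 1:cd]
      dHc_bwd[1L, ] <- dFeat[t, (cd + 1):(2L * cd)]
      gc <- bilstm_backward(cc$bi, cbind(dHc, dHc_bwd), params$cfwd,
                            params$cbwd)
      add <- function(a, b) list(W = a$W + b$W, U = a$U + b$U, b = a$b + b$b)
      grads$cfwd <- add(grads$cfwd, gc$fwd)
      grads$cbwd <- add(grads$cbwd, gc$bwd)
      for (j in seq_len(cc$n)) {
        grads$Ec[cc$cid[[j]], ] <- grads$Ec[cc$cid[[j]], ] + gc$dX[j, ]
      }
    }
  }
  grads
}

#' Encode a token sequence into hidden states
#'
#' Runs the full encoder in evaluation mode (no dropout): embedding lookup,
#' optional character composition, bidirectional LSTM and optional
#' self-attention. Deterministic given the parameters; every output position
#' depends on the whole input through the two LSTM directions.
#'
#' @param token_ids integer vector of word ids in `1..vocab_size`.
#' @param params encoder parameter list (from the fitted model, or
#'   `init_encoder_params`).
#' @param config an [encoder_config].
#' @param char_ids optional list (one integer vector of character ids per
#'   token), required when `config$use_char` is set.
#' @return An `N x D` matrix of hidden states, `D = 2 * hidden_dim`.
#' @export
encode_tokens <- function(token_ids, params, config, char_ids = NULL) {
  encode_forward(token_ids, params, config, char_ids, train = FALSE)$H
}

#' Align word labels to subword pieces
#'
#' For tokenizers that split a word into several pieces (e.g. *depression*
#' into *de*, *##press*, *##ion*), the first piece inherits the word's tag
#' and the remaining pieces receive the sentinel `"[IGN]"`, which downstream
#' losses and metrics exclude. The number of non-ignored labels therefore
#' always equals the original word count.
#'
#' @param words character vector of words.
#' @param labels character vector of tags, same length.
#' @param subword_splits list with one character vector of pieces per word;
#'   every word must map to at least one piece.
#' @return A list with `subtokens` (character vector of all pieces in order)
#'   and `labels` (same length; original tag on first pieces, `"[IGN]"`
#'   elsewhere).
#' @examples
#' align_subword_labels("depression", "B-ADR",
#'                      list(c("de", "##press", "##ion")))
#' @export
align_subword_labels <- function(words, labels, subword_splits) {
  if (length(words) != length(labels) ||
      length(words) != length(subword_splits)) {
    stop("words, labels and subword_splits must have equal length")
  }
  sub_tokens <- character()
  sub_labels <- character()
  for (i in seq_along(words)) {
    pieces <- as.character(subword_splits[[i]])
    if (length(pieces) == 0L) stop("empty split for word ", deparse(words[[i]]))
    sub_tokens <- c(sub_tokens, pieces)
    sub_labels <- c(sub_labels, labels[[i]],
                    rep("[IGN]", length(pieces) - 1L))
  }
  list(subtokens = sub_tokens, labels = sub_labels)
}
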