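#' Fit a (weighted) CRF sequence tagger
#'
#' Trains an embedding + bidirectional LSTM context encoder with one of six
#' output heads on a labeled corpus by mini-batch gradient descent (Adam).
#' The default head is the class-weighted CRF loss: per-token negative log
#' posterior marginals from forward-backward, scaled by class weights so that
#' minority entity classes (e.g. ADR mentions at ~13% of tokens) are not
#' drowned out by the `O` majority. Alternatives are the standard CRF
#' negative log-likelihood and four independent-softmax baselines.
#'
#' @param corpus a non-empty [wcrf_corpus] of training sentences.
#' @param loss output head / objective: `"wcrf"` (class-weighted CRF, the
#'   default), `"crf"`, `"softmax"`, `"wsoftmax"`, `"focal"` or `"dice"`.
#' @param weight_strategy class-weighting rule for the weighted heads; see
#'   [compute_class_weights]. Ignored (forced uniform) for the unweighted
#'   heads.
#' @param encoder an [encoder_config], or `NULL` for the desk-scale default
#'   (embed 32, hidden 32 per direction, dropout 0.1) sized to the corpus
#'   vocabulary.
#' @param epochs number of passes over the corpus; default 20.
#' @param batch_size sentences per gradient step; default 16.
#' @param learning_rate Adam step size; default 1e-2, suited to the small
#'   randomly initialized encoder (a fine-tuned pretrained encoder would use
#'   a much smaller rate, e.g. 2e-5).
#' @param gamma focal-loss focusing exponent; default 2.
#' @param dice_eps dice-loss smoothing constant; default 1.
#' @param dev_split fraction of sentences held out for per-epoch monitoring
#'   (e.g. 0.2 for the usual 8:2 split); default 0 (train on everything).
#' @param seed integer seed governing initialization, shuffling and dropout;
#'   two runs with the same seed are identical.
#' @param verbose print per-epoch losses.
#' @return An object of class `wcrf`: the trained model state (all
#'   parameters, vocabulary, alphabet, class weights, configuration and
#'   per-epoch loss history), usable with [predict.wcrf], [summary.wcrf],
#'   [coef.wcrf], [plot.wcrf] and [simulate.wcrf].
#' @seealso [wcrf_evaluate] for approximate-match scoring of a fitted model.
#' @examples
#' corp <- generate_corpus(generator_config(n_sentences = 8, seed = 1))$corpus
#' m <- wcrf(corp, epochs = 2, verbose = FALSE)
#' predict(m, corp$sequences[[1]]$tokens)
#' @export
wcrf <- function(corpus,
                 loss = c("wcrf", "crf", "softmax", "wsoftmax", "focal",
                          "dice"),
                 weight_strategy = "balanced",
                 encoder = NULL,
                 epochs = 20L,
                 batch_size = 16L,
                 learning_rate = 1e-2,
                 gamma = 2,
                 dice_eps = 1,
                 dev_split = 0,
                 seed = 1L,
                 verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(inherits(corpus, "wcrf_corpus"), epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, dev_split >= 0, dev_split < 1)
  if (length(corpus$sequences) == 0L) stop("empty corpus")
  alphabet <- corpus$alphabet
  K <- alphabet$K

  vocab <- build_vocab(corpus)
  if (is.null(encoder)) {
    encoder <- encoder_config(vocab_size = length(vocab) + 1L, seed = seed)
  } else if (encoder$vocab_size < length(vocab) + 1L) {
    stop("encoder vocab_size too small for corpus vocabulary (need >= ",
         length(vocab) + 1L, ")")
  }

  weighted <- loss %in% c("wcrf", "wsoftmax")
  cw <- if (weighted) {
    compute_class_weights(class_token_counts(corpus), weight_strategy)
  } else {
    compute_class_weights(pmax(class_token_counts(corpus), 1L), "uniform")
  }
  w_tag <- tag_weights(cw, alphabet)

  set.seed(seed)
  params <- init_encoder_params(encoder)
  D <- 2L * encoder$hidden_dim
  params$W_out <- runif_mat(D, K)
  params$b_out <- numeric(K)
  params$A <- matrix(0, K + 2L, K + 2L)

  seqs <- corpus$sequences
  dev_seqs <- list()
  if (dev_split > 0 && length(seqs) >= 2L) {
    n_dev <- max(1L, floor(dev_split * length(seqs)))
    dev_idx <- sample(length(seqs), n_dev)
    dev_seqs <- seqs[dev_idx]
    seqs <- seqs[-dev_idx]
  }
  prep <- lapply(seqs, function(s) {
    list(ids = tokens_to_ids(s$tokens, vocab),
         y = tag_index(s$labels, alphabet),
         chars = if (encoder$use_char) tokens_to_char_ids(s$tokens, vocab)
                 else NULL)
  })

  skeleton <- params
  theta <- unlist(params, use.names = FALSE)
  m_adam <- numeric(length(theta))
  v_adam <- numeric(length(theta))
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        dev_loss = numeric())

  for (epoch in seq_len(epochs)) {
    ord <- sample(length(prep))
    epoch_loss <- 0
    batch_starts <- seq(1L, length(ord), by = batch_size)
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + batch_size - 1L, length(ord))]
      grad <- numeric(length(theta))
      batch_loss <- 0
      for (j in idx) {
        ex <- prep[[j]]
        r <- sentence_grad(ex, params, encoder, loss, w_tag, gamma, dice_eps,
                           train = TRUE)
        batch_loss <- batch_loss + r$loss
        grad <- grad + unlist(r$grads, use.names = FALSE)
      }
      if (!is.finite(batch_loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; try a smaller learning rate")
      }
      grad <- grad / length(idx)
      step <- step + 1L
      m_adam <- 0.9 * m_adam + 0.1 * grad
      v_adam <- 0.999 * v_adam + 0.001 * grad^2
      mhat <- m_adam / (1 - 0.9^step)
      vhat <- v_adam / (1 - 0.999^step)
      theta <- theta - learning_rate * mhat / (sqrt(vhat) + 1e-8)
      params <- utils::relist(theta, skeleton)
      epoch_loss <- epoch_loss + batch_loss
    }
    dev_loss <- NA_real_
    if (length(dev_seqs)) {
      dev_loss <- mean(vapply(dev_seqs, function(s) {
        ex <- list(ids = tokens_to_ids(s$tokens, vocab),
                   y = tag_index(s$labels, alphabet),
                   chars = if (encoder$use_char)
                             tokens_to_char_ids(s$tokens, vocab) else NULL)
        sentence_grad(ex, params, encoder, loss, w_tag, gamma, dice_eps,
                      train = FALSE)$loss
      }, 0))
    }
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = epoch_loss / length(prep),
                                dev_loss = dev_loss))
    if (verbose) {
      cat(sprintf("epoch %3d  train loss %.4f%s\n", epoch,
                  epoch_loss / length(prep),
                  if (is.na(dev_loss)) "" else sprintf("  dev loss %.4f",
                                                       dev_loss)))
    }
  }

  structure(list(params = params, encoder = encoder, vocab = vocab,
                 alphabet = alphabet, loss = loss,
                 class_weights = cw, tag_weights = w_tag,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, gamma = gamma,
                 dice_eps = dice_eps, seed = seed, history = history,
                 call = match.call()),
            class = "wcrf")
}

# loss + full parameter gradient for one sentence; grads ordered like params
sentence_grad <- function(ex, params, encoder, loss, w_tag, gamma, dice_eps,
                          train = FALSE) {
  K <- length(w_tag)
  cache <- encode_forward(ex$ids, params, encoder, ex$chars, train = train)
  H <- cache$H
  logits <- H %*% params$W_out + rep(params$b_out, each = nrow(H))
  uses_crf <- loss %in% c("wcrf", "crf")
  if (uses_crf) {
    pot <- potential_tables(logits, params$A)
    r <- if (loss == "wcrf") weighted_crf_grad(pot, ex$y, w_tag)
         else crf_nll_grad(pot, ex$y)
    d_logits <- r$d_emissions
    dA <- r$d_transitions
  } else {
    r <- switch(loss,
                softmax  = softmax_ce_grad(logits, ex$y, rep(1, K)),
                wsoftmax = softmax_ce_grad(logits, ex$y, w_tag),
                focal    = focal_softmax_grad(logits, ex$y, gamma),
                dice     = dice_softmax_grad(logits, ex$y, dice_eps))
    d_logits <- r$d_logits
    dA <- matrix(0, K + 2L, K + 2L)
  }
  dW_out <- crossprod(H, d_logits)
  db_out <- colSums(d_logits)
  dH <- d_logits %*% t(params$W_out)
  enc_grads <- encode_backward(cache, dH, params, encoder)
  grads <- enc_grads[intersect(names(params), names(enc_grads))]
  grads$W_out <- dW_out
  grads$b_out <- db_out
  grads$A <- dA
  grads <- grads[names(params)]
  list(loss = r$loss, grads = grads)
}

build_vocab <- function(corpus) {
  toks <- unlist(lapply(corpus$sequences, `[[`, "tokens"))
  types <- names(sort(table(toks), decreasing = TRUE))
  stats::setNames(seq_along(types) + 1L, types)  # id 1 reserved for UNK
}

tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- 1L  # UNK
  as.integer(ids)
}

tokens_to_char_ids <- function(tokens, vocab) {
  chars <- sort(unique(unlist(strsplit(names(vocab), ""))))
  cmap <- stats::setNames(seq_along(chars) + 1L, chars)
  lapply(strsplit(tokens, ""), function(cs) {
    ids <- unname(cmap[cs]); ids[is.na(ids)] <- 1L; as.integer(ids)
  })
}
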