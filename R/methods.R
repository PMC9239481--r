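#' @export
print.wcrf <- function(x, ...) {
  cat("Weighted-CRF sequence tagger\n")
  cat("  head:      ", x$loss, "\n")
  cat("  weighting: ", x$class_weights$strategy, "\n")
  cat("  alphabet:  ", paste(x$alphabet$tags, collapse = " "), "\n")
  cat("  vocab:     ", length(x$vocab), "types (+UNK)\n")
  cat("  encoder:    embed", x$encoder$embed_dim, "| hidden",
      x$encoder$hidden_dim, "x2",
      if (x$encoder$use_char) "| char" else "",
      if (x$encoder$use_attention) "| attention" else "", "\n")
  cat("  training:  ", x$epochs, "epochs, final loss",
      sprintf("%.4f", utils::tail(x$history$train_loss, 1L)), "\n")
  invisible(x)
}

#' @export
summary.wcrf <- function(object, ...) {
  structure(list(model = object), class = "summary.wcrf")
}

#' @export
print.summary.wcrf <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nClass weights:\n")
  print(round(m$class_weights$weights, 4))
  cat("\nLoss history (last 5 epochs):\n")
  print(utils::tail(m$history, 5L), row.names = FALSE)
  K <- m$alphabet$K
  tr <- m$params$A[seq_len(K), seq_len(K), drop = FALSE]
  dimnames(tr) <- list(from = m$alphabet$tags, to = m$alphabet$tags)
  cat("\nLearned tag-to-tag transition scores:\n")
  print(round(tr, 3))
  invisible(x)
}

#' Extract fitted CRF parameters
#'
#' Returns the interpretable parameters of a fitted tagger: the full
#' `(K + 2) x (K + 2)` transition score matrix (with the synthetic start row
#' and end column) and the per-class loss weights.
#'
#' @param object a fitted [wcrf] model.
#' @param ... unused.
#' @return A list with `transitions` (dimnamed matrix) and `class_weights`.
#' @export
coef.wcrf <- function(object, ...) {
  A <- object$params$A
  nm <- c(object$alphabet$tags, "<start>", "<end>")
  dimnames(A) <- list(from = nm, to = nm)
  list(transitions = A, class_weights = object$class_weights$weights)
}

#' Plot the training loss curve
#'
#' @param x a fitted [wcrf] model.
#' @param ... passed to [graphics::plot].
#' @export
plot.wcrf <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "mean loss per sentence",
                 main = paste0("wcrf training (", x$loss, " head)"), ...)
  if (any(!is.na(h$dev_loss))) {
    graphics::lines(h$epoch, h$dev_loss, type = "b", lty = 2)
    graphics::legend("topright", c("train", "dev"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

# emission logits for one token sequence under a fitted model (eval mode)
model_logits <- function(object, tokens) {
  ids <- tokens_to_ids(tokens, object$vocab)
  chars <- if (object$encoder$use_char) {
    tokens_to_char_ids(tokens, object$vocab)
  }
  H <- encode_tokens(ids, object$params, object$encoder, chars)
  H %*% object$params$W_out + rep(object$params$b_out, each = nrow(H))
}

# transition matrix with BIO-invalid transitions pushed to a large negative
# score, so Viterbi never emits I-X after anything but B-X/I-X
constrained_transitions <- function(A, alphabet, penalty = -1e4) {
  tags <- alphabet$tags
  K <- alphabet$K
  for (k in seq_len(K)) {
    if (tag_prefix(tags[[k]]) != "I") next
    cls <- tag_class(tags[[k]])
    ok_prev <- tag_prefix(tags) %in% c("B", "I") & tag_class(tags) == cls
    A[seq_len(K)[!ok_prev], k] <- penalty
    A[alphabet$start_index, k] <- penalty
  }
  A
}

model_potentials <- function(object, tokens, constrain = TRUE) {
  A <- object$params$A
  if (constrain) A <- constrained_transitions(A, object$alphabet)
  potential_tables(model_logits(object, tokens), A)
}

#' Predict label sequences
#'
#' Decodes tag sequences for new sentences. CRF heads use Viterbi decoding
#' over the learned transition scores; softmax heads take the per-position
#' argmax. With `constrain = TRUE` (default) BIO-invalid transitions are
#' barred at decode time, so CRF predictions never contain an `I-X`
#' continuation violation.
#'
#' @param object a fitted [wcrf] model.
#' @param newdata a [wcrf_corpus], a list of [labeled_sequence]s or character
#'   token vectors, or a single character vector of tokens.
#' @param type `"labels"` (default) for tag strings, `"marginals"` for the
#'   `N x K` posterior tag probabilities of each sentence (CRF heads: exact
#'   forward-backward marginals; softmax heads: row softmax).
#' @param constrain bar BIO-invalid transitions during CRF decoding.
#' @param ... unused.
#' @return For `type = "labels"`, a list of [labeled_sequence] objects
#'   (tokens with predicted tags); for a single token-vector input, one
#'   [labeled_sequence]. For `type = "marginals"`, a list of matrices.
#' @export
predict.wcrf <- function(object, newdata, type = c("labels", "marginals"),
                         constrain = TRUE, ...) {
  type <- match.arg(type)
  single <- is.character(newdata)
  token_lists <- newdata_tokens(newdata)
  uses_crf <- object$loss %in% c("wcrf", "crf")
  out <- lapply(token_lists, function(tokens) {
    if (length(tokens) == 0L) stop("cannot predict an empty sentence")
    if (uses_crf) {
      pot <- model_potentials(object, tokens, constrain)
      if (type == "marginals") return(posterior_marginals(pot))
      idx <- viterbi_decode(pot)
    } else {
      logits <- model_logits(object, tokens)
      if (type == "marginals") return(row_softmax(logits))
      idx <- apply(logits, 1L, which.max)
    }
    labeled_sequence(tokens, object$alphabet$tags[idx])
  })
  if (single) out[[1L]] else out
}

newdata_tokens <- function(newdata) {
  if (is.character(newdata)) return(list(newdata))
  if (inherits(newdata, "wcrf_corpus")) newdata <- newdata$sequences
  if (inherits(newdata, "labeled_sequence")) newdata <- list(newdata)
  lapply(newdata, function(s) {
    if (inherits(s, "labeled_sequence")) s$tokens else as.character(s)
  })
}

#' Log-likelihood of a corpus under a fitted CRF tagger
#'
#' @param object a fitted [wcrf] model with a CRF head.
#' @param corpus a [wcrf_corpus]; defaults to nothing (required).
#' @param ... unused.
#' @return An object of class `logLik`.
#' @export
logLik.wcrf <- function(object, corpus, ...) {
  if (!object$loss %in% c("wcrf", "crf")) {
    stop("log-likelihood is defined for CRF heads only")
  }
  ll <- sum(vapply(corpus$sequences, function(s) {
    pot <- model_potentials(object, s$tokens, constrain = FALSE)
    -crf_nll(pot, tag_index(s$labels, object$alphabet))
  }, 0))
  structure(ll, df = length(unlist(object$params, use.names = FALSE)),
            class = "logLik")
}

#' Sample label sequences from the fitted CRF posterior
#'
#' Draws labelings from the model's conditional distribution `p(y | X)` by
#' forward filtering / backward sampling, a direct probe of the uncertainty
#' the CRF assigns to a sentence.
#'
#' @param object a fitted [wcrf] model with a CRF head.
#' @param nsim number of samples; default 1.
#' @param seed optional integer seed.
#' @param tokens character vector of tokens to condition on.
#' @param ... unused.
#' @return A list of `nsim` [labeled_sequence] objects.
#' @export
simulate.wcrf <- function(object, nsim = 1, seed = NULL, tokens, ...) {
  if (!object$loss %in% c("wcrf", "crf")) {
    stop("simulation is defined for CRF heads only")
  }
  if (!is.null(seed)) set.seed(seed)
  pot <- model_potentials(object, tokens, constrain = FALSE)
  alpha <- forward_messages(pot)
  K <- pot$K
  A <- pot$transitions[seq_len(K), seq_len(K), drop = FALSE]
  aend <- pot$transitions[seq_len(K), pot$end]
  N <- pot$N
  replicate(nsim, simplify = FALSE, {
    y <- integer(N)
    p_last <- exp(alpha[N, ] + aend - log_sum_exp(alpha[N, ] + aend))
    y[N] <- sample.int(K, 1L, prob = p_last)
    if (N > 1L) {
      for (i in (N - 1L):1L) {
        lw <- alpha[i, ] + A[, y[i + 1L]]
        y[i] <- sample.int(K, 1L, prob = exp(lw - log_sum_exp(lw)))
      }
    }
    labeled_sequence(tokens, object$alphabet$tags[y])
  })
}

#' Evaluate a fitted tagger on a labeled corpus
#'
#' Predicts the corpus and scores each entity class with the
#' approximate-match (or strict) span metrics of [approximate_match_counts]
#' and [precision_recall_f1].
#'
#' @param object a fitted [wcrf] model.
#' @param corpus a labeled [wcrf_corpus].
#' @param match `"approx"` (partial span overlap counts as correct, the
#'   standard ADR convention) or `"strict"` (exact span match).
#' @param constrain bar BIO-invalid transitions during decoding.
#' @return A data frame with one row per entity class: `class`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`.
#' @export
wcrf_evaluate <- function(object, corpus, match = c("approx", "strict"),
                          constrain = TRUE) {
  match <- match.arg(match)
  preds <- predict(object, corpus, constrain = constrain)
  classes <- corpus$alphabet$classes
  rows <- lapply(classes, function(cl) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(preds)) {
      mc <- approximate_match_counts(corpus$sequences[[i]]$labels,
                                     preds[[i]]$labels, cl, match = match)
      tp <- tp + mc$tp; fp <- fp + mc$fp; fn <- fn + mc$fn
    }
    prf <- precision_recall_f1(list(tp = tp, fp = fp, fn = fn))
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Save / load a fitted model
#'
#' Lossless round-trip of the full model state: reloading and predicting
#' yields bitwise-identical output.
#'
#' @param object a fitted [wcrf] model.
#' @param path file path.
#' @return `wcrf_load` returns the model; `wcrf_save` returns `path`
#'   invisibly.
#' @export
wcrf_save <- function(object, path) {
  stopifnot(inherits(object, "wcrf"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname wcrf_save
#' @export
wcrf_load <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "wcrf")) stop("file does not contain a wcrf model")
  object
}
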